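#' Null rejection rate of the burden GLM on simulated counts
#'
#' Simulates cohorts in which per-sample SEV counts follow one common
#' Poisson distribution in both groups (with random sex and age) and
#' measures how often [burden_test()] declares a group difference — the
#' type-I error of the burden comparison at threshold `alpha`.
#'
#' @param n_sim number of simulated cohorts.
#' @param n_cases,n_controls group sizes.
#' @param mean_count common Poisson mean of the counts.
#' @param alpha nominal significance threshold.
#' @param seed integer seed.
#' @return rejection fraction across the `n_sim` cohorts.
#' @export
burden_null_rejection_rate <- function(n_sim = 200L, n_cases = 20L,
                                       n_controls = 20L, mean_count = 10,
                                       alpha = 0.05, seed = 1L) {
  with_seed(seed, {
    mean(vapply(seq_len(n_sim), function(i) {
      ns <- n_cases + n_controls
      sheet <- data.frame(
        sample_id = sprintf("S%03d", seq_len(ns)),
        group = rep(c("case", "control"), c(n_cases, n_controls)),
        sex = sample(c("F", "M"), ns, replace = TRUE),
        age = rlnorm(ns, log(10), 0.6),
        stringsAsFactors = FALSE)
      counts <- rpois(ns, mean_count)
      names(counts) <- sheet$sample_id
      res <- tryCatch(burden_test(counts, sheet, alpha = alpha),
                      error = function(e) NULL)
      !is.null(res) && res$p_value < alpha
    }, logical(1)))
  })
}

#' Power of the burden GLM at a fixed effect size
#'
#' Simulates cohorts where case counts are Poisson with `mean_case` and
#' control counts Poisson with `mean_control`, and measures how often the
#' burden test rejects at `alpha`.
#'
#' @inheritParams burden_null_rejection_rate
#' @param mean_case,mean_control group-specific Poisson means.
#' @return rejection fraction.
#' @export
burden_power <- function(n_sim = 100L, n_cases = 20L, n_controls = 20L,
                         mean_case = 30, mean_control = 10,
                         alpha = 0.01, seed = 1L) {
  with_seed(seed, {
    mean(vapply(seq_len(n_sim), function(i) {
      ns <- n_cases + n_controls
      sheet <- data.frame(
        sample_id = sprintf("S%03d", seq_len(ns)),
        group = rep(c("case", "control"), c(n_cases, n_controls)),
        sex = sample(c("F", "M"), ns, replace = TRUE),
        age = rlnorm(ns, log(10), 0.6),
        stringsAsFactors = FALSE)
      counts <- c(rpois(n_cases, mean_case), rpois(n_controls, mean_control))
      names(counts) <- sheet$sample_id
      res <- tryCatch(burden_test(counts, sheet, alpha = alpha),
                      error = function(e) NULL)
      !is.null(res) && res$group_coefficient > 0 && res$p_value < alpha
    }, logical(1)))
  })
}

#' Full-chain null rejection rate on synthetic cohorts
#'
#' Generates uninjected cohorts (cases and controls drawn from identical
#' settings), runs reference-range construction and SEV detection, and
#' tests the raw SEV burden between the groups. Since there is no true
#' group effect, the rejection fraction estimates the whole chain's
#' type-I error, including any non-exchangeability introduced by building
#' the reference from the controls themselves. That in-sample effect is
#' material for small reference panels (each control partly masks its own
#' outliers in the estimated fences) and negligible at the default
#' 48-control reference, which matches the size this analysis is designed
#' around.
#'
#' @inheritParams burden_null_rejection_rate
#' @param n_probes probes per simulated cohort.
#' @return rejection fraction.
#' @export
sev_chain_null_rejection_rate <- function(n_sim = 200L, n_probes = 2000L,
                                          n_cases = 16L, n_controls = 48L,
                                          alpha = 0.05, seed = 1L) {
  with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n_sim)
    mean(vapply(seq_len(n_sim), function(i) {
      mf <- generate_manifest(n_probes, 2L, 60L, seed = seeds[i])
      ch <- generate_cohort(mf, n_cases, n_controls, seed = seeds[i])
      ranges <- reference_ranges(
        ch$beta[, ch$sheet$sample_id[ch$sheet$group == "control"], drop = FALSE])
      sevs <- detect_sevs(ch$beta, ranges)
      counts <- table(factor(sevs$sample_id, levels = ch$sheet$sample_id))
      cv <- as.numeric(counts)
      names(cv) <- names(counts)
      res <- tryCatch(burden_test(cv, ch$sheet, alpha = alpha),
                      error = function(e) NULL)
      !is.null(res) && res$p_value < alpha
    }, logical(1)))
  })
}

#' Recovery of injected deregulated regions
#'
#' The pilot experiment behind the pipeline's sensitivity floor: simulate
#' cohorts, inject one contiguous gene region (and optionally isolated
#' single-probe SEVs) into case samples at a fixed shift beyond the control
#' fences, run the full pipeline, and record (a) whether the injected
#' region is recovered as a gene locus with the matching direction and (b)
#' whether any injected isolated SEV ends up inside a called locus (it
#' never should: isolated events are either discarded by the enrichment
#' scan or dropped as single-variant loci).
#'
#' @param n_sim number of simulated cohorts.
#' @param n_probes probes per cohort.
#' @param n_cases,n_controls group sizes.
#' @param region_length probes per injected region.
#' @param n_isolated isolated SEVs injected per cohort.
#' @param shift injection distance beyond the fence.
#' @param seed integer seed.
#' @return list: `region_recovery` (fraction of simulations whose injected
#'   region is called with correct direction), `singleton_locus_rate`
#'   (fraction where an isolated injection contaminated a locus), `n_sim`.
#' @export
region_recovery_sim <- function(n_sim = 100L, n_probes = 2000L,
                                n_cases = 8L, n_controls = 24L,
                                region_length = 4L, n_isolated = 2L,
                                shift = 0.15, seed = 1L) {
  with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n_sim)
    hit <- logical(n_sim)
    singleton <- logical(n_sim)
    for (i in seq_len(n_sim)) {
      mf <- generate_manifest(n_probes, 2L, 60L, seed = seeds[i])
      ch <- generate_cohort(mf, n_cases, n_controls, seed = seeds[i])
      inj <- inject_epivariants(ch$beta, mf, ch$sheet,
                                n_isolated = n_isolated, n_regions = 1L,
                                region_length = region_length,
                                direction_mix = 0.5, shift = shift,
                                seed = seeds[i])
      pip <- run_sev_pipeline(inj$beta, mf, ch$sheet,
                              detection_p = ch$detection_p,
                              bead_counts = ch$bead_counts)
      tr <- inj$truth$injected_regions
      hit[i] <- any(pip$loci$sample_id == tr$sample_id[1] &
                    pip$loci$gene == tr$gene[1] &
                    pip$loci$direction == tr$direction[1])
      if (nrow(inj$truth$injected_sevs) > 0 && nrow(pip$loci) > 0) {
        locus_probes <- unlist(strsplit(pip$loci$probe_ids, ";", fixed = TRUE))
        singleton[i] <- any(inj$truth$injected_sevs$probe_id %in% locus_probes)
      }
    }
    list(region_recovery = mean(hit),
         singleton_locus_rate = mean(singleton),
         n_sim = n_sim)
  })
}
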