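#' Generate a synthetic methylation cohort
#'
#' Simulates a probe-by-sample beta-value matrix with the marginal structure
#' typical of 450K blood data: a strongly bimodal per-probe baseline (most
#' probes near-fully methylated or near-fully unmethylated, a minority
#' intermediate), tight Gaussian technical noise around the baseline, and a
#' sparse background of isolated extreme outliers — the stochastic
#' epigenetic variation the downstream fence test is designed to catch.
#' Detection p-value and bead-count layers are emitted alongside so the
#' QC filter has realistic inputs, and a sample sheet assigns group, sex
#' and age to every column.
#'
#' The per-probe baseline is drawn from a three-component mixture with
#' weights 0.4/0.4/0.2 and modes 0.85 / 0.10 / 0.50 (jittered, sd 0.04).
#' Every sample then observes baseline + N(0, `noise_sd`) clipped to [0, 1].
#' Independently, each (probe, sample) cell becomes an isolated outlier with
#' probability `outlier_rate`, displaced by Uniform(0.15, 0.45) in a random
#' direction — the same rate in cases and controls, so an uninjected cohort
#' is a null cohort. Ages are log-normal with medians 6 years (cases) and
#' 12.9 years (controls), emulating a paediatric case series with somewhat
#' older controls.
#'
#' @param manifest probe manifest from [generate_manifest()] (or any
#'   data.frame with a `probe_id` column).
#' @param n_cases,n_controls positive group sizes (default 41 cases vs
#'   48 controls).
#' @param noise_sd technical noise sd on the beta scale (>= 0).
#' @param outlier_rate per-cell probability of an isolated extreme outlier.
#' @param det_fail_rate per-cell probability of a failed detection p-value
#'   (> 0.01); remaining cells get p-values well below 0.01.
#' @param low_bead_rate per-cell probability of a bead count < 3.
#' @param seed integer seed.
#'
#' @return list with elements `beta` (matrix, probes x samples),
#'   `sheet` (data.frame: `sample_id`, `group`, `sex`, `age`),
#'   `detection_p` and `bead_counts` (matrices matching `beta`).
#' @export
#' @examples
#' mf <- generate_manifest(500, 2, 20, seed = 1)
#' ch <- generate_cohort(mf, n_cases = 5, n_controls = 8, seed = 1)
#' dim(ch$beta)
generate_cohort <- function(manifest,
                            n_cases = 41L,
                            n_controls = 48L,
                            noise_sd = 0.03,
                            outlier_rate = 1e-3,
                            det_fail_rate = 5e-4,
                            low_bead_rate = 5e-4,
                            seed = 1L) {
  if (!is.data.frame(manifest) || nrow(manifest) == 0L) {
    stop("`manifest` must be a non-empty data.frame", call. = FALSE)
  }
  n_cases <- assert_count(n_cases, "n_cases")
  n_controls <- assert_count(n_controls, "n_controls")
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be non-negative", call. = FALSE)
  }
  np <- nrow(manifest)
  ns <- n_cases + n_controls
  sample_id <- c(sprintf("CASE%02d", seq_len(n_cases)),
                 sprintf("CTRL%02d", seq_len(n_controls)))

  with_seed(seed, {
    comp <- sample.int(3L, np, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    mode <- c(0.85, 0.10, 0.50)[comp]
    baseline <- clip01(pmin(pmax(rnorm(np, mode, 0.04), 0.02), 0.98))

    beta <- matrix(baseline, nrow = np, ncol = ns) +
      matrix(rnorm(np * ns, 0, noise_sd), nrow = np)
    # sparse isolated extreme outliers, same rate in both groups
    n_out <- rbinom(1L, np * ns, outlier_rate)
    if (n_out > 0) {
      idx <- sample.int(np * ns, n_out)
      shift <- runif(n_out, 0.15, 0.45) * sample(c(-1, 1), n_out, replace = TRUE)
      beta[idx] <- beta[idx] + shift
    }
    beta <- clip01(beta)
    dimnames(beta) <- list(manifest$probe_id, sample_id)

    detection_p <- matrix(runif(np * ns, 0, 0.005), nrow = np,
                          dimnames = dimnames(beta))
    n_fail <- rbinom(1L, np * ns, det_fail_rate)
    if (n_fail > 0) {
      idx <- sample.int(np * ns, n_fail)
      detection_p[idx] <- runif(n_fail, 0.011, 0.10)
    }

    bead_counts <- matrix(3L + rpois(np * ns, 11), nrow = np,
                          dimnames = dimnames(beta))
    n_low <- rbinom(1L, np * ns, low_bead_rate)
    if (n_low > 0) {
      idx <- sample.int(np * ns, n_low)
      bead_counts[idx] <- sample(1:2, n_low, replace = TRUE)
    }

    sheet <- data.frame(
      sample_id = sample_id,
      group = rep(c("case", "control"), c(n_cases, n_controls)),
      sex = sample(c("F", "M"), ns, replace = TRUE),
      age = c(rlnorm(n_cases, log(6), 0.9), rlnorm(n_controls, log(12.9), 0.7)),
      stringsAsFactors = FALSE
    )

    list(beta = beta, sheet = sheet, detection_p = detection_p,
         bead_counts = bead_counts)
  })
}

#' Inject known epivariants into a synthetic cohort
#'
#' Plants ground-truth signal in case samples of a generated cohort:
#' isolated single-probe SEVs and contiguous multi-probe deregulated gene
#' regions. Injection magnitude is defined relative to the control-derived
#' Tukey fences, so every injected value is an SEV by construction: a
#' hyper-methylation event is set to `upper fence + shift` (clipped to 1),
#' a hypo-methylation event to `lower fence - shift` (clipped to 0).
#'
#' Targets are chosen only where the injection can take effect: region
#' targets are runs of `region_length` consecutive probes of one gene whose
#' fences leave room for the shift in the chosen direction; isolated targets
#' are intergenic probes (so an isolated event can never form a gene locus,
#' making the truth record unambiguous for recovery experiments). All
#' targets lie in case samples.
#'
#' @param beta probe x sample beta matrix (named dims).
#' @param manifest probe manifest covering all rows of `beta`.
#' @param sheet sample sheet identifying case and control columns.
#' @param n_isolated number of isolated single-probe SEVs to inject.
#' @param n_regions number of contiguous gene regions to inject.
#' @param region_length probes per injected region (>= 2).
#' @param direction_mix probability that an injected event is
#'   hyper-methylated (the rest are hypo-methylated).
#' @param shift distance beyond the violated fence, beta-scale.
#' @param k fence multiplier used to compute the target fences.
#' @param seed integer seed.
#'
#' @return list with `beta` (modified matrix) and `truth`, itself a list:
#'   `injected_sevs` (data.frame `sample_id`, `probe_id`, `direction`),
#'   `injected_regions` (data.frame `sample_id`, `gene`, `probe_ids`
#'   (`;`-joined), `direction`) and `seed`.
#' @export
inject_epivariants <- function(beta, manifest, sheet,
                               n_isolated = 0L,
                               n_regions = 0L,
                               region_length = 5L,
                               direction_mix = 0.5,
                               shift = 0.1,
                               k = 3,
                               seed = 1L) {
  assert_beta_matrix(beta)
  n_isolated <- assert_count(n_isolated, "n_isolated", min = 0L)
  n_regions <- assert_count(n_regions, "n_regions", min = 0L)
  if (n_regions > 0L) region_length <- assert_count(region_length, "region_length", min = 2L)
  stopifnot(shift > 0, direction_mix >= 0, direction_mix <= 1)

  empty_truth <- list(
    injected_sevs = data.frame(sample_id = character(), probe_id = character(),
                               direction = character(), stringsAsFactors = FALSE),
    injected_regions = data.frame(sample_id = character(), gene = character(),
                                  probe_ids = character(), direction = character(),
                                  stringsAsFactors = FALSE),
    seed = as.integer(seed)
  )
  if (n_isolated == 0L && n_regions == 0L) {
    return(list(beta = beta, truth = empty_truth))
  }

  case_ids <- sheet$sample_id[sheet$group == "case"]
  control_ids <- sheet$sample_id[sheet$group == "control"]
  if (length(case_ids) == 0L || length(control_ids) == 0L) {
    stop("sheet must contain both case and control samples", call. = FALSE)
  }
  mf <- manifest[manifest$probe_id %in% rownames(beta), , drop = FALSE]
  mf <- mf[manifest_order(mf), , drop = FALSE]

  ranges <- reference_ranges(beta[mf$probe_id, control_ids, drop = FALSE], k = k)

  with_seed(seed, {
    truth_sevs <- empty_truth$injected_sevs
    truth_regions <- empty_truth$injected_regions

    # candidate region targets: runs of consecutive same-gene probes whose
    # fences admit the shift in a given direction
    if (n_regions > 0L) {
      ok_hyper <- ranges$upper < 1 - 1e-9
      ok_hypo <- ranges$lower > 1e-9
      runs <- rle(mf$gene)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      candidates <- list()
      for (r in which(runs$values != "" & runs$lengths >= region_length)) {
        for (s in starts[r]:(ends[r] - region_length + 1L)) {
          idx <- s:(s + region_length - 1L)
          dirs <- c(if (all(ok_hyper[idx])) "hyper",
                    if (all(ok_hypo[idx])) "hypo")
          if (length(dirs)) {
            candidates[[length(candidates) + 1L]] <-
              list(idx = idx, gene = runs$values[r], dirs = dirs)
          }
        }
      }
      if (length(candidates) < n_regions) {
        stop("requested region injections exceed available gene runs", call. = FALSE)
      }
      picked_genes <- character(0)
      pool <- sample(candidates)
      done <- 0L
      for (cand in pool) {
        if (done >= n_regions) break
        if (cand$gene %in% picked_genes) next
        want <- if (runif(1) < direction_mix) "hyper" else "hypo"
        dir <- if (want %in% cand$dirs) want else cand$dirs[1]
        smp <- sample(case_ids, 1L)
        pids <- mf$probe_id[cand$idx]
        val <- if (dir == "hyper") {
          clip01(ranges$upper[cand$idx] + shift)
        } else {
          clip01(ranges$lower[cand$idx] - shift)
        }
        beta[pids, smp] <- val
        truth_regions <- rbind(truth_regions, data.frame(
          sample_id = smp, gene = cand$gene,
          probe_ids = paste(pids, collapse = ";"),
          direction = dir, stringsAsFactors = FALSE))
        picked_genes <- c(picked_genes, cand$gene)
        done <- done + 1L
      }
      if (done < n_regions) {
        stop("requested region injections exceed available gene runs", call. = FALSE)
      }
    }

    if (n_isolated > 0L) {
      inter <- which(mf$gene == "")
      dir_iso <- ifelse(runif(n_isolated) < direction_mix, "hyper", "hypo")
      # choose distinct intergenic probes across all isolated injections
      ok_hyper <- intersect(inter, which(ranges$upper < 1 - 1e-9))
      ok_hypo <- intersect(inter, which(ranges$lower > 1e-9))
      used <- integer(0)
      for (i in seq_len(n_isolated)) {
        pool <- setdiff(if (dir_iso[i] == "hyper") ok_hyper else ok_hypo, used)
        if (length(pool) == 0L) {
          stop("requested isolated injections exceed available intergenic probes",
               call. = FALSE)
        }
        j <- if (length(pool) == 1L) pool else sample(pool, 1L)
        used <- c(used, j)
        smp <- sample(case_ids, 1L)
        val <- if (dir_iso[i] == "hyper") clip01(ranges$upper[j] + shift)
               else clip01(ranges$lower[j] - shift)
        beta[mf$probe_id[j], smp] <- val
        truth_sevs <- rbind(truth_sevs, data.frame(
          sample_id = smp, probe_id = mf$probe_id[j],
          direction = dir_iso[i], stringsAsFactors = FALSE))
      }
    }

    list(beta = beta,
         truth = list(injected_sevs = truth_sevs,
                      injected_regions = truth_regions,
                      seed = as.integer(seed)))
  })
}
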