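#' Run the full single-case SEV pipeline
#'
#' Wires the whole chain together on one cohort: probe QC filtering,
#' quantile normalization, control reference ranges, SEV detection in every
#' sample, the sliding-window enrichment scan (cases and controls alike),
#' subtraction of the control retained-SEV union from the case profiles,
#' gene-locus calling, shared-gene tables and burden tests on both raw and
#' retained SEV counts.
#'
#' @param beta probe x sample beta matrix.
#' @param manifest probe manifest covering all probes.
#' @param sheet sample sheet assigning `case`/`control`, `sex`, `age`.
#' @param detection_p,bead_counts optional QC matrices (see
#'   [filter_probes()]); `NULL` skips the corresponding rule.
#' @param k fence multiplier (default 3).
#' @param window sliding-window size (odd, default 11).
#' @param alpha window significance threshold (default 0.05).
#' @param normalize quantile-normalize after QC (default TRUE).
#' @param min_controls minimum controls for reference ranges.
#'
#' @return list of class `sev_pipeline` with elements `qc_report`,
#'   `universe` (retained probe ids in manifest order), `ranges`, `sevs`
#'   (all samples), `scan`, `retained` (all samples), `case_retained`
#'   (after control subtraction), `control_retained`, `loci`,
#'   `shared_hyper`, `shared_hypo`, `burden_raw`, `burden_retained`
#'   (burden tests are `NULL` when the counts are degenerate, e.g. all
#'   zero), and `params`.
#' @export
run_sev_pipeline <- function(beta, manifest, sheet,
                             detection_p = NULL, bead_counts = NULL,
                             k = 3, window = 11L, alpha = 0.05,
                             normalize = TRUE, min_controls = 4L) {
  qc <- filter_probes(beta, detection_p, bead_counts, manifest)
  b <- qc$beta
  if (normalize && ncol(b) > 1L) b <- quantile_normalize(b)

  control_ids <- sheet$sample_id[sheet$group == "control"]
  case_ids <- sheet$sample_id[sheet$group == "case"]
  ranges <- reference_ranges(b[, control_ids, drop = FALSE], k = k,
                             min_controls = min_controls)
  sevs <- detect_sevs(b, ranges)
  universe <- rownames(b)
  scan <- sliding_window_scan(sevs, manifest, universe, n = window, alpha = alpha)
  retained <- retained_sevs(scan, sevs)

  control_retained <- retained[retained$sample_id %in% control_ids, , drop = FALSE]
  case_retained <- retained[retained$sample_id %in% case_ids, , drop = FALSE]
  case_subtracted <- subtract_control_profile(case_retained, control_retained)

  loci <- call_gene_loci(case_subtracted, manifest)

  count_per_sample <- function(calls) {
    cnt <- table(factor(calls$sample_id, levels = sheet$sample_id))
    out <- as.numeric(cnt)
    names(out) <- names(cnt)
    out
  }
  try_burden <- function(counts) {
    tryCatch(burden_test(counts, sheet), error = function(e) NULL)
  }

  structure(list(
    qc_report = qc$report,
    universe = universe,
    ranges = ranges,
    sevs = sevs,
    scan = scan,
    retained = retained,
    case_retained = case_subtracted,
    control_retained = control_retained,
    loci = loci,
    shared_hyper = shared_gene_table(loci, "hyper"),
    shared_hypo = shared_gene_table(loci, "hypo"),
    burden_raw = try_burden(count_per_sample(sevs)),
    burden_retained = try_burden(count_per_sample(retained)),
    params = list(k = k, window = window, alpha = alpha,
                  normalize = normalize)
  ), class = "sev_pipeline")
}

#' @export
print.sev_pipeline <- function(x, ...) {
  cat("SEV pipeline result\n")
  cat(sprintf("  universe: %d probes retained of %d (saturated fraction %.3f)\n",
              length(x$universe), x$qc_report$n_input,
              sev_saturation(x$ranges)))
  cat(sprintf("  SEV calls: %d; retained after enrichment: %d\n",
              nrow(x$sevs), nrow(x$retained)))
  cat(sprintf("  gene loci (cases, after control subtraction): %d\n",
              nrow(x$loci)))
  if (!is.null(x$burden_raw)) {
    cat(sprintf("  raw-burden case effect p = %.3g\n", x$burden_raw$p_value))
  }
  invisible(x)
}
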