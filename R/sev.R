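#' Per-probe reference ranges from control samples
#'
#' Builds the SEV decision boundary for every probe from the methylation
#' profiles of healthy controls: Tukey fences at
#' `lower = Q1 - k * IQR` and `upper = Q3 + k * IQR`, with `IQR = Q3 - Q1`
#' and `k = 3` by default ("extreme" outlier fences). Quartiles use linear
#' interpolation between order statistics (R quantile type 7) unless
#' another type is requested.
#'
#' Fences may fall outside [0, 1]; when `upper >= 1` and `lower <= 0` the
#' probe is saturated and can never yield an SEV (see [sev_saturation()]).
#' A degenerate spread (IQR = 0) collapses both fences onto the quartiles;
#' `min_halfwidth` optionally enforces a minimal fence half-width around the
#' median for such probes (default 0: faithful to the formula).
#'
#' @param control_beta probe x control beta matrix.
#' @param k fence multiplier (default 3).
#' @param min_controls minimum number of control samples required.
#' @param quartile_type quantile algorithm type (see [stats::quantile()]).
#' @param min_halfwidth optional minimal fence half-width.
#'
#' @return data.frame with one row per probe: `probe_id`, `q1`, `median`,
#'   `q3`, `iqr`, `lower`, `upper`, `k`.
#' @export
#' @examples
#' m <- matrix(c(0.10, 0.12, 0.14, 0.16, 0.18), nrow = 1,
#'             dimnames = list("cg1", paste0("c", 1:5)))
#' reference_ranges(m)  # q1 0.12, q3 0.16, lower 0.00, upper 0.28
reference_ranges <- function(control_beta, k = 3, min_controls = 4L,
                             quartile_type = 7L, min_halfwidth = 0) {
  assert_beta_matrix(control_beta)
  if (ncol(control_beta) < min_controls) {
    stop(sprintf("reference ranges need >= %d controls, got %d",
                 min_controls, ncol(control_beta)), call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || k < 0) {
    stop("`k` must be a single non-negative number", call. = FALSE)
  }
  qs <- apply(control_beta, 1L, quantile, probs = c(0.25, 0.5, 0.75),
              type = quartile_type, names = FALSE, na.rm = TRUE)
  q1 <- qs[1L, ]
  med <- qs[2L, ]
  q3 <- qs[3L, ]
  iqr <- q3 - q1
  lower <- q1 - k * iqr
  upper <- q3 + k * iqr
  if (min_halfwidth > 0) {
    lower <- pmin(lower, med - min_halfwidth)
    upper <- pmax(upper, med + min_halfwidth)
  }
  data.frame(probe_id = rownames(control_beta),
             q1 = q1, median = med, q3 = q3, iqr = iqr,
             lower = lower, upper = upper, k = k,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fraction of saturated probes
#'
#' A probe whose fences span the whole beta scale (`upper >= 1` and
#' `lower <= 0`) can never yield an SEV in any sample; reporting this
#' fraction tells how much of the array is effectively blind to the test.
#'
#' @param ranges reference ranges from [reference_ranges()].
#' @return fraction of probes with `upper >= 1 & lower <= 0`.
#' @export
sev_saturation <- function(ranges) {
  mean(ranges$upper >= 1 & ranges$lower <= 0)
}

#' Detect Stochastic Epigenetic Variants
#'
#' Calls an SEV wherever a sample's beta value falls strictly outside the
#' probe's reference fences: `beta > upper` is hyper-methylated,
#' `beta < lower` hypo-methylated (equivalently, on the far side of the
#' control median). Values exactly on a fence are not outliers.
#'
#' @param beta probe x sample beta matrix (cases and/or controls).
#' @param ranges reference ranges covering every probe of `beta`.
#' @param samples sample ids to scan (default: all columns).
#'
#' @return data.frame of calls: `sample_id`, `probe_id`, `direction`
#'   (`"hyper"`/`"hypo"`), `beta`, `excess` (distance beyond the violated
#'   fence, > 0). Carries the saturated-probe fraction as attribute
#'   `saturated_frac`.
#' @export
detect_sevs <- function(beta, ranges, samples = NULL) {
  assert_beta_matrix(beta)
  if (is.null(samples)) samples <- colnames(beta)
  stopifnot(all(samples %in% colnames(beta)))
  ri <- match(rownames(beta), ranges$probe_id)
  if (anyNA(ri)) {
    stop(sprintf("%d probes in `beta` have no reference range", sum(is.na(ri))),
         call. = FALSE)
  }
  upper <- ranges$upper[ri]
  lower <- ranges$lower[ri]

  calls <- lapply(samples, function(s) {
    v <- beta[, s]
    hyper <- which(v > upper)
    hypo <- which(v < lower)
    data.frame(
      sample_id = rep(s, length(hyper) + length(hypo)),
      probe_id = c(rownames(beta)[hyper], rownames(beta)[hypo]),
      direction = rep(c("hyper", "hypo"), c(length(hyper), length(hypo))),
      beta = c(v[hyper], v[hypo]),
      excess = c(v[hyper] - upper[hyper], lower[hypo] - v[hypo]),
      row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  attr(out, "saturated_frac") <- sev_saturation(ranges[ri, , drop = FALSE])
  out
}
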