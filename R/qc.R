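#' Probe-level quality filtering
#'
#' Removes unreliable probes from a beta matrix before reference-range
#' construction, applying the rules in a fixed order and counting each
#' removed probe under the first rule it fails:
#'
#' 1. detection failure: detection p-value > `det_p_max` in more than
#'    `det_p_frac` of samples (default: in any sample),
#' 2. low bead count: bead count < `bead_min` in at least `bead_sample_frac`
#'    of samples,
#' 3. `non_cpg` manifest flag,
#' 4. `snp_affected` manifest flag,
#' 5. `multi_mapping` manifest flag,
#' 6. `sex_chromosome` manifest flag.
#'
#' @param beta probe x sample beta matrix.
#' @param detection_p,bead_counts matrices on the same axes as `beta`; either
#'   may be `NULL` to skip its rule.
#' @param manifest probe manifest covering every row of `beta` (`flags`
#'   column consulted for rules 3-6).
#' @param det_p_max detection p-value threshold (default 0.01).
#' @param det_p_frac a probe fails the detection rule when the fraction of
#'   samples with p > `det_p_max` exceeds this (default 0 = any sample).
#' @param bead_min minimum acceptable bead count (default 3).
#' @param bead_sample_frac fraction of samples at/above which low bead
#'   counts remove the probe (default 0.05).
#'
#' @return list with `beta` (the filtered matrix) and `report`: a list with
#'   `n_input`, `removed_by_rule` (named integer vector, first-match
#'   accounting) and `retained`. Removals plus retained always sum to the
#'   input probe count.
#' @export
filter_probes <- function(beta, detection_p = NULL, bead_counts = NULL,
                          manifest = NULL,
                          det_p_max = 0.01, det_p_frac = 0,
                          bead_min = 3L, bead_sample_frac = 0.05) {
  assert_beta_matrix(beta)
  ns <- ncol(beta)
  check_axes <- function(m, what) {
    if (!identical(dim(m), dim(beta)) ||
        !identical(rownames(m), rownames(beta)) ||
        !identical(colnames(m), colnames(beta))) {
      stop(sprintf("`%s` axes do not match `beta`", what), call. = FALSE)
    }
  }

  rules <- c("detection_p", "bead_count", "non_cpg", "snp_affected",
             "multi_mapping", "sex_chromosome")
  fail <- matrix(FALSE, nrow = nrow(beta), ncol = length(rules),
                 dimnames = list(rownames(beta), rules))

  if (!is.null(detection_p)) {
    check_axes(detection_p, "detection_p")
    fail[, "detection_p"] <- rowSums(detection_p > det_p_max) / ns > det_p_frac
  }
  if (!is.null(bead_counts)) {
    check_axes(bead_counts, "bead_counts")
    fail[, "bead_count"] <- rowSums(bead_counts < bead_min) / ns >= bead_sample_frac
  }
  if (!is.null(manifest)) {
    mf <- manifest[match(rownames(beta), manifest$probe_id), , drop = FALSE]
    if (anyNA(mf$probe_id)) {
      stop("manifest does not cover all probes in `beta`", call. = FALSE)
    }
    for (fl in c("non_cpg", "snp_affected", "multi_mapping", "sex_chromosome")) {
      fail[, fl] <- manifest_has_flag(mf, fl)
    }
  }

  # first-match accounting
  first <- apply(fail, 1L, function(row) {
    w <- which(row)
    if (length(w)) w[1] else NA_integer_
  })
  removed_by_rule <- vapply(seq_along(rules),
                            function(i) sum(first == i, na.rm = TRUE), integer(1))
  names(removed_by_rule) <- rules

  keep <- is.na(first)
  if (!any(keep)) warning("all probes removed by QC filtering")
  list(beta = beta[keep, , drop = FALSE],
       report = list(n_input = nrow(beta),
                     removed_by_rule = removed_by_rule,
                     retained = sum(keep)))
}

#' Drop probes with missing values
#'
#' Pre-step for [quantile_normalize()], which requires complete data.
#'
#' @param beta probe x sample beta matrix, possibly with `NA`s.
#' @return the matrix restricted to probes observed in every sample.
#' @export
drop_incomplete_probes <- function(beta) {
  keep <- rowSums(is.na(beta)) == 0L
  beta[keep, , drop = FALSE]
}

#' Quantile normalization of a beta matrix
#'
#' Forces every sample's beta-value distribution onto the common reference
#' distribution (the across-sample mean of sorted values), preserving each
#' sample's within-sample rank order. Tied input values receive the mean of
#' the reference values at their tied ranks. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param beta probe x sample beta matrix with no missing values (see
#'   [drop_incomplete_probes()]).
#' @return the normalized matrix, same dimnames; values stay in [0, 1].
#' @export
#' @examples
#' m <- cbind(s1 = c(0.1, 0.5, 0.9), s2 = c(0.2, 0.4, 0.6))
#' rownames(m) <- paste0("cg", 1:3)
#' quantile_normalize(m)  # both columns become 0.15, 0.45, 0.75
quantile_normalize <- function(beta) {
  if (anyNA(beta)) {
    stop("beta matrix contains missing values; run drop_incomplete_probes() first",
         call. = FALSE)
  }
  if (ncol(beta) < 2L) {
    warning("single-sample matrix: quantile normalization is a no-op")
    return(beta)
  }
  out <- limma::normalizeQuantiles(beta, ties = TRUE)
  dimnames(out) <- dimnames(beta)
  out
}
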