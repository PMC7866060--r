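#' Site-level differential methylation between groups
#'
#' Per-probe two-group comparison of mean beta values: a Welch t-test by
#' default, or limma's moderated t (empirical-Bayes shrunk variances) with
#' `method = "limma"`. This is a deliberately minimal group-level surface
#' for volcano-style filtering; it fits no surrogate variables or other
#' confounder adjustments.
#'
#' @param beta probe x sample beta matrix.
#' @param sheet sample sheet assigning `case`/`control` to every column.
#' @param method `"welch"` (default) or `"limma"`.
#' @return data.frame: `probe_id`, `mean_case`, `mean_control`, `diff`
#'   (case minus control), `p_value`, `degenerate` (TRUE where both groups
#'   are constant and identical, reported as p = 1).
#' @export
site_diff_meth <- function(beta, sheet, method = c("welch", "limma")) {
  method <- match.arg(method)
  grp <- sheet$group[match(colnames(beta), sheet$sample_id)]
  if (anyNA(grp)) stop("sample sheet does not cover all samples", call. = FALSE)
  n1 <- sum(grp == "case")
  n2 <- sum(grp == "control")
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 samples", call. = FALSE)

  x <- beta[, grp == "case", drop = FALSE]
  y <- beta[, grp == "control", drop = FALSE]
  m1 <- rowMeans(x)
  m2 <- rowMeans(y)
  d <- m1 - m2
  degenerate <- logical(nrow(beta))

  if (method == "welch") {
    v1 <- rowSums((x - m1)^2) / (n1 - 1L)
    v2 <- rowSums((y - m2)^2) / (n2 - 1L)
    se2 <- v1 / n1 + v2 / n2
    p <- rep(1, nrow(beta))
    ok <- se2 > 0
    tt <- d[ok] / sqrt(se2[ok])
    dfree <- se2[ok]^2 /
      ((v1[ok] / n1)^2 / (n1 - 1L) + (v2[ok] / n2)^2 / (n2 - 1L))
    p[ok] <- 2 * pt(-abs(tt), dfree)
    # zero within-group variance: identical groups get p = 1 (flagged),
    # separated constant groups an effectively zero p
    p[!ok & d != 0] <- 0
    degenerate <- !ok
  } else {
    design <- cbind(Intercept = 1, case = as.integer(grp == "case"))
    fit <- limma::eBayes(limma::lmFit(beta, design))
    p <- fit$p.value[, "case"]
  }

  data.frame(probe_id = rownames(beta),
             mean_case = unname(m1), mean_control = unname(m2),
             diff = unname(d), p_value = unname(p),
             degenerate = unname(degenerate),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Volcano-style significance filter
#'
#' Retains sites passing both a genome-wide p-value threshold (default
#' 1e-7) and an absolute mean-difference cutoff (default 10% on the beta
#' scale), split by direction of change.
#'
#' @param results output of [site_diff_meth()].
#' @param p_threshold p-value cutoff (strict `<`).
#' @param diff_threshold absolute difference cutoff (strict `>`).
#' @return list: `hyper` and `hypo` (significant subsets with positive /
#'   negative differences), `n_hyper`, `n_hypo`, `n_significant`.
#' @export
volcano_filter <- function(results, p_threshold = 1e-7, diff_threshold = 0.10) {
  sig <- results$p_value < p_threshold & abs(results$diff) > diff_threshold
  hyper <- results[sig & results$diff > 0, , drop = FALSE]
  hypo <- results[sig & results$diff < 0, , drop = FALSE]
  list(hyper = hyper, hypo = hypo,
       n_hyper = nrow(hyper), n_hypo = nrow(hypo),
       n_significant = nrow(hyper) + nrow(hypo))
}

#' Most variable probes
#'
#' Selects the `n` probes with the largest across-sample variance, the
#' usual input to unsupervised clustering. Ties are broken by probe id for
#' determinism.
#'
#' @param beta probe x sample beta matrix.
#' @param n number of probes to keep (1 <= n <= nrow).
#' @return character vector of `n` probe ids, most variable first.
#' @export
top_variable_loci <- function(beta, n = 1000L) {
  n <- assert_count(n, "n")
  if (n > nrow(beta)) stop("`n` exceeds the number of probes", call. = FALSE)
  m <- rowMeans(beta)
  v <- rowSums((beta - m)^2) / (ncol(beta) - 1L)
  ord <- order(-v, rownames(beta))
  rownames(beta)[ord][seq_len(n)]
}

#' Mean beta per region
#'
#' Simple exploratory aggregator: average beta of each sample over the
#' probes of each gene (or other manifest grouping column).
#'
#' @param beta probe x sample beta matrix.
#' @param manifest probe manifest; rows with empty `by` labels are skipped.
#' @param by manifest column to group probes by (default `"gene"`).
#' @return region x sample matrix of mean betas.
#' @export
region_mean_beta <- function(beta, manifest, by = "gene") {
  lab <- manifest[[by]][match(rownames(beta), manifest$probe_id)]
  keep <- !is.na(lab) & lab != ""
  rowsum(beta[keep, , drop = FALSE], lab[keep]) /
    as.vector(table(lab[keep])[sort(unique(lab[keep]))])
}
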