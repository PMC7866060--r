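#' Case-vs-control SEV burden test
#'
#' Compares per-sample SEV counts (raw calls or retained calls) between
#' cases and controls with a generalized linear model adjusted for sex and
#' age: `count ~ group + sex + age`, Poisson family with log link. When the
#' Poisson fit is overdispersed (Pearson chi-square / df > 2) the model is
#' refit as quasi-Poisson so the group test is not anti-conservative; the
#' family actually used is reported in the result.
#'
#' @param counts per-sample SEV counts: a named numeric vector
#'   (names = sample ids) or a data.frame with `sample_id` and `count`.
#' @param sheet sample sheet with `sample_id`, `group` (`case`/`control`),
#'   `sex`, `age` for every counted sample.
#' @param family `"auto"` (default: Poisson with overdispersion switch),
#'   `"poisson"` or `"quasipoisson"`.
#' @param alpha significance threshold recorded in the result.
#'
#' @return list of class `sev_burden`: `per_sample_counts`,
#'   `group_coefficient` (log-scale case effect), `p_value`, `model`
#'   (descriptor string), `dispersion`, `significant`, `fit` (the `glm`
#'   object).
#' @export
burden_test <- function(counts, sheet, family = c("auto", "poisson", "quasipoisson"),
                        alpha = 0.05) {
  family <- match.arg(family)
  if (is.data.frame(counts)) {
    cv <- counts$count
    names(cv) <- counts$sample_id
    counts <- cv
  }
  if (is.null(names(counts))) stop("`counts` must be named by sample id", call. = FALSE)
  df <- data.frame(sample_id = names(counts), count = as.numeric(counts),
                   stringsAsFactors = FALSE)
  df <- merge(df, sheet, by = "sample_id")
  if (nrow(df) < length(counts)) {
    stop("sample sheet does not cover all counted samples", call. = FALSE)
  }
  if (anyNA(df$age) || anyNA(df$sex)) {
    stop("age and sex must be available for all samples", call. = FALSE)
  }
  df$group <- factor(df$group, levels = c("control", "case"))
  if (any(table(df$group) < 2L)) {
    stop("burden test needs at least 2 samples per group", call. = FALSE)
  }
  if (var(df$count) == 0) {
    stop("degenerate fit: SEV counts are constant across samples", call. = FALSE)
  }
  df$sex <- factor(df$sex)

  fit <- glm(count ~ group + sex + age, data = df, family = poisson())
  dispersion <- sum(residuals(fit, type = "pearson")^2) / fit$df.residual
  used <- "poisson"
  if (family == "quasipoisson" || (family == "auto" && dispersion > 2)) {
    fit <- glm(count ~ group + sex + age, data = df, family = quasipoisson())
    used <- "quasipoisson"
  }
  co <- summary(fit)$coefficients
  if (!"groupcase" %in% rownames(co)) {
    stop("degenerate fit: group coefficient not estimable", call. = FALSE)
  }
  p <- co["groupcase", 4L]
  structure(list(
    per_sample_counts = counts,
    group_coefficient = unname(co["groupcase", 1L]),
    p_value = unname(p),
    model = sprintf("count ~ group + sex + age, family = %s (log link)", used),
    dispersion = dispersion,
    significant = p < alpha,
    fit = fit
  ), class = "sev_burden")
}

#' @export
print.sev_burden <- function(x, ...) {
  cat("SEV burden test:", x$model, "\n")
  cat(sprintf("  group (case) coefficient: %.4f  p = %.4g  dispersion = %.2f\n",
              x$group_coefficient, x$p_value, x$dispersion))
  invisible(x)
}

#' Wilcoxon comparison of a covariate between groups
#'
#' Two-sided Wilcoxon rank-sum test of a per-sample quantity (age,
#' estimated cell proportions, ...) between cases and controls.
#'
#' @param sheet sample sheet with `sample_id` and `group`.
#' @param values named numeric vector of per-sample values.
#' @return list: `p_value`, `median_case`, `median_control`, `statistic`.
#' @export
covariate_compare <- function(sheet, values) {
  if (is.null(names(values))) stop("`values` must be named by sample id", call. = FALSE)
  grp <- sheet$group[match(names(values), sheet$sample_id)]
  x <- values[grp == "case"]
  y <- values[grp == "control"]
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups need at least one value", call. = FALSE)
  }
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  list(p_value = wt$p.value,
       median_case = median(x),
       median_control = median(y),
       statistic = unname(wt$statistic))
}

#' Clinical feature prevalence table
#'
#' Summarises per-sample binary clinical flags as `n/N` counts and
#' percentages. Percentages are rounded to the nearest integer, except
#' values below 10%, which keep one decimal (so rare features are not
#' flattened to single digits).
#'
#' @param clinical data.frame of logical feature columns (an optional
#'   `sample_id` column is ignored for counting).
#' @return data.frame: `feature`, `n_affected`, `n_total`, `percent`.
#' @export
#' @examples
#' clin <- data.frame(a = c(rep(TRUE, 39), rep(FALSE, 2)),
#'                    b = c(rep(TRUE, 3), rep(FALSE, 38)))
#' prevalence_table(clin)  # 95% and 7.3%
prevalence_table <- function(clinical) {
  feats <- clinical[, setdiff(names(clinical), "sample_id"), drop = FALSE]
  if (!all(vapply(feats, is.logical, logical(1)))) {
    stop("all feature columns must be logical", call. = FALSE)
  }
  n_total <- nrow(feats)
  n_affected <- vapply(feats, sum, integer(1))
  raw <- 100 * n_affected / n_total
  percent <- ifelse(raw < 10, round(raw, 1), round(raw))
  data.frame(feature = names(feats),
             n_affected = unname(n_affected),
             n_total = n_total,
             percent = unname(percent),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Packaged synthetic clinical fixture
#'
#' Loads the synthetic 41-sample clinical table shipped with the package
#' (one logical column per clinical feature of an OAVS-like craniofacial
#' cohort). The per-feature counts match the published cohort summary; the
#' per-sample assignment of flags is synthetic.
#'
#' @return data.frame with `sample_id` plus 12 logical feature columns.
#' @export
load_clinical_fixture <- function() {
  path <- system.file("extdata", "oavs_clinical_synthetic.csv",
                      package = "sevscan", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in setdiff(names(df), "sample_id")) df[[col]] <- as.logical(df[[col]])
  df
}
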