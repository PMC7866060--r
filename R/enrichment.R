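#' Upper-tail cumulative hypergeometric probability
#'
#' Exact probability of observing at least `x` successes when drawing `n`
#' items without replacement from a universe of `N` items containing `K`
#' successes: `P(X >= x)` for `X ~ Hypergeometric(N, K, n)`. This is the
#' window statistic of the enrichment scan: `x` SEVs in a window of `n`
#' probes, given `K` SEVs of the sample among `N` retained probes.
#'
#' Computed exactly via [stats::phyper()] (no normal approximation).
#' Vectorised over all four arguments.
#'
#' @param x observed success count (>= 0).
#' @param K successes in the universe (0 <= K <= N).
#' @param n draws, i.e. window size (0 <= n <= N).
#' @param N universe size.
#' @return `P(X >= x)` in [0, 1]; 1 when `x <= 0`, 0 when
#'   `x > min(n, K)` (impossible count).
#' @export
#' @examples
#' hypergeom_upper_tail(5, K = 5, n = 11, N = 20)  # 5005/167960
hypergeom_upper_tail <- function(x, K, n, N) {
  if (any(K < 0) || any(n < 0) || any(x < 0) || any(K > N) || any(n > N)) {
    stop("require 0 <= K <= N, 0 <= n <= N, x >= 0", call. = FALSE)
  }
  m <- pmin(n, K)
  p <- phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  p[x <= 0] <- 1
  p[x > m] <- 0
  pmin(pmax(p, 0), 1)
}

#' Sliding-window hypergeometric enrichment scan
#'
#' Walks the retained-probe universe in manifest order with a window of `n`
#' consecutive probes (default 11), testing each window for
#' over-representation of a sample's SEVs with the cumulative hypergeometric
#' test: `x` = sample's SEVs inside the window, `K` = sample's total SEVs in
#' the universe, `N` = universe size. The central probe of a significant
#' window (`p < alpha`) is retained — but only if that central probe is
#' itself an SEV of the sample; otherwise it is discarded. This filters
#' spurious isolated SEVs while keeping clustered ones.
#'
#' Windows never span chromosomes, and only central probes with a full
#' complement of `(n-1)/2` same-chromosome flanking probes on each side are
#' tested (constant window size keeps the test exchangeable across centres).
#' `K` and `N` are genome-wide, not per-chromosome. By default hyper- and
#' hypo-methylated SEVs are pooled for `x` and `K`; `per_direction = TRUE`
#' scans each direction separately.
#'
#' @param sevs SEV calls from [detect_sevs()] (one or several samples; the
#'   scan is run per sample).
#' @param manifest probe manifest defining genomic order.
#' @param universe character vector of retained probe ids (the post-QC
#'   probe set); SEVs outside it are ignored.
#' @param n odd window size >= 3 (default 11).
#' @param alpha significance threshold for window retention (default 0.05).
#' @param per_direction scan hyper and hypo SEVs separately.
#'
#' @return data.frame of window tests, one row per (sample, central probe):
#'   `sample_id`, `central_probe`, `chromosome`, `x`, `K`, `N`, `n`,
#'   `p_value`, `central_is_sev`, `retained`. Attribute `alpha` records the
#'   threshold used.
#' @export
sliding_window_scan <- function(sevs, manifest, universe, n = 11L,
                                alpha = 0.05, per_direction = FALSE) {
  n <- assert_count(n, "n", min = 3L)
  if (n %% 2L == 0L) {
    stop("window size `n` must be odd so a central probe exists", call. = FALSE)
  }
  stopifnot(is.character(universe), !anyDuplicated(universe))
  mf <- manifest[match(universe, manifest$probe_id), , drop = FALSE]
  if (anyNA(mf$probe_id)) {
    stop("universe contains probes absent from the manifest", call. = FALSE)
  }
  ord <- manifest_order(mf)
  uni <- mf$probe_id[ord]
  chrom <- mf$chromosome[ord]
  N <- length(uni)
  half <- (n - 1L) %/% 2L

  if (per_direction) {
    out <- do.call(rbind, lapply(split(sevs, sevs$direction), function(sd) {
      sliding_window_scan(sd, manifest, universe, n = n, alpha = alpha,
                          per_direction = FALSE)
    }))
    rownames(out) <- NULL
    attr(out, "alpha") <- alpha
    return(out)
  }

  scan_one <- function(sample_id, probe_ids) {
    ind <- as.integer(uni %in% probe_ids)
    K <- sum(ind)
    blocks <- split(seq_len(N), factor(chrom, levels = unique(chrom)))
    res <- lapply(blocks, function(idx) {
      len <- length(idx)
      if (len < n) return(NULL)
      cs <- c(0L, cumsum(ind[idx]))
      centers <- (half + 1L):(len - half)
      x <- cs[centers + half + 1L] - cs[centers - half]
      data.frame(central_probe = uni[idx[centers]],
                 chromosome = chrom[idx[centers]],
                 x = x, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    if (is.null(res)) {
      return(data.frame(sample_id = character(), central_probe = character(),
                        chromosome = character(), x = integer(), K = integer(),
                        N = integer(), n = integer(), p_value = numeric(),
                        central_is_sev = logical(), retained = logical(),
                        stringsAsFactors = FALSE))
    }
    res$sample_id <- sample_id
    res$K <- K
    res$N <- N
    res$n <- n
    res$p_value <- hypergeom_upper_tail(res$x, K = K, n = n, N = N)
    res$central_is_sev <- res$central_probe %in% probe_ids
    res$retained <- res$p_value < alpha & res$central_is_sev
    res[, c("sample_id", "central_probe", "chromosome", "x", "K", "N", "n",
            "p_value", "central_is_sev", "retained")]
  }

  by_sample <- split(sevs$probe_id[sevs$probe_id %in% uni],
                     sevs$sample_id[sevs$probe_id %in% uni])
  out <- do.call(rbind, lapply(sort(names(by_sample)), function(s) {
    scan_one(s, by_sample[[s]])
  }))
  if (is.null(out)) {
    out <- data.frame(sample_id = character(), central_probe = character(),
                      chromosome = character(), x = integer(), K = integer(),
                      N = integer(), n = integer(), p_value = numeric(),
                      central_is_sev = logical(), retained = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}

#' Retained SEVs of a scan
#'
#' Extracts the SEV calls that survived the enrichment scan (central probes
#' of significant windows that are themselves SEVs), re-attaching direction,
#' beta and excess from the original calls.
#'
#' @param scan output of [sliding_window_scan()].
#' @param sevs the SEV calls that were scanned.
#' @return subset of `sevs` rows (plus `p_value`) whose probes were retained
#'   for the matching sample.
#' @export
retained_sevs <- function(scan, sevs) {
  kept <- scan[scan$retained, c("sample_id", "central_probe", "p_value")]
  out <- merge(sevs, kept,
               by.x = c("sample_id", "probe_id"),
               by.y = c("sample_id", "central_probe"))
  out[order(out$sample_id, out$probe_id), , drop = FALSE]
}
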