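# internal helpers

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state (all package randomness flows through this).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

assert_beta_matrix <- function(beta) {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    stop("`beta` must be a numeric matrix (probes x samples)", call. = FALSE)
  }
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop("`beta` must carry probe ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(beta)) || anyDuplicated(colnames(beta))) {
    stop("duplicate probe or sample ids in beta matrix", call. = FALSE)
  }
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    stop("beta values must lie in [0, 1]", call. = FALSE)
  }
  invisible(beta)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# manifest rows in genomic walking order: chromosomes in order of first
# appearance (natural for generated and 450K-style manifests), positions
# increasing within a chromosome
manifest_order <- function(manifest) {
  order(match(manifest$chromosome, unique(manifest$chromosome)),
        manifest$position)
}

# does each manifest row carry `flag` in its ";"-separated flags string?
manifest_has_flag <- function(manifest, flag) {
  vapply(strsplit(ifelse(is.na(manifest$flags), "", manifest$flags), ";",
                  fixed = TRUE),
         function(f) flag %in% f, logical(1))
}
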