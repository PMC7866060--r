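# shared fixtures and independent oracles

# exact upper-tail hypergeometric by brute-force enumeration of pmf terms;
# deliberately independent of hypergeom_upper_tail()'s implementation
hyper_tail_oracle <- function(x, K, n, N) {
  m <- min(n, K)
  if (x > m) return(0)
  if (x <= 0) return(1)
  i <- x:m
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# a beta matrix with named dims from a plain numeric matrix
named_beta <- function(m, probe_prefix = "cg", sample_prefix = "s") {
  rownames(m) <- sprintf("%s%03d", probe_prefix, seq_len(nrow(m)))
  colnames(m) <- sprintf("%s%02d", sample_prefix, seq_len(ncol(m)))
  m
}

# a hand-built manifest for one chromosome: probes at regular positions,
# gene labels supplied directly
toy_manifest <- function(genes, chromosome = "chr1", spacing = 1000L) {
  n <- length(genes)
  data.frame(probe_id = sprintf("cg%03d", seq_len(n)),
             chromosome = chromosome,
             position = seq_len(n) * spacing,
             gene = genes,
             island_relation = "open_sea",
             flags = "",
             stringsAsFactors = FALSE)
}

# small generated cohort reused across tests
small_cohort <- function(n_probes = 1500, n_cases = 6, n_controls = 12,
                         seed = 42, ...) {
  mf <- generate_manifest(n_probes, 2, 40, seed = seed)
  ch <- generate_cohort(mf, n_cases, n_controls, seed = seed, ...)
  c(list(manifest = mf), ch)
}
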