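#' Generate a synthetic 450K-like probe manifest
#'
#' Builds an ordered probe annotation table emulating the structure of an
#' Illumina methylation array manifest: probes laid out along chromosomes at
#' strictly increasing positions, organised into contiguous gene blocks
#' separated by intergenic probes, with CpG-island relations and the
#' quality-control flags the probe filter acts on.
#'
#' Probes are split as evenly as possible across chromosomes (earlier
#' chromosomes absorb any remainder). Within a chromosome, gene blocks of
#' 2 + Poisson(6) consecutive probes alternate with short intergenic runs; a
#' small fraction of blocks receives a composite "A;B" label emulating probes
#' annotated to two overlapping genes. QC flags are drawn independently per
#' probe at the rates in `flag_fracs`.
#'
#' @param n_probes total number of probes (>= `n_chromosomes`).
#' @param n_chromosomes number of chromosomes to spread probes over.
#' @param genes_per_chromosome maximum number of gene blocks per chromosome.
#' @param seed integer seed; the same seed reproduces the manifest exactly.
#' @param flag_fracs named numeric vector of per-probe flag probabilities for
#'   `snp_affected`, `non_cpg`, `multi_mapping` and `sex_chromosome`.
#'   Defaults approximate the relative prevalence of these classes on the
#'   450K array (SNP-affected probes dominate).
#'
#' @return A `data.frame` with columns `probe_id`, `chromosome`, `position`
#'   (1-based bp), `gene` (`""` for intergenic, `"A;B"` for multi-gene),
#'   `island_relation` (`island`/`shore`/`open_sea`) and `flags`
#'   (`;`-separated subset of the flag names, `""` if clean), ordered by
#'   (chromosome, position).
#' @seealso [generate_cohort()], [inject_epivariants()]
#' @export
#' @examples
#' mf <- generate_manifest(n_probes = 200, n_chromosomes = 2,
#'                         genes_per_chromosome = 10, seed = 1)
#' head(mf)
generate_manifest <- function(n_probes,
                              n_chromosomes = 2L,
                              genes_per_chromosome = 50L,
                              seed = 1L,
                              flag_fracs = c(snp_affected = 0.08,
                                             non_cpg = 0.01,
                                             multi_mapping = 0.002,
                                             sex_chromosome = 0.02)) {
  n_probes <- assert_count(n_probes, "n_probes")
  n_chromosomes <- assert_count(n_chromosomes, "n_chromosomes")
  genes_per_chromosome <- assert_count(genes_per_chromosome, "genes_per_chromosome")
  if (n_probes < n_chromosomes) {
    stop("`n_probes` must be at least `n_chromosomes`", call. = FALSE)
  }
  known_flags <- c("snp_affected", "non_cpg", "multi_mapping", "sex_chromosome")
  stopifnot(all(names(flag_fracs) %in% known_flags))

  with_seed(seed, {
    per_chrom <- rep(n_probes %/% n_chromosomes, n_chromosomes)
    rem <- n_probes %% n_chromosomes
    if (rem > 0) per_chrom[seq_len(rem)] <- per_chrom[seq_len(rem)] + 1L

    chrom <- rep(paste0("chr", seq_len(n_chromosomes)), per_chrom)
    # strictly increasing positions: random inter-probe gaps of 50..5000 bp
    position <- unlist(lapply(per_chrom, function(np) {
      100000L + cumsum(sample(50:5000, np, replace = TRUE))
    }), use.names = FALSE)

    # contiguous gene blocks separated by intergenic runs
    gene <- character(n_probes)
    offset <- 0L
    for (ci in seq_len(n_chromosomes)) {
      np <- per_chrom[ci]
      pos <- 1L
      gi <- 1L
      while (pos <= np && gi <= genes_per_chromosome) {
        gap <- rpois(1, 2)
        pos <- pos + gap
        if (pos > np) break
        len <- min(2L + rpois(1, 6), np - pos + 1L)
        label <- sprintf("G%d_%d", ci, gi)
        if (runif(1) < 0.03) label <- paste0(label, ";", label, "B")
        gene[offset + pos:(pos + len - 1L)] <- label
        pos <- pos + len
        gi <- gi + 1L
      }
      offset <- offset + np
    }

    island_relation <- sample(c("island", "shore", "open_sea"), n_probes,
                              replace = TRUE, prob = c(0.30, 0.25, 0.45))

    flag_mat <- vapply(known_flags, function(f) {
      p <- if (f %in% names(flag_fracs)) flag_fracs[[f]] else 0
      runif(n_probes) < p
    }, logical(n_probes))
    flags <- apply(flag_mat, 1L, function(row) {
      paste(known_flags[row], collapse = ";")
    })

    data.frame(
      probe_id = sprintf("cg%08d", seq_len(n_probes)),
      chromosome = chrom,
      position = position,
      gene = gene,
      island_relation = island_relation,
      flags = flags,
      stringsAsFactors = FALSE
    )
  })
}
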