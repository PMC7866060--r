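#' Subtract control deregulations from case profiles
#'
#' Removes from each case's retained SEVs every probe that also appears
#' among the retained SEVs of any control ("non-specific or physiological"
#' deregulations). The default granularity is the probe: the union of
#' control retained probes is subtracted. `level = "gene"` instead drops
#' all case probes annotated to a gene that harbours any control retained
#' SEV (requires `manifest`).
#'
#' @param case_retained retained SEV calls of the cases
#'   (see [retained_sevs()]).
#' @param control_retained retained SEV calls across all controls.
#' @param level `"probe"` (default, strictest) or `"gene"`.
#' @param manifest probe manifest, required for `level = "gene"`.
#' @return `case_retained` without the subtracted rows.
#' @export
subtract_control_profile <- function(case_retained, control_retained,
                                     level = c("probe", "gene"),
                                     manifest = NULL) {
  level <- match.arg(level)
  if (is.null(control_retained) || nrow(control_retained) == 0L) {
    return(case_retained)
  }
  if (level == "probe") {
    drop <- case_retained$probe_id %in% unique(control_retained$probe_id)
  } else {
    if (is.null(manifest)) stop("`manifest` required for gene-level subtraction",
                                call. = FALSE)
    gene_of <- function(p) manifest$gene[match(p, manifest$probe_id)]
    bad_genes <- setdiff(unique(gene_of(control_retained$probe_id)), "")
    drop <- gene_of(case_retained$probe_id) %in% bad_genes
  }
  case_retained[!drop, , drop = FALSE]
}

#' Group retained SEVs into per-sample deregulated gene loci
#'
#' Annotates retained SEVs to genes via the manifest, drops intergenic
#' probes (empty gene string) and, per sample, groups the rest by gene.
#' Loci supported by a single epigenetic variant are excluded; composite
#' gene strings (e.g. `"SIX3;SIX2"`) are kept verbatim as one locus key.
#'
#' @param retained retained (and typically control-subtracted) SEV calls.
#' @param manifest probe manifest covering all probes.
#' @return data.frame of loci: `sample_id`, `gene`, `n_sevs` (>= 2),
#'   `direction` (`hyper`/`hypo` when unanimous, else `mixed`), `probe_ids`
#'   (`;`-joined). Attribute `n_intergenic_dropped` counts retained SEVs
#'   discarded for lacking a gene annotation.
#' @export
call_gene_loci <- function(retained, manifest) {
  empty <- data.frame(sample_id = character(), gene = character(),
                      n_sevs = integer(), direction = character(),
                      probe_ids = character(), stringsAsFactors = FALSE)
  if (is.null(retained) || nrow(retained) == 0L) {
    attr(empty, "n_intergenic_dropped") <- 0L
    return(empty)
  }
  gene <- manifest$gene[match(retained$probe_id, manifest$probe_id)]
  if (anyNA(gene)) stop("manifest does not cover all retained probes", call. = FALSE)
  inter <- is.na(gene) | gene == ""
  n_inter <- sum(inter)
  df <- retained[!inter, , drop = FALSE]
  df$gene <- gene[!inter]
  if (nrow(df) == 0L) {
    attr(empty, "n_intergenic_dropped") <- n_inter
    return(empty)
  }
  dt <- data.table::as.data.table(df)
  loci <- dt[, list(
    n_sevs = .N,
    direction = if (data.table::uniqueN(direction) == 1L) direction[1] else "mixed",
    probe_ids = paste(sort(probe_id), collapse = ";")
  ), by = c("sample_id", "gene")]
  loci <- loci[loci$n_sevs >= 2L, ]
  out <- as.data.frame(loci[order(loci$sample_id, loci$gene), ])
  rownames(out) <- NULL
  attr(out, "n_intergenic_dropped") <- n_inter
  out
}

#' Shared-gene frequency table
#'
#' Tabulates, for one direction of deregulation, how many distinct cases
#' carry a locus at each gene and the per-case retained-SEV counts, the
#' per-gene sharing summary of a cohort. Mixed-direction loci are excluded
#' (the tables are strictly directional).
#'
#' @param loci gene loci across all cases from [call_gene_loci()].
#' @param direction `"hyper"` or `"hypo"`.
#' @return data.frame: `gene`, `n_cases`, `cases` (comma-separated
#'   `"SAMPLE (n)"` entries ordered by decreasing SEV count then sample id),
#'   sorted by decreasing `n_cases` then gene.
#' @export
shared_gene_table <- function(loci, direction = c("hyper", "hypo")) {
  direction <- match.arg(direction)
  sub <- loci[loci$direction == direction, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(data.frame(gene = character(), n_cases = integer(),
                      cases = character(), stringsAsFactors = FALSE))
  }
  dt <- data.table::as.data.table(sub)
  dt <- dt[order(-dt$n_sevs, dt$sample_id), ]
  tab <- dt[, list(
    n_cases = data.table::uniqueN(sample_id),
    cases = paste(sprintf("%s (%d)", sample_id, n_sevs), collapse = ", ")
  ), by = "gene"]
  out <- as.data.frame(tab[order(-tab$n_cases, tab$gene), ])
  rownames(out) <- NULL
  out
}

#' Read a BED file of labelled regions
#'
#' Minimal validating reader for 3+ column BED (chrom, start, end,
#' optional name), 0-based half-open coordinates. Track/browser/comment
#' lines are skipped; malformed lines raise an error naming the line
#' number.
#'
#' @param path BED file path.
#' @return data.frame: `chrom`, `start`, `end` (0-based half-open),
#'   `name` (auto-generated `region<i>` when absent).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  out <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop(sprintf("malformed BED line %d: fewer than 3 fields", i), call. = FALSE)
    }
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end) || start < 0 || end < start ||
        start != floor(start) || end != floor(end)) {
      stop(sprintf("malformed BED line %d: bad coordinates '%s'-'%s'",
                   i, f[2], f[3]), call. = FALSE)
    }
    out[[length(out) + 1L]] <- data.frame(
      chrom = f[1], start = as.integer(start), end = as.integer(end),
      name = if (length(f) >= 4L && nzchar(f[4])) f[4]
             else sprintf("region%d", length(out) + 1L),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Intersect retained SEVs with labelled region sets
#'
#' Counts, per sample and region (e.g. imprinted DMRs or RARE +/- 10 kb
#' sets), how many retained SEVs fall inside the region, alongside the
#' total number of universe probes the region covers — the
#' "five out of seven probes" style of report. BED regions are 0-based
#' half-open; manifest positions are 1-based (converted internally).
#'
#' @param retained retained SEV calls.
#' @param regions BED-style data.frame from [read_bed()] (columns `chrom`,
#'   `start`, `end`, `name`).
#' @param manifest probe manifest supplying probe coordinates.
#' @param universe retained probe ids defining the denominator.
#' @return data.frame with one row per (sample, region) having at least one
#'   retained SEV inside: `sample_id`, `region`, `chrom`, `start`, `end`,
#'   `n_sev` (retained SEVs inside), `n_hyper`, `n_hypo`, `n_probes`
#'   (universe probes inside).
#' @export
intersect_region_sets <- function(retained, regions, manifest, universe) {
  empty <- data.frame(sample_id = character(), region = character(),
                      chrom = character(), start = integer(), end = integer(),
                      n_sev = integer(), n_hyper = integer(), n_hypo = integer(),
                      n_probes = integer(), stringsAsFactors = FALSE)
  if (nrow(regions) == 0L || is.null(retained) || nrow(retained) == 0L) {
    return(empty)
  }
  gr_regions <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(start = regions$start + 1L, end = regions$end))

  mf <- manifest[match(universe, manifest$probe_id), , drop = FALSE]
  gr_universe <- GenomicRanges::GRanges(
    mf$chromosome, IRanges::IRanges(start = mf$position, width = 1L))
  uni_hits <- GenomicRanges::findOverlaps(gr_universe, gr_regions)
  n_probes <- tabulate(S4Vectors::subjectHits(uni_hits), nbins = nrow(regions))

  ri <- match(retained$probe_id, manifest$probe_id)
  gr_sev <- GenomicRanges::GRanges(
    manifest$chromosome[ri], IRanges::IRanges(start = manifest$position[ri], width = 1L))
  sev_hits <- GenomicRanges::findOverlaps(gr_sev, gr_regions)
  if (length(sev_hits) == 0L) return(empty)

  hit_df <- data.frame(
    sample_id = retained$sample_id[S4Vectors::queryHits(sev_hits)],
    direction = retained$direction[S4Vectors::queryHits(sev_hits)],
    region_idx = S4Vectors::subjectHits(sev_hits),
    stringsAsFactors = FALSE)
  dt <- data.table::as.data.table(hit_df)
  agg <- dt[, list(n_sev = .N,
                   n_hyper = sum(direction == "hyper"),
                   n_hypo = sum(direction == "hypo")),
            by = c("sample_id", "region_idx")]
  out <- data.frame(
    sample_id = agg$sample_id,
    region = regions$name[agg$region_idx],
    chrom = regions$chrom[agg$region_idx],
    start = regions$start[agg$region_idx],
    end = regions$end[agg$region_idx],
    n_sev = agg$n_sev,
    n_hyper = agg$n_hyper,
    n_hypo = agg$n_hypo,
    n_probes = n_probes[agg$region_idx],
    stringsAsFactors = FALSE)
  out <- out[order(out$sample_id, out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}
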