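#' Read and write pipeline tables
#'
#' Plain-text interchange for the pipeline's data structures: beta /
#' detection-p / bead-count matrices as TSV (rows = probes, first column
#' `probe_id`, remaining columns samples), manifests as TSV, sample sheets
#' as CSV and injection truth records as JSON.
#'
#' @param beta probe x sample matrix with named dims.
#' @param path file path.
#' @name sevscan-io
NULL

#' @rdname sevscan-io
#' @export
write_beta_tsv <- function(beta, path) {
  dt <- data.table::data.table(probe_id = rownames(beta), beta)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname sevscan-io
#' @export
read_beta_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt$probe_id
  m
}

#' @rdname sevscan-io
#' @param manifest probe manifest data.frame.
#' @export
write_manifest_tsv <- function(manifest, path) {
  data.table::fwrite(manifest, path, sep = "\t")
  invisible(path)
}

#' @rdname sevscan-io
#' @export
read_manifest_tsv <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t",
                                        colClasses = list(character = c("gene", "flags"))))
  df$gene[is.na(df$gene)] <- ""
  df$flags[is.na(df$flags)] <- ""
  df
}

#' @rdname sevscan-io
#' @param sheet sample sheet data.frame.
#' @export
write_sample_sheet_csv <- function(sheet, path) {
  data.table::fwrite(sheet, path)
  invisible(path)
}

#' @rdname sevscan-io
#' @export
read_sample_sheet_csv <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' @rdname sevscan-io
#' @param truth injection truth record from [inject_epivariants()].
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname sevscan-io
#' @export
read_truth_json <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$seed <- as.integer(tr$seed)
  tr
}
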