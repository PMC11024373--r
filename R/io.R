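#' Read and write the pipeline's plain-text formats
#'
#' The pipeline exchanges five tabular formats, all plain text:
#' \itemize{
#'   \item genotypes: TSV, rows = samples; columns `sample_id`,
#'     `sample_kind` (`individual` or `pool`), then one column per marker
#'     (dosages 0/1/2 for individuals, continuous 0-2 for pools; empty =
#'     missing);
#'   \item marker map: TSV with `marker_id`, `chrom`, `pos` (1-based),
#'     `ref`, `alt`;
#'   \item phenotypes: long-format CSV with `sample_id`, `environment`,
#'     `trait`, `value`;
#'   \item pool read counts: TSV per pool with `marker_id`, `alt_reads`,
#'     `depth`;
#'   \item pool specifications: JSON (id, environment, trait, category,
#'     members, mean phenotypes);
#'   \item kinship: TSV with sample ids as first column and header.
#' }
#' A samples-x-markers allele-frequency deposit in the genotype layout can
#' be ingested with `read_genotypes()` directly.
#'
#' @param path file path.
#' @param x object to write.
#' @name poolgp-io
NULL

#' @rdname poolgp-io
#' @param kind character vector of `sample_kind` values, recycled.
#' @export
write_genotypes <- function(x, path, kind = "individual") {
  df <- data.frame(sample_id = rownames(x),
                   sample_kind = rep_len(kind, nrow(x)),
                   as.data.frame(x, check.names = FALSE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname poolgp-io
#' @return `read_genotypes()`: a numeric matrix with sample ids as row
#'   names and `attr(, "sample_kind")`.
#' @export
read_genotypes <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "sample_kind") %in% names(df)))
  m <- as.matrix(df[, setdiff(names(df), c("sample_id", "sample_kind")),
                    drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$sample_id
  attr(m, "sample_kind") <- df$sample_kind
  m
}

#' @rdname poolgp-io
#' @export
write_marker_map <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname poolgp-io
#' @export
read_marker_map <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(marker_id = "character", ref = "character",
                            alt = "character"))
}

#' @rdname poolgp-io
#' @export
write_phenotypes <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname poolgp-io
#' @export
read_phenotypes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "environment", "trait", "value") %in% names(df)))
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' @rdname poolgp-io
#' @export
write_pool_reads <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname poolgp-io
#' @export
read_pool_reads <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("marker_id", "alt_reads", "depth") %in% names(df)))
  class(df) <- c("pool_reads", "data.frame")
  df
}

#' @rdname poolgp-io
#' @param specs list of pool specifications from [build_pools()].
#' @export
write_pool_specs <- function(specs, path) {
  jsonlite::write_json(lapply(specs, function(s) {
    s <- unclass(s)
    s$mean_phenotype <- as.list(s$mean_phenotype)
    s
  }), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname poolgp-io
#' @export
read_pool_specs <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(s) {
    s$members <- as.character(s$members)
    s$mean_phenotype <- unlist(s$mean_phenotype)
    class(s) <- "pool_spec"
    s
  })
}

#' @rdname poolgp-io
#' @export
write_kinship <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname poolgp-io
#' @export
read_kinship <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
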