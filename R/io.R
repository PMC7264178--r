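# Readers and writers for the plain-text interchange formats:
# counts TSV (first column = feature id), design TSV, BED3+name regions,
# spike-in TSV, gene-annotation TSV, GMT gene sets, JSON truth/report,
# YAML config.

#' Read a counts TSV into a matrix
#'
#' First column holds feature identifiers; remaining columns are samples.
#'
#' @param path Path to a tab-separated counts file.
#' @return Integer matrix with feature row names.
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a counts matrix as TSV
#'
#' @param counts Matrix with feature row names and sample column names.
#' @param path Output path.
#' @param id_col Name for the feature-id column (default `"feature"`).
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, id_col = "feature") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design TSV
#'
#' Expected columns: `sample`, `genotype`, and optionally `assay`, `role`,
#' `total_reads`.
#'
#' @param path Path to a tab-separated design file.
#' @return Data frame.
#' @export
read_design <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "genotype")
  if (!all(need %in% names(d)))
    abort("design file must have columns: ", paste(need, collapse = ", "))
  d$sample <- as.character(d$sample)
  d
}

#' Read a BED3+name region file
#'
#' Coordinates are 0-based, half-open, as in the BED standard.
#'
#' @param path Path to a BED file (chrom, start, end, name).
#' @return Data frame with columns `region`, `chrom`, `start`, `end`.
#' @export
read_regions_bed <- function(path) {
  b <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(b) < 4) abort("regions BED needs 4 columns (chrom,start,end,name)")
  out <- data.frame(region = as.character(b[[4]]), chrom = as.character(b[[1]]),
                    start = as.integer(b[[2]]), end = as.integer(b[[3]]),
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) abort("BED regions must satisfy start < end")
  out
}

#' Write regions as BED3+name
#'
#' @param regions Data frame with columns `region`, `chrom`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  stopifnot(all(regions$start < regions$end))
  write.table(regions[, c("chrom", "start", "end", "region")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a spike-in barcode count table
#'
#' Long-format TSV with columns `barcode`, `modification`, `sample`, `count`.
#'
#' @param path Path to the spike TSV.
#' @return Data frame.
#' @export
read_spike_table <- function(path) {
  s <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("barcode", "modification", "sample", "count")
  if (!all(need %in% names(s)))
    abort("spike table must have columns: ", paste(need, collapse = ", "))
  if (any(s$count < 0)) abort("spike counts must be non-negative")
  s
}

#' Read a gene annotation TSV
#'
#' Required columns: `gene`, `chrom`, `strand`, `tss` (0-based coordinate of
#' the transcription start site; for minus-strand genes this is the interval
#' end). Optional columns: `tx_start`, `tx_end` (gene body, 0-based
#' half-open) and `exon_starts`/`exon_ends` (comma-separated lists).
#'
#' @param path Path to the annotation TSV.
#' @return Data frame.
#' @export
read_gene_annotation <- function(path) {
  g <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "strand", "tss")
  if (!all(need %in% names(g)))
    abort("gene annotation must have columns: ", paste(need, collapse = ", "))
  if (!all(g$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  g
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then member genes, tab-separated.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) abort("malformed GMT line: ", substr(l, 1, 40))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes)
    paste(c(nm, desc, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}
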