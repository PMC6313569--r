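## Readers and writers for the non-VCF files the pipeline touches.
##
## Coordinate conventions, applied strictly and only at I/O boundaries:
##   * point variants: 1-based inclusive (VCF convention);
##   * intervals (exons, CDS, depth bins, CNV segments): 0-based half-open
##     (BED convention).

#' Read a reference genome
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] named by contig.
#' @export
read_reference <- function(path) {
  ref <- readDNAStringSet(path)
  ## drop FASTA description after first whitespace
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

#' Write a reference genome
#'
#' @param ref Named [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output FASTA path.
#' @export
write_reference <- function(ref, path) {
  if (is.character(ref)) ref <- DNAStringSet(ref)
  writeXStringSet(ref, path, width = 70L)
  invisible(path)
}

## --- gene models ------------------------------------------------------------

#' @noRd
parse_int_list <- function(s) {
  if (is.na(s) || !nzchar(s)) return(integer())
  as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
}

#' @noRd
validate_gene_models <- function(gm) {
  for (i in seq_len(nrow(gm))) {
    st <- gm$exon_starts[[i]]
    en <- gm$exon_ends[[i]]
    id <- gm$transcript[i]
    if (length(st) != length(en) || length(st) == 0L)
      .stopf("transcript %s: exon start/end lists malformed", id)
    if (any(en <= st))
      .stopf("transcript %s: empty or inverted exon", id)
    if (is.unsorted(st, strictly = TRUE) || any(st[-1] < en[-length(en)]))
      .stopf("transcript %s: exons must be sorted and non-overlapping", id)
    if (!gm$strand[i] %in% c("+", "-"))
      .stopf("transcript %s: strand must be + or -", id)
    if (gm$is_coding[i]) {
      cs <- gm$cds_start[i]; ce <- gm$cds_end[i]
      if (is.na(cs) || is.na(ce) || ce <= cs)
        .stopf("transcript %s: coding transcript needs a valid CDS interval", id)
      in_exon <- function(p) any(p >= st & p < en)
      if (!in_exon(cs) || !in_exon(ce - 1L))
        .stopf("transcript %s: cds outside exons", id)
    } else if (!is.na(gm$cds_start[i]) || !is.na(gm$cds_end[i])) {
      .stopf("transcript %s: non-coding transcript must have empty cds", id)
    }
  }
  class(gm) <- c("gene_models", "data.frame")
  gm
}

#' Read transcript gene models
#'
#' Tab-separated, one transcript per row, 0-based half-open intervals:
#' columns `gene`, `transcript`, `strand`, `exon_starts`, `exon_ends`
#' (comma-separated), `cds_start`, `cds_end` (empty/NA for non-coding
#' transcripts).
#'
#' @param path TSV file.
#' @return Data frame of class `gene_models` with list-columns `exon_starts`
#'   and `exon_ends`, plus `contig`, `gene`, `transcript`, `strand`,
#'   `is_coding`, `cds_start`, `cds_end`.
#' @export
read_gene_models <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = list(exon_starts = "character",
                                      exon_ends = "character"))
  if (nrow(raw) == 0L) {
    gm <- data.frame(contig = character(), gene = character(),
                     transcript = character(), strand = character(),
                     is_coding = logical(), cds_start = integer(),
                     cds_end = integer(), stringsAsFactors = FALSE)
    gm$exon_starts <- list(); gm$exon_ends <- list()
    class(gm) <- c("gene_models", "data.frame")
    return(gm)
  }
  need <- c("contig", "gene", "transcript", "strand",
            "exon_starts", "exon_ends", "cds_start", "cds_end")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    .stopf("gene model file lacks column(s): %s", paste(miss, collapse = ", "))
  gm <- raw[need[1:4]]
  gm$is_coding <- !is.na(raw$cds_start) & raw$cds_start != ""
  gm$cds_start <- suppressWarnings(as.integer(raw$cds_start))
  gm$cds_end <- suppressWarnings(as.integer(raw$cds_end))
  gm$exon_starts <- lapply(raw$exon_starts, parse_int_list)
  gm$exon_ends <- lapply(raw$exon_ends, parse_int_list)
  validate_gene_models(gm)
}

#' Write transcript gene models
#'
#' @param gm A `gene_models` data frame (see [read_gene_models()]).
#' @param path Output TSV path.
#' @export
write_gene_models <- function(gm, path) {
  out <- data.frame(
    contig = gm$contig, gene = gm$gene, transcript = gm$transcript,
    strand = gm$strand,
    exon_starts = vapply(gm$exon_starts, paste, "", collapse = ","),
    exon_ends = vapply(gm$exon_ends, paste, "", collapse = ","),
    cds_start = gm$cds_start, cds_end = gm$cds_end,
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## --- depth bins -------------------------------------------------------------

#' Read a binned depth-of-coverage table
#'
#' Columns: `contig`, `start`, `end` (0-based half-open bins),
#' `depth_father`, `depth_mother`, `depth_proband`.
#'
#' @param path TSV file.
#' @return Data frame of depth bins.
#' @export
read_depth_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "start", "end",
            "depth_father", "depth_mother", "depth_proband")
  miss <- setdiff(need, names(d))
  if (length(miss))
    .stopf("depth table lacks column(s): %s", paste(miss, collapse = ", "))
  if (any(d$end <= d$start)) .stopf("depth table: empty or inverted bin")
  if (any(d[, 4:6] < 0)) .stopf("depth table: negative depth")
  d
}

#' Write a binned depth-of-coverage table
#' @param d Depth-bin data frame (see [read_depth_table()]).
#' @param path Output TSV path.
#' @export
write_depth_table <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## --- known-site catalogs and allele frequencies -----------------------------

#' Read a known-sites catalog
#'
#' A site list standing in for a population catalog (dbSNP-like,
#' 1000G-like, or a local healthy-cohort panel).  TSV columns: `contig`,
#' `pos` (1-based), `ref`, `alt`.  Lookup is by exact allele match.
#'
#' @param path TSV file.
#' @param name Catalog display name.
#' @return Object of class `known_sites` (a keyed site set).
#' @export
read_known_sites <- function(path, name = basename(path)) {
  ## allele columns must never be type-converted ("T" is not a logical)
  d <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("contig", "pos", "ref", "alt")
  miss <- setdiff(need, names(d))
  if (length(miss))
    .stopf("known-sites file lacks column(s): %s", paste(miss, collapse = ", "))
  d$pos <- as.integer(d$pos)
  structure(list(name = name,
                 keys = unique(variant_key(d$contig, d$pos, d$ref, d$alt))),
            class = "known_sites")
}

#' Write a known-sites catalog
#' @param sites Data frame with `contig`, `pos`, `ref`, `alt`.
#' @param path Output TSV path.
#' @export
write_known_sites <- function(sites, path) {
  write.table(sites[, c("contig", "pos", "ref", "alt")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Membership test against a known-sites catalog.
#' @noRd
in_catalog <- function(catalog, contig, pos, ref, alt) {
  variant_key(contig, pos, ref, alt) %in% catalog$keys
}

#' Read a population allele-frequency table
#'
#' TSV columns: `contig`, `pos`, `ref`, `alt`, `population`, `af`.
#' Variants absent from the table are treated as frequency 0 downstream.
#'
#' @param path TSV file.
#' @return Data frame with a precomputed `key` column.
#' @export
read_af_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("contig", "pos", "ref", "alt", "population", "af")
  miss <- setdiff(need, names(d))
  if (length(miss))
    .stopf("AF table lacks column(s): %s", paste(miss, collapse = ", "))
  d$pos <- as.integer(d$pos)
  d$af <- as.numeric(d$af)
  if (any(d$af < 0 | d$af > 1)) .stopf("AF table: af outside [0,1]")
  d$key <- variant_key(d$contig, d$pos, d$ref, d$alt)
  d
}

## --- congener panel ---------------------------------------------------------

#' Read a congener concentration table
#'
#' TSV columns: `congener`, `family` (`PCDD`/`PCDF`/`PCB`), `concentration`
#' (pg/g lipid; NA for non-detects), `detected` (logical),
#' `detection_limit` (pg/g lipid; NA for detected rows).
#'
#' @param path TSV file.
#' @return Data frame of congener measurements.
#' @export
read_congener_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  d$detected <- as.logical(d$detected)
  check_congener_df(d)
  d
}
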