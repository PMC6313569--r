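## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## --- genotype helpers -------------------------------------------------------
## Genotypes are stored as "a/b" strings after multi-allelic decomposition,
## with a,b in {0,1} or "." for missing.  Phase separators are normalized to
## "/" at the I/O boundary; allele order is not meaningful.

#' Split a genotype string into an integer allele vector (NA = missing).
#' @noRd
gt_alleles <- function(gt) {
  a <- strsplit(gt, "[/|]")[[1]]
  suppressWarnings(as.integer(ifelse(a == ".", NA, a)))
}

#' @noRd
gt_called <- function(gt) !grepl("\\.", gt) & nzchar(gt)

#' TRUE when the genotype carries at least one copy of the (single) alt allele.
#' Vectorized over character genotypes.
#' @noRd
gt_has_alt <- function(gt) grepl("1", gt, fixed = TRUE)

#' @noRd
gt_is_het <- function(gt) gt %in% c("0/1", "1/0", "0|1", "1|0")

#' @noRd
gt_is_hom_alt <- function(gt) gt %in% c("1/1", "1|1")

#' @noRd
gt_is_hom_ref <- function(gt) gt %in% c("0/0", "0|0")

#' Canonical site key used by catalogs and allele-frequency tables.
#' @noRd
variant_key <- function(contig, pos, ref, alt) {
  paste(contig, pos, ref, alt, sep = ":")
}

#' Classify a ref/alt pair into SNV / insertion / deletion / mnp.
#' @noRd
variant_type <- function(ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  ifelse(nr == 1L & na == 1L, "SNV",
    ifelse(na > nr, "insertion",
      ifelse(nr > na, "deletion", "mnp")))
}

#' Derive a stage sub-seed from a master seed, kept below 2^31.
#' @noRd
sub_seed <- function(seed, stage) {
  offs <- c(reference = 11L, genes = 23L, inherited = 37L, denovo = 53L,
            compound = 71L, depth = 89L, readsupport = 97L, cnv = 113L,
            pipeline = 131L, genotypes = 151L)
  o <- offs[[stage]]
  as.integer((as.double(seed) * 1009 + o * 9176) %% 2147483647)
}

#' Sample k elements from a vector without R's scalar-expansion trap.
#' @noRd
sample_vec <- function(x, k) x[sample.int(length(x), k)]

#' Empty trio variant table with the canonical column set.
#' @noRd
empty_variants <- function() {
  data.frame(
    contig = character(), pos = integer(), ref = character(),
    alt = character(), vtype = character(),
    gt_father = character(), gt_mother = character(), gt_proband = character(),
    dp_father = integer(), dp_mother = integer(), dp_proband = integer(),
    gq_father = integer(), gq_mother = integer(), gq_proband = integer(),
    rl_proband = integer(), ro_proband = character(),
    af = numeric(),
    stringsAsFactors = FALSE
  )
}
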