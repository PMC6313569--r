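## De novo candidate detection by dual parent-proband comparison, the
## edge-of-read indel artifact filter, and mutation-spectrum statistics.
##
## Detection is deterministic set logic, not a likelihood model: the proband
## is compared with each parent separately, and a variant is a de novo
## candidate only when the proband carries an alt allele absent from BOTH
## parents' called genotypes.  Sites where any trio member fails QC (missing
## genotype, low depth, low genotype quality) are "unevaluable" and never
## counted as de novo, so the candidate count is conservative.

#' Default per-sample genotype QC thresholds.
#' @noRd
default_qc <- function() list(min_dp = 10L, min_gq = 20L)

#' A genotype is evaluable when it is called and passes QC; missing DP/GQ
#' metadata does not fail QC (there is no evidence against the call).
#' @noRd
gt_evaluable <- function(gt, dp, gq, qc) {
  gt_called(gt) &
    (is.na(dp) | dp >= qc$min_dp) &
    (is.na(gq) | gq >= qc$min_gq)
}

#' Single-parent de novo comparison
#'
#' TRUE when the proband carries the alt allele and the parent's genotype
#' does not contain it.  Both genotypes must be called; use
#' [detect_denovo()] for QC-aware site handling.
#'
#' @param parent_gt,proband_gt Genotype strings over alleles `{0,1,.}`.
#' @return Logical vector; NA where either genotype is missing.
#' @export
pairwise_absent <- function(parent_gt, proband_gt) {
  ok <- gt_called(parent_gt) & gt_called(proband_gt)
  out <- gt_has_alt(proband_gt) & !gt_has_alt(parent_gt)
  out[!ok] <- NA
  out
}

#' Edge-of-read indel artifact filter
#'
#' Short indels supported only by the edges of reads (within `edge_margin`
#' bases of the read start or end, boundary inclusive) are typical alignment
#' artifacts and are removed.  An indel is kept iff at least one supporting
#' read places it more than `edge_margin` bases away from both read ends.
#' Indels without read-support metadata are kept, with a warning
#' (conservative).
#'
#' @param variants Trio variant data frame with `rl_proband` (read length)
#'   and `ro_proband` (pipe-separated 0-based offsets of the variant start
#'   within supporting reads).
#' @param edge_margin Edge width in bp (default 10).
#' @return Logical keep flags, one per row (TRUE for non-indels).
#' @export
filter_edge_indels <- function(variants, edge_margin = 10L) {
  keep <- rep(TRUE, nrow(variants))
  idx <- which(variants$vtype %in% c("insertion", "deletion"))
  warned <- FALSE
  for (k in idx) {
    ro <- variants$ro_proband[k]
    rl <- variants$rl_proband[k]
    if (is.na(ro) || is.na(rl)) {
      if (!warned) {
        .warnf("indel(s) without read-support metadata kept unfiltered")
        warned <- TRUE
      }
      next
    }
    off <- as.integer(strsplit(ro, "|", fixed = TRUE)[[1]])
    central <- off > edge_margin & (rl - 1L - off) > edge_margin
    keep[k] <- any(central)
  }
  keep
}

#' Detect de novo candidate variants in a trio
#'
#' A site is a candidate iff the proband's alt allele is absent from the
#' mother (comparison 1) AND absent from the father (comparison 2); indel
#' candidates must additionally survive the edge-of-read filter.  Sites
#' where any sample fails QC are flagged unevaluable and excluded.
#'
#' @param variants Trio variant data frame, ideally pre-annotated with
#'   [annotate_variants()] so candidates carry region/CpG/transition flags.
#' @param qc List with `min_dp` and `min_gq` (defaults 10 and 20).
#' @param edge_margin Edge width for the indel filter (bp).
#' @return The candidate subset of `variants`, with an `unevaluable`
#'   attribute giving the number of sites excluded by QC.
#' @export
detect_denovo <- function(variants, qc = default_qc(), edge_margin = 10L) {
  v <- variants
  ev <- gt_evaluable(v$gt_father, v$dp_father, v$gq_father, qc) &
        gt_evaluable(v$gt_mother, v$dp_mother, v$gq_mother, qc) &
        gt_evaluable(v$gt_proband, v$dp_proband, v$gq_proband, qc)
  vs_father <- pairwise_absent(v$gt_father, v$gt_proband)
  vs_mother <- pairwise_absent(v$gt_mother, v$gt_proband)
  cand <- ev & !is.na(vs_father) & !is.na(vs_mother) & vs_father & vs_mother
  out <- v[cand, , drop = FALSE]
  keep <- filter_edge_indels(out, edge_margin = edge_margin)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unevaluable") <- sum(!ev)
  out
}

#' De novo mutation spectrum
#'
#' Counts, transition/transversion ratio, CpG-context proportion and the
#' per-nucleotide per-generation rate of a de novo candidate set.  The rate
#' is `n_total / (2 * L)`: each generation transmits two haploid genomes of
#' length `L`.
#'
#' @param candidates Annotated de novo candidate data frame (needs
#'   `vtype`, `is_transition`, `is_cpg`).
#' @param L Haploid genome length in bp.  The default is the hg19 total
#'   assembly length; real analyses should pass their callable length.
#' @return Object of class `mutation_spectrum`.
#' @export
mutation_spectrum <- function(candidates, L = 3137161264) {
  snv <- candidates$vtype == "SNV"
  n_ts <- sum(candidates$is_transition[snv], na.rm = TRUE)
  n_tv <- sum(!candidates$is_transition[snv], na.rm = TRUE)
  n_cpg <- sum(candidates$is_cpg[snv], na.rm = TRUE)
  n_total <- nrow(candidates)
  structure(list(
    n_total = n_total,
    n_snv = sum(snv),
    n_indel = sum(!snv),
    n_cpg = n_cpg,
    n_transition = n_ts,
    n_transversion = n_tv,
    titv = if (n_tv > 0) n_ts / n_tv else NA_real_,
    cpg_proportion = if (sum(snv) > 0) n_cpg / sum(snv) else NA_real_,
    rate = n_total / (2 * L),
    genome_length = L
  ), class = "mutation_spectrum")
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat(sprintf("De novo spectrum: %d candidates (%d SNV, %d indel)\n",
              x$n_total, x$n_snv, x$n_indel))
  cat(sprintf("  Ts/Tv: %d/%d%s\n", x$n_transition, x$n_transversion,
              if (is.na(x$titv)) " (undefined)"
              else sprintf(" = %.1f", x$titv)))
  cat(sprintf("  CpG-context: %d/%d%s\n", x$n_cpg, x$n_snv,
              if (is.na(x$cpg_proportion)) ""
              else sprintf(" = %.2f", x$cpg_proportion)))
  cat(sprintf("  rate: %.3g per nucleotide per generation (L = %.0f bp)\n",
              x$rate, x$genome_length))
  invisible(x)
}
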