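## Recessive-model filtering: compound heterozygosity with parental-origin
## assignment, homozygous-recessive calls, and population allele-frequency
## exclusion.
##
## Phasing is by transmission, not by reads: a proband heterozygote is
## paternal-only when the father carries the alt allele and the mother does
## not (and vice versa).  A compound-heterozygous gene requires one
## paternal-only and one maternal-only variant (trans configuration) — a cis
## pair inherited from one parent leaves one intact gene copy and is not a
## recessive hit.  Alleles present in both parents have ambiguous origin and
## are excluded from pairing.

## Effects accepted under the recessive model: non-synonymous SNVs, coding
## indels, and splice-site variants.
.RECESSIVE_EFFECTS <- c("missense", "nonsense", "frameshift",
                        "inframe_indel", "splice_site")

#' Functional-effect filter for the recessive model
#'
#' @param effect Character vector of coding effects.
#' @return TRUE for non-synonymous SNVs, coding indels and splice-site
#'   variants.
#' @export
effect_filter <- function(effect) {
  !is.na(effect) & effect %in% .RECESSIVE_EFFECTS
}

#' Population allele-frequency filter
#'
#' @param af_max Max allele frequency across populations (0 for variants
#'   with no frequency record; NA is treated as 0).
#' @param threshold Maximum tolerated frequency (default 0.01).
#' @param in_panel Optional logical: presence in a local healthy-cohort
#'   panel excludes the variant regardless of frequency.
#' @return Logical pass flags.
#' @export
frequency_filter <- function(af_max, threshold = 0.01, in_panel = NULL) {
  af_max[is.na(af_max)] <- 0
  pass <- af_max <= threshold
  if (!is.null(in_panel)) pass <- pass & !in_panel
  pass
}

#' @noRd
recessive_pass <- function(v, max_af, panel) {
  af <- if ("af_max" %in% names(v)) v$af_max else v$af
  in_panel <- if (!is.null(panel))
    in_catalog(panel, v$contig, v$pos, v$ref, v$alt) else NULL
  effect_filter(v$effect) & frequency_filter(af, max_af, in_panel)
}

#' Parental origin of a proband heterozygote.
#' @noRd
variant_origin <- function(v) {
  pat <- gt_has_alt(v$gt_father)
  mat <- gt_has_alt(v$gt_mother)
  ifelse(pat & mat, "ambiguous",
    ifelse(pat, "paternal", ifelse(mat, "maternal", "neither")))
}

#' Find compound-heterozygous genes
#'
#' For each gene, reports every variant pair with one paternal-only and one
#' maternal-only proband heterozygote (trans configuration), both passing
#' the effect and frequency filters.  Variants whose alt allele is present
#' in both parents have ambiguous origin and never pair.
#'
#' @param variants Annotated trio variant data frame (needs `gene`,
#'   `effect`, genotype columns, and `af_max` or `af`).
#' @param max_af Frequency threshold passed to [frequency_filter()].
#' @param panel Optional `known_sites` healthy-cohort panel; panel members
#'   are excluded.
#' @return Data frame with one row per (gene, paternal variant, maternal
#'   variant) pair.
#' @export
find_compound_het <- function(variants, max_af = 0.01, panel = NULL) {
  v <- variants
  empty <- data.frame(gene = character(),
                      contig = character(),
                      pos_paternal = integer(), pos_maternal = integer(),
                      aa_paternal = character(), aa_maternal = character(),
                      effect_paternal = character(),
                      effect_maternal = character(),
                      stringsAsFactors = FALSE)
  if (nrow(v) == 0L) return(empty)
  keep <- !is.na(v$gene) & gt_is_het(v$gt_proband) &
    recessive_pass(v, max_af, panel)
  v <- v[keep, , drop = FALSE]
  if (nrow(v) == 0L) return(empty)
  v$origin <- variant_origin(v)
  v <- v[v$origin %in% c("paternal", "maternal"), , drop = FALSE]
  out <- empty
  for (g in unique(v$gene)) {
    vg <- v[v$gene == g, , drop = FALSE]
    pat <- vg[vg$origin == "paternal", , drop = FALSE]
    mat <- vg[vg$origin == "maternal", , drop = FALSE]
    if (nrow(pat) == 0L || nrow(mat) == 0L) next
    for (i in seq_len(nrow(pat))) for (j in seq_len(nrow(mat))) {
      out <- rbind(out, data.frame(
        gene = g, contig = pat$contig[i],
        pos_paternal = pat$pos[i], pos_maternal = mat$pos[j],
        aa_paternal = pat$aa_change[i] %||% NA_character_,
        aa_maternal = mat$aa_change[j] %||% NA_character_,
        effect_paternal = pat$effect[i], effect_maternal = mat$effect[j],
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Find homozygous-recessive candidate variants
#'
#' Proband homozygous-alt with both parents heterozygous, passing the
#' effect and frequency filters.
#'
#' @inheritParams find_compound_het
#' @return Subset of `variants`.
#' @export
find_homozygous_recessive <- function(variants, max_af = 0.01, panel = NULL) {
  v <- variants
  if (nrow(v) == 0L) return(v)
  keep <- gt_is_hom_alt(v$gt_proband) &
    gt_is_het(v$gt_father) & gt_is_het(v$gt_mother) &
    recessive_pass(v, max_af, panel)
  out <- v[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
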