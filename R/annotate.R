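## Region classification, coding effect, and sequence-context features.

## Category precedence when a variant hits several transcripts/features.
## The rarest, most diagnostically relevant categories win.
.REGION_LEVELS <- c("splicing", "exonic", "UTR5", "UTR3", "ncRNA_exonic",
                    "intronic", "ncRNA_intronic", "intergenic")

## Effect severity used for the per-gene "most severe transcript" choice.
.EFFECT_SEVERITY <- c("nonsense", "frameshift", "splice_site", "missense",
                      "inframe_indel", "synonymous")

## Width of the splice region: intronic positions within this many bases of
## an exon boundary (the canonical splice dinucleotides) are "splicing".
.SPLICE_WIDTH <- 2L

#' First reference base altered by a variant (1-based).
#' Indels use the VCF anchor-base convention: the change starts one base
#' after `pos`.
#' @noRd
effective_pos <- function(pos, vtype) {
  ifelse(vtype %in% c("insertion", "deletion"), pos + 1L, pos)
}

#' Classify one position against one transcript model row.
#' @noRd
region_in_transcript <- function(p0, gm, i) {
  ## p0: 0-based position of the first altered base
  st <- gm$exon_starts[[i]]; en <- gm$exon_ends[[i]]
  if (p0 < st[1] || p0 >= en[length(en)]) return(NA_character_)
  in_ex <- any(p0 >= st & p0 < en)
  if (!gm$is_coding[i]) {
    return(if (in_ex) "ncRNA_exonic" else "ncRNA_intronic")
  }
  if (in_ex) {
    if (p0 >= gm$cds_start[i] && p0 < gm$cds_end[i]) return("exonic")
    left_of_cds <- p0 < gm$cds_start[i]
    if (gm$strand[i] == "+") return(if (left_of_cds) "UTR5" else "UTR3")
    return(if (left_of_cds) "UTR3" else "UTR5")
  }
  ## intronic: distance to the nearest exon boundary
  d <- min(abs(c(p0 - (en - 1L), p0 - st)))
  if (d <= .SPLICE_WIDTH) "splicing" else "intronic"
}

#' Classify variants by genomic region
#'
#' Assigns exactly one region category per variant against a gene-model set,
#' with precedence `splicing > exonic > UTR5 > UTR3 > ncRNA_exonic >
#' intronic > ncRNA_intronic > intergenic` across overlapping transcripts.
#' Variants overlapping no transcript are `intergenic`.
#'
#' @param variants Trio variant data frame (or any data frame with `contig`,
#'   `pos`, `vtype`).
#' @param models A `gene_models` data frame.
#' @return Character vector of region categories, one per variant row.
#' @export
classify_region <- function(variants, models) {
  assign_transcripts(variants, models)$best$region
}

#' Per-variant transcript assignment.
#' Returns `best` (winning region/gene/transcript per variant, by region
#' precedence then transcript name) and `hits` (all variant x transcript
#' categories), so callers can apply most-severe-effect selection among
#' transcripts tied at the winning region.
#' @noRd
assign_transcripts <- function(variants, models) {
  n <- nrow(variants)
  best <- data.frame(region = rep("intergenic", n),
                     gene = rep(NA_character_, n),
                     transcript = rep(NA_character_, n),
                     tx_row = rep(NA_integer_, n), stringsAsFactors = FALSE)
  hits_df <- data.frame(vi = integer(), ti = integer(), cat = character(),
                        stringsAsFactors = FALSE)
  if (n == 0L || nrow(models) == 0L)
    return(list(best = best, hits = hits_df))

  p <- effective_pos(variants$pos, variants$vtype)
  span_start <- vapply(models$exon_starts, function(x) x[1], 0L)
  span_end <- vapply(models$exon_ends, function(x) x[length(x)], 0L)
  tx_gr <- GRanges(models$contig, IRanges(span_start + 1L, span_end))
  v_gr <- GRanges(variants$contig, IRanges(p, p))
  hits <- findOverlaps(v_gr, tx_gr)
  vi <- queryHits(hits); ti <- subjectHits(hits)
  if (length(vi)) {
    cat <- character(length(vi))
    for (k in seq_along(vi))
      cat[k] <- region_in_transcript(p[vi[k]] - 1L, models, ti[k])
    ord <- order(vi, match(cat, .REGION_LEVELS), models$transcript[ti])
    sel <- ord[!duplicated(vi[ord])]
    best$region[vi[sel]] <- cat[sel]
    best$gene[vi[sel]] <- models$gene[ti[sel]]
    best$transcript[vi[sel]] <- models$transcript[ti[sel]]
    best$tx_row[vi[sel]] <- ti[sel]
    hits_df <- data.frame(vi = vi, ti = ti, cat = cat,
                          stringsAsFactors = FALSE)
  }
  list(best = best, hits = hits_df)
}

#' 0-based genomic positions of a transcript's coding bases, 5' to 3'.
#' @noRd
cds_genomic_positions <- function(gm, i) {
  st <- gm$exon_starts[[i]]; en <- gm$exon_ends[[i]]
  cs <- gm$cds_start[i]; ce <- gm$cds_end[i]
  pos <- unlist(lapply(seq_along(st), function(e) {
    a <- max(st[e], cs); b <- min(en[e], ce)
    if (b > a) seq.int(a, b - 1L) else integer()
  }))
  if (gm$strand[i] == "-") rev(pos) else pos
}

#' @noRd
.comp <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

#' Coding effect of a variant on one transcript
#'
#' Maps the variant into CDS coordinates with strand handling, extracts the
#' affected codon, and applies the standard genetic code.  In-frame coding
#' indels (length divisible by 3) are `inframe_indel`; others `frameshift`.
#'
#' @param v One-row variant data frame (`contig`, `pos`, `ref`, `alt`,
#'   `vtype`).
#' @param model A `gene_models` data frame; `tx` selects the transcript row.
#' @param reference Named character vector or DNAStringSet of contig
#'   sequences.
#' @param tx Row index of the transcript in `model` (default 1).
#' @return List with `effect`, `aa_pos`, `ref_aa`, `alt_aa`, `aa_change`
#'   (e.g. `"R502W"`; `NA` for indels).
#' @export
coding_effect <- function(v, model, reference, tx = 1L) {
  if (!is.character(reference)) reference <- as.character(reference)
  seqstr <- reference[[v$contig]]
  ## reference/VCF consistency check
  obs <- substring(seqstr, v$pos, v$pos + nchar(v$ref) - 1L)
  if (toupper(obs) != toupper(v$ref))
    .stopf("reference mismatch at %s:%d: VCF ref '%s', reference '%s'",
           v$contig, v$pos, v$ref, obs)

  cds_pos <- cds_genomic_positions(model, tx)
  strand <- model$strand[tx]

  if (v$vtype %in% c("insertion", "deletion")) {
    shift <- abs(nchar(v$ref) - nchar(v$alt))
    eff <- if (shift %% 3L == 0L) "inframe_indel" else "frameshift"
    return(list(effect = eff, aa_pos = NA_integer_, ref_aa = NA_character_,
                alt_aa = NA_character_, aa_change = NA_character_))
  }
  if (v$vtype != "SNV") .stopf("coding_effect handles SNVs and indels only")

  ci <- match(v$pos - 1L, cds_pos)   # 1-based index into the CDS
  if (is.na(ci))
    .stopf("variant %s:%d is not in the CDS of transcript %s",
           v$contig, v$pos, model$transcript[tx])
  codon_i <- (ci - 1L) %/% 3L
  codon_cds <- codon_i * 3L + 1:3
  codon_gpos <- cds_pos[codon_cds]
  bases <- toupper(substring(seqstr, codon_gpos + 1L, codon_gpos + 1L))
  if (strand == "-") bases <- .comp(bases)
  ref_codon <- paste(bases, collapse = "")
  off <- ci - codon_i * 3L           # 1..3 within codon
  alt_base <- toupper(v$alt)
  if (strand == "-") alt_base <- .comp(alt_base)
  alt_bases <- bases
  alt_bases[off] <- alt_base
  alt_codon <- paste(alt_bases, collapse = "")
  ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
  alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
  effect <- if (ref_aa == alt_aa) "synonymous"
            else if (alt_aa == "*") "nonsense"
            else "missense"
  aa_pos <- codon_i + 1L
  list(effect = effect, aa_pos = aa_pos, ref_aa = ref_aa, alt_aa = alt_aa,
       aa_change = if (effect == "synonymous") NA_character_
                   else paste0(ref_aa, aa_pos, alt_aa))
}

#' CpG dinucleotide context of SNVs
#'
#' TRUE when the reference dinucleotide at (pos, pos+1) or (pos-1, pos) is
#' CG; contig edges contribute FALSE on the missing side.  The definition is
#' strand-symmetric: both the C and the G of a CpG are in context.
#'
#' @param variants Data frame with `contig`, `pos`, `vtype`.
#' @param reference Named character vector or DNAStringSet of contig
#'   sequences.
#' @return Logical vector (NA for non-SNVs).
#' @export
cpg_context <- function(variants, reference) {
  if (!is.character(reference)) reference <- as.character(reference)
  n <- nrow(variants)
  out <- rep(NA, n)
  for (ct in unique(variants$contig)) {
    i <- which(variants$contig == ct & variants$vtype == "SNV")
    if (!length(i)) next
    s <- reference[[ct]]
    pos <- variants$pos[i]
    right <- toupper(substring(s, pos, pos + 1L)) == "CG"
    left <- pos > 1L & toupper(substring(s, pmax(pos - 1L, 1L), pos)) == "CG"
    out[i] <- right | left
  }
  out
}

#' Transition flag for SNVs
#'
#' TRUE for transitions (A<->G, C<->T), FALSE for transversions.
#'
#' @param ref,alt Single-base allele vectors.
#' @return Logical vector.
#' @export
transition_flag <- function(ref, alt) {
  if (any(nchar(ref) != 1L | nchar(alt) != 1L))
    .stopf("transition_flag is defined for SNVs only")
  pur <- c("A", "G")
  (toupper(ref) %in% pur) == (toupper(alt) %in% pur) &
    toupper(ref) != toupper(alt)
}

#' Annotate trio variants
#'
#' Adds region category, winning gene/transcript, coding effect, amino-acid
#' change, CpG-context flag and transition flag to a trio variant table.
#' The winning transcript is chosen by region precedence, then effect
#' severity, then transcript name (deterministic tie-break).
#'
#' @param variants Trio variant data frame.
#' @param reference Named character vector or DNAStringSet.
#' @param models A `gene_models` data frame.
#' @param af_table Optional allele-frequency table ([read_af_table()]); adds
#'   an `af_max` column (max across populations; 0 when absent).
#' @return The variant data frame with annotation columns appended.
#' @export
annotate_variants <- function(variants, reference, models, af_table = NULL) {
  if (!is.character(reference)) reference <- as.character(reference)
  at <- assign_transcripts(variants, models)
  ann <- at$best
  v <- variants
  v$region <- ann$region
  v$gene <- ann$gene
  v$transcript <- ann$transcript
  v$effect <- NA_character_
  v$aa_change <- NA_character_

  v$effect[v$region == "splicing"] <- "splice_site"
  for (k in which(v$region == "exonic")) {
    ## all transcripts for which this variant is exonic; keep the most
    ## severe effect, tie-break by transcript name
    cand <- at$hits$ti[at$hits$vi == k & at$hits$cat == "exonic"]
    cand <- cand[order(models$transcript[cand])]
    eff <- lapply(cand, function(ti)
      coding_effect(v[k, , drop = FALSE], models, reference, tx = ti))
    sev <- vapply(eff, function(e) match(e$effect, .EFFECT_SEVERITY), 0L)
    pick <- which.min(sev)
    v$effect[k] <- eff[[pick]]$effect
    v$aa_change[k] <- eff[[pick]]$aa_change
    v$gene[k] <- models$gene[cand[pick]]
    v$transcript[k] <- models$transcript[cand[pick]]
  }

  v$is_cpg <- cpg_context(v, reference)
  v$is_transition <- rep(NA, nrow(v))
  snv <- v$vtype == "SNV"
  if (any(snv))
    v$is_transition[snv] <- transition_flag(v$ref[snv], v$alt[snv])

  if (!is.null(af_table)) {
    key <- variant_key(v$contig, v$pos, v$ref, v$alt)
    tk <- af_table$key %||% variant_key(af_table$contig, af_table$pos,
                                        af_table$ref, af_table$alt)
    mx <- tapply(af_table$af, tk, max)
    v$af_max <- unname(ifelse(key %in% names(mx), mx[key], 0))
  }
  v
}
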