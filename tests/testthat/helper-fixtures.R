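# Shared fixture builders.  Everything is constructed in code; no binary
# fixtures are stored.

# Trio variant rows with all canonical columns filled with passing defaults.
make_variants <- function(contig, pos, ref, alt,
                          gt_father = "0/0", gt_mother = "0/0",
                          gt_proband = "0/1",
                          dp = 30L, gq = 99L,
                          rl_proband = NA_integer_,
                          ro_proband = NA_character_,
                          af = NA_real_) {
  n <- max(lengths(list(contig, pos, ref, alt)))
  data.frame(
    contig = rep_len(contig, n), pos = rep_len(as.integer(pos), n),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    vtype = trioscan:::variant_type(rep_len(ref, n), rep_len(alt, n)),
    gt_father = rep_len(gt_father, n), gt_mother = rep_len(gt_mother, n),
    gt_proband = rep_len(gt_proband, n),
    dp_father = rep_len(dp, n), dp_mother = rep_len(dp, n),
    dp_proband = rep_len(dp, n),
    gq_father = rep_len(gq, n), gq_mother = rep_len(gq, n),
    gq_proband = rep_len(gq, n),
    rl_proband = rep_len(rl_proband, n),
    ro_proband = rep_len(ro_proband, n),
    af = rep_len(af, n),
    stringsAsFactors = FALSE)
}

# One-transcript gene model table from plain vectors.
make_gene_models <- function(contig, gene, strand, exon_starts, exon_ends,
                             cds_start = NA_integer_,
                             cds_end = NA_integer_) {
  gm <- data.frame(contig = contig, gene = gene,
                   transcript = paste0(gene, ".t1"), strand = strand,
                   is_coding = !is.na(cds_start),
                   cds_start = as.integer(cds_start),
                   cds_end = as.integer(cds_end),
                   stringsAsFactors = FALSE)
  gm$exon_starts <- list(as.integer(exon_starts))
  gm$exon_ends <- list(as.integer(exon_ends))
  trioscan:::validate_gene_models(gm)
}

rbind_models <- function(...) {
  gm <- do.call(rbind, list(...))
  trioscan:::validate_gene_models(gm)
}

# A 200-codon single-exon plus-strand toy gene with no internal stops,
# plus its reference contig.  Returns list(reference, models).
toy_coding_gene <- function(seed = 11, n_codons = 200L, offset = 100L,
                            strand = "+") {
  set.seed(seed)
  # codons without stop triplets
  codons <- c()
  aa_ok <- setdiff(names(Biostrings::GENETIC_CODE),
                   names(which(Biostrings::GENETIC_CODE == "*")))
  start_codon <- "ATG"
  codons <- c(start_codon, sample(aa_ok, n_codons - 2L, replace = TRUE), "TAA")
  cds <- paste(codons, collapse = "")
  flank5 <- paste(sample(c("A", "C", "G", "T"), offset, replace = TRUE),
                  collapse = "")
  flank3 <- paste(sample(c("A", "C", "G", "T"), offset, replace = TRUE),
                  collapse = "")
  if (strand == "-") {
    cds_genomic <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  } else cds_genomic <- cds
  seq <- paste0(flank5, cds_genomic, flank3)
  L <- nchar(seq)
  cds_start <- offset                  # 0-based
  cds_end <- offset + nchar(cds)
  gm <- make_gene_models("chrT", "TOY", strand,
                         exon_starts = cds_start - 20L,
                         exon_ends = cds_end + 20L,
                         cds_start = cds_start, cds_end = cds_end)
  list(reference = c(chrT = seq), models = gm, cds = cds,
       cds_start = cds_start, cds_end = cds_end)
}

# Full-CDS retranslation oracle: rebuild the CDS with the variant applied,
# translate both, and classify the difference.  Independent of the codon
# arithmetic in coding_effect().
oracle_coding_effect <- function(v, fix) {
  seq <- fix$reference[["chrT"]]
  gm <- fix$models
  p0 <- v$pos - 1L
  stopifnot(p0 >= gm$cds_start, p0 < gm$cds_end)
  ref_cds <- fix$cds
  idx_fwd <- p0 - gm$cds_start               # 0-based within genomic CDS
  alt_seq <- paste0(substring(seq, 1, v$pos - 1L), v$alt,
                    substring(seq, v$pos + nchar(v$ref), nchar(seq)))
  alt_cds_genomic <- substring(alt_seq, gm$cds_start + 1L,
                               gm$cds_end - (nchar(v$ref) - nchar(v$alt)))
  if (gm$strand == "-") {
    alt_cds <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(alt_cds_genomic)))
  } else alt_cds <- alt_cds_genomic
  shift <- abs(nchar(v$ref) - nchar(v$alt))
  if (shift > 0) {
    return(if (shift %% 3 == 0) "inframe_indel" else "frameshift")
  }
  tr <- function(s) as.character(Biostrings::translate(
    Biostrings::DNAString(s), if.fuzzy.codon = "X", no.init.codon = TRUE))
  aa_ref <- tr(ref_cds)
  aa_alt <- tr(alt_cds)
  if (aa_ref == aa_alt) return("synonymous")
  d <- which(strsplit(aa_ref, "")[[1]] != strsplit(aa_alt, "")[[1]])[1]
  if (substring(aa_alt, d, d) == "*") "nonsense" else "missense"
}

# Small, fast simulation config for unit tests; ... overrides defaults.
mini_sim_config <- function(seed = 7, ...) {
  defaults <- list(seed = seed,
                   contigs = c(chr1 = 200000L, chr2 = 150000L),
                   n_genes = 12L, n_inherited_variants = 500L,
                   n_denovo_snv = 12L, n_denovo_indel = 1L,
                   n_denovo_exonic = 2L,
                   cpg_fraction = 0.25, ts_fraction = 0.66,
                   compound_het_genes = 1L, n_artifact_indels = 1L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Mendelian-consistency audit of a genotype triple: is there an assignment
# of one proband allele to each parent such that each is carried by that
# parent?  Exhaustive over the two assignments.
mendelian_consistent <- function(gt_father, gt_mother, gt_proband) {
  al <- function(g) trioscan:::gt_alleles(g)
  f <- al(gt_father); m <- al(gt_mother); p <- al(gt_proband)
  if (anyNA(c(f, m, p))) return(NA)
  (p[1] %in% f && p[2] %in% m) || (p[2] %in% f && p[1] %in% m)
}

# Exhaustive best-arc oracle: scan every admissible (i, j) pair directly.
cbs_oracle_best <- function(x, min_w = 3L) {
  n <- length(x)
  S <- c(0, cumsum(x)); Q <- c(0, cumsum(x^2))
  best <- list(t = 0, i = -1L, j = -1L)
  for (i in 0:(n - 1)) {
    if (i != 0 && i < min_w) next
    for (j in (i + 1):n) {
      k <- j - i; m <- n - k
      if (k < min_w || m < min_w) next
      if (j != n && n - j < min_w) next
      sa <- S[j + 1] - S[i + 1]; sb <- S[n + 1] - sa
      qa <- Q[j + 1] - Q[i + 1]; qb <- Q[n + 1] - qa
      ma <- sa / k; mb <- sb / m
      ssw <- (qa - k * ma^2) + (qb - m * mb^2)
      t <- if (ssw <= 1e-12) {
        if (abs(ma - mb) <= 1e-12) 0 else Inf
      } else abs(ma - mb) / sqrt(ssw / (n - 2) * (1 / k + 1 / m))
      if (t > best$t) best <- list(t = t, i = i, j = j)
    }
  }
  best
}

# Boundary set induced by an arc split (the arc and its complement induce
# the same split, so argmax comparisons must be representation-free).
split_boundaries <- function(b, n) setdiff(c(b$i, b$j), c(0L, n))

# Brute-force compound-het oracle: enumerate every variant pair in every
# gene and apply the definitional predicates directly.
oracle_compound_het <- function(v, max_af = 0.01) {
  af <- if ("af_max" %in% names(v)) v$af_max else v$af
  af[is.na(af)] <- 0
  out <- NULL
  has <- function(g) grepl("1", g, fixed = TRUE)
  ok <- !is.na(v$gene) &
    v$gt_proband %in% c("0/1", "1/0") &
    !is.na(v$effect) &
    v$effect %in% c("missense", "nonsense", "frameshift", "inframe_indel",
                    "splice_site") &
    af <= max_af
  idx <- which(ok)
  for (a in idx) for (b in idx) {
    if (a == b || v$gene[a] != v$gene[b]) next
    pat_a <- has(v$gt_father[a]) && !has(v$gt_mother[a])
    mat_b <- has(v$gt_mother[b]) && !has(v$gt_father[b])
    if (pat_a && mat_b)
      out <- rbind(out, data.frame(gene = v$gene[a],
                                   pos_paternal = v$pos[a],
                                   pos_maternal = v$pos[b],
                                   stringsAsFactors = FALSE))
  }
  out
}
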