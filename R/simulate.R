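## Seeded synthetic trio-data generator.
##
## Emits a Mendelian-consistent trio world: reference FASTA, transcript gene
## models, trio VCF (father, mother, proband), known-site catalogs, allele
## frequency table, binned depth profile, and a machine-readable truth table
## of every planted event (de novo SNV/indel, trans compound heterozygotes,
## CNVs).  Everything is driven by one master seed; each stage draws from
## its own derived sub-stream, so adding events to one stage does not
## shuffle the draws of another.
##
## Planted variant positions are kept >= 8 bp apart and away from exon
## boundaries (non-exonic events), so CpG-context planting and deletion
## alleles never interact with neighbouring events or categories.

.MIN_SPACING <- 8L

#' Simulation configuration
#'
#' @param seed Master seed (integer).
#' @param contigs Named integer vector of contig lengths (bp).
#' @param n_genes Number of transcripts to place.
#' @param n_inherited_variants Mendelian-inherited sites segregating in the
#'   parents.
#' @param n_denovo_snv,n_denovo_indel Planted de novo events (heterozygous
#'   in the proband, absent from both parents).
#' @param n_denovo_exonic How many of the de novo SNVs fall in coding exons.
#' @param cpg_fraction Fraction of de novo SNVs planted in CpG context.
#' @param ts_fraction Fraction of de novo SNVs that are transitions.
#' @param compound_het_genes Genes carrying a planted trans-configured
#'   missense pair.
#' @param n_artifact_indels De novo-looking indels supported only by read
#'   edges (removed by the edge filter; not truth events).
#' @param cnv_events Data frame `contig`, `start`, `end` (0-based
#'   half-open), `child_copies`, `parent_copies`; NULL for none.
#' @param bin_size Depth bin width (bp).
#' @param depth_mean Mean autosomal read depth at copy number 2.
#' @param depth_noise_sd Depth noise SD at copy number 2; scales with
#'   `sqrt(copy/2)` so a homozygous deletion has exactly zero depth.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       contigs = c(chr1 = 1200000L, chr2 = 800000L),
                       n_genes = 60L,
                       n_inherited_variants = 12000L,
                       n_denovo_snv = 92L,
                       n_denovo_indel = 1L,
                       n_denovo_exonic = 3L,
                       cpg_fraction = 18 / 92,
                       ts_fraction = 62 / 94,
                       compound_het_genes = 2L,
                       n_artifact_indels = 1L,
                       cnv_events = NULL,
                       bin_size = 1000L,
                       depth_mean = 30,
                       depth_noise_sd = 3) {
  cfg <- list(seed = as.integer(seed), contigs = contigs, n_genes = n_genes,
              n_inherited_variants = n_inherited_variants,
              n_denovo_snv = n_denovo_snv, n_denovo_indel = n_denovo_indel,
              n_denovo_exonic = n_denovo_exonic,
              cpg_fraction = cpg_fraction, ts_fraction = ts_fraction,
              compound_het_genes = compound_het_genes,
              n_artifact_indels = n_artifact_indels,
              cnv_events = cnv_events, bin_size = as.integer(bin_size),
              depth_mean = depth_mean, depth_noise_sd = depth_noise_sd)
  validate_sim_config(cfg)
}

#' @noRd
validate_sim_config <- function(cfg) {
  if (is.null(names(cfg$contigs)) || any(!nzchar(names(cfg$contigs))))
    .stopf("contigs must be a named vector of lengths")
  if (any(cfg$contigs < 10L * cfg$bin_size))
    .stopf("every contig must be at least 10 bins long")
  if (cfg$n_denovo_exonic > cfg$n_denovo_snv + cfg$n_denovo_indel)
    .stopf("n_denovo_exonic exceeds the number of de novo events")
  if (cfg$n_denovo_exonic > cfg$n_denovo_snv)
    .stopf("exonic de novo events are drawn from the SNVs; n_denovo_exonic must be <= n_denovo_snv")
  if (cfg$cpg_fraction < 0 || cfg$cpg_fraction > 1 ||
      cfg$ts_fraction < 0 || cfg$ts_fraction > 1)
    .stopf("cpg_fraction and ts_fraction must lie in [0,1]")
  ev <- cfg$cnv_events
  if (!is.null(ev) && nrow(ev)) {
    need <- c("contig", "start", "end", "child_copies", "parent_copies")
    if (!all(need %in% names(ev)))
      .stopf("cnv_events needs columns: %s", paste(need, collapse = ", "))
    if (any(!ev$contig %in% names(cfg$contigs)))
      .stopf("cnv_events reference unknown contig")
    if (any(ev$start < 0 | ev$end > cfg$contigs[ev$contig]))
      .stopf("cnv_events outside contig bounds")
    if (any(ev$end <= ev$start)) .stopf("cnv_events: empty interval")
    for (ct in unique(ev$contig)) {
      e <- ev[ev$contig == ct, , drop = FALSE]
      e <- e[order(e$start), , drop = FALSE]
      if (nrow(e) > 1L && any(e$start[-1] < e$end[-nrow(e)]))
        .stopf("cnv_events must be non-overlapping per contig")
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Built-in simulation presets
#'
#' `paper_trio`: a two-contig 2-Mb genome with 12,000 Mendelian-inherited
#' sites and 93 planted de novo events (92 SNVs + one 5-bp non-coding
#' deletion), 3 of them in coding exons, 18 SNVs in CpG context, a
#' transition fraction of 62/94, two trans compound-heterozygous missense
#' gene pairs, and one edge-supported artifact indel.
#'
#' `paper_cnv`: a 5-Mb contig of 1-kb depth bins carrying a 150-kb and a
#' 10-kb deletion, both homozygous in the child and hemizygous in each
#' parent, at 30x mean coverage.
#'
#' @param name `"paper_trio"` or `"paper_cnv"`.
#' @param seed Master seed (default 42).
#' @return A `sim_config`.
#' @export
sim_preset <- function(name = c("paper_trio", "paper_cnv"), seed = 42L) {
  name <- match.arg(name)
  switch(name,
    paper_trio = sim_config(seed = seed),
    paper_cnv = sim_config(
      seed = seed,
      contigs = c(chr1 = 5000000L),
      n_genes = 0L, n_inherited_variants = 0L,
      n_denovo_snv = 0L, n_denovo_indel = 0L, n_denovo_exonic = 0L,
      compound_het_genes = 0L, n_artifact_indels = 0L,
      cnv_events = data.frame(
        contig = c("chr1", "chr1"),
        start = c(1040000L, 3580000L),
        end = c(1190000L, 3590000L),
        child_copies = c(0L, 0L),
        parent_copies = c(1L, 1L),
        stringsAsFactors = FALSE),
      bin_size = 1000L, depth_mean = 30, depth_noise_sd = 3))
}

## --- gene placement ---------------------------------------------------------

#' @noRd
simulate_gene_models <- function(cfg) {
  set.seed(sub_seed(cfg$seed, "genes"))
  gm <- NULL
  if (cfg$n_genes == 0L) {
    gm <- data.frame(contig = character(), gene = character(),
                     transcript = character(), strand = character(),
                     is_coding = logical(), cds_start = integer(),
                     cds_end = integer(), stringsAsFactors = FALSE)
    gm$exon_starts <- list(); gm$exon_ends <- list()
    class(gm) <- c("gene_models", "data.frame")
    return(gm)
  }
  n_per <- round(cfg$n_genes * cfg$contigs / sum(cfg$contigs))
  ## rounding drift goes to the first contig
  n_per[1] <- cfg$n_genes - sum(n_per[-1])
  gi <- 0L
  rows <- list()
  for (ct in names(cfg$contigs)) {
    cursor <- 5000L
    L <- cfg$contigs[[ct]]
    for (k in seq_len(n_per[[ct]])) {
      n_ex <- sample(2:4, 1)
      ex_len <- sample(150:400, n_ex, replace = TRUE)
      in_len <- if (n_ex > 1) sample(300:1500, n_ex - 1, replace = TRUE)
                else integer()
      st <- integer(n_ex); en <- integer(n_ex)
      pos <- cursor
      for (e in seq_len(n_ex)) {
        st[e] <- pos
        en[e] <- pos + ex_len[e]
        pos <- en[e] + if (e < n_ex) in_len[e] else 0L
      }
      if (pos > L - 5000L) break
      gi <- gi + 1L
      gene <- sprintf("G%04d", gi)
      coding <- runif(1) < 0.8
      cds_start <- NA_integer_; cds_end <- NA_integer_
      if (coding) {
        utr5 <- sample(30:min(120L, ex_len[1] - 30L), 1)
        utr3 <- sample(30:min(120L, ex_len[n_ex] - 30L), 1)
        cds_start <- st[1] + utr5
        cds_end <- en[n_ex] - utr3
        cds_len <- sum(pmin(en, cds_end) - pmax(st, cds_start))
        cds_end <- cds_end - cds_len %% 3L
      }
      rows[[gi]] <- list(contig = ct, gene = gene,
                         transcript = paste0(gene, ".t1"),
                         strand = sample(c("+", "-"), 1),
                         is_coding = coding,
                         cds_start = cds_start, cds_end = cds_end,
                         exon_starts = st, exon_ends = en)
      cursor <- pos + sample(2000:15000, 1)
    }
  }
  gm <- data.frame(
    contig = vapply(rows, `[[`, "", "contig"),
    gene = vapply(rows, `[[`, "", "gene"),
    transcript = vapply(rows, `[[`, "", "transcript"),
    strand = vapply(rows, `[[`, "", "strand"),
    is_coding = vapply(rows, `[[`, TRUE, "is_coding"),
    cds_start = vapply(rows, `[[`, 1L, "cds_start"),
    cds_end = vapply(rows, `[[`, 1L, "cds_end"),
    stringsAsFactors = FALSE)
  gm$exon_starts <- lapply(rows, `[[`, "exon_starts")
  gm$exon_ends <- lapply(rows, `[[`, "exon_ends")
  validate_gene_models(gm)
}

## --- position sampling ------------------------------------------------------

#' Sample well-spaced candidate positions on every contig, classified into
#' CDS / near-exon / free pools.
#' @noRd
sample_positions <- function(cfg, gm) {
  needed <- cfg$n_inherited_variants + cfg$n_denovo_snv +
    cfg$n_denovo_indel + cfg$n_artifact_indels +
    2L * cfg$compound_het_genes
  out <- NULL
  for (ct in names(cfg$contigs)) {
    L <- as.double(cfg$contigs[[ct]])
    want <- ceiling(needed * L / sum(as.double(cfg$contigs))) * 3L
    want <- min(want, (L - 20L) %/% (2L * .MIN_SPACING))
    if (want <= 0L) next
    cand <- sort(sample.int(L - 2L * .MIN_SPACING, want)) + .MIN_SPACING
    ## greedy spacing pass
    acc <- logical(length(cand))
    last <- -1e9
    for (k in seq_along(cand)) {
      if (cand[k] - last >= .MIN_SPACING) { acc[k] <- TRUE; last <- cand[k] }
    }
    cand <- cand[acc]
    out <- rbind(out, data.frame(contig = ct, pos = cand,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(contig = character(), pos = integer(),
                      stringsAsFactors = FALSE)
  ## classify against exons
  gmc <- gm[gm$contig %in% unique(out$contig), , drop = FALSE]
  pool <- rep("free", nrow(out))
  gene <- rep(NA_character_, nrow(out))
  if (nrow(gmc)) {
    ex <- data.frame(
      contig = rep(gmc$contig, lengths(gmc$exon_starts)),
      start = unlist(gmc$exon_starts), end = unlist(gmc$exon_ends))
    ex_gr <- GRanges(ex$contig,
                     IRanges(ex$start + 1L - .MIN_SPACING,
                             ex$end + .MIN_SPACING))
    p_gr <- GRanges(out$contig, IRanges(out$pos, out$pos))
    near <- unique(queryHits(findOverlaps(p_gr, ex_gr)))
    pool[near] <- "near_exon"
    cod <- gmc[gmc$is_coding, , drop = FALSE]
    if (nrow(cod)) {
      cds_iv <- do.call(rbind, lapply(seq_len(nrow(cod)), function(i) {
        st <- cod$exon_starts[[i]]; en <- cod$exon_ends[[i]]
        a <- pmax(st, cod$cds_start[i]); b <- pmin(en, cod$cds_end[i])
        ok <- (b - a) > 8L   # room for the 3-bp interior margin on each side
        if (!any(ok)) return(NULL)
        data.frame(contig = cod$contig[i], start = a[ok], end = b[ok],
                   gene = cod$gene[i], stringsAsFactors = FALSE)
      }))
      if (!is.null(cds_iv)) {
        ## interior CDS positions only (3 bp off the CDS-exon edges so small
        ## edits never straddle a boundary)
        cds_gr <- GRanges(cds_iv$contig,
                          IRanges(cds_iv$start + 4L, cds_iv$end - 3L))
        hits <- findOverlaps(p_gr, cds_gr)
        pool[queryHits(hits)] <- "cds"
        gene[queryHits(hits)] <- cds_iv$gene[subjectHits(hits)]
      }
    }
  }
  out$pool <- pool
  out$gene <- gene
  out
}

## --- trio generation --------------------------------------------------------

.TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
.TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                     C = c("A", "G"), T = c("A", "G"))

#' Generate a synthetic trio dataset
#'
#' Builds the reference, gene models, trio VCF, known-site catalogs, allele
#' frequency table, depth profile and truth table for a configuration, and
#' optionally writes them to a directory.  Running twice with the same
#' config and seed produces byte-identical outputs.
#'
#' Proband genotypes are Mendelian-consistent everywhere except at planted
#' de novo sites, which are heterozygous in the proband and homozygous
#' reference in both parents.
#'
#' @param cfg A `sim_config`.
#' @param out_dir Optional output directory (created if needed); when given,
#'   writes `reference.fa`, `genes.tsv`, `trio.vcf`, `depth.tsv`,
#'   `dbsnp_like.tsv`, `g1000_like.tsv`, `panel.tsv`, `af_table.tsv`,
#'   `truth.json`.
#' @return List with `reference` (DNAStringSet), `gene_models`, `variants`
#'   (trio variant data frame), `depth`, `truth` (class `trio_truth`),
#'   `catalogs` and `af_table`; plus `paths` when `out_dir` is given.
#' @export
generate_trio <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))

  ## 1. reference bases, one character vector per contig
  set.seed(sub_seed(cfg$seed, "reference"))
  bases <- lapply(cfg$contigs, function(L)
    sample(c("A", "C", "G", "T"), L, replace = TRUE))

  ## 2. gene models
  gm <- simulate_gene_models(cfg)

  ## 3. event positions
  set.seed(sub_seed(cfg$seed, "inherited"))
  pos_tab <- sample_positions(cfg, gm)

  n_snv <- cfg$n_denovo_snv
  n_cpg <- round(cfg$cpg_fraction * n_snv)
  n_ts <- round(cfg$ts_fraction * n_snv)
  if (n_cpg > n_ts)
    .stopf("cpg_fraction implies more CpG transitions than total transitions")
  if (n_cpg > n_snv - cfg$n_denovo_exonic)
    .stopf("not enough non-exonic de novo SNVs to hold the CpG events")

  cds_idx <- which(pos_tab$pool == "cds")
  free_idx <- which(pos_tab$pool == "free")

  if (length(cds_idx) < cfg$n_denovo_exonic + 2L * cfg$compound_het_genes)
    .stopf("config requests more exonic events than available exonic bases")

  ## compound-het genes: coding genes with the most sampled CDS positions.
  ## Keep, per gene, the first two positions where a missense substitution
  ## exists (third positions of fourfold-degenerate codons cannot yield one).
  cht_gene_pos <- list()
  used_cds <- integer()
  if (cfg$compound_het_genes > 0L) {
    pre_ref <- vapply(bases, paste, "", collapse = "")
    tab <- table(pos_tab$gene[cds_idx])
    tab <- tab[tab >= 2L]
    if (length(tab) < cfg$compound_het_genes)
      .stopf("not enough coding genes with 2+ usable CDS positions")
    genes <- names(tab)[order(-as.integer(tab), names(tab))]
    for (g in genes) {
      idx <- cds_idx[pos_tab$gene[cds_idx] %in% g]
      tx <- which(gm$gene == g)
      ok <- idx[vapply(idx, function(i)
        !is.na(missense_alt(pre_ref[[pos_tab$contig[i]]], pos_tab$pos[i],
                            gm, tx)), TRUE)]
      if (length(ok) >= 2L) {
        cht_gene_pos[[g]] <- ok[1:2]
        used_cds <- c(used_cds, ok[1:2])
      }
      if (length(cht_gene_pos) == cfg$compound_het_genes) break
    }
    if (length(cht_gene_pos) < cfg$compound_het_genes)
      .stopf("not enough coding genes with two missense-capable positions")
  }
  cds_rest <- setdiff(cds_idx, used_cds)
  exon_dn_idx <- if (cfg$n_denovo_exonic > 0L)
    sample_vec(cds_rest, cfg$n_denovo_exonic) else integer()

  n_free_needed <- (n_snv - cfg$n_denovo_exonic) + cfg$n_denovo_indel +
    cfg$n_artifact_indels
  if (length(free_idx) < n_free_needed + 0L)
    .stopf("genome too small for the requested non-exonic de novo events")
  free_dn <- sample_vec(free_idx, n_free_needed)
  k <- n_snv - cfg$n_denovo_exonic
  nonexonic_snv_idx <- head(free_dn, k)
  indel_idx <- free_dn[seq_len(cfg$n_denovo_indel) + k]
  artifact_idx <- tail(free_dn, cfg$n_artifact_indels)
  if (cfg$n_denovo_indel == 0L) indel_idx <- integer()
  if (cfg$n_artifact_indels == 0L) artifact_idx <- integer()

  ## CpG subset among the non-exonic de novo SNVs
  cpg_idx <- if (n_cpg > 0L) sample_vec(nonexonic_snv_idx, n_cpg)
             else integer()
  snv_dn_idx <- c(exon_dn_idx, nonexonic_snv_idx)

  ## inherited sites from what remains
  remaining <- setdiff(seq_len(nrow(pos_tab)),
                       c(used_cds, exon_dn_idx, free_dn))
  if (length(remaining) < cfg$n_inherited_variants)
    .stopf("genome too small for %d inherited variants",
           cfg$n_inherited_variants)
  inh_idx <- sample_vec(remaining, cfg$n_inherited_variants)

  ## 4. reference edits: plant CpG context, scrub accidental CpG context at
  ## non-CpG de novo SNVs, plant the de novo deletion allele
  for (i in cpg_idx) {
    ct <- pos_tab$contig[i]; p <- pos_tab$pos[i]
    bases[[ct]][p] <- "C"; bases[[ct]][p + 1L] <- "G"
  }
  non_cpg_snv <- setdiff(snv_dn_idx, cpg_idx)
  for (i in non_cpg_snv) {
    ct <- pos_tab$contig[i]; p <- pos_tab$pos[i]
    b <- bases[[ct]]
    if (b[p] == "C" && b[p + 1L] == "G") bases[[ct]][p + 1L] <- "T"
    if (p > 1L && b[p - 1L] == "C" && b[p] == "G") bases[[ct]][p - 1L] <- "T"
  }
  set.seed(sub_seed(cfg$seed, "denovo"))
  ## the planted de novo deletion allele is TGGAC (a validated 5-bp
  ## non-coding deletion is part of the emulated event mix)
  for (i in indel_idx) {
    ct <- pos_tab$contig[i]; p <- pos_tab$pos[i]
    bases[[ct]][(p + 1L):(p + 5L)] <- c("T", "G", "G", "A", "C")
  }

  refstr <- vapply(bases, paste, "", collapse = "")

  ## 5. de novo SNV alleles: CpG sites are C>T transitions; the rest are
  ## assigned transition/transversion to hit the configured fractions
  n_ts_rest <- n_ts - n_cpg
  ts_rest_idx <- if (n_ts_rest > 0L) sample_vec(non_cpg_snv, n_ts_rest)
                 else integer()
  dn_rows <- lapply(snv_dn_idx, function(i) {
    ct <- pos_tab$contig[i]; p <- pos_tab$pos[i]
    rb <- bases[[ct]][p]
    is_ts <- i %in% c(cpg_idx, ts_rest_idx)
    ab <- if (is_ts) .TS_PARTNER[[rb]]
          else sample(.TV_PARTNERS[[rb]], 1)
    list(contig = ct, pos = p, ref = rb, alt = ab, vtype = "SNV",
         is_exonic = i %in% exon_dn_idx, is_cpg = i %in% cpg_idx,
         is_transition = is_ts)
  })
  dn_indel_rows <- lapply(indel_idx, function(i) {
    ct <- pos_tab$contig[i]; p <- pos_tab$pos[i]
    refal <- paste(bases[[ct]][p:(p + 5L)], collapse = "")
    list(contig = ct, pos = p, ref = refal, alt = bases[[ct]][p],
         vtype = "deletion", is_exonic = FALSE, is_cpg = NA,
         is_transition = NA)
  })
  artifact_rows <- lapply(artifact_idx, function(i) {
    ct <- pos_tab$contig[i]; p <- pos_tab$pos[i]
    refal <- paste(bases[[ct]][p:(p + 2L)], collapse = "")
    list(contig = ct, pos = p, ref = refal, alt = bases[[ct]][p],
         vtype = "deletion")
  })

  ## 6. inherited sites: allele frequencies from Beta(0.5, 0.5); parental
  ## alleles are redrawn until the site segregates in the parents, so every
  ## emitted site is a real trio variant site; the child inherits one
  ## random allele from each parent (Mendelian by construction)
  n_inh <- cfg$n_inherited_variants
  inh <- NULL
  set.seed(sub_seed(cfg$seed, "genotypes"))
  if (n_inh > 0L) {
    af <- rbeta(n_inh, 0.5, 0.5)
    af <- pmin(pmax(af, 1e-4), 1 - 1e-4)
    fa1 <- rbinom(n_inh, 1, af); fa2 <- rbinom(n_inh, 1, af)
    mo1 <- rbinom(n_inh, 1, af); mo2 <- rbinom(n_inh, 1, af)
    for (iter in 1:100) {
      none <- fa1 + fa2 + mo1 + mo2 == 0L
      if (!any(none)) break
      fa1[none] <- rbinom(sum(none), 1, af[none])
      fa2[none] <- rbinom(sum(none), 1, af[none])
      mo1[none] <- rbinom(sum(none), 1, af[none])
      mo2[none] <- rbinom(sum(none), 1, af[none])
    }
    ch_f <- ifelse(rbinom(n_inh, 1, 0.5) == 1L, fa1, fa2)
    ch_m <- ifelse(rbinom(n_inh, 1, 0.5) == 1L, mo1, mo2)
    is_del <- runif(n_inh) < 0.1
    del_len <- sample(1:3, n_inh, replace = TRUE)
    ct <- pos_tab$contig[inh_idx]; p <- pos_tab$pos[inh_idx]
    ref <- character(n_inh); alt <- character(n_inh)
    for (k in seq_len(n_inh)) {
      b <- bases[[ct[k]]]
      if (is_del[k]) {
        ref[k] <- paste(b[p[k]:(p[k] + del_len[k])], collapse = "")
        alt[k] <- b[p[k]]
      } else {
        ref[k] <- b[p[k]]
        alt[k] <- sample(setdiff(c("A", "C", "G", "T"), ref[k]), 1)
      }
    }
    gt <- function(a1, a2) paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
    inh <- data.frame(contig = ct, pos = p, ref = ref, alt = alt,
                      vtype = ifelse(is_del, "deletion", "SNV"),
                      gt_father = gt(fa1, fa2), gt_mother = gt(mo1, mo2),
                      gt_proband = gt(ch_f, ch_m), af = af,
                      stringsAsFactors = FALSE)
  }

  ## 7. compound heterozygotes: one paternal-only + one maternal-only
  ## missense heterozygote per selected gene (trans configuration)
  set.seed(sub_seed(cfg$seed, "compound"))
  cht_rows <- NULL
  cht_truth <- NULL
  cht_af_pairs <- list(c(8.32e-6, NA), c(0.0015, 5.8e-5))
  gi <- 0L
  for (g in names(cht_gene_pos)) {
    gi <- gi + 1L
    idx2 <- cht_gene_pos[[g]]
    tx <- which(gm$gene == g)
    origin <- c("paternal", "maternal")
    afs <- cht_af_pairs[[((gi - 1L) %% length(cht_af_pairs)) + 1L]]
    for (k in 1:2) {
      i <- idx2[k]
      ct <- pos_tab$contig[i]; p <- pos_tab$pos[i]
      alt <- missense_alt(refstr[[ct]], p, gm, tx)
      if (is.na(alt))
        .stopf("no missense substitution available at %s:%d", ct, p)
      cht_rows <- rbind(cht_rows, data.frame(
        contig = ct, pos = p, ref = substring(refstr[[ct]], p, p), alt = alt,
        vtype = "SNV",
        gt_father = if (origin[k] == "paternal") "0/1" else "0/0",
        gt_mother = if (origin[k] == "maternal") "0/1" else "0/0",
        gt_proband = "0/1", af = afs[k], stringsAsFactors = FALSE))
      cht_truth <- rbind(cht_truth, data.frame(
        gene = g, contig = ct, pos = p, origin = origin[k],
        stringsAsFactors = FALSE))
    }
  }

  ## 8. assemble the trio variant table
  mk_dn <- function(rows, gt_child = "0/1") {
    if (!length(rows)) return(NULL)
    do.call(rbind, lapply(rows, function(r) data.frame(
      contig = r$contig, pos = r$pos, ref = r$ref, alt = r$alt,
      vtype = r$vtype, gt_father = "0/0", gt_mother = "0/0",
      gt_proband = gt_child, af = NA_real_, stringsAsFactors = FALSE)))
  }
  v <- rbind(inh, mk_dn(dn_rows), mk_dn(dn_indel_rows), mk_dn(artifact_rows),
             cht_rows)
  if (is.null(v)) {
    v <- empty_variants()
  } else {
    v <- v[order(match(v$contig, names(cfg$contigs)), v$pos), , drop = FALSE]
    rownames(v) <- NULL
    v$dp_father <- 30L; v$dp_mother <- 30L; v$dp_proband <- 30L
    v$gq_father <- 99L; v$gq_mother <- 99L; v$gq_proband <- 99L
    v$rl_proband <- NA_integer_
    v$ro_proband <- NA_character_
    v <- v[, names(empty_variants())]
  }

  ## read support: the true de novo indel is centrally supported, the
  ## artifact indel only by read edges
  set.seed(sub_seed(cfg$seed, "readsupport"))
  key <- variant_key(v$contig, v$pos, v$ref, v$alt)
  for (r in dn_indel_rows) {
    i <- match(variant_key(r$contig, r$pos, r$ref, r$alt), key)
    off <- generate_read_support(edge_only = FALSE, read_length = 101L)
    v$rl_proband[i] <- 101L
    v$ro_proband[i] <- paste(off, collapse = "|")
  }
  for (r in artifact_rows) {
    i <- match(variant_key(r$contig, r$pos, r$ref, r$alt), key)
    off <- generate_read_support(edge_only = TRUE, read_length = 101L)
    v$rl_proband[i] <- 101L
    v$ro_proband[i] <- paste(off, collapse = "|")
  }

  ## 9. catalogs: common inherited sites are "known"; de novo and
  ## compound-het sites never are
  dbsnp <- NULL; g1000 <- NULL; panel <- NULL
  if (!is.null(inh)) {
    dbsnp <- inh[inh$af >= 0.01, c("contig", "pos", "ref", "alt")]
    g1000 <- inh[inh$af >= 0.003, c("contig", "pos", "ref", "alt")]
    panel <- inh[inh$af >= 0.2, c("contig", "pos", "ref", "alt")]
    panel <- head(panel, 200L)
  }

  af_rows <- v[!is.na(v$af), c("contig", "pos", "ref", "alt", "af")]
  af_table <- data.frame(contig = af_rows$contig, pos = af_rows$pos,
                         ref = af_rows$ref, alt = af_rows$alt,
                         population = rep("EAS", nrow(af_rows)),
                         af = af_rows$af, stringsAsFactors = FALSE)

  ## 10. depth profile
  depth <- generate_depth_profile(cfg)

  truth <- structure(list(
    denovo_events = do.call(rbind, lapply(c(dn_rows, dn_indel_rows),
      function(r) data.frame(contig = r$contig, pos = r$pos, ref = r$ref,
                             alt = r$alt, vtype = r$vtype,
                             is_exonic = r$is_exonic, is_cpg = r$is_cpg,
                             is_transition = r$is_transition,
                             stringsAsFactors = FALSE))),
    compound_het_events = cht_truth,
    cnv_events = cfg$cnv_events
  ), class = "trio_truth")

  res <- list(reference = DNAStringSet(refstr), gene_models = gm,
              variants = v, depth = depth, truth = truth,
              catalogs = list(dbsnp_like = dbsnp, g1000_like = g1000,
                              panel = panel),
              af_table = af_table, config = cfg)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      reference = file.path(out_dir, "reference.fa"),
      genes = file.path(out_dir, "genes.tsv"),
      vcf = file.path(out_dir, "trio.vcf"),
      depth = file.path(out_dir, "depth.tsv"),
      dbsnp = file.path(out_dir, "dbsnp_like.tsv"),
      g1000 = file.path(out_dir, "g1000_like.tsv"),
      panel = file.path(out_dir, "panel.tsv"),
      af = file.path(out_dir, "af_table.tsv"),
      truth = file.path(out_dir, "truth.json"))
    write_reference(res$reference, paths$reference)
    write_gene_models(gm, paths$genes)
    write_trio_vcf(v, paths$vcf, contigs = cfg$contigs)
    write_depth_table(depth, paths$depth)
    for (nm in c("dbsnp", "g1000", "panel")) {
      cat_df <- switch(nm, dbsnp = dbsnp, g1000 = g1000, panel = panel)
      if (is.null(cat_df))
        cat_df <- data.frame(contig = character(), pos = integer(),
                             ref = character(), alt = character())
      write_known_sites(cat_df, paths[[nm]])
    }
    write.table(af_table, paths$af, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_json(unclass(truth), paths$truth, auto_unbox = TRUE, digits = NA,
               na = "null", pretty = TRUE)
    res$paths <- paths
  }
  res
}

#' Pick an alt base making a missense change at CDS position p (1-based).
#' @noRd
missense_alt <- function(seqstr, p, gm, tx) {
  v0 <- data.frame(contig = gm$contig[tx], pos = p, ref = substring(seqstr, p, p),
                   alt = "N", vtype = "SNV", stringsAsFactors = FALSE)
  ref_named <- setNames(seqstr, gm$contig[tx])
  for (ab in setdiff(c("A", "C", "G", "T"), v0$ref)) {
    v0$alt <- ab
    ce <- coding_effect(v0, gm, ref_named, tx = tx)
    if (ce$effect == "missense") return(ab)
  }
  NA_character_
}

#' @export
print.trio_truth <- function(x, ...) {
  cat(sprintf("Truth table: %d de novo events (%d exonic), %d compound-het variants, %d CNV events\n",
              NROW(x$denovo_events), sum(x$denovo_events$is_exonic %in% TRUE),
              NROW(x$compound_het_events), NROW(x$cnv_events)))
  invisible(x)
}

#' Generate a trio depth-of-coverage profile
#'
#' Per-sample binned depths at `depth_mean` for copy number 2, scaled by
#' copy/2 inside configured CNV events, with seeded Gaussian noise truncated
#' at zero.  Noise scales with `sqrt(copy/2)` (read sampling is counting
#' noise), so a homozygous deletion has exactly zero depth.
#'
#' @param cfg A `sim_config`.
#' @return Depth-bin data frame ([read_depth_table()] layout).
#' @export
generate_depth_profile <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(sub_seed(cfg$seed, "depth"))
  out <- NULL
  ev <- cfg$cnv_events
  for (ct in names(cfg$contigs)) {
    L <- cfg$contigs[[ct]]
    start <- seq.int(0L, L - 1L, by = cfg$bin_size)
    end <- pmin(start + cfg$bin_size, L)
    mid <- (start + end) / 2
    copies <- matrix(2, nrow = length(start), ncol = 3)
    if (!is.null(ev) && nrow(ev)) {
      for (e in which(ev$contig == ct)) {
        in_ev <- mid >= ev$start[e] & mid < ev$end[e]
        copies[in_ev, 1] <- ev$parent_copies[e]
        copies[in_ev, 2] <- ev$parent_copies[e]
        copies[in_ev, 3] <- ev$child_copies[e]
      }
    }
    mk <- function(j) {
      mu <- cfg$depth_mean * copies[, j] / 2
      sd <- cfg$depth_noise_sd * sqrt(copies[, j] / 2)
      pmax(0, rnorm(length(mu), mu, sd))
    }
    out <- rbind(out, data.frame(
      contig = ct, start = start, end = end,
      depth_father = mk(1), depth_mother = mk(2), depth_proband = mk(3),
      stringsAsFactors = FALSE))
  }
  out
}

#' Generate read-support offsets for an indel
#'
#' Emits 0-based offsets of an indel start within supporting reads.  With
#' `edge_only`, every offset lies within `edge_margin` bases of a read end
#' (the alignment-artifact signature the edge filter removes); otherwise at
#' least one read places the indel centrally.
#'
#' @param edge_only Logical.
#' @param read_length Read length in bp (> 20).
#' @param n_reads Number of supporting reads.
#' @param edge_margin Edge width in bp.
#' @return Integer offsets in `[0, read_length - 1]`.
#' @export
generate_read_support <- function(edge_only, read_length = 101L,
                                  n_reads = 2L, edge_margin = 10L) {
  stopifnot(read_length > 20L, n_reads >= 1L)
  edge_pool <- c(0:edge_margin, (read_length - 1L - edge_margin):(read_length - 1L))
  central_pool <- (edge_margin + 1L):(read_length - 2L - edge_margin)
  if (edge_only) {
    sort(sample(edge_pool, n_reads, replace = TRUE))
  } else {
    sort(c(sample(central_pool, 1L),
           if (n_reads > 1L)
             sample(0:(read_length - 1L), n_reads - 1L, replace = TRUE)))
  }
}
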