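# A compact hand-built locus: one plus-strand coding gene, one minus-strand
# coding gene, one non-coding transcript.
local_models <- function() {
  rbind_models(
    make_gene_models("chr1", "CODP", "+", c(100L, 400L), c(250L, 600L),
                     cds_start = 130L, cds_end = 550L),
    make_gene_models("chr1", "CODM", "-", c(2000L, 2400L), c(2200L, 2600L),
                     cds_start = 2050L, cds_end = 2500L),
    make_gene_models("chr1", "NCR", "+", c(5000L, 5400L), c(5200L, 5600L)))
}

test_that("region classification covers every category", {
  gm <- local_models()
  v <- make_variants("chr1",
                     pos = c(150L, 110L, 580L, 5100L, 5300L, 300L, 9000L,
                             2030L, 2580L),
                     ref = "A", alt = "T")
  reg <- classify_region(v, gm)
  expect_equal(reg, c("exonic",      # inside CDS
                      "UTR5",        # exon, left of CDS, + strand
                      "UTR3",        # exon, right of CDS, + strand
                      "ncRNA_exonic",
                      "ncRNA_intronic",
                      "intronic",    # deep intron
                      "intergenic",
                      "UTR3",        # minus strand: genomic left is 3'
                      "UTR5"))
})

test_that("minus-strand UTR orientation follows the strand", {
  gm <- make_gene_models("chr1", "GM", "-", 100L, 400L,
                         cds_start = 150L, cds_end = 350L)
  v <- make_variants("chr1", pos = c(120L, 380L), ref = "A", alt = "T")
  # genomically-left exon bases are downstream (3') on the minus strand
  expect_equal(classify_region(v, gm), c("UTR3", "UTR5"))
})

test_that("splice region is the 2 bp of intron flanking each exon boundary", {
  gm <- make_gene_models("chr1", "G1", "+", c(100L, 400L), c(250L, 600L),
                         cds_start = 130L, cds_end = 550L)
  # intron spans 0-based [250, 400); 1-based positions 251..400
  for (p in c(251L, 252L, 399L, 400L)) {
    expect_equal(classify_region(make_variants("chr1", p, "A", "T"), gm),
                 "splicing", info = paste("pos", p))
  }
  for (p in c(253L, 300L, 398L)) {
    expect_equal(classify_region(make_variants("chr1", p, "A", "T"), gm),
                 "intronic", info = paste("pos", p))
  }
})

test_that("classification is a partition over any variant set", {
  sim <- generate_trio(mini_sim_config(seed = 3))
  reg <- classify_region(sim$variants, sim$gene_models)
  expect_equal(length(reg), nrow(sim$variants))
  expect_false(anyNA(reg))
  expect_equal(sum(table(reg)), nrow(sim$variants))
  expect_true(all(reg %in% trioscan:::.REGION_LEVELS))
})

test_that("codon arithmetic reproduces an R502W-style change", {
  # codon 502 is CGG (Arg); a C>T at its first base (c.1504, since
  # 1504 = 3*501 + 1) gives TGG (Trp)
  fix <- toy_coding_gene(seed = 5, n_codons = 600L)
  seq <- fix$reference
  substr(seq, fix$cds_start + 501 * 3 + 1, fix$cds_start + 501 * 3 + 3) <- "CGG"
  pos <- fix$cds_start + 1504L           # genomic 1-based of c.1504
  v <- make_variants("chrT", pos, "C", "T")
  eff <- coding_effect(v, fix$models, seq)
  expect_equal(eff$effect, "missense")
  expect_equal(eff$aa_change, "R502W")
})

test_that("synonymous, frameshift and in-frame indels are classified", {
  fix <- toy_coding_gene(seed = 8)
  seq <- fix$reference[["chrT"]]
  # third base of codon 10 in a fourfold-degenerate context: force codon CTx
  codon_start <- fix$cds_start + 9 * 3   # 0-based
  s <- seq
  substr(s, codon_start + 1, codon_start + 3) <- "CTA"
  refs <- c(chrT = s)
  v <- make_variants("chrT", codon_start + 3L, "A", "G")
  expect_equal(coding_effect(v, fix$models, refs)$effect, "synonymous")

  p <- fix$cds_start + 30L
  del4 <- make_variants("chrT", p,
                        ref = substring(s, p, p + 4L),
                        alt = substring(s, p, p))
  expect_equal(coding_effect(del4, fix$models, refs)$effect, "frameshift")
  del3 <- make_variants("chrT", p,
                        ref = substring(s, p, p + 3L),
                        alt = substring(s, p, p))
  expect_equal(coding_effect(del3, fix$models, refs)$effect, "inframe_indel")
})

test_that("coding_effect rejects a reference/VCF mismatch", {
  fix <- toy_coding_gene(seed = 9)
  p <- fix$cds_start + 10L
  truebase <- substring(fix$reference[["chrT"]], p, p)
  wrong <- setdiff(c("A", "C", "G", "T"), truebase)[1]
  v <- make_variants("chrT", p, wrong, truebase)
  expect_error(coding_effect(v, fix$models, fix$reference),
               "reference mismatch")
})

test_that("coding_effect matches the retranslation oracle on both strands", {
  for (strand in c("+", "-")) {
    fix <- toy_coding_gene(seed = 21, n_codons = 60L, strand = strand)
    seq <- fix$reference[["chrT"]]
    set.seed(33)
    positions <- sample((fix$cds_start + 1L):fix$cds_end, 40L)
    for (p in positions) {
      rb <- substring(seq, p, p)
      for (ab in setdiff(c("A", "C", "G", "T"), rb)) {
        v <- make_variants("chrT", p, rb, ab)
        got <- coding_effect(v, fix$models, fix$reference)$effect
        want <- oracle_coding_effect(v, fix)
        expect_equal(got, want,
                     info = sprintf("%s strand pos %d %s>%s",
                                    strand, p, rb, ab))
      }
    }
  }
})

test_that("CpG context is detected on both strands of the dinucleotide", {
  refs <- c(chr1 = "AACGTT")
  atC <- make_variants("chr1", 3L, "C", "T")
  atG <- make_variants("chr1", 4L, "G", "A")
  expect_true(cpg_context(atC, refs))
  expect_true(cpg_context(atG, refs))
  refs2 <- c(chr1 = "ATTA")
  for (p in 1:4) {
    b <- substring(refs2[["chr1"]], p, p)
    expect_false(cpg_context(make_variants("chr1", p, b,
                                           setdiff(c("A","C","G","T"), b)[1]),
                             refs2))
  }
  # contig edges: missing neighbour contributes false
  refs3 <- c(chr1 = "CG")
  expect_true(cpg_context(make_variants("chr1", 1L, "C", "T"), refs3))
  expect_true(cpg_context(make_variants("chr1", 2L, "G", "A"), refs3))
  refs4 <- c(chr1 = "GC")
  expect_false(cpg_context(make_variants("chr1", 1L, "G", "A"), refs4))
  expect_false(cpg_context(make_variants("chr1", 2L, "C", "T"), refs4))
})

test_that("exactly 4 of the 12 ordered substitutions are transitions", {
  bases <- c("A", "C", "G", "T")
  subs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  subs <- subs[subs$ref != subs$alt, ]
  flags <- transition_flag(subs$ref, subs$alt)
  expect_equal(sum(flags), 4L)
  expect_true(all(flags[paste(subs$ref, subs$alt) %in%
                          c("A G", "G A", "C T", "T C")]))
  expect_error(transition_flag("AT", "A"), "SNV")
})
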