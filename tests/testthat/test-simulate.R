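test_that("identical config and seed give byte-identical outputs", {
  cfg <- mini_sim_config(seed = 13)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_trio(cfg, out_dir = d1)
  generate_trio(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
  # and a different seed changes the data
  d3 <- withr::local_tempdir()
  generate_trio(mini_sim_config(seed = 14), out_dir = d3)
  expect_false(identical(readLines(file.path(d1, "trio.vcf")),
                         readLines(file.path(d3, "trio.vcf"))))
})

test_that("truth table counts honour the configuration", {
  cfg <- mini_sim_config(seed = 2)
  sim <- generate_trio(cfg)
  tr <- sim$truth$denovo_events
  expect_equal(nrow(tr), cfg$n_denovo_snv + cfg$n_denovo_indel)
  expect_equal(sum(tr$is_exonic), cfg$n_denovo_exonic)
  snv <- tr$vtype == "SNV"
  expect_equal(sum(tr$is_cpg[snv]), round(cfg$cpg_fraction * cfg$n_denovo_snv))
  expect_equal(sum(tr$is_transition[snv]),
               round(cfg$ts_fraction * cfg$n_denovo_snv))
  expect_equal(length(unique(sim$truth$compound_het_events$gene)),
               cfg$compound_het_genes)
  # truth events appear exactly once in the VCF
  vk <- trioscan:::variant_key(sim$variants$contig, sim$variants$pos,
                               sim$variants$ref, sim$variants$alt)
  tk <- trioscan:::variant_key(tr$contig, tr$pos, tr$ref, tr$alt)
  expect_equal(unname(table(tk %in% vk)[["TRUE"]]), nrow(tr))
  expect_false(anyDuplicated(vk) > 0)
})

test_that("planted flags agree with the annotation of the emitted files", {
  sim <- generate_trio(mini_sim_config(seed = 17))
  ann <- annotate_variants(sim$variants, sim$reference, sim$gene_models)
  tr <- sim$truth$denovo_events
  key <- trioscan:::variant_key(ann$contig, ann$pos, ann$ref, ann$alt)
  idx <- match(trioscan:::variant_key(tr$contig, tr$pos, tr$ref, tr$alt), key)
  expect_equal(ann$region[idx] == "exonic", tr$is_exonic)
  snv <- tr$vtype == "SNV"
  expect_equal(ann$is_cpg[idx][snv], tr$is_cpg[snv])
  expect_equal(ann$is_transition[idx][snv], tr$is_transition[snv])
})

test_that("all non-truth sites are Mendelian-consistent", {
  sim <- generate_trio(mini_sim_config(seed = 29))
  v <- sim$variants
  tr <- sim$truth$denovo_events
  truth_key <- paste(tr$contig, tr$pos)
  is_truth <- paste(v$contig, v$pos) %in% truth_key
  # the planted artifact indel is also a (non-truth) Mendelian violation by
  # construction; identify it by its edge-only read support
  artifact <- !is.na(v$ro_proband) & !suppressWarnings(filter_edge_indels(v))
  audit <- mapply(mendelian_consistent, v$gt_father, v$gt_mother,
                  v$gt_proband)
  expect_true(all(audit[!is_truth & !artifact]))
  expect_false(any(audit[is_truth]))
})

test_that("round-tripping the written files reproduces the in-memory trio", {
  dir <- withr::local_tempdir()
  sim <- generate_trio(mini_sim_config(seed = 31), out_dir = dir)
  back <- read_trio_vcf(file.path(dir, "trio.vcf"))
  expect_equal(back, sim$variants, tolerance = 1e-12)
  gm <- read_gene_models(file.path(dir, "genes.tsv"))
  expect_equal(gm$gene, sim$gene_models$gene)
  expect_equal(gm$cds_start, sim$gene_models$cds_start)
  ref <- read_reference(file.path(dir, "reference.fa"))
  expect_equal(as.character(ref), as.character(sim$reference))
})

test_that("read-support generation matches the edge/central contract", {
  set.seed(41)
  for (r in 1:20) {
    edge <- generate_read_support(edge_only = TRUE, read_length = 101L)
    expect_true(all(edge <= 10L | edge >= 90L))
    expect_true(all(edge >= 0L & edge <= 100L))
    central <- generate_read_support(edge_only = FALSE, read_length = 101L)
    expect_true(any(central > 10L & central < 90L))
  }
  expect_error(generate_read_support(TRUE, read_length = 15L))
})

test_that("impossible configurations error out explicitly", {
  expect_error(sim_config(n_denovo_exonic = 99L, n_denovo_snv = 10L,
                          n_denovo_indel = 2L),
               "exceeds")
  # no genes at all: no exonic bases available
  expect_error(
    generate_trio(sim_config(seed = 1, contigs = c(chr1 = 100000L),
                             n_genes = 0L, n_inherited_variants = 10L,
                             n_denovo_snv = 5L, n_denovo_indel = 0L,
                             n_denovo_exonic = 2L, cpg_fraction = 0,
                             ts_fraction = 0.5, compound_het_genes = 0L,
                             n_artifact_indels = 0L)),
    "exonic")
  expect_error(sim_config(contigs = c(chr1 = 5000L), bin_size = 1000L),
               "10 bins")
})
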