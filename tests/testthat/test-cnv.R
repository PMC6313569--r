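test_that("depth normalization is a per-sample median ratio", {
  d <- data.frame(contig = "chr1", start = (0:9) * 1000L,
                  end = (1:10) * 1000L,
                  depth_father = rep(30, 10), depth_mother = rep(60, 10),
                  depth_proband = rep(30, 10))
  n <- normalize_depth(d)
  expect_true(all(n$depth_father == 1))
  expect_true(all(n$depth_mother == 1))   # scale invariance
  d2 <- d; d2$depth_proband[5] <- 90
  n2 <- normalize_depth(d2)
  expect_equal(n2$depth_proband[5], 3)
  d3 <- d; d3$depth_father <- 0
  expect_error(normalize_depth(d3), "not positive")
})

test_that("constant sequences yield no changepoints", {
  set.seed(1)
  expect_equal(segment_cbs(rep(1, 50)), integer())
  expect_equal(segment_cbs(rep(0, 200)), integer())
  # fewer points than 2 * min_width: single segment
  expect_equal(segment_cbs(c(1, 0, 5), min_width = 3L), integer())
})

test_that("a noiseless step is split exactly at the step", {
  x <- c(rep(1, 100), rep(0, 150))
  set.seed(2)
  expect_equal(segment_cbs(x), 100L)
  # the chosen split agrees with the exhaustive arc search
  b <- trioscan:::.cbs_best_split(x, 3L)
  o <- cbs_oracle_best(x, 3L)
  expect_equal(b$t, o$t)
  expect_equal(c(b$i, b$j), c(o$i, o$j))
})

test_that("best split matches the exhaustive oracle on noisy inputs", {
  set.seed(14)
  for (rep in 1:5) {
    n <- sample(30:120, 1)
    x <- rnorm(n) + rep(c(0, sample(c(0, 2), 1)), c(n %/% 2, n - n %/% 2))
    b <- trioscan:::.cbs_best_split(x, 3L)
    o <- cbs_oracle_best(x, 3L)
    expect_equal(b$t, o$t, tolerance = 1e-10)
    expect_setequal(split_boundaries(b, n), split_boundaries(o, n))
  }
})

test_that("segmentation is shift-invariant and scale-equivariant", {
  set.seed(3)
  x <- c(rnorm(80, 1, 0.1), rnorm(60, 0.2, 0.1), rnorm(80, 1, 0.1))
  set.seed(10); a <- segment_cbs(x)
  set.seed(10); b <- segment_cbs(x + 5)
  set.seed(10); c <- segment_cbs(x * 7)
  expect_equal(a, b)
  expect_equal(a, c)
  expect_true(length(a) > 0)
})

test_that("copy states follow the normalized-depth thresholds", {
  segs <- data.frame(contig = "chr1", start = c(0L, 1000L), end = c(1000L, 2000L),
                     n_bins = 1L,
                     mean_father = c(0.51, 1.0), mean_mother = c(0.49, 1.0),
                     mean_proband = c(0.02, 1.0))
  st <- call_copy_states(segs)
  expect_equal(st$state_proband, c("hom_del", "normal"))
  expect_equal(st$state_father, c("hemi", "normal"))
  expect_equal(st$state_mother, c("hemi", "normal"))
  cls <- classify_inheritance(st)
  expect_equal(cls$inheritance, c("inherited_recessive", "other"))
  # boundary arithmetic of the state map
  expect_equal(unname(trioscan:::depth_state(c(0, 0.249, 0.25, 0.749, 0.75,
                                               1.249, 1.25, 2))),
               c("hom_del", "hom_del", "hemi", "hemi", "normal", "normal",
                 "gain", "gain"))
})

test_that("inheritance rule distinguishes de novo from inherited loss", {
  segs <- data.frame(contig = "chr1", start = c(0L, 1L, 2L) * 1000L,
                     end = c(1L, 2L, 3L) * 1000L, n_bins = 1L,
                     mean_father = c(0.5, 1, 1), mean_mother = c(0.5, 1, 1),
                     mean_proband = c(0.1, 0.5, 1))
  cls <- classify_inheritance(call_copy_states(segs))
  expect_equal(cls$inheritance, c("inherited_recessive", "de_novo", "other"))
})

test_that("depth simulation honours copy states and noise settings", {
  cfg <- sim_config(seed = 5, contigs = c(chr1 = 100000L), n_genes = 0L,
                    n_inherited_variants = 0L, n_denovo_snv = 0L,
                    n_denovo_indel = 0L, n_denovo_exonic = 0L,
                    cpg_fraction = 0, ts_fraction = 0,
                    compound_het_genes = 0L, n_artifact_indels = 0L,
                    depth_noise_sd = 0,
                    cnv_events = data.frame(contig = "chr1", start = 20000L,
                                            end = 50000L, child_copies = 0L,
                                            parent_copies = 1L))
  d <- generate_depth_profile(cfg)
  inside <- d$start >= 20000 & d$end <= 50000
  expect_true(all(d$depth_proband[inside] == 0))
  expect_true(all(d$depth_father[inside] == 15))
  expect_true(all(d$depth_proband[!inside] == 30))   # sd 0: exact mean
  # single-bin deletion: exactly one low bin
  cfg1 <- sim_config(seed = 5, contigs = c(chr1 = 100000L), n_genes = 0L,
                     n_inherited_variants = 0L, n_denovo_snv = 0L,
                     n_denovo_indel = 0L, n_denovo_exonic = 0L,
                     cpg_fraction = 0, ts_fraction = 0,
                     compound_het_genes = 0L, n_artifact_indels = 0L,
                     depth_noise_sd = 0,
                     cnv_events = data.frame(contig = "chr1", start = 7000L,
                                             end = 8000L, child_copies = 0L,
                                             parent_copies = 2L))
  d1 <- generate_depth_profile(cfg1)
  expect_equal(sum(d1$depth_proband == 0), 1L)
  expect_equal(which(d1$depth_proband == 0), 8L)
  # overlapping events rejected
  expect_error(sim_config(seed = 1, contigs = c(chr1 = 100000L),
                          cnv_events = data.frame(
                            contig = "chr1", start = c(0L, 5000L),
                            end = c(10000L, 15000L),
                            child_copies = 0L, parent_copies = 1L)),
               "non-overlapping")
})

test_that("trio segmentation recovers a planted deletion with states", {
  cfg <- sim_config(seed = 9, contigs = c(chr1 = 300000L), n_genes = 0L,
                    n_inherited_variants = 0L, n_denovo_snv = 0L,
                    n_denovo_indel = 0L, n_denovo_exonic = 0L,
                    cpg_fraction = 0, ts_fraction = 0,
                    compound_het_genes = 0L, n_artifact_indels = 0L,
                    cnv_events = data.frame(contig = "chr1", start = 100000L,
                                            end = 140000L, child_copies = 0L,
                                            parent_copies = 1L))
  d <- normalize_depth(generate_depth_profile(cfg))
  set.seed(31)
  segs <- classify_inheritance(call_copy_states(segment_trio(d)))
  hd <- segs[segs$state_proband == "hom_del", ]
  expect_equal(nrow(hd), 1L)
  expect_equal(hd$start, 100000L)
  expect_equal(hd$end, 140000L)
  expect_equal(hd$inheritance, "inherited_recessive")
  # segments partition the contig
  expect_equal(sum(segs$end - segs$start), 300000L)
  expect_equal(segs$start[-1], segs$end[-nrow(segs)])
})
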