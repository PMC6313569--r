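test_that("pairwise_absent matches exhaustive enumeration over the 3x3 grid", {
  gts <- c("0/0", "0/1", "1/1")
  grid <- expand.grid(parent = gts, proband = gts, stringsAsFactors = FALSE)
  got <- pairwise_absent(grid$parent, grid$proband)
  # brute-force oracle: parse allele sets directly
  oracle <- mapply(function(pa, pr) {
    pa_al <- as.integer(strsplit(pa, "/")[[1]])
    pr_al <- as.integer(strsplit(pr, "/")[[1]])
    any(pr_al == 1L) && !any(pa_al == 1L)
  }, grid$parent, grid$proband)
  expect_equal(got, unname(oracle))
  # missing genotypes are NA, not FALSE
  expect_true(is.na(pairwise_absent("./.", "0/1")))
  expect_true(is.na(pairwise_absent("0/0", "./.")))
})

test_that("detect_denovo requires absence from BOTH parents", {
  v <- make_variants("chr1", c(10L, 20L, 30L), "A", "T",
                     gt_father = c("0/0", "0/1", "0/0"),
                     gt_mother = c("0/0", "0/0", "0/1"),
                     gt_proband = c("0/1", "0/1", "0/1"))
  cand <- detect_denovo(v)
  expect_equal(cand$pos, 10L)
  # intersection identity with the two single-parent comparisons
  vs_f <- pairwise_absent(v$gt_father, v$gt_proband)
  vs_m <- pairwise_absent(v$gt_mother, v$gt_proband)
  expect_equal(cand$pos, v$pos[vs_f & vs_m])
})

test_that("detection is invariant to swapping the parents", {
  sim <- generate_trio(mini_sim_config(seed = 11))
  v <- sim$variants
  sw <- v
  sw$gt_father <- v$gt_mother; sw$gt_mother <- v$gt_father
  sw$dp_father <- v$dp_mother; sw$dp_mother <- v$dp_father
  sw$gq_father <- v$gq_mother; sw$gq_mother <- v$gq_father
  a <- detect_denovo(v); b <- detect_denovo(sw)
  expect_equal(a$pos, b$pos)
  expect_equal(a$contig, b$contig)
})

test_that("QC failures make sites unevaluable, never de novo", {
  v <- make_variants("chr1", c(10L, 20L, 30L, 40L), "A", "T")
  v$gq_mother[2] <- 5L          # below min_gq
  v$dp_father[3] <- 4L          # below min_dp
  v$gt_mother[4] <- "./."
  cand <- detect_denovo(v)
  expect_equal(cand$pos, 10L)
  expect_equal(attr(cand, "unevaluable"), 3L)
  # thresholds are configurable
  cand2 <- detect_denovo(v, qc = list(min_dp = 1L, min_gq = 1L))
  expect_equal(cand2$pos, c(10L, 20L, 30L))
})

test_that("edge-read indel filter applies the inclusive 10 bp margin", {
  v <- make_variants("chr1", c(10L, 20L, 30L, 40L),
                     ref = c("ATT", "ATT", "ATT", "ATT"), alt = "A",
                     rl_proband = 101L,
                     ro_proband = c("3|97", "50", "10", "11"))
  keep <- filter_edge_indels(v)
  expect_equal(keep, c(FALSE, TRUE, FALSE, TRUE))
  # no read support: kept, with a warning
  v2 <- make_variants("chr1", 10L, "ATT", "A")
  expect_warning(k2 <- filter_edge_indels(v2), "read-support")
  expect_true(k2)
  # SNVs are never touched
  v3 <- make_variants("chr1", 10L, "A", "T")
  expect_true(filter_edge_indels(v3))
  # candidates with edge-only support are dropped by detect_denovo
  cand <- detect_denovo(v)
  expect_equal(cand$pos, c(20L, 40L))
})

test_that("spectrum reproduces the worked ratio and proportion examples", {
  n_ts <- 62L; n_tv <- 32L; n_cpg <- 18L
  cand <- make_variants("chr1", seq_len(n_ts + n_tv) * 10L,
                        ref = "C",
                        alt = c(rep("T", n_ts), rep("A", n_tv)))
  cand$is_transition <- c(rep(TRUE, n_ts), rep(FALSE, n_tv))
  cand$is_cpg <- c(rep(TRUE, n_cpg), rep(FALSE, n_ts + n_tv - n_cpg))
  spec <- mutation_spectrum(cand, L = 3137161264)
  expect_equal(round(spec$titv, 1), 1.9)
  expect_equal(round(spec$cpg_proportion, 2), 0.19)
  expect_equal(spec$n_transition + spec$n_transversion, spec$n_snv)
})

test_that("rate is homogeneous in genome length and zero for empty input", {
  cand <- make_variants("chr1", (1:10) * 5L, "A", "G")
  cand$is_transition <- TRUE; cand$is_cpg <- FALSE
  s1 <- mutation_spectrum(cand, L = 1e6)
  s2 <- mutation_spectrum(cand, L = 2e6)
  expect_equal(s1$rate, 2 * s2$rate)
  expect_equal(s1$rate, 10 / (2 * 1e6))
  empty <- cand[0, ]
  s0 <- mutation_spectrum(empty, L = 1e6)
  expect_equal(s0$rate, 0)
  expect_true(is.na(s0$titv))   # undefined, reported as absent
})

test_that("a null simulation yields no de novo candidates", {
  cfg <- mini_sim_config(seed = 4, n_denovo_snv = 0L, n_denovo_indel = 0L,
                         n_denovo_exonic = 0L, cpg_fraction = 0,
                         ts_fraction = 0, n_artifact_indels = 0L)
  sim <- generate_trio(cfg)
  expect_equal(nrow(detect_denovo(sim$variants)), 0L)
})

test_that("detector recovers exactly the planted truth on simulations", {
  for (seed in c(5, 23)) {
    sim <- generate_trio(mini_sim_config(seed = seed))
    cand <- detect_denovo(sim$variants)
    truth <- sim$truth$denovo_events
    expect_equal(nrow(cand), nrow(truth))
    expect_setequal(paste(cand$contig, cand$pos),
                    paste(truth$contig, truth$pos))
  }
})
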