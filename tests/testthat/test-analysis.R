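test_that("downsample caps at availability and keeps composition unbiased", {
  p <- tiny_panel()
  sim <- simulate_reads(p, sim_config(level = 0.5, mean_coverage = 500,
                                      dispersion = 0, conversion_rate = 1,
                                      seq_error = 0, seed = 61))
  asg <- assign_reads(sim$reads, p)
  # available < target: unchanged
  full <- downsample(asg, 1000, seed = 1)
  expect_equal(nrow(full), nrow(asg))
  ds <- downsample(asg, 100, seed = 2)
  expect_equal(unname(table(ds$amplicon)), c(100L, 100L),
               ignore_attr = TRUE)
  # deterministic under seed
  expect_equal(downsample(asg, 100, seed = 2), ds)
  # expectation of downsampled beta equals full-data beta (averaged
  # over seeds)
  beta_full <- summarise_amplicons(call_methylation(asg, p))$amplicon_beta
  betas <- vapply(1:30, function(s) {
    d <- downsample(asg, 100, seed = s)
    mean(summarise_amplicons(call_methylation(d, p))$amplicon_beta)
  }, numeric(1))
  expect_lt(abs(mean(betas) - mean(beta_full)), 0.02)
  # all reads identical: beta unchanged exactly
  asg_c <- dplyr::mutate(asg, pattern = strrep("C", nchar(pattern)))
  d <- downsample(asg_c, 50, seed = 3)
  expect_true(all(call_methylation(d, p)$beta == 1))
})

test_that("downsample_counts follows the hypergeometric expectation", {
  draws <- vapply(1:1000, function(s) {
    downsample_counts(30, 70, 50, seed = s)$meth
  }, numeric(1))
  expect_gte(mean(draws), 14.5)
  expect_lte(mean(draws), 15.5)
  # cap at availability
  expect_equal(downsample_counts(3, 4, 100, seed = 1),
               tibble::tibble(meth = 3L, unmeth = 4L),
               ignore_attr = TRUE)
})

test_that("sensitivity_test separates a 5% spike from the 0% control", {
  pools <- sensitivity_pools(levels = c(0, 0.05), replicates = 3,
                             depth = 10000, n_cpg = 4,
                             conversion_rate = 0.995, seed = 62)
  res <- sensitivity_test(pools, coverages = c(100, 10000), seed = 63)
  expect_equal(nrow(res), 2)
  deep <- dplyr::filter(res, coverage == 10000)
  expect_lt(deep$p, 0.001)
  expect_true(deep$stars %in% c("***", "****"))
  expect_gt(deep$delta, 0.03)
  # identical groups (same seed, same level) are not significant
  pools0 <- sensitivity_pools(levels = 0, replicates = 3, depth = 10000,
                              n_cpg = 4, conversion_rate = 0.995, seed = 69)
  pools_null <- dplyr::bind_rows(pools0,
                                 dplyr::mutate(pools0, level = 1e-9))
  res_null <- sensitivity_test(pools_null, baseline = 0,
                               coverages = 10000, seed = 64)
  expect_gt(res_null$p, 0.05)
  expect_equal(res_null$stars, "ns")
})

test_that("zero-variance groups yield NA p-values, not fabricated ones", {
  pools <- sensitivity_pools(levels = c(0, 0.01), replicates = 3,
                             depth = 50, n_cpg = 2,
                             conversion_rate = 1, seed = 65)
  # at conversion 1 and level 0 every replicate beta is exactly 0; force
  # the spike-in replicates constant too
  pools$calls <- lapply(pools$calls, function(m) {
    m[] <- 0L
    m
  })
  res <- sensitivity_test(pools, coverages = 50, seed = 66)
  expect_true(is.na(res$p))
  expect_true(is.na(res$stars))
  expect_false(res$significant)
})

test_that("binomial pooled test is available as an alternative", {
  pools <- sensitivity_pools(levels = c(0, 0.05), replicates = 3,
                             depth = 5000, n_cpg = 4,
                             conversion_rate = 0.995, seed = 67)
  res <- sensitivity_test(pools, coverages = 5000, test = "binomial",
                          seed = 68)
  expect_lt(res$p, 1e-4)
})

test_that("pattern_matrix tabulates epiallele frequencies", {
  asg <- tibble::tibble(
    read_id = sprintf("r%03d", 1:100), amplicon = "amp36", strand = "OT",
    offset = 0L, n_mismatch = 0L,
    pattern = c(rep("TTTT", 96), rep("CTTT", 4)),
    n_conv = 0L, n_ret = 0L
  )
  pm <- pattern_matrix(asg, sample = "LNCaP")
  expect_equal(pm$frequency[pm$pattern == "TTTT"], 0.96)
  expect_equal(pm$frequency[pm$pattern == "CTTT"], 0.04)
  mm <- pattern_mean_meth(pm)
  expect_equal(mm$mean_meth, 0.04 * 1 / 4)
  # all-methylated reads: single pattern, mean 100%
  asg$pattern <- "CCCC"
  pm2 <- pattern_matrix(asg)
  expect_equal(nrow(pm2), 1)
  expect_equal(pattern_mean_meth(pm2)$mean_meth, 1)
  # empty input
  expect_equal(nrow(pattern_matrix(asg[0, ])), 0)
  # N-containing patterns are reported but excluded from normalisation
  asg3 <- dplyr::mutate(asg,
                        pattern = c(rep("CCCC", 50), rep("CNCC", 10),
                                    rep("TTTT", 40)))
  pm3 <- pattern_matrix(asg3)
  expect_true(is.na(pm3$frequency[pm3$pattern == "CNCC"]))
  expect_equal(sum(pm3$frequency, na.rm = TRUE), 1)
})

test_that("pattern-weighted mean equals per-CpG mean beta on N-free reads", {
  p <- tiny_panel()
  for (s in 1:3) {
    sim <- simulate_reads(p, sim_config(level = runif(1),
                                        mean_coverage = 200,
                                        dispersion = 0, seq_error = 0,
                                        conversion_rate = 0.99, seed = s))
    asg <- assign_reads(sim$reads, p)
    pm <- pattern_mean_meth(pattern_matrix(asg))
    tab <- summarise_amplicons(call_methylation(asg, p))
    j <- dplyr::inner_join(pm, tab, by = c("sample", "amplicon"))
    expect_equal(j$mean_meth, j$amplicon_beta, tolerance = 1e-12)
  }
})

test_that("platform_compare reports per-sample correlation over shared CpGs", {
  base <- tidyr::expand_grid(
    sample = c("LNCaP", "PrEC"),
    amplicon = sprintf("a%02d", 1:20),
    cpg_offset = c(0L, 10L, 20L, 30L)
  )
  withr::with_seed(71, {
    base$beta <- runif(nrow(base))
  })
  # identical tables: r = 1
  res <- platform_compare(base, base)
  expect_equal(res$r, c(1, 1))
  expect_equal(res$n_sites, c(80L, 80L))
  # anti-symmetric tables: r = -1
  flipped <- dplyr::mutate(base, beta = 1 - beta)
  expect_equal(platform_compare(base, flipped)$r, c(-1, -1))
  # additive noise over 158 shared sites keeps r in [0.9, 1]
  sites <- tidyr::expand_grid(sample = "s", amplicon = sprintf("a%03d", 1:79),
                              cpg_offset = c(0L, 10L))
  hits <- vapply(1:60, function(s) {
    withr::with_seed(200 + s, {
      a <- dplyr::mutate(sites, beta = runif(dplyr::n()))
      b <- dplyr::mutate(a, beta = pmin(1, pmax(0, beta + rnorm(dplyr::n(), 0, 0.05))))
      r <- platform_compare(a, b)$r
      r >= 0.9 && r <= 1
    })
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # fewer than 3 shared sites is an error
  expect_error(platform_compare(base[1:2, ], base[1:2, ]), "fewer than 3")
})

test_that("delta mode correlates per-amplicon methylation differences", {
  base <- tidyr::expand_grid(
    sample = c("LNCaP", "PrEC"),
    amplicon = sprintf("a%02d", 1:15),
    cpg_offset = c(0L, 10L)
  )
  withr::with_seed(72, base$beta <- runif(nrow(base)))
  res <- platform_compare(base, base, mode = "delta",
                          pair = c("LNCaP", "PrEC"))
  expect_equal(res$r, 1)
  expect_equal(res$n_sites, 15L)
  expect_equal(res$sample, "LNCaP-PrEC")
})

test_that("detection_limits extracts minimum significant level and coverage", {
  res <- tibble::tibble(
    amplicon = "a", coverage = c(100, 1000, 100, 1000),
    level = c(0.01, 0.01, 0.05, 0.05), baseline = 0,
    delta = 0.01, p = c(0.4, 0.01, 0.001, 0.001),
    stars = p_stars(p), significant = p < 0.05
  )
  lim <- detection_limits(res)
  expect_equal(lim$min_level$min_level[lim$min_level$coverage == 100], 0.05)
  expect_equal(lim$min_level$min_level[lim$min_level$coverage == 1000], 0.01)
  expect_equal(
    lim$min_coverage$min_coverage[lim$min_coverage$level == 0.01], 1000)
})
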