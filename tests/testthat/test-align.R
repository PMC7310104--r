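test_that("trim_reads clips, quality-trims and length-filters", {
  # 25 bp all-Q40: only the end clip applies
  out <- trim_reads(read_tbl(strrep("A", 25)))
  expect_equal(nchar(out$seq), 23)
  # 30 bp with a 10-base Q2 tail: forced below min_len, discarded
  qual <- paste0(strrep("I", 20), strrep("#", 10))
  out <- suppressMessages(trim_reads(read_tbl(strrep("A", 30), qual)))
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "n_discarded"), 1)
  # boundary: retained length exactly min_len is kept
  out <- trim_reads(read_tbl(strrep("A", 22)))
  expect_equal(nchar(out$seq), 20)
  # quality trimming + length filter (clip already applied) is idempotent
  p <- tiny_panel()
  cfg <- sim_config(level = 0.2, mean_coverage = 100, dispersion = 0,
                    quality = list(model = "degraded", q = 40,
                                   degrade_prob = 0.4, tail = 15,
                                   tail_q = 2),
                    seed = 21)
  reads <- simulate_reads(p, cfg)$reads
  once <- suppressMessages(trim_reads(reads, clip = 0))
  twice <- suppressMessages(trim_reads(once, clip = 0))
  expect_equal(twice, once, ignore_attr = TRUE)
})

test_that("assign_reads matches bisulphite-converted reads and applies the mismatch cap", {
  p <- tiny_panel()
  # OT bisulphite reference with all CpGs read as T = fully unmethylated read
  ref <- p$amplicons$ref_seq[1]
  unmeth <- chartr("C", "T", ref)
  asg <- assign_reads(read_tbl(unmeth), p)
  expect_equal(asg$amplicon, "ampA")
  expect_equal(asg$strand, "OT")
  expect_equal(asg$n_mismatch, 0L)
  expect_equal(asg$pattern, strrep("T", length(p$amplicons$cpg_offsets[[1]])))
  # two substitutions at non-C, non-CpG positions exceed max_mismatch = 1
  ch <- s2c(unmeth)
  at <- which(ch == "A")[1:2]
  ch[at] <- "G"
  asg2 <- assign_reads(read_tbl(paste(ch, collapse = "")), p)
  expect_equal(asg2$amplicon, "UNASSIGNED")
  # a read matching two identical amplicons equally is AMBIGUOUS
  pdup <- bs_panel(tibble::tibble(
    id = c("d1", "d2"), chrom = "c", start = 0,
    end = nchar(ref), ref_seq = ref
  ))
  asg3 <- assign_reads(read_tbl(unmeth), pdup)
  expect_equal(asg3$amplicon, "AMBIGUOUS")
  tab <- call_methylation(asg3, pdup)
  expect_true(all(tab$coverage == 0))
  expect_error(assign_reads(read_tbl(unmeth),
                            bs_panel(tibble::tibble(
                              id = character(), chrom = character(),
                              start = integer(), end = integer(),
                              ref_seq = character()))),
               "amplicons")
})

test_that("OB-strand reads are recognised and read out through G/A", {
  p <- tiny_panel()
  cfg <- sim_config(level = 0.5, conversion_rate = 1, seq_error = 0,
                    mean_coverage = 60, dispersion = 0, strand_mix = 0,
                    seed = 22)
  sim <- simulate_reads(p, cfg)
  asg <- assign_reads(sim$reads, p)
  expect_true(all(asg$strand == "OB"))
  j <- dplyr::inner_join(asg, sim$truth,
                         by = c(read_id = "read_id"),
                         suffix = c("", ".truth"))
  expect_equal(j$pattern,
               callable_pattern(j$apparent, j$amplicon_id, p))
})

test_that("call_methylation counts reads per CpG and averages per amplicon", {
  p <- bs_panel(tibble::tibble(
    id = "a", chrom = "c", start = 0, end = 12, ref_seq = "ATCGATTACGAT"
  ))
  asg <- tibble::tibble(
    read_id = sprintf("r%d", 1:4), amplicon = "a", strand = "OT",
    offset = 0L, n_mismatch = 0L,
    pattern = c("CT", "CT", "CT", "TT"),
    n_conv = 0L, n_ret = 0L
  )
  tab <- call_methylation(asg, p)
  expect_equal(tab$meth, c(3L, 0L))
  expect_equal(tab$unmeth, c(1L, 4L))
  expect_equal(tab$beta, c(0.75, 0))
  expect_equal(tab$coverage, c(4L, 4L))
  sm <- summarise_amplicons(tab)
  expect_equal(sm$amplicon_beta, 0.375)
  # all-C saturation
  asg$pattern <- "CC"
  expect_true(all(call_methylation(asg, p)$beta == 1))
  # no reads: coverage 0, betas undefined
  tab0 <- call_methylation(asg[0, ], p)
  expect_equal(tab0$coverage, c(0L, 0L))
  expect_true(all(is.na(tab0$beta)))
  expect_true(is.na(summarise_amplicons(tab0)$amplicon_beta))
})

test_that("N calls count towards neither allele", {
  p <- bs_panel(tibble::tibble(
    id = "a", chrom = "c", start = 0, end = 12, ref_seq = "ATCGATTACGAT"
  ))
  asg <- tibble::tibble(
    read_id = c("r1", "r2"), amplicon = "a", strand = "OT", offset = 0L,
    n_mismatch = 0L, pattern = c("CN", "TT"), n_conv = 0L, n_ret = 0L
  )
  tab <- call_methylation(asg, p)
  expect_equal(tab$meth + tab$unmeth, c(2L, 1L))
  expect_true(all(tab$meth + tab$unmeth <= tab$coverage))
})

test_that("conversion rate is estimated from non-CpG cytosines", {
  # direct arithmetic: 995 converted of 1000 informative positions
  asg <- tibble::tibble(
    read_id = "r", amplicon = "a", strand = "OT", offset = 0L,
    n_mismatch = 0L, pattern = "T", n_conv = 995L, n_ret = 5L
  )
  expect_equal(conversion_rate(asg), 0.995)
  # perfect conversion in simulation
  p <- tiny_panel()
  sim <- simulate_reads(p, sim_config(level = 0, conversion_rate = 1,
                                      seq_error = 0, mean_coverage = 50,
                                      dispersion = 0, seed = 23))
  expect_equal(conversion_rate(assign_reads(sim$reads, p)), 1)
  # c = 0.99 recovered within 3 binomial SE with >= 10,000 informative sites
  p2 <- synthetic_panel(n_amplicons = 2, n_cpg = 3, seed = 25)
  sim2 <- simulate_reads(p2, sim_config(level = 0, conversion_rate = 0.99,
                                        seq_error = 0, mean_coverage = 400,
                                        dispersion = 0, seed = 24))
  asg2 <- assign_reads(sim2$reads, p2)
  n_inf <- sum(asg2$n_conv + asg2$n_ret, na.rm = TRUE)
  expect_gt(n_inf, 10000)
  se <- sqrt(0.99 * 0.01 / n_inf)
  expect_lt(abs(conversion_rate(asg2) - 0.99), 3 * se)
  # no informative positions -> NA with warning
  expect_warning(out <- conversion_rate(asg[0, ]), "informative")
  expect_true(is.na(out))
})

test_that("matcher agrees with the exhaustive brute-force oracle", {
  set.seed(31)
  n_cases <- 150
  for (case in seq_len(n_cases)) {
    p <- random_small_panel()
    i <- sample(nrow(p$amplicons), 1)
    ref <- p$amplicons$ref_seq[i]
    len <- nchar(ref)
    kind <- sample(c("sim", "mutated", "random"), 1,
                   prob = c(0.4, 0.4, 0.2))
    seq <- if (kind == "random") {
      paste(sample(c("A", "C", "G", "T"), sample(25:len, 1),
                   replace = TRUE), collapse = "")
    } else {
      cfg <- sim_config(level = runif(1), mean_coverage = 1,
                        dispersion = 0, conversion_rate = runif(1, 0.9, 1),
                        seq_error = 0, strand_mix = sample(0:1, 1))
      s <- simulate_reads(p, cfg)$reads$seq[i]
      if (kind == "mutated") {
        ch <- s2c(s)
        nmut <- sample(0:3, 1)
        at <- sample(length(ch), nmut)
        ch[at] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
        s <- paste(ch, collapse = "")
      }
      # random sub-window
      w <- sample(20:nchar(s), 1)
      st <- sample(nchar(s) - w + 1, 1)
      substr(s, st, st + w - 1)
    }
    got <- assign_reads(read_tbl(seq), p)
    want <- oracle_assign(seq, p)
    expect_equal(got$amplicon, want$amplicon,
                 info = sprintf("case %d (%s)", case, kind))
    if (!want$amplicon %in% c("UNASSIGNED", "AMBIGUOUS")) {
      expect_equal(got$strand, want$strand, info = paste("case", case))
      expect_equal(got$offset, want$offset, info = paste("case", case))
      expect_equal(got$n_mismatch, want$n_mismatch,
                   info = paste("case", case))
    }
  }
})
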