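#' Downsample assigned reads per amplicon
#'
#' Uniform sampling without replacement to `min(target, available)` reads
#' per amplicon — the in-silico analogue of sequencing at lower depth.
#'
#' @param assignments tibble from [assign_reads()].
#' @param target_coverage reads to retain per amplicon (>= 1).
#' @param seed optional RNG seed (deterministic when given).
#' @param replace sample with replacement (bootstrap) instead of the
#'   default without-replacement subsample.
#' @return downsampled assignment tibble (unassigned/ambiguous rows are
#'   dropped).
#' @export
downsample <- function(assignments, target_coverage, seed = NULL,
                       replace = FALSE) {
  stopifnot(target_coverage >= 1)
  asg <- filter(assignments,
                !.data$amplicon %in% c("UNASSIGNED", "AMBIGUOUS"))
  with_seed_if(seed, {
    asg |>
      group_by(.data$amplicon) |>
      dplyr::slice_sample(n = target_coverage, replace = replace) |>
      ungroup()
  })
}

#' Downsample methylated/unmethylated counts
#'
#' Hypergeometric draw of the methylated count when a CpG's read pool is
#' subsampled without replacement to `target` reads.
#'
#' @param meth,unmeth observed counts (vectors recycle).
#' @param target target total count.
#' @param seed optional RNG seed.
#' @return tibble `meth`, `unmeth` after downsampling (totals capped at
#'   the available reads).
#' @export
downsample_counts <- function(meth, unmeth, target, seed = NULL) {
  stopifnot(target >= 1)
  n <- pmin(meth + unmeth, target)
  with_seed_if(seed, {
    m2 <- rhyper(length(meth), meth, unmeth, n)
    tibble(meth = m2, unmeth = n - m2)
  })
}

# Per-amplicon mean beta of a call matrix subsampled to `target` reads.
beta_at_coverage <- function(calls, target) {
  n <- nrow(calls)
  if (target < n) calls <- calls[sample.int(n, target), , drop = FALSE]
  mean(colMeans(calls))
}

#' Simulate replicate control read pools for sensitivity analysis
#'
#' One deep pool of per-read CpG calls per (level, replicate, amplicon),
#' generated with [simulate_calls()] at fixed depth — the in-silico
#' analogue of replicate sequencing runs of a methylated-control gradient.
#'
#' @param panel a [bs_panel] (its callable CpG counts size the patterns);
#'   alternatively pass `n_cpg` directly.
#' @param levels expected methylation fractions.
#' @param replicates replicates per level (>= 2 for testing).
#' @param depth reads per amplicon pool.
#' @param n_cpg integer vector of CpG counts, used when `panel` is `NULL`.
#' @param conversion_rate,inappropriate,bias as in [sim_config()].
#' @param seed optional RNG seed.
#' @return tibble `level`, `replicate`, `amplicon`, `n_cpg`, `calls`
#'   (list-column of call matrices).
#' @export
sensitivity_pools <- function(panel = NULL, levels, replicates = 3,
                              depth = 10000, n_cpg = NULL,
                              conversion_rate = 0.995, inappropriate = 0,
                              bias = 1, seed = NULL) {
  if (!is.null(panel)) {
    stopifnot(inherits(panel, "bs_panel"))
    amp_ids <- panel$amplicons$id
    n_cpg <- purrr::map_int(panel$amplicons$callable, sum)
  } else {
    stopifnot(!is.null(n_cpg))
    amp_ids <- sprintf("amp%02d", seq_along(n_cpg))
  }
  grid <- tidyr::expand_grid(
    level = levels, replicate = seq_len(replicates),
    tibble(amplicon = amp_ids, n_cpg = as.integer(n_cpg))
  )
  with_seed_if(seed, {
    grid$calls <- purrr::pmap(
      list(grid$level, grid$n_cpg),
      function(lv, k) {
        simulate_calls(depth, k, lv, conversion_rate = conversion_rate,
                       inappropriate = inappropriate, bias = bias)
      }
    )
    grid
  })
}

#' Sensitivity of methylation detection across a coverage grid
#'
#' For each coverage in the grid, each replicate pool is downsampled
#' without replacement, the per-amplicon mean beta computed, and each
#' non-baseline level compared with the baseline across replicates by a
#' one-sided (greater) Welch t-test — mirroring replicate sequencing runs
#' of a 0/1/5% control gradient. A pooled-count one-sided proportion test
#' is available as an alternative. p-values map onto the star scheme of
#' [p_stars()]; when both groups have zero variance the p-value is `NA`
#' rather than fabricated.
#'
#' @param pools tibble from [sensitivity_pools()].
#' @param baseline baseline level (default 0).
#' @param coverages coverage grid (default `c(100, 1000, 10000, 100000)`).
#' @param alpha significance level for the `significant` column.
#' @param test `"welch"` (default) or `"binomial"` (pooled counts).
#' @param p_adjust p-value adjustment method across amplicons per
#'   coverage/level (default `"none"`; the conventional report is
#'   per-amplicon stars).
#' @param seed optional RNG seed governing the downsampling draws.
#' @return tibble `amplicon`, `coverage`, `level`, `baseline`, `delta`
#'   (mean beta difference), `p`, `stars`, `significant`.
#' @export
sensitivity_test <- function(pools, baseline = 0,
                             coverages = c(100, 1000, 10000, 100000),
                             alpha = 0.05, test = c("welch", "binomial"),
                             p_adjust = "none", seed = NULL) {
  test <- match.arg(test)
  lv_other <- setdiff(unique(pools$level), baseline)
  if (!baseline %in% pools$level) abort("baseline level absent from pools")
  if (min(table(pools$level, pools$amplicon)) < 2 && test == "welch") {
    abort("need >= 2 replicates per level")
  }
  with_seed_if(seed, {
    rows <- purrr::map(coverages, function(cv) {
      # per replicate per amplicon: downsampled mean beta (+ pooled counts)
      stat <- pools |>
        mutate(
          n_eff = purrr::map_int(.data$calls, ~ min(nrow(.x), cv)),
          beta = purrr::map_dbl(.data$calls, beta_at_coverage, target = cv)
        )
      purrr::map(lv_other, function(lv) {
        purrr::map(unique(stat$amplicon), function(a) {
          x <- filter(stat, .data$level == lv, .data$amplicon == a)
          y <- filter(stat, .data$level == baseline, .data$amplicon == a)
          p <- if (test == "welch") {
            welch_p(x$beta, y$beta)
          } else {
            binom_p(x, y)
          }
          tibble(amplicon = a, coverage = cv, level = lv,
                 baseline = baseline,
                 delta = mean(x$beta) - mean(y$beta), p = p)
        }) |> bind_rows()
      }) |> bind_rows()
    }) |> bind_rows()
    rows <- rows |>
      group_by(.data$coverage, .data$level) |>
      mutate(p = p.adjust(.data$p, method = p_adjust)) |>
      ungroup() |>
      mutate(stars = p_stars(.data$p),
             significant = !is.na(.data$p) & .data$p < alpha)
    rows
  })
}

# One-sided Welch t-test (greater); NA when both groups are constant.
welch_p <- function(x, y) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) return(NA_real_)
  tryCatch(t.test(x, y, alternative = "greater")$p.value,
           error = function(e) NA_real_)
}

# Pooled-count one-sided proportion test on the downsampled pools.
binom_p <- function(x, y) {
  k <- x$n_cpg[1]
  mx <- round(sum(x$beta * x$n_eff * k)); nx <- sum(x$n_eff) * k
  my <- round(sum(y$beta * y$n_eff * k)); ny <- sum(y$n_eff) * k
  if (nx == 0 || ny == 0) return(NA_real_)
  suppressWarnings(
    prop.test(c(mx, my), c(nx, ny), alternative = "greater")$p.value
  )
}

#' Detection limits from a sensitivity result
#'
#' @param result tibble from [sensitivity_test()].
#' @param alpha significance level.
#' @return list with `min_level` (per amplicon x coverage, the smallest
#'   level significantly above baseline) and `min_coverage` (per amplicon
#'   x level, the lowest coverage at which that level is significant);
#'   `NA` where nothing is significant.
#' @export
detection_limits <- function(result, alpha = 0.05) {
  sig <- mutate(result, sig = !is.na(.data$p) & .data$p < alpha)
  min_level <- sig |>
    group_by(.data$amplicon, .data$coverage) |>
    summarise(
      min_level = if (any(.data$sig)) min(.data$level[.data$sig]) else NA_real_,
      .groups = "drop"
    )
  min_coverage <- sig |>
    group_by(.data$amplicon, .data$level) |>
    summarise(
      min_coverage = if (any(.data$sig)) min(.data$coverage[.data$sig]) else NA_real_,
      .groups = "drop"
    )
  list(min_level = min_level, min_coverage = min_coverage)
}

#' Repeat a sensitivity experiment over seeds
#'
#' Runs the full simulate-downsample-test experiment once per seed and
#' returns the stacked results, for power estimation and modal detection
#' limits.
#'
#' @param n_seeds number of repetitions.
#' @param seed master seed; per-repetition seeds derive from it.
#' @inheritParams sensitivity_pools
#' @inheritParams sensitivity_test
#' @return tibble of [sensitivity_test()] results with a `seed_index`
#'   column.
#' @export
sensitivity_power <- function(n_seeds = 50, seed = 1, panel = NULL,
                              levels = c(0, 0.01, 0.05), replicates = 3,
                              depth = 10000, n_cpg = NULL,
                              conversion_rate = 0.995, baseline = 0,
                              coverages = c(100, 1000, 10000, 100000),
                              alpha = 0.05, test = "welch") {
  sub_seeds <- with_seed_if(seed, sample.int(.Machine$integer.max - 1L,
                                             n_seeds))
  purrr::map2(seq_len(n_seeds), sub_seeds, function(i, s) {
    pools <- sensitivity_pools(panel = panel, levels = levels,
                               replicates = replicates, depth = depth,
                               n_cpg = n_cpg,
                               conversion_rate = conversion_rate, seed = s)
    sensitivity_test(pools, baseline = baseline, coverages = coverages,
                     alpha = alpha, test = test, seed = s + 1L) |>
      mutate(seed_index = i)
  }) |> bind_rows()
}

#' Epiallele pattern matrix
#'
#' Tabulates the distinct read-level methylation patterns (strings over
#' `C` = methylated, `T` = unmethylated per CpG) of each (sample,
#' amplicon), with counts and frequencies. Patterns containing `N`
#' (no-call) are reported but excluded from frequency normalisation by
#' default. The pattern-weighted mean methylation is the
#' frequency-weighted fraction of `C` symbols.
#'
#' @param assignments tibble from [assign_reads()], or several samples'
#'   assignments with a `sample` column.
#' @param sample sample label used when `assignments` has no `sample`
#'   column.
#' @return tibble of class `pattern_matrix`: `sample`, `amplicon`,
#'   `pattern`, `count`, `frequency`, `has_n`.
#' @export
pattern_matrix <- function(assignments, sample = "sample1") {
  asg <- filter(assignments,
                !.data$amplicon %in% c("UNASSIGNED", "AMBIGUOUS"),
                !is.na(.data$pattern), nchar(.data$pattern) > 0)
  if (!"sample" %in% names(asg)) asg$sample <- sample
  out <- asg |>
    count(.data$sample, .data$amplicon, .data$pattern, name = "count") |>
    mutate(has_n = stringr::str_detect(.data$pattern, "N")) |>
    group_by(.data$sample, .data$amplicon) |>
    mutate(frequency = if_else(
      .data$has_n, NA_real_,
      .data$count / sum(.data$count[!.data$has_n])
    )) |>
    ungroup() |>
    arrange(.data$sample, .data$amplicon, dplyr::desc(.data$count))
  class(out) <- c("pattern_matrix", class(out))
  out
}

#' Pattern-weighted mean methylation
#'
#' @param pm a [pattern_matrix()].
#' @return tibble `sample`, `amplicon`, `mean_meth` (frequency-weighted
#'   fraction of methylated CpG calls, over N-free patterns).
#' @export
pattern_mean_meth <- function(pm) {
  pm |>
    filter(!.data$has_n) |>
    mutate(c_frac = stringr::str_count(.data$pattern, "C") /
             nchar(.data$pattern)) |>
    group_by(.data$sample, .data$amplicon) |>
    summarise(mean_meth = sum(.data$frequency * .data$c_frac),
              .groups = "drop")
}

#' Cross-platform per-CpG methylation comparison
#'
#' Pearson correlation between two per-CpG beta tables over their shared
#' (amplicon, CpG) keys — e.g. a targeted multiplex assay against
#' whole-genome bisulphite data. `mode = "absolute"` correlates betas per
#' shared sample; `mode = "delta"` correlates per-amplicon mean
#' methylation differences between a pair of samples (`pair = c(s1, s2)`,
#' difference s1 - s2) as measured by the two platforms.
#'
#' @param table_a,table_b tibbles with `sample`, `amplicon`, `cpg_offset`,
#'   `beta`.
#' @param mode `"absolute"` or `"delta"`.
#' @param pair length-2 sample labels for `mode = "delta"`.
#' @return tibble with one row per sample (or one row for the pair):
#'   `sample`, `n_sites`, `r`, `p`.
#' @export
platform_compare <- function(table_a, table_b,
                             mode = c("absolute", "delta"), pair = NULL) {
  mode <- match.arg(mode)
  if (mode == "absolute") {
    joined <- inner_join(
      select(table_a, "sample", "amplicon", "cpg_offset", beta_a = "beta"),
      select(table_b, "sample", "amplicon", "cpg_offset", beta_b = "beta"),
      by = c("sample", "amplicon", "cpg_offset")
    ) |> filter(!is.na(.data$beta_a), !is.na(.data$beta_b))
    out <- purrr::map(split(joined, joined$sample), function(d) {
      if (nrow(d) < 3) {
        abort(sprintf("fewer than 3 shared CpG sites for sample %s",
                      d$sample[1]))
      }
      ct <- cor.test(d$beta_a, d$beta_b)
      tibble(sample = d$sample[1], n_sites = nrow(d),
             r = unname(ct$estimate), p = ct$p.value)
    })
    if (length(out) == 0) abort("no shared (sample, amplicon, CpG) keys")
    return(bind_rows(out))
  }
  stopifnot(length(pair) == 2)
  amp_delta <- function(tbl) {
    tbl |>
      filter(.data$sample %in% pair) |>
      group_by(.data$sample, .data$amplicon) |>
      summarise(mean_beta = mean(.data$beta, na.rm = TRUE),
                .groups = "drop") |>
      tidyr::pivot_wider(names_from = "sample", values_from = "mean_beta") |>
      mutate(delta = .data[[pair[1]]] - .data[[pair[2]]]) |>
      select("amplicon", "delta")
  }
  joined <- inner_join(amp_delta(table_a), amp_delta(table_b),
                       by = "amplicon", suffix = c("_a", "_b")) |>
    filter(!is.na(.data$delta_a), !is.na(.data$delta_b))
  if (nrow(joined) < 3) abort("fewer than 3 shared amplicons")
  ct <- cor.test(joined$delta_a, joined$delta_b)
  tibble(sample = paste(pair, collapse = "-"), n_sites = nrow(joined),
         r = unname(ct$estimate), p = ct$p.value)
}
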