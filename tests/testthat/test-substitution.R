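# Molecular-evolution statistics: densities, uniformity test, Fisher exact
# comparisons, Ka/Ks tallies, homoplasy detection.

test_that("segment densities reproduce the observed bp-per-change figures", {
  dens <- segment_density(c(17, 21, 27), c(L = 6374, M = 4063, S = 2948))
  expect_equal(dens$bp_per_change, c(375, 193, 109), tolerance = 0.005)
  # density x count recovers the segment length algebraically
  expect_equal(dens$bp_per_change * dens$count, dens$length)
  # zero counts are flagged, not a division error
  d0 <- segment_density(c(0, 5, 0), c(L = 6374, M = 4063, S = 2948))
  expect_true(all(d0$no_changes[c(1, 3)]))
  expect_true(all(is.na(d0$bp_per_change[c(1, 3)])))
})

test_that("chi-square uniformity test matches the Pearson formula and a MC null", {
  res <- chisq_uniform_test(c(17, 21, 27), c(6374, 4063, 2948))
  expect_equal(res$statistic, 17.61, tolerance = 0.001)
  expect_equal(res$df, 2)
  expect_lt(res$p.value, 0.05)
  expect_equal(res$expected, 65 * c(6374, 4063, 2948) / 13385)
  # counts exactly proportional to lengths: statistic 0, p = 1
  res0 <- chisq_uniform_test(c(6374, 4063, 2948) / 13385 * 100,
                             c(6374, 4063, 2948))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p.value, 1)
  # statistic invariant under scaling all lengths
  res2 <- chisq_uniform_test(c(17, 21, 27), 10 * c(6374, 4063, 2948))
  expect_equal(res2$statistic, res$statistic)
  # Monte-Carlo multinomial null agrees within 3 binomial s.e.
  set.seed(31)
  probs <- c(6374, 4063, 2948) / 13385
  draws <- stats::rmultinom(1e5, 65, probs)
  exp_counts <- 65 * probs
  stats_mc <- colSums((draws - exp_counts)^2 / exp_counts)
  p_mc <- mean(stats_mc >= res$statistic)
  se <- sqrt(res$p.value * (1 - res$p.value) / 1e5)
  expect_lt(abs(p_mc - res$p.value), 3 * se + 1e-6)
})

test_that("Fisher exact p-values match the printed bounds and enumeration", {
  p1 <- fisher_exact_2x2(matrix(c(5, 3, 5, 5), 2))    # incr vs decr, Ka/Ks
  expect_gt(p1, 0.66)
  expect_equal(p1, 0.664, tolerance = 0.001)
  p2 <- fisher_exact_2x2(matrix(c(2, 2, 0, 5), 2))    # PP vs ERA bottlenecks
  expect_equal(p2, 1 / 6, tolerance = 1e-8)
  expect_gt(p2, 0.05)
  # identical rows -> p = 1; empty margin -> p = 1 by convention
  expect_equal(fisher_exact_2x2(matrix(c(4, 4, 2, 2), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 5), 2)), 1)
  # equals full hypergeometric enumeration for random tables with N <= 50
  set.seed(13)
  for (i in 1:40) {
    tab <- matrix(stats::rpois(4, sample(1:8, 1)), 2)
    if (sum(tab) > 50) next
    expect_equal(fisher_exact_2x2(tab), oracle_fisher(tab), tolerance = 1e-10)
  }
})

test_that("Ka/Ks tallies preserve rows and recover planted classes", {
  planted <- data.frame(
    branch = c("b1", "b1", "b2", "b2", "b2", "b3"),
    segment = "S", position = 1:6, ref = "A", alt = "C",
    class = c("nonsynonymous", "synonymous", "nonsynonymous",
              "nonsynonymous", "noncoding", "synonymous"),
    gene = "", label = "", stringsAsFactors = FALSE)
  regimes <- c(b1 = "ERA_large", b2 = "PP_large", b3 = "PP_large")
  st <- substitution_table(planted, regimes)
  kk <- kaks_by_regime(st)
  expect_equal(kk$ka[kk$regime == "ERA_large"], 1)
  expect_equal(kk$ks[kk$regime == "ERA_large"], 1)
  expect_equal(kk$ka[kk$regime == "PP_large"], 2)
  expect_equal(kk$ks[kk$regime == "PP_large"], 1)
  expect_equal(kk$noncoding[kk$regime == "PP_large"], 1)
  # row conservation: no substitutions lost by the group-by
  expect_equal(sum(kk$total), nrow(planted))
  # empty table -> all zeros for requested regimes
  kk0 <- kaks_by_regime(st[0, ], regimes = c("PP_large"))
  expect_equal(kk0$total, 0)
  # unknown regime label is an error
  expect_error(kaks_by_regime(st, regimes = c("PP_large")), "unknown regime")
  expect_error(substitution_table(planted, regimes[1:2]), "without a regime")
})

test_that("homoplasy detection finds planted reversions and parallels", {
  d <- small_design()
  # single forward mutation: nothing to report
  one <- data.frame(branch = "B1", segment = "S", position = 10,
                    ref = "T", alt = "C", stringsAsFactors = FALSE)
  rep0 <- detect_homoplasy(d, one)
  expect_equal(nrow(rep0$reversions), 0L)
  expect_equal(nrow(rep0$parallels), 0L)
  # forward T->C on an early branch, C->T on a descendant: one reversion
  ev <- rbind(one, data.frame(branch = "F1", segment = "S", position = 10,
                              ref = "C", alt = "T"))
  rep1 <- detect_homoplasy(d, ev)
  expect_equal(nrow(rep1$reversions), 1L)
  expect_identical(rep1$reversions$forward_branch, "B1")
  expect_identical(rep1$reversions$reverting_branch, "F1")
  # identical change on non-ancestral branches: one parallel event
  ev2 <- data.frame(branch = c("C1", "C2"), segment = "M", position = 5,
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  rep2 <- detect_homoplasy(d, ev2)
  expect_equal(nrow(rep2$parallels), 1L)
  expect_identical(rep2$parallels$branches, "C1,C2")
  # the same change on an ancestral path is NOT parallel
  ev3 <- data.frame(branch = c("B1", "F1"), segment = "M", position = 5,
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  rep3 <- detect_homoplasy(d, ev3)
  expect_equal(nrow(rep3$parallels), 0L)
  expect_error(detect_homoplasy(d, data.frame(branch = "Z9", segment = "S",
                                              position = 1, ref = "A",
                                              alt = "C")),
               "not in tree")
})

test_that("homoplasy report matches a brute-force pairwise oracle", {
  d <- small_design()
  anc_of <- list(B1 = character(0), C1 = "B1", C2 = "B1",
                 F1 = c("C1", "B1"), F2 = c("C1", "B1"),
                 F3 = c("C2", "B1"), F4 = c("C2", "B1"))
  set.seed(41)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    ev <- data.frame(
      branch = sample(d$branch, n, replace = TRUE),
      segment = "S",
      position = sample(1:4, n, replace = TRUE),
      ref = sample(c("A", "C"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    ev$alt <- ifelse(ev$ref == "A", "C", "A")
    got <- detect_homoplasy(d, ev)
    # oracle: quadratic scan over ordered event pairs
    n_rev <- 0; par_pairs <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      same_site <- ev$position[i] == ev$position[j]
      if (!same_site) next
      if (ev$branch[i] %in% anc_of[[ev$branch[j]]] &&
          ev$alt[j] == ev$ref[i] && ev$ref[j] == ev$alt[i])
        n_rev <- n_rev + 1
    }
    expect_equal(nrow(got$reversions), n_rev)
    # every reported parallel set is pairwise non-ancestral with identical
    # events present in the input
    if (nrow(got$parallels)) {
      for (r in seq_len(nrow(got$parallels))) {
        brs <- strsplit(got$parallels$branches[r], ",")[[1]]
        expect_gte(length(brs), 2)
        for (a in brs) for (b in setdiff(brs, a))
          expect_false(a %in% anc_of[[b]])
        for (b in brs)
          expect_true(any(ev$branch == b &
                            ev$position == got$parallels$position[r] &
                            ev$ref == got$parallels$ref[r] &
                            ev$alt == got$parallels$alt[r]))
      }
    }
  }
})

test_that("sparse mutation histories yield empty homoplasy reports", {
  # when every site mutates at most once there is nothing homoplasious
  d <- small_design()
  set.seed(51)
  for (rep in 1:10) {
    pos <- sample(1:2948, 6)          # distinct sites
    ev <- data.frame(branch = sample(d$branch, 6, replace = TRUE),
                     segment = "S", position = pos, ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
    got <- detect_homoplasy(d, ev)
    expect_equal(nrow(got$reversions) + nrow(got$parallels), 0L)
  }
})
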