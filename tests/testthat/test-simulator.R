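# Forward simulator: plaque model, mutation draws, serial transfers, and the
# full bifurcating experiment.

test_that("plaque growth model is exact integer arithmetic", {
  expect_identical(plaque_final_size(100, 5), 1e10)
  expect_identical(plaque_final_size(7, 0), 1)
  # equals repeated multiplication for assorted cases
  for (b in c(2, 3, 10)) for (g in c(1, 4, 7)) {
    prod <- 1; for (i in seq_len(g)) prod <- prod * b
    expect_identical(plaque_final_size(b, g), prod)
  }
  expect_error(plaque_final_size(0, 3))
  expect_error(plaque_final_size(100, -1))
})

test_that("expected bottleneck load matches its Monte-Carlo counterpart", {
  expect_equal(expected_fixed_mutations(0.067, 20), 1.34)
  expect_equal(expected_fixed_mutations(0, 50), 0)
  totals <- simulate_bottleneck_load(1e5, n_events = 20, u_event = 0.067,
                                     seed = 4)
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - expected_fixed_mutations(0.067, 20)), 3 * se)
})

test_that("lineage mutation draws follow the stamping-machine Poisson model", {
  p <- sim_params()
  expect_identical(draw_lineage_mutations(sim_params(mu = 0), 13385, 5,
                                          n = 100)$counts,
                   rep(0L, 100))
  set.seed(5)
  d <- draw_lineage_mutations(p, 13385, 5, n = 1e5)
  lambda <- 2e-6 * 13385 * 5
  se <- sqrt(lambda / 1e5)
  expect_lt(abs(mean(d$counts) - lambda), 3 * se)
  # geometric mode: same mean, larger variance
  pg <- sim_params(replication = "geometric")
  dg <- draw_lineage_mutations(pg, 13385, 5, n = 1e5)
  expect_lt(abs(mean(dg$counts) - lambda), 4 * se)
  expect_gt(var(dg$counts), var(d$counts))
  # determinism under a fixed seed
  a <- local({
    set.seed(77); draw_lineage_mutations(p, 1000, 5, n = 50, positions = TRUE)
  })
  b <- local({
    set.seed(77); draw_lineage_mutations(p, 1000, 5, n = 50, positions = TRUE)
  })
  expect_identical(a, b)
})

test_that("a transfer with mu = 0 changes nothing but the day counter", {
  p <- sim_params(mu = 0)
  st <- lineage_state(default_genome(), p)
  set.seed(9)
  st2 <- run_transfer(st, "PP", 1, p)
  expect_identical(st2$genotypes, st$genotypes)
  expect_identical(st2$day, st$day + 1L)
  # population bound: exactly N * burst^gens after growth
  expect_equal(sum(st2$counts), 1 * 100^5)
  st3 <- run_transfer(st2, "PP", 1000, p)
  expect_equal(sum(st3$counts), 1000 * 100^5)
})

test_that("extinction is an explicit condition, not a silent empty state", {
  # founder fixed for a host-lethal allele, no mutation supply to escape
  pl <- data.frame(segment = "S", position = 1126, ref = "T", alt = "C",
                   s_pp = -1, s_era = 0.5)
  p <- sim_params(mu = 0, pleiotropy = pl, track_background = FALSE)
  g <- default_genome()
  site <- phi6kp:::segment_to_site("S", 1126, segment_lengths(g))
  st <- lineage_state(g, p, genotypes = list(list(sites = site, alts = "C")))
  expect_error(run_transfer(st, "PP", 10, p), class = "phi6kp_extinction")
  # the same lineage thrives on the other host
  expect_silent(st2 <- run_transfer(st, "ERA", 10, p))
})

test_that("a strongly beneficial allele does not decline in expectation", {
  pl <- data.frame(segment = "S", position = 1126, ref = "T", alt = "C",
                   s_pp = 0.5, s_era = 0.5)
  p <- sim_params(mu = 0, pleiotropy = pl, track_background = FALSE)
  g <- default_genome()
  site <- phi6kp:::segment_to_site("S", 1126, segment_lengths(g))
  finals <- vapply(1:30, function(s) {
    with_seed(s, {
      st <- lineage_state(g, p,
                          genotypes = list(list(sites = integer(0),
                                                alts = character(0)),
                                           list(sites = site, alts = "C")),
                          counts = c(0.5, 0.5))
      for (d in 1:3) st <- run_transfer(st, "PP", 1000, p)
      carrier <- vapply(st$genotypes, function(gt) length(gt$sites) > 0, TRUE)
      sum(st$counts[carrier]) / sum(st$counts)
    })
  }, numeric(1))
  expect_gt(mean(finals), 0.5)
})

test_that("a small simulated experiment is reproducible ground truth", {
  d <- small_design()
  p <- sim_params()
  ex <- simulate_experiment(d, p, seed = 3)
  # one clone per node/tip plus the ancestor
  expect_setequal(names(ex$clones), c("A1", d$branch))
  # topology equals the design tree
  expect_equal(clade_errors(design_tree(d), ex$tree)$rf, 0)
  # replaying each branch's events from the parent clone reproduces the child
  for (b in d$branch) {
    ev <- ex$events[ex$events$branch == b, ]
    par <- d$parent[d$branch == b]
    expect_identical(unclass(apply_mutations(ex$clones[[par]], ev)),
                     unclass(ex$clones[[b]]))
  }
  # bit-identical reruns from the same seed
  ex2 <- simulate_experiment(d, p, seed = 3)
  expect_identical(ex2$events, ex$events)
  expect_identical(lapply(ex2$clones, unclass), lapply(ex$clones, unclass))
  ex3 <- simulate_experiment(d, p, seed = 4)
  expect_false(identical(ex3$events, ex$events))
})

test_that("mu = 0 yields clones identical to the ancestor", {
  ex <- simulate_experiment(small_design(), sim_params(mu = 0), seed = 1)
  expect_equal(nrow(ex$events), 0L)
  for (cl in names(ex$clones))
    expect_identical(unclass(ex$clones[[cl]]), unclass(ex$clones$A1))
})

test_that("neutral N = 1 divergence is Poisson with mean mu * L * generations", {
  # one branch, 10 daily single-plaque transfers, all mutations neutral
  d <- validate_design(data.frame(
    branch = c("B1", "C1", "C2"), parent = c("A1", "B1", "B1"),
    host = "PP", schedule = "1", days = c(10L, 1L, 1L), gens_per_day = 5L,
    stringsAsFactors = FALSE))
  p <- sim_params(frac_deleterious = 0, pleiotropy = NULL)
  counts <- vapply(1:150, function(s) {
    ex <- simulate_experiment(d, p, seed = s)
    nrow(diff_genomes(ex$clones$A1, ex$clones$B1, annotation = NULL))
  }, numeric(1))
  lambda <- 2e-6 * 13385 * 50
  se <- sqrt(lambda / length(counts))
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("the default design encodes the published experiment dimensions", {
  d <- default_design()
  gens <- design_generations(d)
  expect_equal(gens$total, 2750)
  expect_equal(gens$root_to_tip, 350)
  expect_identical(nrow(d), 31L)                  # 32 clones incl. ancestor
  tips <- setdiff(d$branch, d$parent)
  expect_identical(length(tips), 16L)
  # regime generation totals
  reg <- design_regimes(d)
  per_branch <- d$days * d$gens_per_day
  names(per_branch) <- d$branch
  sums <- tapply(per_branch[names(reg)], reg, sum)
  expect_equal(sums[["PP_large"]], 500)
  expect_equal(sums[["ERA_large"]], 450)
  expect_equal(sums[["PP_N1"]], 200)
  expect_equal(sums[["ERA_N1"]], 200)
  expect_equal(sums[["ALT_N1"]], 200)
  expect_equal(sums[["increasing"]], 600)
  expect_equal(sums[["decreasing"]], 600)
})

test_that("design validation enforces binary bifurcations and allowed sizes", {
  d <- small_design()
  bad <- d; bad$schedule[1] <- "55"
  expect_error(validate_design(bad), "bottleneck sizes")
  tri <- rbind(d, data.frame(branch = "C3", parent = "B1", host = "PP",
                             schedule = "1000", days = 5L, gens_per_day = 5L))
  expect_error(validate_design(tri), "bifurcate")
})

test_that("reversion assay respects trivial limits and bounds", {
  # neutral allele and no mutation: the reverted allele can never appear
  pl <- data.frame(segment = "S", position = 1126, ref = "T", alt = "C",
                   s_pp = 0, s_era = 0)
  p0 <- sim_params(mu = 0, pleiotropy = pl, track_background = FALSE)
  expect_equal(simulate_reversion_assay(100, days = 5, params = p0, seed = 1), 0)
  # frequencies always within [0, 1]
  p <- sim_params(track_background = FALSE)
  f <- vapply(1:5, function(s)
    simulate_reversion_assay(1000, days = 5, params = p, seed = s), 0)
  expect_true(all(f >= 0 & f <= 1))
})
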