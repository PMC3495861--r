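# Shared simulated experiments, memoised so expensive forward runs are
# performed once per session and reused across test files.

.fixture_env <- new.env(parent = emptyenv())

# A compact 4-tip design (two bifurcation levels) for fast simulator tests.
small_design <- function() {
  d <- data.frame(
    branch = c("B1", "C1", "C2", "F1", "F2", "F3", "F4"),
    parent = c("A1", "B1", "B1", "C1", "C1", "C2", "C2"),
    host = c("PP", "ERA", "PP", "ERA", "PP", "PP", "PP"),
    schedule = c("1000", "1000", "1000", "1000", "1", "1000", "1000"),
    days = c(5L, 5L, 5L, 5L, 5L, 5L, 5L),
    gens_per_day = 5L, stringsAsFactors = FALSE)
  validate_design(d)
}

shared_default_experiments <- function(seeds = 1:5) {
  key <- paste0("default_", paste(seeds, collapse = "_"))
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- lapply(seeds, function(s)
      simulate_experiment(seed = s))
  .fixture_env[[key]]
}

# High-mutation-supply validation scenario: the same 16-tip tree shape and
# branch durations as the default design, simulated with a 5x mutation rate
# and a neutral background so that every internal branch carries several
# unique marker substitutions (many informative sites, negligible homoplasy).
highmu_conditions <- function() {
  d <- default_design()
  d$schedule <- "100"
  list(design = validate_design(d),
       params = sim_params(mu = 1e-5, frac_deleterious = 0,
                           pleiotropy = NULL))
}

shared_highmu_experiment <- function(seed = 101) {
  key <- paste0("highmu_", seed)
  if (is.null(.fixture_env[[key]])) {
    hc <- highmu_conditions()
    .fixture_env[[key]] <- simulate_experiment(hc$design, hc$params,
                                               seed = seed)
  }
  .fixture_env[[key]]
}
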