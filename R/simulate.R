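# Forward-time simulator of bifurcating-deme serial passage.
#
# One serial-transfer day is modelled as: (i) a bottleneck - N founder
# particles are sampled from the pooled lysate of the previous day (particle
# proportions already reflect the previous day's within-plaque selection);
# (ii) plaque growth - every founder grows into a plaque of burst^gens
# particles over `gens_per_plaque` generations of burst replication, with
# per-generation growth weighted by host-specific genotype fitness
# (within-plaque selection) and with new mutations arising during
# replication; (iii) pooling of all plaques into the next lysate.
#
# Populations are tracked as genotype -> count tables, never as individual
# particles.  Two mutation routes are used, at different resolutions:
#   * sites under host-specific selection (the antagonistic-pleiotropy table)
#     receive full within-plaque treatment: at every generation a
#     Poisson-distributed number of particles switches allele at each focal
#     site, and the resulting classes are then amplified (or purged) by the
#     remaining generations of within-plaque growth - this is what makes
#     allele dynamics bottleneck-size dependent;
#   * the remaining genome is effectively neutral (or unconditionally
#     deleterious) within a single plaque, so its mutations are attached to
#     the replication ancestry of each sampled founder: a founder drawn from
#     a plaque carries Poisson(mu * sites * g) new mutations under the
#     stamping-machine replication model (g replication events in its
#     ancestry), with positions uniform over sites.

#' Simulation parameters
#'
#' @param mu Per-base mutation rate per round of replication
#'   (default 2e-6).  The rate of a specific base-to-base substitution is
#'   \code{mu/3}.
#' @param u_deleterious Genomic deleterious mutation rate per generation
#'   (default 0.067); used by the aggregated bottleneck-load model
#'   (\code{\link{simulate_bottleneck_load}}).
#' @param burst Burst size: particles per infected cell per generation
#'   (default 100).
#' @param gens_per_plaque Generations of growth within one plaque / one
#'   serial-transfer day (default 5).
#' @param replication \code{"stamping"} (all progeny of a cell are copied
#'   from the founder genome; a sampled genome has exactly
#'   \code{gens_per_plaque} replication events in its within-plaque ancestry)
#'   or \code{"geometric"} (the per-genome replication-event count is random,
#'   uniform on 1..(2*gens_per_plaque - 1): same mean, larger variance).
#' @param frac_deleterious Fraction of background mutations that are
#'   deleterious (default 0.6); the rest are neutral.
#' @param s_deleterious Per-generation fitness cost of a deleterious
#'   background mutation on either host (default 0.05).
#' @param pleiotropy Antagonistic-pleiotropy table: data frame with columns
#'   \code{segment}, \code{position}, \code{ref}, \code{alt}, \code{s_pp},
#'   \code{s_era} (see \code{\link{default_pleiotropy}}).
#' @param track_background If \code{FALSE}, only the pleiotropy sites are
#'   simulated.  Background mutations elsewhere in the genome are neutral or
#'   unconditionally deleterious, so they do not alter focal-allele
#'   frequency dynamics; switching them off is appropriate for single-locus
#'   assays.
#' @param lengths Segment lengths of the simulated genome.
#' @return List of class \code{sim_params}.
#' @export
sim_params <- function(mu = 2e-6, u_deleterious = 0.067, burst = 100,
                       gens_per_plaque = 5,
                       replication = c("stamping", "geometric"),
                       frac_deleterious = 0.6, s_deleterious = 0.05,
                       pleiotropy = default_pleiotropy(),
                       track_background = TRUE,
                       lengths = default_segment_lengths()) {
  replication <- match.arg(replication)
  if (mu < 0) stop("mu must be >= 0")
  if (u_deleterious < 0) stop("u_deleterious must be >= 0")
  if (burst < 1) stop("burst must be >= 1")
  if (gens_per_plaque < 1) stop("gens_per_plaque must be >= 1")
  if (frac_deleterious < 0 || frac_deleterious > 1)
    stop("frac_deleterious must be in [0, 1]")
  structure(list(mu = mu, u_deleterious = u_deleterious, burst = burst,
                 gens_per_plaque = as.integer(gens_per_plaque),
                 replication = replication,
                 frac_deleterious = frac_deleterious,
                 s_deleterious = s_deleterious,
                 pleiotropy = pleiotropy,
                 track_background = isTRUE(track_background),
                 lengths = lengths),
            class = "sim_params")
}

#' Default antagonistic-pleiotropy table
#'
#' One locus: the F176L analogue in gene P12 on segment S (position 1126 of
#' the default synthetic annotation, first base of codon 176; T in the
#' ancestor).  The derived C allele (F176L) is beneficial on the novel host
#' ERA and deleterious on the original host PP.  The selection coefficients
#' (+0.8 / -0.8 per generation) are a synthetic calibration chosen so that,
#' under the default plaque model, reversion on PP sweeps within 20 days at
#' bottlenecks of 1000 and 10000 but not at 10 or 100.
#'
#' @return Data frame with columns \code{segment}, \code{position},
#'   \code{ref}, \code{alt}, \code{s_pp}, \code{s_era}.
#' @export
default_pleiotropy <- function() {
  data.frame(segment = "S", position = 1126L, ref = "T", alt = "C",
             s_pp = -0.8, s_era = 0.8, stringsAsFactors = FALSE)
}

#' Final plaque population size
#'
#' Population of a plaque founded by a single particle after \code{gens}
#' generations of burst replication: \code{burst^gens}, computed by repeated
#' multiplication (exact for all desk-scale arguments; 100^5 = 1e10).
#'
#' @param burst Burst size (particles per infected cell), >= 1.
#' @param gens Number of generations, >= 0.
#' @return Numeric scalar \code{burst^gens}.
#' @export
plaque_final_size <- function(burst, gens) {
  if (burst < 1 || gens < 0 || burst != round(burst) || gens != round(gens))
    stop("burst must be an integer >= 1 and gens an integer >= 0")
  out <- 1
  for (i in seq_len(gens)) out <- out * burst
  out
}

#' Expected mutations fixed by repeated bottlenecking
#'
#' Under the aggregated load model, each single-plaque bottleneck event fixes
#' a Poisson-distributed number of mutations with mean \code{u_event}; the
#' expectation after \code{n_events} events is their product (0.067 x 20 =
#' 1.34, i.e. roughly one mutation fixed per 20 days of bottlenecking).
#'
#' @param u_event Mean mutations fixed per bottleneck event, >= 0.
#' @param n_events Number of bottleneck events, >= 0.
#' @return \code{u_event * n_events}.
#' @export
expected_fixed_mutations <- function(u_event, n_events) {
  if (u_event < 0 || n_events < 0) stop("arguments must be >= 0")
  u_event * n_events
}

#' Simulate mutation accumulation under repeated single-plaque bottlenecks
#'
#' Draws, for each of \code{n_lineages} replicate lineages, the total number
#' of mutations fixed over \code{n_events} bottleneck events, with the count
#' fixed per event Poisson-distributed with mean \code{u_event}.
#'
#' @param n_lineages Number of replicate lineages.
#' @param n_events Bottleneck events per lineage (default 20).
#' @param u_event Mean mutations fixed per event (default 0.067, the phi6
#'   genomic deleterious rate applied per transfer).
#' @param seed Optional seed.
#' @return Integer vector of per-lineage totals (length \code{n_lineages}).
#' @export
simulate_bottleneck_load <- function(n_lineages, n_events = 20,
                                     u_event = 0.067, seed = NULL) {
  with_seed(seed, {
    per_event <- matrix(stats::rpois(n_lineages * n_events, u_event),
                        nrow = n_lineages)
    as.integer(rowSums(per_event))
  })
}

#' Draw mutations along a sampled genome's replication ancestry
#'
#' Number (and positions) of new mutations carried by genomes sampled at the
#' end of one plaque, relative to the plaque founder.  Under stamping-machine
#' replication a sampled genome's ancestry contains exactly
#' \code{generations} replication events, so the count is
#' Poisson(\code{mu * n_sites * generations}); under the geometric mode the
#' event count of each draw is itself random (uniform on
#' 1..(2*generations-1), preserving the mean), inflating the variance.
#'
#' @param params \code{sim_params}.
#' @param n_sites Number of mutable sites.
#' @param generations Replication events per sampled genome under stamping
#'   (plaque generations).
#' @param n Number of independent genomes to draw.
#' @param positions If \code{TRUE} also return mutated site indices
#'   (uniform over sites).
#' @return List with \code{counts} (integer vector, length \code{n}) and,
#'   when requested, \code{sites} (list of integer vectors).
#' @export
draw_lineage_mutations <- function(params, n_sites, generations, n = 1,
                                   positions = FALSE) {
  if (n_sites < 0 || generations < 0) stop("arguments must be >= 0")
  g_eff <- if (params$replication == "stamping") rep(generations, n)
           else sample(seq_len(max(1L, 2L * generations - 1L)), n, replace = TRUE)
  counts <- stats::rpois(n, params$mu * n_sites * g_eff)
  out <- list(counts = as.integer(counts))
  if (positions)
    out$sites <- lapply(out$counts, function(k)
      if (k > 0L) sample.int(n_sites, k, replace = TRUE) else integer(0))
  out
}

# --- lineage state ---------------------------------------------------------

#' Construct a lineage state
#'
#' A lineage state is the genotype -> count table of one evolving deme,
#' together with the ancestor sequence against which genotypes are recorded.
#' Genotypes are sets of substitutions relative to the ancestor, stored as
#' (global site index, alternative base) pairs; global site indices run over
#' the concatenated segments in L, M, S order.
#'
#' @param ancestor Ancestral \code{segmented_genome}.
#' @param params \code{sim_params} (supplies the pleiotropy effects).
#' @param genotypes List of genotypes, each \code{list(sites =, alts =)}.
#' @param counts Numeric vector of genotype counts.
#' @param day Starting day counter.
#' @return Object of class \code{lineage_state}.
#' @export
lineage_state <- function(ancestor = default_genome(), params = sim_params(),
                          genotypes = list(list(sites = integer(0),
                                                alts = character(0))),
                          counts = 1, day = 0L) {
  lengths <- segment_lengths(ancestor)
  anc_base <- strsplit(paste(unlist(ancestor), collapse = ""), "")[[1]]
  effects <- new.env(parent = emptyenv())
  pl <- params$pleiotropy
  focal_sites <- integer(0)
  if (!is.null(pl) && nrow(pl)) {
    focal_sites <- segment_to_site(pl$segment, pl$position, lengths)
    for (i in seq_len(nrow(pl))) {
      if (anc_base[focal_sites[i]] != pl$ref[i])
        stop("pleiotropy ref at ", pl$segment[i], ":", pl$position[i],
             " does not match the ancestor")
      assign(paste0(focal_sites[i], ":", pl$alt[i]),
             c(pp = pl$s_pp[i], era = pl$s_era[i]), envir = effects)
    }
  }
  st <- list(anc_base = anc_base, lengths = lengths, n_sites = length(anc_base),
             focal_sites = focal_sites, effects = effects,
             genotypes = genotypes, counts = as.numeric(counts),
             day = as.integer(day))
  st$w_pp <- vapply(genotypes, function(g) genotype_fitness(st, g, "PP"), 0)
  st$w_era <- vapply(genotypes, function(g) genotype_fitness(st, g, "ERA"), 0)
  class(st) <- "lineage_state"
  st
}

# Fitness effect (per generation) of a (site, alt) substitution; background
# effects are drawn once per run and memoised so a recurring substitution
# always has the same effect.
substitution_effect <- function(state, params, site, alt) {
  key <- paste0(site, ":", alt)
  if (!is.null(e <- get0(key, envir = state$effects))) return(e)
  e <- if (stats::runif(1) < params$frac_deleterious)
    c(pp = -params$s_deleterious, era = -params$s_deleterious)
  else c(pp = 0, era = 0)
  assign(key, e, envir = state$effects)
  e
}

# Multiplicative fitness factor of carrying `base` at `site` (1 when `base`
# is the ancestral state or the substitution has no recorded effect).
effect_factor <- function(state, site, base) {
  if (base == state$anc_base[site]) return(c(pp = 1, era = 1))
  e <- get0(paste0(site, ":", base), envir = state$effects)
  if (is.null(e)) c(pp = 1, era = 1) else pmax(1 + e, 0)
}

genotype_fitness <- function(state, g, host) {
  if (!length(g$sites)) return(1)
  w <- 1
  col <- if (host == "PP") "pp" else "era"
  for (i in seq_along(g$sites))
    w <- w * effect_factor(state, g$sites[i], g$alts[i])[[col]]
  w
}

# Set the base carried at `site` (relative to the ancestor) in a genotype.
genotype_set_base <- function(state, g, site, base) {
  i <- match(site, g$sites)
  if (base == state$anc_base[site]) {
    if (!is.na(i)) { g$sites <- g$sites[-i]; g$alts <- g$alts[-i] }
  } else if (is.na(i)) {
    g$sites <- c(g$sites, site); g$alts <- c(g$alts, base)
  } else {
    g$alts[i] <- base
  }
  g
}

genotype_base_at <- function(state, g, site) {
  i <- match(site, g$sites)
  if (is.na(i)) state$anc_base[site] else g$alts[i]
}


extinction_stop <- function(msg) {
  stop(structure(class = c("phi6kp_extinction", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Run one serial-transfer day
#'
#' Applies one bottleneck-and-regrowth cycle to a lineage state: samples
#' \code{n_founders} particles from the pooled lysate (a multinomial draw
#' over genotype counts, which already carry the previous day's within-plaque
#' selection; for \code{n_founders = 1} this is the single-plaque transfer in
#' which drift dominates), attaches background mutations to each founder's
#' replication ancestry, then grows every founder through
#' \code{gens_per_plaque} generations of fitness-weighted burst replication
#' with Poisson mutation flux at the pleiotropy sites, and pools the plaques.
#' The pooled population is normalised to exactly
#' \code{n_founders * burst^gens}.
#'
#' @param state A \code{lineage_state}.
#' @param host \code{"PP"} or \code{"ERA"} (the day's host lawn).
#' @param n_founders Bottleneck size N for this transfer.
#' @param params \code{sim_params}.
#' @return The updated \code{lineage_state} (day counter advanced).
#' @export
run_transfer <- function(state, host, n_founders, params) {
  stopifnot(inherits(state, "lineage_state"), host %in% c("PP", "ERA"))
  n_founders <- as.integer(n_founders)
  if (n_founders < 1L) stop("n_founders must be >= 1")
  if (sum(state$counts) <= 0) extinction_stop("lineage is extinct")

  ## Unpack the class table into local vectors: appends on local objects stay
  ## O(1) amortised, keeping the whole transfer linear in the class count.
  genotypes <- state$genotypes
  w_pp <- state$w_pp
  w_era <- state$w_era

  ## (i) bottleneck: sample founders from the pooled lysate
  if (length(state$counts) == 1L) {
    founders <- n_founders
  } else {
    founders <- as.numeric(stats::rmultinom(1, n_founders,
                                            state$counts / sum(state$counts)))
  }
  keep <- founders > 0
  genotypes <- genotypes[keep]
  w_pp <- w_pp[keep]
  w_era <- w_era[keep]
  counts <- founders[keep]

  ## (ii) background mutations on founder replication ancestries
  if (params$track_background && params$mu > 0) {
    n_bg <- state$n_sites - length(state$focal_sites)
    draws <- draw_lineage_mutations(params, n_bg,
                                    params$gens_per_plaque, n = n_founders)
    hit <- which(draws$counts > 0L)
    if (length(hit)) {
      # founder index -> class index, in class order
      class_of <- rep(seq_along(counts), counts)
      for (f in hit) {
        ci <- class_of[f]
        g <- genotypes[[ci]]
        wp <- w_pp[ci]; we <- w_era[ci]
        for (j in seq_len(draws$counts[f])) {
          repeat {
            site <- sample.int(state$n_sites, 1L)
            if (!site %in% state$focal_sites) break
          }
          cur <- genotype_base_at(state, g, site)
          new <- sample(setdiff(DNA_BASES, cur), 1L)
          substitution_effect(state, params, site, new)  # memoise the effect
          f_old <- effect_factor(state, site, cur)
          f_new <- effect_factor(state, site, new)
          g <- genotype_set_base(state, g, site, new)
          if (f_old[["pp"]] > 0 && f_old[["era"]] > 0) {
            wp <- wp / f_old[["pp"]] * f_new[["pp"]]
            we <- we / f_old[["era"]] * f_new[["era"]]
          } else {
            wp <- genotype_fitness(state, g, "PP")
            we <- genotype_fitness(state, g, "ERA")
          }
        }
        counts[ci] <- counts[ci] - 1
        n <- length(counts) + 1L
        genotypes[[n]] <- g; counts[n] <- 1; w_pp[n] <- wp; w_era[n] <- we
      }
      keep <- counts > 0
      genotypes <- genotypes[keep]
      w_pp <- w_pp[keep]
      w_era <- w_era[keep]
      counts <- counts[keep]
    }
  }

  ## (iii) within-plaque growth with focal-site mutation flux
  w <- if (host == "PP") w_pp else w_era
  site_rate <- params$mu / 3  # specific base-to-base substitution rate
  do_flux <- length(state$focal_sites) > 0L && params$mu > 0
  if (do_flux) {
    # per-class base carried at each focal site, maintained incrementally
    base_tab <- lapply(state$focal_sites, function(site)
      vapply(genotypes, function(g)
        genotype_base_at(state, g, site), character(1)))
  }
  for (gen in seq_len(params$gens_per_plaque)) {
    counts <- counts * params$burst * w
    if (do_flux) {
      pl <- params$pleiotropy
      for (p in seq_len(nrow(pl))) {
        site <- state$focal_sites[p]
        for (dir in list(c(pl$ref[p], pl$alt[p]), c(pl$alt[p], pl$ref[p]))) {
          src <- which(base_tab[[p]] == dir[1] & counts > 0)
          if (!length(src)) next
          flux <- stats::rpois(length(src), counts[src] * site_rate)
          f_old <- effect_factor(state, site, dir[1])
          f_new <- effect_factor(state, site, dir[2])
          for (k in which(flux > 0L)) {
            ci <- src[k]
            moved <- min(flux[k], counts[ci])
            g2 <- genotype_set_base(state, genotypes[[ci]], site, dir[2])
            wp <- if (f_old[["pp"]] > 0)
              w_pp[ci] / f_old[["pp"]] * f_new[["pp"]]
            else genotype_fitness(state, g2, "PP")
            we <- if (f_old[["era"]] > 0)
              w_era[ci] / f_old[["era"]] * f_new[["era"]]
            else genotype_fitness(state, g2, "ERA")
            counts[ci] <- counts[ci] - moved
            n <- length(counts) + 1L
            genotypes[[n]] <- g2; counts[n] <- moved
            w_pp[n] <- wp; w_era[n] <- we
            for (q in seq_along(base_tab))
              base_tab[[q]][n] <- if (q == p) dir[2] else base_tab[[q]][ci]
          }
        }
      }
    }
    w <- if (host == "PP") w_pp else w_era
  }

  total <- sum(counts)
  if (total <= 0) extinction_stop("all genotypes have zero fitness")
  ## pool and normalise to exactly N * burst^gens
  target <- n_founders * plaque_final_size(params$burst, params$gens_per_plaque)
  counts <- counts * (target / total)
  ## prune vanishingly rare classes to bound the table size
  keep <- counts / target > 1e-12
  state$genotypes <- genotypes[keep]
  state$w_pp <- w_pp[keep]
  state$w_era <- w_era[keep]
  state$counts <- counts[keep]
  state$day <- state$day + 1L
  state
}

# Sample one particle from the pooled lysate (the "sequenced clone").
sample_clone <- function(state) {
  i <- sample.int(length(state$counts), 1L,
                  prob = state$counts / sum(state$counts))
  state$genotypes[[i]]
}

genotype_to_genome <- function(state, g) {
  bases <- state$anc_base
  if (length(g$sites)) bases[g$sites] <- g$alts
  off <- site_offsets(state$lengths)
  segs <- lapply(seq_along(state$lengths), function(i)
    paste(bases[(off[i] + 1L):(off[i] + state$lengths[i])], collapse = ""))
  names(segs) <- names(state$lengths)
  segmented_genome(segs)
}

#' Simulate the full known-phylogeny experiment
#'
#' Runs every branch of the design through \code{\link{run_transfer}},
#' sampling one clone (a single particle) at every node and tip; each
#' daughter branch is founded from its parent's sampled clone, exactly as the
#' serial-passage protocol founds each bifurcation from a single isolated
#' plaque.  Per-branch substitution events are recorded relative to the
#' sampled parent clone (so a lost allele appears as a reversion
#' substitution), giving complete ground truth for reconstruction-accuracy
#' studies.
#'
#' @param design An \code{experiment_design} (default
#'   \code{\link{default_design}}).
#' @param params \code{sim_params}.
#' @param seed Integer seed; the run is fully reproducible from it.
#' @param ancestor Ancestral genome (default \code{\link{default_genome}}).
#' @param annotation Gene annotation used to classify recorded events.
#' @return Object of class \code{simulated_experiment}: list with the true
#'   \code{tree} (\code{phylo}, internal labels = clone names), \code{clones}
#'   (named list of \code{segmented_genome}, one per sampled clone including
#'   the ancestor), \code{events} (per-branch classified mutation table),
#'   \code{regimes}, \code{design}, \code{params} and \code{seed}.
#' @export
simulate_experiment <- function(design = default_design(),
                                params = sim_params(), seed = 1,
                                ancestor = default_genome(),
                                annotation = default_annotation()) {
  stopifnot(inherits(design, "experiment_design"))
  if (!identical(unname(segment_lengths(ancestor)), unname(params$lengths)))
    stop("ancestor segment lengths disagree with params$lengths")
  with_seed(derive_seed(seed, "simulate"), {
    root <- setdiff(design$parent, design$branch)
    clones <- list()
    genotypes <- list()
    clones[[root]] <- ancestor
    genotypes[[root]] <- list(sites = integer(0), alts = character(0))
    events <- list()
    ## breadth-first over branches so parents are simulated first
    todo <- design$branch[design$parent == root]
    while (length(todo)) {
      b <- todo[1]; todo <- todo[-1]
      row <- design[design$branch == b, ]
      state <- lineage_state(ancestor, params,
                             genotypes = list(genotypes[[row$parent]]),
                             counts = 1)
      hosts <- day_hosts(row$host, row$days)
      sizes <- schedule_sizes(row$schedule, row$days)
      for (d in seq_len(row$days)) {
        state <- tryCatch(
          run_transfer(state, hosts[d], sizes[d], params),
          phi6kp_extinction = function(e)
            stop("branch ", b, " went extinct on day ", d, ": ",
                 conditionMessage(e)))
      }
      genotypes[[b]] <- sample_clone(state)
      clones[[b]] <- genotype_to_genome(state, genotypes[[b]])
      ev <- diff_genomes(clones[[row$parent]], clones[[b]], annotation)
      if (nrow(ev)) ev <- cbind(branch = b, ev)
      events[[b]] <- ev
      todo <- c(todo, design$branch[design$parent == b])
    }
    ev <- do.call(rbind, Filter(function(x) !is.null(x) && nrow(x), events))
    if (is.null(ev)) ev <- cbind(branch = character(0), empty_mutation_table())
    rownames(ev) <- NULL
    structure(list(tree = design_tree(design), clones = clones, events = ev,
                   regimes = design_regimes(design), design = design,
                   params = params, seed = seed, ancestor_label = root),
              class = "simulated_experiment")
  })
}

#' @export
print.simulated_experiment <- function(x, ...) {
  cat("simulated known-phylogeny experiment:",
      length(x$clones), "sampled clones,",
      nrow(x$events), "recorded substitution events (seed", x$seed, ")\n")
  invisible(x)
}

#' Simulate the reversion evolution assay
#'
#' Follow-up assay for an antagonistically pleiotropic allele: a population
#' fixed for the derived allele (deleterious on the assay host) is evolved
#' for \code{days} serial transfers at a constant bottleneck, and the final
#' frequency of the reverted (ancestral) allele is returned.  Background
#' mutations are not tracked: they are neutral or unconditionally deleterious
#' and therefore independent of the focal-allele dynamics.
#'
#' @param n_bottleneck Bottleneck size N (the assay supports 10, 100, 1000,
#'   10000).
#' @param days Number of serial transfers (default 20, i.e. 100 generations).
#' @param params \code{sim_params}; its first pleiotropy row is the focal
#'   locus.
#' @param host Assay host (default \code{"PP"}, on which the derived allele
#'   is deleterious).
#' @param seed Optional seed.
#' @return Frequency (in [0, 1]) of the reverted allele after the run.
#' @export
simulate_reversion_assay <- function(n_bottleneck, days = 20,
                                     params = sim_params(track_background = FALSE),
                                     host = "PP", seed = NULL) {
  pl <- params$pleiotropy
  if (is.null(pl) || !nrow(pl)) stop("params$pleiotropy must contain the focal allele")
  with_seed(seed, {
    ancestor <- default_genome()
    site <- segment_to_site(pl$segment[1], pl$position[1],
                            segment_lengths(ancestor))
    founder <- list(sites = site, alts = pl$alt[1])
    state <- lineage_state(ancestor, params, genotypes = list(founder),
                           counts = 1)
    for (d in seq_len(days))
      state <- run_transfer(state, host, n_bottleneck, params)
    bases <- vapply(state$genotypes, function(g)
      genotype_base_at(state, g, site), character(1))
    sum(state$counts[bases == pl$ref[1]]) / sum(state$counts)
  })
}
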