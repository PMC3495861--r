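# Molecular-evolution statistics over recorded substitution events:
# per-segment substitution densities, a chi-square test of uniformity across
# segments, Ka/Ks tallies per treatment regime with Fisher exact
# comparisons, and detection of reversion and parallel (homoplasious)
# mutations against the known tree.

#' Build the per-branch substitution table of an experiment
#'
#' Joins recorded mutation events with the treatment-regime label of the
#' branch each event occurred on.
#'
#' @param events Mutation-event data frame with a \code{branch} column (as in
#'   \code{simulated_experiment$events}), or a \code{simulated_experiment}.
#' @param regimes Named character vector mapping branch to regime label
#'   (ignored when \code{events} is a \code{simulated_experiment}).
#' @return Data frame of class \code{substitution_table}: the events with a
#'   \code{regime} column added.
#' @export
substitution_table <- function(events, regimes = NULL) {
  if (inherits(events, "simulated_experiment")) {
    regimes <- events$regimes
    events <- events$events
  }
  if (is.null(regimes)) stop("regimes must be supplied")
  if (!all(events$branch %in% names(regimes)))
    stop("events reference branches without a regime label: ",
         paste(setdiff(events$branch, names(regimes)), collapse = ", "))
  out <- cbind(events, regime = unname(regimes[events$branch]))
  class(out) <- c("substitution_table", "data.frame")
  out
}

#' Per-segment substitution density
#'
#' Average number of base pairs per observed change, per segment
#' (\code{length / count}); segments with no changes are flagged rather than
#' producing a division error.
#'
#' @param counts Named (or positionally matched) substitution counts per
#'   segment.
#' @param lengths Segment lengths in bp.
#' @return Data frame with columns \code{segment}, \code{count},
#'   \code{length}, \code{bp_per_change} (\code{NA} when count is 0) and
#'   \code{no_changes}.
#' @export
segment_density <- function(counts, lengths = default_segment_lengths()) {
  if (length(counts) != length(lengths)) stop("counts/lengths length mismatch")
  if (any(counts < 0) || any(lengths <= 0)) stop("invalid counts or lengths")
  segs <- if (!is.null(names(lengths))) names(lengths)
          else as.character(seq_along(lengths))
  data.frame(segment = segs, count = as.numeric(counts),
             length = as.numeric(lengths),
             bp_per_change = ifelse(counts > 0, lengths / counts, NA_real_),
             no_changes = counts == 0,
             stringsAsFactors = FALSE)
}

#' Chi-square test of substitution uniformity across segments
#'
#' Pearson goodness-of-fit test of observed per-segment substitution counts
#' against expectation proportional to segment length, without continuity
#' correction; df = number of segments - 1.
#'
#' @param counts Observed substitution counts per segment.
#' @param lengths Segment lengths (expected counts are
#'   \code{total * length / sum(length)}).
#' @return List with \code{statistic}, \code{df}, \code{p.value} and
#'   \code{expected}.
#' @export
chisq_uniform_test <- function(counts, lengths = default_segment_lengths()) {
  if (length(counts) < 2) stop("need at least two segments")
  if (sum(counts) == 0) stop("no substitutions: test undefined")
  ct <- suppressWarnings(
    stats::chisq.test(counts, p = lengths / sum(lengths)))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value, expected = unname(ct$expected))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact p-value by hypergeometric enumeration: the sum of the probabilities
#' of all tables with the same margins whose probability does not exceed that
#' of the observed table (the standard two-sided rule).  Tables with an empty
#' margin have p = 1 by convention.
#'
#' @param tab 2x2 matrix (or something coercible) of nonnegative counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- matrix(as.numeric(tab), 2, 2)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table must contain nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Ka/Ks substitution tallies per treatment regime
#'
#' Counts of nonsynonymous (Ka), synonymous (Ks) and noncoding substitutions
#' per regime.  These are raw substitution counts, exactly as tabulated in
#' small experimental datasets (e.g. "Ka/Ks = 9/4"), not per-site-normalised
#' dN/dS rates; set \code{normalise = TRUE} to additionally report counts per
#' nonsynonymous/synonymous site computed from the annotation.
#'
#' @param table A \code{substitution_table}.
#' @param regimes Optional character vector of all valid regime labels (rows
#'   with labels outside it raise an error); defaults to the labels present.
#' @param normalise Also compute per-site rates (off by default).
#' @param annotation,genome Used only when \code{normalise = TRUE}.
#' @return Data frame with columns \code{regime}, \code{ka}, \code{ks},
#'   \code{noncoding}, \code{total} (plus \code{ka_per_site}/\code{ks_per_site}
#'   when normalised).
#' @export
kaks_by_regime <- function(table, regimes = NULL, normalise = FALSE,
                           annotation = default_annotation(),
                           genome = default_genome()) {
  if (is.null(regimes)) regimes <- sort(unique(as.character(table$regime)))
  bad <- setdiff(unique(as.character(table$regime)), regimes)
  if (length(bad)) stop("unknown regime label(s): ", paste(bad, collapse = ", "))
  tally <- function(r) {
    rows <- table[table$regime == r, , drop = FALSE]
    c(ka = sum(rows$class == "nonsynonymous"),
      ks = sum(rows$class == "synonymous"),
      noncoding = sum(rows$class == "noncoding"))
  }
  m <- t(vapply(regimes, tally, c(ka = 0, ks = 0, noncoding = 0)))
  out <- data.frame(regime = regimes, ka = m[, "ka"], ks = m[, "ks"],
                    noncoding = m[, "noncoding"],
                    total = rowSums(m), row.names = NULL,
                    stringsAsFactors = FALSE)
  if (normalise) {
    sites <- syn_nonsyn_sites(genome, annotation)
    out$ka_per_site <- out$ka / sites[["nonsynonymous"]]
    out$ks_per_site <- out$ks / sites[["synonymous"]]
  }
  out
}

# Count synonymous/nonsynonymous site opportunities: each coding position
# contributes its fraction of the three possible changes that are
# synonymous/nonsynonymous (positions outside every CDS are ignored).
syn_nonsyn_sites <- function(genome, annotation) {
  syn <- 0; nonsyn <- 0
  for (i in seq_len(nrow(annotation))) {
    seg <- annotation$segment[i]
    cds_start <- annotation$start[i] + annotation$frame[i]
    for (pos in cds_start:annotation$end[i]) {
      cur <- substr(genome[[seg]], pos, pos)
      for (alt in setdiff(DNA_BASES, cur)) {
        cl <- classify_mutation(genome, annotation, seg, pos, alt)$class
        if (cl == "synonymous") syn <- syn + 1 / 3
        else nonsyn <- nonsyn + 1 / 3
      }
    }
  }
  c(synonymous = syn, nonsynonymous = nonsyn)
}

#' Detect reversion and parallel mutations against the known tree
#'
#' A reversion is a substitution on a branch that restores, at a previously
#' mutated site, the state its lineage carried before an ancestral branch's
#' forward mutation (alt of the descendant event equals ref of the ancestral
#' event and vice versa).  A parallel event is the identical substitution
#' (same site, same ref-to-alt change) occurring on branches neither of which
#' is ancestral to the other.
#'
#' @param tree Rooted \code{phylo} with node labels naming the clones, or an
#'   \code{experiment_design} (branches are identified by their child clone
#'   label).
#' @param events Mutation-event data frame with columns \code{branch},
#'   \code{segment}, \code{position}, \code{ref}, \code{alt}.
#' @return List of class \code{homoplasy_report} with data frames
#'   \code{reversions} (site, forward/reverting branch) and \code{parallels}
#'   (site, substitution, comma-joined branch set).
#' @export
detect_homoplasy <- function(tree, events) {
  anc <- branch_ancestors(tree)
  if (!all(events$branch %in% names(anc)))
    stop("branch id(s) not in tree: ",
         paste(setdiff(events$branch, names(anc)), collapse = ", "))
  is_anc <- function(a, b) a %in% anc[[b]]  # is a an ancestor branch of b?
  rev_rows <- list(); par_rows <- list()
  key <- paste(events$segment, events$position)
  for (k in unique(key[duplicated(key)])) {
    ev <- events[key == k, , drop = FALSE]
    ## reversions: ordered pairs (forward i, reverting j)
    for (i in seq_len(nrow(ev))) for (j in seq_len(nrow(ev))) {
      if (i == j) next
      if (is_anc(ev$branch[i], ev$branch[j]) &&
          ev$alt[j] == ev$ref[i] && ev$ref[j] == ev$alt[i])
        rev_rows[[length(rev_rows) + 1L]] <-
          data.frame(segment = ev$segment[i], position = ev$position[i],
                     forward_branch = ev$branch[i],
                     reverting_branch = ev$branch[j],
                     stringsAsFactors = FALSE)
    }
    ## parallels: identical events on pairwise non-ancestral branches
    ekey <- paste(ev$ref, ev$alt)
    for (e in unique(ekey[duplicated(ekey)])) {
      br <- unique(ev$branch[ekey == e])
      if (length(br) < 2) next
      # drop branches ancestral to another carrier: the rest is an antichain
      indep <- br[!vapply(br, function(a)
        any(vapply(setdiff(br, a), function(b) is_anc(a, b), TRUE)), TRUE)]
      if (length(indep) >= 2)
        par_rows[[length(par_rows) + 1L]] <-
          data.frame(segment = ev$segment[1], position = ev$position[1],
                     ref = ev$ref[ekey == e][1], alt = ev$alt[ekey == e][1],
                     branches = paste(sort(indep), collapse = ","),
                     stringsAsFactors = FALSE)
    }
  }
  empty_rev <- data.frame(segment = character(0), position = integer(0),
                          forward_branch = character(0),
                          reverting_branch = character(0))
  empty_par <- data.frame(segment = character(0), position = integer(0),
                          ref = character(0), alt = character(0),
                          branches = character(0))
  structure(list(
    reversions = if (length(rev_rows)) do.call(rbind, rev_rows) else empty_rev,
    parallels = if (length(par_rows)) do.call(rbind, par_rows) else empty_par),
    class = "homoplasy_report")
}

#' @export
print.homoplasy_report <- function(x, ...) {
  cat("homoplasy report:", nrow(x$reversions), "reversion event(s),",
      nrow(x$parallels), "parallel event(s)\n")
  invisible(x)
}

# For every branch (identified by its child node label), the set of strictly
# ancestral branch labels up to the root.
branch_ancestors <- function(tree) {
  if (inherits(tree, "experiment_design")) {
    pm <- design_parent_map(tree)
    labels <- names(pm)
  } else if (inherits(tree, "phylo")) {
    labs <- c(tree$tip.label, tree$node.label)
    pm <- character(0)
    for (i in seq_len(nrow(tree$edge)))
      pm[labs[tree$edge[i, 2]]] <- labs[tree$edge[i, 1]]
    labels <- names(pm)
  } else stop("tree must be a phylo or an experiment_design")
  out <- lapply(labels, function(b) {
    path <- character(0)
    p <- pm[[b]]
    while (!is.null(p) && p %in% labels) {
      path <- c(path, p)
      p <- if (is.na(pm[p])) NULL else pm[[p]]
    }
    path
  })
  names(out) <- labels
  out
}
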