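# In-package phylogenetic reconstruction: Fitch parsimony scoring, exact
# branch-and-bound maximum-parsimony search, neighbor joining, site
# bootstrap, and ancestral-state reconstruction (unit-cost parsimony with
# full most-parsimonious-reconstruction sets, or marginal likelihood under a
# single-rate reversible model with an invariant-site proportion).

BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

#' Build a concatenated alignment from clone genomes
#'
#' Concatenates each clone's segments in L, M, S order into one gap-free
#' alignment row.  All clones must share segment names and lengths (no
#' indels are modelled).
#'
#' @param clones Named list of \code{segmented_genome} objects.
#' @param order Segment concatenation order.
#' @return Object of class \code{clone_alignment}: list with \code{labels},
#'   \code{seqs} (named character vector) and \code{n_sites}.
#' @export
build_alignment <- function(clones, order = c("L", "M", "S")) {
  if (is.null(names(clones)) || any(names(clones) == ""))
    stop("clones must be named")
  segs <- names(clones[[1]])
  ord <- c(intersect(order, segs), setdiff(segs, order))
  seqs <- vapply(clones, function(g) {
    if (!setequal(names(g), segs)) stop("clones have differing segment sets")
    paste(unlist(g[ord]), collapse = "")
  }, character(1))
  if (length(unique(nchar(seqs))) != 1L)
    stop("clones have differing total lengths")
  structure(list(labels = names(clones), seqs = seqs,
                 n_sites = nchar(seqs[[1]])),
            class = "clone_alignment")
}

#' @export
print.clone_alignment <- function(x, ...) {
  cat("alignment:", length(x$labels), "sequences x", x$n_sites, "sites\n")
  invisible(x)
}

# Compress an alignment to unique site patterns.  Returns the bit-encoded
# pattern matrix (patterns x tips), the per-pattern site weights, and for
# each original site the index of its pattern.
aln_patterns <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$seqs), ""))  # tips x sites
  bad <- setdiff(unique(as.vector(m)), names(BASE_BITS))
  if (length(bad)) stop("alignment contains non-ACGT characters: ",
                        paste(bad, collapse = ", "))
  key <- apply(m, 2, paste, collapse = "")
  u <- unique(key)
  idx <- match(key, u)
  first <- match(u, key)
  states <- matrix(BASE_BITS[as.vector(m[, first, drop = FALSE])],
                   nrow = length(aln$labels))
  list(states = t(states),                     # patterns x tips
       weights = as.numeric(tabulate(idx, nbins = length(u))),
       site_pattern = idx, labels = aln$labels)
}

# --- Fitch parsimony -------------------------------------------------------

# children[[node]] for a phylo object, plus a postorder node sequence.
tree_traversal <- function(tree) {
  n_tip <- length(tree$tip.label)
  children <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    children[[p]] <- c(children[[p]], tree$edge[i, 2])
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  post <- integer(0)
  stack <- root; emit <- integer(0)
  while (length(stack)) {               # iterative DFS, children before parent
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    emit <- c(emit, v)
    stack <- c(stack, children[[v]])
  }
  list(children = children, root = root, postorder = rev(emit), n_tip = n_tip)
}

fitch_core <- function(tree, pat) {
  tv <- tree_traversal(tree)
  ord <- match(tree$tip.label, pat$labels)
  npat <- nrow(pat$states)
  sets <- vector("list", length(tv$children))
  changes <- numeric(npat)
  for (v in tv$postorder) {
    if (v <= tv$n_tip) {
      sets[[v]] <- pat$states[, ord[v]]
    } else {
      s <- NULL
      for (ch in tv$children[[v]]) {
        if (is.null(s)) { s <- sets[[ch]]; next }
        inter <- bitwAnd(s, sets[[ch]])
        zero <- inter == 0L
        if (any(zero)) {
          changes[zero] <- changes[zero] + 1
          inter[zero] <- bitwOr(s[zero], sets[[ch]][zero])
        }
        s <- inter
      }
      sets[[v]] <- s
    }
  }
  list(score = sum(changes * pat$weights), sets = sets, traversal = tv)
}

#' Fitch parsimony score of a tree
#'
#' Minimum number of substitutions the alignment requires on the given tree
#' (the maximum-parsimony objective), computed by the Fitch set-intersection
#' dynamic programme summed over sites.
#'
#' @param tree \code{phylo}; tip labels must match the alignment labels.
#' @param aln A \code{clone_alignment}.
#' @return Integer parsimony length.
#' @export
fitch_score <- function(tree, aln) {
  if (!setequal(tree$tip.label, aln$labels))
    stop("tree tip labels do not match alignment labels")
  pat <- aln_patterns(aln)
  fitch_core(tree, pat)$score
}

# --- edge-matrix machinery for tree search ---------------------------------
# Partial trees in the branch-and-bound search are plain 2-column edge
# matrices over node ids: tips keep their global taxon index (1..n),
# internal nodes are numbered from n+1 upward.

# Fitch score of an edge-matrix tree (tips = taxon column indices of states).
# `site_floor`, when given, is a per-pattern lower bound on the changes any
# COMPLETE tree must spend at that pattern (number of states over all taxa
# minus one); the returned value is then the admissible bound
# sum(max(changes, site_floor) * w), which sharpens pruning for partial
# trees whose unplaced taxa still carry unavoidable changes.
fitch_edges <- function(edges, states, weights, stop_above = Inf,
                        site_floor = NULL) {
  n_nodes <- max(edges)
  children <- vector("list", n_nodes)
  has_parent <- logical(n_nodes)
  for (i in seq_len(nrow(edges))) {
    children[[edges[i, 1]]] <- c(children[[edges[i, 1]]], edges[i, 2])
    has_parent[edges[i, 2]] <- TRUE
  }
  root <- which(!has_parent & lengths(children) > 0)[1]
  post <- integer(0); stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    post <- c(post, v)
    stack <- c(stack, children[[v]])
  }
  sets <- vector("list", n_nodes)
  changes <- numeric(nrow(states))
  bound <- function() {
    if (is.null(site_floor)) sum(changes * weights)
    else sum(pmax(changes, site_floor) * weights)
  }
  for (v in rev(post)) {
    ch <- children[[v]]
    if (!length(ch)) { sets[[v]] <- states[, v]; next }
    s <- NULL
    for (c2 in ch) {
      if (is.null(s)) { s <- sets[[c2]]; next }
      inter <- bitwAnd(s, sets[[c2]])
      zero <- inter == 0L
      if (any(zero)) {
        changes[zero] <- changes[zero] + 1
        inter[zero] <- bitwOr(s[zero], sets[[c2]][zero])
      }
      s <- inter
    }
    sets[[v]] <- s
    if (bound() > stop_above) return(Inf)  # bound exceeded: prune early
  }
  bound()
}

# Unique canonical Newick string of an unrooted edge-matrix tree: rooted at
# the neighbour of the lexicographically smallest tip, children ordered by
# their smallest descendant label.
canonical_edges_newick <- function(edges, labels) {
  adj <- vector("list", max(edges))
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  present_tips <- intersect(which(lengths(adj) > 0), seq_along(labels))
  t0 <- present_tips[order(labels[present_tips])[1]]
  build <- function(v, from) {
    nb <- setdiff(adj[[v]], from)
    if (!length(nb)) return(list(str = labels[v], min = labels[v]))
    subs <- lapply(nb, build, from = v)
    subs <- subs[order(vapply(subs, `[[`, "", "min"))]
    list(str = paste0("(", paste(vapply(subs, `[[`, "", "str"),
                                 collapse = ","), ")"),
         min = vapply(subs, `[[`, "", "min")[1])
  }
  root <- adj[[t0]][1]                 # the smallest tip's unique neighbour
  subs <- c(list(list(str = labels[t0], min = labels[t0])),
            lapply(setdiff(adj[[root]], t0), build, from = root))
  subs <- subs[order(vapply(subs, `[[`, "", "min"))]
  paste0("(", paste(vapply(subs, `[[`, "", "str"), collapse = ","), ");")
}

#' Exact maximum-parsimony tree search by branch and bound
#'
#' Finds the global minimum Fitch parsimony length over all unrooted binary
#' topologies, returning every optimal topology.  Taxa are added in order of
#' decreasing divergence; the initial upper bound is the parsimony score of
#' the neighbor-joining tree; partial trees whose score already exceeds the
#' current bound are pruned (scores only grow as taxa are added, so the
#' search is exact).  When the alignment contains no parsimony-informative
#' site every topology attains the same score: the search is skipped and a
#' single canonical (caterpillar) topology is returned with
#' \code{uninformative = TRUE}.
#'
#' @param aln A \code{clone_alignment} with >= 2 sequences (intended scale
#'   4-16 taxa).
#' @param weights Optional per-site-pattern weight override (used by the site
#'   bootstrap); for internal use.
#' @param max_optimal Maximum number of tying optimal topologies to collect;
#'   if more exist (very weak data), collection stops and
#'   \code{truncated = TRUE} is reported (the score remains exact).
#' @return List of class \code{mp_search}: \code{score}, \code{trees}
#'   (\code{multiPhylo} of all optimal topologies in canonical order),
#'   \code{newicks}, \code{n_optimal}, \code{uninformative} and
#'   \code{truncated}.
#' @export
branch_and_bound_mp <- function(aln, weights = NULL, max_optimal = 20000) {
  max_optima <- max_optimal
  pat <- aln_patterns(aln)
  if (!is.null(weights)) pat$weights <- weights
  labels <- pat$labels
  n <- length(labels)
  if (n < 2) stop("need at least two sequences")
  keep <- pat$weights > 0
  states <- pat$states[keep, , drop = FALSE]  # patterns x tips
  w <- pat$weights[keep]

  popcount <- function(x) (bitwAnd(x, 1L) > 0) + (bitwAnd(x, 2L) > 0) +
    (bitwAnd(x, 4L) > 0) + (bitwAnd(x, 8L) > 0)
  ## per-pattern floor: any complete tree spends >= (#states - 1) changes
  union_bits <- apply(states, 1, function(r) Reduce(bitwOr, r))
  site_floor <- popcount(union_bits) - 1
  min_score <- sum(site_floor * w)
  informative <- vapply(seq_len(nrow(states)), function(i) {
    tab <- table(states[i, ])
    sum(tab >= 2) >= 2
  }, logical(1))

  make_result <- function(newicks, score, uninformative = FALSE,
                          truncated = FALSE) {
    newicks <- sort(unique(newicks))
    trees <- lapply(newicks, function(s) ape::read.tree(text = s))
    class(trees) <- "multiPhylo"
    structure(list(score = score, trees = trees, newicks = newicks,
                   n_optimal = length(newicks),
                   uninformative = uninformative, truncated = truncated),
              class = "mp_search")
  }

  if (n == 2)
    return(make_result(paste0("(", paste(sort(labels), collapse = ","), ");"),
                       min_score, uninformative = TRUE))
  if (n == 3 || !any(informative)) {
    ## single canonical topology; all topologies tie when uninformative
    sl <- sort(labels)
    cat_nwk <- paste0("(", sl[1], ",", sl[2], ",",
                      Reduce(function(acc, x) paste0("(", acc, ",", x, ")"),
                             sl[-(1:2)]), ");")
    if (n == 3) cat_nwk <- paste0("(", paste(sl, collapse = ","), ");")
    return(make_result(cat_nwk, min_score, uninformative = n > 3))
  }

  ## addition order: most divergent taxa first (deterministic)
  d <- alignment_distances(aln)
  ord <- order(-rowSums(d), labels)
  ## upper bound: score of the NJ topology under the current site weights
  njt <- neighbor_joining(d)
  pat_w <- pat; pat_w$weights <- if (is.null(weights)) pat$weights else weights
  upper <- fitch_core(njt, pat_w)$score
  best <- list(score = upper, newicks = character(0), truncated = FALSE)
  next_internal <- function(m) n + (m - 2L)   # internal id when adding m-th tip

  recurse <- function(edges, m) {
    if (m > n) {
      sc <- fitch_edges(edges, states, w, stop_above = best$score,
                        site_floor = site_floor)
      if (sc < best$score) {
        best$score <<- sc
        best$newicks <<- canonical_edges_newick(edges, labels)
        best$truncated <<- FALSE
      } else if (sc == best$score) {
        if (length(best$newicks) < max_optima)
          best$newicks <<- c(best$newicks,
                             canonical_edges_newick(edges, labels))
        else best$truncated <<- TRUE
      }
      return(invisible(NULL))
    }
    sc <- fitch_edges(edges, states, w, stop_above = best$score,
                      site_floor = site_floor)
    if (sc > best$score) return(invisible(NULL))   # prune
    tip <- ord[m]
    node <- next_internal(m)
    for (e in seq_len(nrow(edges))) {
      new_edges <- rbind(edges[-e, , drop = FALSE],
                         c(edges[e, 1], node),
                         c(node, edges[e, 2]),
                         c(node, tip))
      recurse(new_edges, m + 1L)
    }
    invisible(NULL)
  }

  root0 <- n + 1L
  edges0 <- rbind(c(root0, ord[1]), c(root0, ord[2]), c(root0, ord[3]))
  recurse(edges0, 4L)
  make_result(best$newicks, best$score, truncated = best$truncated)
}

#' Pairwise substitution-count distances of an alignment
#'
#' Raw Hamming distances (number of differing sites) between all sequence
#' pairs.
#'
#' @param aln A \code{clone_alignment}.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
alignment_distances <- function(aln) {
  pat <- aln_patterns(aln)
  n <- length(aln$labels)
  d <- matrix(0, n, n, dimnames = list(aln$labels, aln$labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dij <- sum(pat$weights[pat$states[, i] != pat$states[, j]])
    d[i, j] <- d[j, i] <- dij
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via \code{ape::nj}); on additive
#' distance matrices the true topology is recovered exactly.  Negative
#' branch-length estimates are clamped to zero with a warning.
#'
#' @param d Symmetric distance matrix with zero diagonal (>= 3 taxa).
#' @return A \code{phylo}.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0))
    stop("distance matrix must be symmetric with zero diagonal")
  if (anyNA(d)) stop("distance matrix contains NA")
  n <- nrow(d)
  if (n < 3) stop("need at least three taxa")
  if (n == 3) {
    lab <- colnames(d)
    bl <- c((d[1, 2] + d[1, 3] - d[2, 3]) / 2,
            (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
            (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
    tr <- ape::read.tree(text = paste0("(", lab[1], ":", max(0, bl[1]), ",",
                                       lab[2], ":", max(0, bl[2]), ",",
                                       lab[3], ":", max(0, bl[3]), ");"))
    return(tr)
  }
  tr <- ape::nj(d)
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to zero")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Bootstrap clade support
#'
#' Resamples alignment sites with replacement, re-estimates the tree for each
#' replicate, and reports for every nontrivial clade of the point-estimate
#' tree the fraction of replicates supporting it.  For maximum parsimony the
#' point estimate is the strict consensus of all optimal topologies, and a
#' replicate supports a clade only if the clade occurs in every optimal
#' topology of that replicate (strict-consensus rule: conservative and
#' deterministic).  Replicates with no parsimony-informative variation
#' support no clades.
#'
#' @param aln A \code{clone_alignment}.
#' @param n_replicates Number of bootstrap replicates.
#' @param method \code{"mp"} (branch and bound) or \code{"nj"}.
#' @param seed Seed for the site resampling.
#' @return List of class \code{bootstrap_support}: \code{tree} (point
#'   estimate; \code{NULL} with \code{uninformative = TRUE} when the original
#'   alignment has no informative sites), \code{support} (data frame: clade
#'   label, support fraction), \code{method}, \code{n_replicates}.
#' @export
bootstrap_support <- function(aln, n_replicates = 100,
                              method = c("mp", "nj"), seed = NULL) {
  method <- match.arg(method)
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  pat <- aln_patterns(aln)

  point <- estimate_clades(aln, pat$weights, method)
  if (method == "mp" && point$uninformative) {
    return(structure(list(tree = NULL,
                          support = data.frame(clade = character(0),
                                               support = numeric(0)),
                          uninformative = TRUE, method = method,
                          n_replicates = n_replicates),
                     class = "bootstrap_support"))
  }
  counts <- stats::setNames(numeric(length(point$clades)), point$clades)
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      w <- as.numeric(stats::rmultinom(1, aln$n_sites,
                                       pat$weights / aln$n_sites))
      rep_clades <- estimate_clades(aln, w, method)$clades
      hit <- intersect(point$clades, rep_clades)
      counts[hit] <- counts[hit] + 1
    }
  })
  structure(list(tree = point$tree,
                 support = data.frame(clade = names(counts),
                                      support = unname(counts) / n_replicates,
                                      stringsAsFactors = FALSE),
                 uninformative = FALSE, method = method,
                 n_replicates = n_replicates),
            class = "bootstrap_support")
}

# Clades supported by one estimation run on (possibly reweighted) sites.
# For MP: intersection of the bipartition sets of all optimal topologies
# (strict consensus); for NJ: bipartitions of the NJ tree.
estimate_clades <- function(aln, weights, method) {
  if (method == "mp") {
    res <- branch_and_bound_mp(aln, weights = weights)
    if (res$uninformative)
      return(list(clades = character(0), tree = NULL, uninformative = TRUE))
    sets <- lapply(res$trees, clade_set)
    clades <- Reduce(intersect, sets)
    list(clades = clades,
         tree = tree_from_splits(clades, aln$labels),  # strict consensus
         uninformative = FALSE)
  } else {
    pat <- aln_patterns(aln)
    n <- length(aln$labels)
    d <- matrix(0, n, n, dimnames = list(aln$labels, aln$labels))
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- sum(weights[pat$states[, i] != pat$states[, j]])
    tr <- neighbor_joining(d)
    list(clades = clade_set(tr), tree = tr, uninformative = FALSE)
  }
}

# --- ancestral states ------------------------------------------------------

IUPAC_FROM_BITS <- c("A", "C", "M", "G", "R", "S", "V",
                     "T", "W", "Y", "H", "K", "D", "B", "N")

#' Ancestral sequence reconstruction
#'
#' Reconstructs internal-node states on a rooted tree, site by site, either
#' by unit-cost parsimony - reporting the full most-parsimonious
#' reconstruction (MPR) state set of every node, with ambiguity preserved as
#' IUPAC codes - or by marginal likelihood under a single-rate reversible
#' (Jukes-Cantor) model mixed with an invariant-site class (default
#' proportion 0.97, appropriate for datasets where almost all sites never
#' change), reporting the posterior-maximum state and its posterior
#' probability.
#'
#' @param tree Rooted \code{phylo} whose tips match the alignment; for
#'   \code{"marginal_likelihood"} an unrooted tree is an error.  Missing
#'   branch lengths default to \code{branch_length}.
#' @param aln A \code{clone_alignment}.
#' @param mode \code{"fitch_parsimony"} or \code{"marginal_likelihood"}.
#' @param p_inv Invariant-site proportion of the likelihood model.
#' @param branch_length Substitutions/site assumed for edges without lengths.
#' @return List of class \code{ancestral_states}: \code{sequences} (named
#'   character vector over internal nodes; IUPAC ambiguity codes in parsimony
#'   mode), \code{ambiguous} (per-node count of ambiguous sites, parsimony
#'   mode) or \code{posterior} (per-node 4 x n_sites matrices) and
#'   \code{posterior_max}, plus \code{mode}.
#' @export
ancestral_states <- function(tree, aln,
                             mode = c("fitch_parsimony", "marginal_likelihood"),
                             p_inv = 0.97, branch_length = 0.01) {
  mode <- match.arg(mode)
  if (!setequal(tree$tip.label, aln$labels))
    stop("tree tips do not match alignment labels")
  if (mode == "marginal_likelihood" && !ape::is.rooted(tree))
    stop("marginal-likelihood reconstruction requires a rooted tree")
  pat <- aln_patterns(aln)
  tv <- tree_traversal(tree)
  n_tip <- tv$n_tip
  n_node <- length(tv$children)
  tip_idx <- match(tree$tip.label, pat$labels)
  npat <- nrow(pat$states)
  node_names <- if (!is.null(tree$node.label) &&
                    length(tree$node.label) == n_node - n_tip)
    tree$node.label else paste0("node", (n_tip + 1):n_node)

  ## per-tip 4 x npat indicator matrices
  tip_states <- lapply(seq_len(n_tip), function(v) {
    bits <- pat$states[, tip_idx[v]]
    rbind(A = bitwAnd(bits, 1L) > 0, C = bitwAnd(bits, 2L) > 0,
          G = bitwAnd(bits, 4L) > 0, T = bitwAnd(bits, 8L) > 0)
  })

  internal <- (n_tip + 1):n_node
  if (mode == "fitch_parsimony") {
    BIG <- 1e9
    C <- vector("list", n_node)     # subtree cost per state
    for (v in tv$postorder) {
      if (v <= n_tip) {
        C[[v]] <- ifelse(tip_states[[v]], 0, BIG)
      } else {
        acc <- matrix(0, 4, npat)
        for (ch in tv$children[[v]]) {
          cc <- C[[ch]]
          mn <- apply(cc, 2, min)
          acc <- acc + pmin(cc, rep(mn + 1, each = 4))
        }
        C[[v]] <- acc
      }
    }
    ## outside costs (cost of the rest of the tree given the node's state)
    A <- vector("list", n_node)
    A[[tv$root]] <- matrix(0, 4, npat)
    for (v in tv$postorder[rev(seq_along(tv$postorder))]) { # preorder
      if (v <= n_tip) next
      for (ch in tv$children[[v]]) {
        m <- A[[v]]
        for (sb in setdiff(tv$children[[v]], ch)) {
          cc <- C[[sb]]
          mn <- apply(cc, 2, min)
          m <- m + pmin(cc, rep(mn + 1, each = 4))
        }
        mnm <- apply(m, 2, min)
        A[[ch]] <- pmin(m, rep(mnm + 1, each = 4))
      }
    }
    seqs <- character(0); ambig <- integer(0)
    sets <- vector("list", length(internal))
    for (k in seq_along(internal)) {
      v <- internal[k]
      tot <- C[[v]] + A[[v]]
      mn <- apply(tot, 2, min)
      in_set <- tot <= rep(mn, each = 4)       # MPR state sets
      bits <- colSums(in_set * c(1L, 2L, 4L, 8L))
      chars <- IUPAC_FROM_BITS[bits]
      seqs[node_names[k]] <- paste(chars[pat$site_pattern], collapse = "")
      ambig[node_names[k]] <- sum((colSums(in_set) > 1)[pat$site_pattern])
      sets[[k]] <- in_set
    }
    names(sets) <- node_names
    return(structure(list(sequences = seqs, ambiguous = ambig, sets = sets,
                          site_pattern = pat$site_pattern, mode = mode),
                     class = "ancestral_states"))
  }

  ## marginal likelihood, JC + invariant class
  el <- tree$edge.length
  if (is.null(el)) el <- rep(branch_length, nrow(tree$edge))
  edge_len <- numeric(n_node)
  edge_len[tree$edge[, 2]] <- el
  rates <- c(0, 1 / (1 - p_inv))
  cat_w <- c(p_inv, 1 - p_inv)
  jc_P <- function(t, r) {
    e <- exp(-4 * r * t / 3)
    matrix((1 - e) / 4, 4, 4) + diag(rep(e, 4))
  }
  post_num <- vector("list", n_node)   # accumulated over categories
  for (v in internal) post_num[[v]] <- matrix(0, 4, npat)
  lik_site <- numeric(npat)
  for (ci in seq_along(rates)) {
    P <- lapply(seq_len(n_node), function(v) jc_P(edge_len[v], rates[ci]))
    L <- vector("list", n_node)        # conditional (subtree) likelihoods
    for (v in tv$postorder) {
      if (v <= n_tip) { L[[v]] <- tip_states[[v]] * 1; next }
      acc <- matrix(1, 4, npat)
      for (ch in tv$children[[v]]) acc <- acc * (P[[ch]] %*% L[[ch]])
      L[[v]] <- acc
    }
    D <- vector("list", n_node)        # outside likelihoods
    D[[tv$root]] <- matrix(1, 4, npat)
    for (v in rev(tv$postorder)) {     # preorder
      if (v <= n_tip) next
      for (ch in tv$children[[v]]) {
        m <- D[[v]]
        for (sb in setdiff(tv$children[[v]], ch))
          m <- m * (P[[sb]] %*% L[[sb]])
        D[[ch]] <- t(P[[ch]]) %*% m
      }
    }
    for (v in internal)
      post_num[[v]] <- post_num[[v]] + cat_w[ci] * (L[[v]] * D[[v]]) / 4
    lik_site <- lik_site + cat_w[ci] * colSums(L[[tv$root]] / 4)
  }
  seqs <- character(0)
  posterior <- list(); post_max <- list()
  for (k in seq_along(internal)) {
    v <- internal[k]
    pp <- sweep(post_num[[v]], 2, colSums(post_num[[v]]), "/")
    rownames(pp) <- names(BASE_BITS)
    amax <- apply(pp, 2, which.max)    # ties: first state in ACGT order
    chars <- names(BASE_BITS)[amax]
    seqs[node_names[k]] <- paste(chars[pat$site_pattern], collapse = "")
    posterior[[node_names[k]]] <- pp[, pat$site_pattern, drop = FALSE]
    post_max[[node_names[k]]] <-
      pp[cbind(amax, seq_len(npat))][pat$site_pattern]
  }
  structure(list(sequences = seqs, posterior = posterior,
                 posterior_max = post_max, mode = mode),
            class = "ancestral_states")
}

# Canonical Newick of a phylo object: children sorted recursively by their
# smallest descendant tip label.
canonical_phylo_newick <- function(tree) {
  tv <- tree_traversal(tree)
  build <- function(v) {
    if (v <= tv$n_tip) return(list(str = tree$tip.label[v],
                                   min = tree$tip.label[v]))
    subs <- lapply(tv$children[[v]], build)
    subs <- subs[order(vapply(subs, `[[`, "", "min"))]
    lab <- if (!is.null(tree$node.label)) tree$node.label[v - tv$n_tip] else ""
    if (is.na(lab)) lab <- ""
    list(str = paste0("(", paste(vapply(subs, `[[`, "", "str"),
                                 collapse = ","), ")", lab),
         min = vapply(subs, `[[`, "", "min")[1])
  }
  paste0(build(tv$root)$str, ";")
}
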