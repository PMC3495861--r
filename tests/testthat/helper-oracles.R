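# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: translation goes through seqinr, tree scoring
# through exhaustive enumeration or phangorn, Fisher p through direct
# hypergeometric enumeration.

# Translate a codon with seqinr (independent of the package's genetic-code
# lookup); seqinr uses "*" for stop codons as we do.
oracle_translate <- function(codon) {
  seqinr::translate(strsplit(tolower(codon), "")[[1]])
}

# Exact two-sided Fisher p by direct enumeration of all tables with the
# observed margins, summing probabilities <= the observed table's
# (with the customary 1 + 1e-7 tolerance for ties).
oracle_fisher <- function(tab) {
  tab <- matrix(as.numeric(tab), 2, 2)
  r <- rowSums(tab); c2 <- colSums(tab); n <- sum(tab)
  if (any(r == 0) || any(c2 == 0)) return(1)
  a_vals <- max(0, c2[1] - r[2]):min(r[1], c2[1])
  probs <- vapply(a_vals, function(a)
    stats::dhyper(a, r[1], r[2], c2[1]), numeric(1))
  p_obs <- stats::dhyper(tab[1, 1], r[1], r[2], c2[1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force parsimony length of one tree: minimum number of changes over
# all internal-node state assignments, summed over sites.
oracle_parsimony <- function(tree, seq_strings) {
  m <- do.call(rbind, strsplit(unname(seq_strings), ""))
  rownames(m) <- names(seq_strings)
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  bases <- c("A", "C", "G", "T")
  total <- 0
  for (site in seq_len(ncol(m))) {
    tip_state <- m[tree$tip.label, site]
    best <- Inf
    grid <- expand.grid(rep(list(bases), n_int), stringsAsFactors = FALSE)
    for (g in seq_len(nrow(grid))) {
      assign_int <- unlist(grid[g, ])
      state_of <- function(v) if (v <= n_tip) tip_state[v]
                              else assign_int[v - n_tip]
      changes <- sum(vapply(seq_len(nrow(tree$edge)), function(e)
        state_of(tree$edge[e, 1]) != state_of(tree$edge[e, 2]), TRUE))
      best <- min(best, changes)
    }
    total <- total + best
  }
  total
}

# Per-site sets of states each internal node takes in at least one
# most-parsimonious labeling (brute force).
oracle_mpr_sets <- function(tree, seq_strings, site) {
  m <- do.call(rbind, strsplit(unname(seq_strings), ""))
  rownames(m) <- names(seq_strings)
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  bases <- c("A", "C", "G", "T")
  tip_state <- m[tree$tip.label, site]
  grid <- expand.grid(rep(list(bases), n_int), stringsAsFactors = FALSE)
  cost <- vapply(seq_len(nrow(grid)), function(g) {
    assign_int <- unlist(grid[g, ])
    state_of <- function(v) if (v <= n_tip) tip_state[v]
                            else assign_int[v - n_tip]
    sum(vapply(seq_len(nrow(tree$edge)), function(e)
      state_of(tree$edge[e, 1]) != state_of(tree$edge[e, 2]), TRUE))
  }, numeric(1))
  opt <- grid[cost == min(cost), , drop = FALSE]
  lapply(seq_len(n_int), function(k) sort(unique(opt[[k]])))
}

# Enumerate all unrooted topologies and find the minimum phangorn Fitch
# score and the number of optima (fully independent MP oracle).
oracle_mp_exhaustive <- function(seq_strings) {
  labs <- names(seq_strings)
  m <- do.call(rbind, strsplit(unname(seq_strings), ""))
  rownames(m) <- labs
  pd <- phangorn::phyDat(m)
  trees <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  scores <- vapply(trees, function(t) phangorn::fitch(t, pd), numeric(1))
  list(score = min(scores), n_optimal = sum(scores == min(scores)),
       optima = trees[scores == min(scores)])
}

# Random clone set over a single segment (for alignment-level tests).
random_clones <- function(n_tips, n_sites, labels = paste0("t", seq_len(n_tips))) {
  m <- matrix(sample(c("A", "C", "G", "T"), n_tips * n_sites, replace = TRUE),
              nrow = n_tips)
  out <- lapply(seq_len(n_tips), function(i)
    segmented_genome(list(L = paste(m[i, ], collapse = ""))))
  names(out) <- labels
  out
}

# Simulate sequences on a known tree: start from a random root sequence and
# apply a fixed number of unique-site substitutions on every branch
# (guaranteeing no homoplasy), returning tip sequences.
simulate_on_tree <- function(tree, n_sites, per_branch) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[root]] <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  free_sites <- sample(n_sites)   # each site used at most once: no homoplasy
  ptr <- 0
  for (e in rev(seq_len(nrow(tree$edge)))) {   # preorder
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    s <- seqs[[par]]
    for (k in seq_len(per_branch)) {
      ptr <- ptr + 1
      site <- free_sites[ptr]
      s[site] <- sample(setdiff(c("A", "C", "G", "T"), s[site]), 1)
    }
    seqs[[ch]] <- s
  }
  tips <- lapply(seq_len(n_tip), function(i)
    segmented_genome(list(L = paste(seqs[[i]], collapse = ""))))
  names(tips) <- tree$tip.label
  tips
}
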