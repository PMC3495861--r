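# Scoring an inferred phylogeny and inferred ancestral sequences against the
# recorded truth: clade false positives/negatives and Robinson-Foulds
# distance via canonical bipartition sets, and per-node per-site ancestral
# sequence accuracy with clade-based node mapping.

#' Nontrivial bipartitions of a tree
#'
#' Every internal edge of the (implicitly unrooted) tree defines a
#' bipartition of the tips; each is encoded canonically as the sorted tip
#' set of its smaller side (ties broken lexicographically), joined by
#' \code{"|"}, so the encoding is independent of rooting and orientation.
#' Trivial bipartitions (single tip / all tips) are excluded;
#' multifurcating trees simply yield fewer bipartitions.
#'
#' @param tree A \code{phylo}.
#' @return Character vector of canonical bipartition encodings (possibly
#'   empty), sorted.
#' @export
clade_set <- function(tree) {
  tv <- tree_traversal(tree)
  all_tips <- sort(tree$tip.label)
  n <- length(all_tips)
  below <- rooted_clades(tree)
  enc <- vapply(below, function(tips) {
    if (length(tips) <= 1 || length(tips) >= n - 1) return(NA_character_)
    other <- setdiff(all_tips, tips)
    a <- paste(sort(tips), collapse = "|")
    b <- paste(sort(other), collapse = "|")
    if (length(tips) < length(other)) a
    else if (length(other) < length(tips)) b
    else min(a, b)
  }, character(1))
  sort(unique(enc[!is.na(enc)]))
}

# Tip sets below each internal node of a rooted (or arbitrarily rooted)
# tree, named by node label when available.
rooted_clades <- function(tree) {
  tv <- tree_traversal(tree)
  n_tip <- tv$n_tip
  below <- vector("list", length(tv$children))
  for (v in tv$postorder) {
    below[[v]] <- if (v <= n_tip) tree$tip.label[v]
                  else sort(unlist(lapply(tv$children[[v]], function(ch)
                    below[[ch]])))
  }
  internal <- (n_tip + 1):length(tv$children)
  out <- below[internal]
  names(out) <- if (!is.null(tree$node.label)) tree$node.label
                else paste0("node", internal)
  out
}

#' Clade errors of an inferred tree against the true tree
#'
#' Compares the nontrivial bipartition sets of the two trees: false positives
#' are bipartitions of the inferred tree absent from the true tree, false
#' negatives the reverse; the Robinson-Foulds distance is their sum.
#' Multifurcations in the inferred tree can only produce false negatives
#' (unresolved clades are missing, never wrong).
#'
#' @param true,inferred \code{phylo} objects over the same tip set.
#' @return List of class \code{accuracy_clades}: \code{false_positives},
#'   \code{false_negatives} (character vectors of bipartition encodings),
#'   \code{rf} and the per-tree bipartition counts.
#' @export
clade_errors <- function(true, inferred) {
  if (!setequal(true$tip.label, inferred$tip.label)) {
    d1 <- setdiff(true$tip.label, inferred$tip.label)
    d2 <- setdiff(inferred$tip.label, true$tip.label)
    stop("tip sets differ; only in true: {", paste(d1, collapse = ", "),
         "}; only in inferred: {", paste(d2, collapse = ", "), "}")
  }
  ct <- clade_set(true)
  ci <- clade_set(inferred)
  fp <- setdiff(ci, ct)
  fn <- setdiff(ct, ci)
  structure(list(false_positives = fp, false_negatives = fn,
                 rf = length(fp) + length(fn),
                 n_true = length(ct), n_inferred = length(ci)),
            class = "accuracy_clades")
}

#' @export
print.accuracy_clades <- function(x, ...) {
  cat("clade accuracy: RF =", x$rf, "(", length(x$false_positives),
      "false positive,", length(x$false_negatives), "false negative )\n")
  invisible(x)
}

#' Ancestral-sequence reconstruction accuracy
#'
#' Maps internal nodes of the inferred tree to internal nodes of the true
#' tree by clade content (the set of tip labels below the node), then scores
#' inferred node sequences against true node sequences site by site.
#' Ambiguous inferred states (IUPAC codes outside A/C/G/T) are counted as
#' incorrect but flagged separately; true nodes whose clade has no
#' counterpart in the inferred tree are skipped and reported.
#'
#' @param true_tree,inferred_tree Rooted \code{phylo} objects (same tips).
#' @param true_seqs Named character vector of true internal-node sequences
#'   (names = node labels of \code{true_tree}).
#' @param inferred_seqs Named character vector of inferred internal-node
#'   sequences (names = node labels of \code{inferred_tree}).
#' @return List of class \code{accuracy_ancestral}: \code{per_node} (data
#'   frame: true node, inferred node, sites, matches, ambiguous, accuracy),
#'   \code{mis_sites} (data frame: node, site, true/inferred state,
#'   ambiguous), \code{unmapped} (true node labels without an inferred
#'   counterpart), and \code{overall_accuracy}.
#' @export
ancestral_accuracy <- function(true_tree, inferred_tree,
                               true_seqs, inferred_seqs) {
  if (!setequal(true_tree$tip.label, inferred_tree$tip.label))
    stop("tip sets of the two trees differ")
  tc <- rooted_clades(true_tree)
  ic <- rooted_clades(inferred_tree)
  tc <- tc[names(tc) %in% names(true_seqs)]
  ic_key <- vapply(ic, paste, "", collapse = "|")
  per_node <- list(); mis <- list(); unmapped <- character(0)
  for (tn in names(tc)) {
    key <- paste(tc[[tn]], collapse = "|")
    hit <- names(ic)[ic_key == key]
    hit <- hit[hit %in% names(inferred_seqs)]
    if (!length(hit)) { unmapped <- c(unmapped, tn); next }
    infn <- hit[1]
    ts <- strsplit(true_seqs[[tn]], "")[[1]]
    is_ <- strsplit(inferred_seqs[[infn]], "")[[1]]
    if (length(ts) != length(is_))
      stop("sequence length mismatch at node ", tn)
    ambig <- !(is_ %in% DNA_BASES)
    ok <- ts == is_ & !ambig
    bad <- which(!ok)
    per_node[[tn]] <- data.frame(
      true_node = tn, inferred_node = infn, sites = length(ts),
      matches = sum(ok), ambiguous = sum(ambig),
      accuracy = mean(ok), stringsAsFactors = FALSE)
    if (length(bad))
      mis[[tn]] <- data.frame(node = tn, site = bad, true = ts[bad],
                              inferred = is_[bad], ambiguous = ambig[bad],
                              stringsAsFactors = FALSE)
  }
  empty_mis <- data.frame(node = character(0), site = integer(0),
                          true = character(0), inferred = character(0),
                          ambiguous = logical(0))
  pn <- if (length(per_node)) do.call(rbind, per_node) else
    data.frame(true_node = character(0), inferred_node = character(0),
               sites = integer(0), matches = integer(0),
               ambiguous = integer(0), accuracy = numeric(0))
  rownames(pn) <- NULL
  structure(list(per_node = pn,
                 mis_sites = if (length(mis)) {
                   m <- do.call(rbind, mis); rownames(m) <- NULL; m
                 } else empty_mis,
                 unmapped = unmapped,
                 overall_accuracy = if (nrow(pn)) sum(pn$matches) / sum(pn$sites)
                                    else NA_real_),
            class = "accuracy_ancestral")
}

#' @export
print.accuracy_ancestral <- function(x, ...) {
  cat("ancestral accuracy:", nrow(x$per_node), "node(s) scored, overall",
      format(x$overall_accuracy, digits = 6), "-", nrow(x$mis_sites),
      "mis-reconstructed (node, site) pair(s)\n")
  invisible(x)
}

# Build the (possibly multifurcating) unrooted tree displaying exactly the
# given compatible bipartitions; used for strict-consensus point estimates.
tree_from_splits <- function(splits, labels) {
  labels <- sort(labels)
  sides <- lapply(splits, function(s) strsplit(s, "\\|")[[1]])
  # orient every split as the side not containing the first label
  sides <- lapply(sides, function(s)
    if (labels[1] %in% s) setdiff(labels, s) else s)
  sides <- sides[order(lengths(sides), decreasing = TRUE)]
  # nest each split (and finally each tip) under its smallest enclosing split
  children <- list(g0 = character(0))
  for (i in seq_along(sides)) {
    gid <- paste0("g", i)
    parent <- "g0"
    for (j in seq_len(i - 1))
      if (all(sides[[i]] %in% sides[[j]])) parent <- paste0("g", j)
    children[[parent]] <- c(children[[parent]], gid)
    children[[gid]] <- character(0)
  }
  for (lab in labels) {
    parent <- "g0"
    for (j in seq_along(sides))
      if (lab %in% sides[[j]]) parent <- paste0("g", j)
    children[[parent]] <- c(children[[parent]], lab)
  }
  render <- function(id) {
    parts <- vapply(children[[id]], function(k)
      if (k %in% names(children)) render(k) else k, character(1))
    paste0("(", paste(sort(parts), collapse = ","), ")")
  }
  ape::read.tree(text = paste0(render("g0"), ";"))
}
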