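# Tree inference: Fitch scoring, exact branch-and-bound search, NJ,
# bootstrap, ancestral states.  Oracles: brute-force labeling enumeration,
# exhaustive topology search scored with phangorn, independent resampling.

aln_of <- function(seqs) {
  build_alignment(lapply(seqs, function(s) segmented_genome(list(L = s))))
}

test_that("Fitch score reproduces hand-checked cases", {
  aln <- aln_of(c(A = "AAAA", B = "AAAA", C = "AAAA", D = "AAAA"))
  expect_equal(fitch_score(ape::read.tree(text = "((A,B),(C,D));"), aln), 0)
  # one site with states A,A,C,C
  aln2 <- aln_of(c(t1 = "A", t2 = "A", t3 = "C", t4 = "C"))
  expect_equal(fitch_score(ape::read.tree(text = "((t1,t2),(t3,t4));"), aln2), 1)
  expect_equal(fitch_score(ape::read.tree(text = "((t1,t3),(t2,t4));"), aln2), 2)
  expect_error(fitch_score(ape::read.tree(text = "((a,b),(c,d));"), aln2),
               "labels")
})

test_that("Fitch score equals brute-force minimal labeling on random data", {
  skip_if_not_installed("phangorn")
  set.seed(61)
  for (rep in 1:3) {
    n <- 6
    seqs <- stats::setNames(vapply(1:n, function(i)
      paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""),
      ""), paste0("t", 1:n))
    aln <- aln_of(seqs)
    tr <- ape::rtree(n, tip.label = paste0("t", 1:n), br = NULL)
    expect_equal(fitch_score(tr, aln), oracle_parsimony(tr, seqs))
    # site order and tip-label permutation invariance
    perm <- sample(20)
    seqs_p <- vapply(seqs, function(s)
      paste(strsplit(s, "")[[1]][perm], collapse = ""), "")
    expect_equal(fitch_score(tr, aln_of(seqs_p)), fitch_score(tr, aln))
    relab <- stats::setNames(paste0("u", 1:n), paste0("t", 1:n))
    tr2 <- tr; tr2$tip.label <- unname(relab[tr$tip.label])
    seqs_r <- stats::setNames(seqs, unname(relab[names(seqs)]))
    expect_equal(fitch_score(tr2, aln_of(seqs_r)), fitch_score(tr, aln))
  }
})

test_that("branch and bound equals exhaustive search on 5-7 taxa", {
  skip_if_not_installed("phangorn")
  set.seed(71)
  for (rep in 1:6) {
    n <- sample(5:7, 1)
    seqs <- stats::setNames(vapply(1:n, function(i)
      paste(sample(c("A", "C", "G", "T"), 15, TRUE), collapse = ""),
      ""), paste0("t", 1:n))
    res <- branch_and_bound_mp(aln_of(seqs))
    ora <- oracle_mp_exhaustive(seqs)
    expect_equal(res$score, ora$score)
    expect_equal(res$n_optimal, ora$n_optimal)
    # every returned optimum scores at the optimum
    for (tr in res$trees)
      expect_equal(fitch_score(tr, aln_of(seqs)), res$score)
  }
})

test_that("branch and bound recovers a clean generating topology uniquely", {
  set.seed(81)
  tr <- ape::rtree(6, tip.label = paste0("t", 1:6))
  tips <- simulate_on_tree(tr, n_sites = 400, per_branch = 8)
  res <- branch_and_bound_mp(build_alignment(tips))
  expect_equal(res$n_optimal, 1L)
  expect_equal(clade_errors(tr, res$trees[[1]])$rf, 0)
})

test_that("identical sequences are reported as uninformative, not searched", {
  aln <- aln_of(stats::setNames(rep("ACGTACGT", 5), paste0("t", 1:5)))
  res <- branch_and_bound_mp(aln)
  expect_true(res$uninformative)
  expect_equal(res$score, 0)
  expect_equal(res$n_optimal, 1L)
})

test_that("NJ recovers topology from additive matrices and is label-stable", {
  set.seed(91)
  for (rep in 1:100) {
    n <- sample(5:10, 1)
    tr <- ape::rtree(n)
    d <- stats::cophenetic(tr)   # additive by construction
    expect_equal(clade_errors(tr, neighbor_joining(d))$rf, 0)
  }
  # permuting the input label order leaves the unrooted topology unchanged
  tr <- ape::rtree(8)
  d <- stats::cophenetic(tr)
  perm <- sample(8)
  expect_equal(clade_errors(neighbor_joining(d),
                            neighbor_joining(d[perm, perm]))$rf, 0)
  # three taxa give the unique topology
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(sort(neighbor_joining(d3)$tip.label), letters[1:3])
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2)), "symmetric|taxa")
})

test_that("bootstrap support is 1 for a clade fixed by the only pattern", {
  # one site pattern (spanning several sites, so every resample retains it)
  # supports clade {t1,t2}; all other sites are constant
  seqs <- c(t1 = paste0(strrep("C", 8), strrep("A", 30)),
            t2 = paste0(strrep("C", 8), strrep("A", 30)),
            t3 = paste0(strrep("G", 8), strrep("A", 30)),
            t4 = paste0(strrep("G", 8), strrep("A", 30)))
  bs <- bootstrap_support(aln_of(seqs), n_replicates = 40, method = "mp",
                          seed = 5)
  expect_false(bs$uninformative)
  expect_equal(nrow(bs$support), 1L)
  expect_identical(bs$support$clade, "t1|t2")
  expect_equal(bs$support$support, 1)
  # identical sequences: uninformative flag and no supports
  bs0 <- bootstrap_support(aln_of(stats::setNames(rep("AAAA", 4),
                                                  paste0("t", 1:4))),
                           n_replicates = 5, method = "mp", seed = 1)
  expect_true(bs0$uninformative)
  expect_equal(nrow(bs0$support), 0L)
})

test_that("bootstrap frequencies agree with an independent resampling oracle", {
  set.seed(101)
  tr <- ape::rtree(6, tip.label = paste0("t", 1:6))
  tips <- simulate_on_tree(tr, n_sites = 60, per_branch = 2)
  aln <- build_alignment(tips)
  bs <- bootstrap_support(aln, n_replicates = 200, method = "nj", seed = 17)
  # oracle: hand-rolled site resampling + ape::nj + ape::prop.part
  m <- do.call(rbind, strsplit(unname(aln$seqs), ""))
  rownames(m) <- aln$labels
  enc <- function(tipset, all) {
    other <- setdiff(all, tipset)
    a <- paste(sort(tipset), collapse = "|")
    b <- paste(sort(other), collapse = "|")
    if (length(tipset) < length(other)) a
    else if (length(other) < length(tipset)) b else min(a, b)
  }
  nj_clades <- function(mm) {
    d <- matrix(0, nrow(mm), nrow(mm), dimnames = list(rownames(mm),
                                                       rownames(mm)))
    for (i in seq_len(nrow(mm) - 1)) for (j in (i + 1):nrow(mm))
      d[i, j] <- d[j, i] <- sum(mm[i, ] != mm[j, ])
    t2 <- ape::nj(d)
    pp <- ape::prop.part(t2)
    labs <- attr(pp, "labels")
    out <- vapply(pp, function(idx) enc(labs[idx], labs), "")
    unique(out[vapply(pp, function(idx)
      length(idx) > 1 && length(idx) < nrow(mm) - 1, TRUE)])
  }
  set.seed(400)
  n_rep <- 200
  counts <- stats::setNames(numeric(nrow(bs$support)), bs$support$clade)
  for (r in seq_len(n_rep)) {
    mm <- m[, sample(ncol(m), replace = TRUE), drop = FALSE]
    hit <- intersect(names(counts), nj_clades(mm))
    counts[hit] <- counts[hit] + 1
  }
  ora <- counts / n_rep
  for (cl in names(ora)) {
    p <- ora[[cl]]
    se <- sqrt(max(p * (1 - p), 0.25 / n_rep) / n_rep)
    got <- bs$support$support[bs$support$clade == cl]
    expect_lt(abs(got - p), 3 * se + 0.02)
  }
})

test_that("parsimony ancestral sets equal brute-force MPR sets on 5 tips", {
  set.seed(111)
  tr <- ape::read.tree(text = "(((t1,t2)n1,t3)n2,(t4,t5)n3)r;")
  for (rep in 1:2) {
    seqs <- stats::setNames(vapply(1:5, function(i)
      paste(sample(c("A", "C", "G", "T"), 6, TRUE), collapse = ""), ""),
      paste0("t", 1:5))
    anc <- ancestral_states(tr, aln_of(seqs), "fitch_parsimony")
    iupac_bits <- c(A = 1L, C = 2L, M = 3L, G = 4L, R = 5L, S = 6L, V = 7L,
                    T = 8L, W = 9L, Y = 10L, H = 11L, K = 12L, D = 13L,
                    B = 14L, N = 15L)
    bit_states <- function(b) c("A", "C", "G", "T")[
      which(bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0)]
    for (site in 1:6) {
      ora <- oracle_mpr_sets(tr, seqs, site)
      for (k in seq_along(tr$node.label)) {
        lab <- tr$node.label[k]
        got <- bit_states(iupac_bits[[substr(anc$sequences[[lab]],
                                             site, site)]])
        expect_identical(got, ora[[k]])
      }
    }
  }
})

test_that("likelihood ancestral posteriors are proper and sensible", {
  tr <- ape::read.tree(text = "((A,B)n1,(C,D)n2)r;")
  aln <- aln_of(c(A = "AAGA", B = "AAGA", C = "AAGA", D = "ACGA"))
  anc <- ancestral_states(tr, aln, "marginal_likelihood")
  for (nd in names(anc$posterior))
    expect_equal(colSums(anc$posterior[[nd]]), rep(1, 4), tolerance = 1e-12)
  # a constant site is reconstructed as that state with posterior ~ 1
  expect_identical(substr(anc$sequences[["r"]], 1, 1), "A")
  expect_gt(anc$posterior[["r"]]["A", 1], 0.999)
  # site 2: C only in one tip; ancestor should still be A
  expect_identical(substr(anc$sequences[["r"]], 2, 2), "A")
  expect_error(ancestral_states(ape::unroot(tr), aln, "marginal_likelihood"),
               "rooted")
})

test_that("an exact reversion on one path hides the mutation from reconstruction", {
  # forward T->C below the root, exact reversion C->T on the only sampled
  # descendant path: every tip shows T, so the true intermediate C cannot be
  # recovered and the ancestral estimate equals the tip state
  tr <- ape::read.tree(text = "(((t1,t2)n1,t3)n2,t4)r;")
  seqs <- c(t1 = "T", t2 = "T", t3 = "T", t4 = "T")  # after the reversion
  for (mode in c("fitch_parsimony", "marginal_likelihood")) {
    anc <- ancestral_states(tr, aln_of(seqs), mode)
    expect_identical(unname(substr(anc$sequences[["n1"]], 1, 1)), "T")
  }
})
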