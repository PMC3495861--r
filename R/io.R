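# Shared readers/writers and the end-to-end pipeline.  Sequence sets travel
# as FASTA with record ids "<clone>|<segment>"; trees as Newick in a
# canonical form (children sorted by smallest contained tip label) so
# repeated runs are byte-identical; tables as TSV.

#' Read clone genomes from FASTA
#'
#' Record ids must follow \code{"<clone>|<segment>"} (e.g. \code{"F7|S"});
#' every clone must carry the same segments with consistent lengths.
#'
#' @param path FASTA file.
#' @return Named list of \code{segmented_genome} objects.
#' @export
read_clone_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- names(ss)
  if (anyDuplicated(ids))
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  parts <- strsplit(ids, "|", fixed = TRUE)
  bad <- vapply(parts, length, 0L) != 2L
  if (any(bad))
    stop("record id(s) not of the form '<clone>|<segment>': ",
         paste(ids[bad], collapse = ", "))
  clone <- vapply(parts, `[`, "", 1L)
  seg <- vapply(parts, `[`, "", 2L)
  out <- lapply(unique(clone), function(cl) {
    idx <- which(clone == cl)
    segs <- as.character(ss[idx])
    names(segs) <- seg[idx]
    segmented_genome(as.list(segs))
  })
  names(out) <- unique(clone)
  lens <- lapply(out, segment_lengths)
  if (length(unique(vapply(lens, paste, "", collapse = ","))) != 1L)
    stop("clones have inconsistent segment lengths")
  out
}

#' Write clone genomes to FASTA
#'
#' Inverse of \code{\link{read_clone_fasta}}: one record per
#' (clone, segment), 60-column wrapped, byte-stable.
#'
#' @param clones Named list of \code{segmented_genome} objects.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_clone_fasta <- function(clones, path) {
  seqs <- character(0)
  for (cl in names(clones))
    for (sg in names(clones[[cl]]))
      seqs[paste0(cl, "|", sg)] <- clones[[cl]][[sg]]
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 60)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Newick file (internal labels and branch lengths preserved).
#' @return A \code{phylo}.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in ", path,
                                          ": ", conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip label(s) in ", path, ": ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' Write a Newick tree in canonical form
#'
#' Children of every node are ordered by their smallest contained tip label,
#' so topologically identical trees always serialise identically.  Branch
#' lengths are dropped; internal node labels are preserved.
#'
#' @param tree A \code{phylo}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_newick <- function(tree, path) {
  writeLines(canonical_phylo_newick(tree), path)
  invisible(path)
}

#' Write a mutation-event table as TSV
#'
#' @param events Mutation-event data frame (with or without \code{branch}).
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_mutation_table <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a mutation-event table
#' @param path TSV written by \code{\link{write_mutation_table}}.
#' @return Data frame.
#' @export
read_mutation_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in order - \code{simulate} (forward
#' simulation; writes clone FASTA, true tree, mutation-history TSV),
#' \code{stats} (per-segment density + uniformity test, Ka/Ks per regime,
#' homoplasy report), \code{infer} (tree reconstruction from the tip clones),
#' \code{evaluate} (clade errors of the inferred vs true tree) - and writes a
#' manifest of every artifact with its MD5 checksum.  Identical inputs,
#' configuration and seed give a byte-identical manifest.  When
#' \code{simulate} is disabled, user-supplied clone FASTA and true-tree files
#' already in \code{out_dir} are used instead.
#'
#' @param out_dir Output directory (created if needed).
#' @param design Experiment design.
#' @param params Simulation parameters.
#' @param seed Integer run seed (echoed, with parameters, to the run log;
#'   every stage derives its own stream from it).
#' @param stages Character vector of stages to run.
#' @param infer_method \code{"mp"} or \code{"nj"}.
#' @return Invisibly, a list with the stage outputs and the manifest path.
#' @export
run_pipeline <- function(out_dir, design = default_design(),
                         params = sim_params(), seed = 1,
                         stages = c("simulate", "stats", "infer", "evaluate"),
                         infer_method = c("mp", "nj")) {
  infer_method <- match.arg(infer_method)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    clones = file.path(out_dir, "clones.fasta"),
    tree = file.path(out_dir, "true_tree.nwk"),
    events = file.path(out_dir, "mutation_history.tsv"),
    density = file.path(out_dir, "segment_density.tsv"),
    kaks = file.path(out_dir, "kaks_by_regime.tsv"),
    tests = file.path(out_dir, "stat_tests.tsv"),
    homoplasy = file.path(out_dir, "homoplasy.tsv"),
    inferred = file.path(out_dir, "inferred_tree.nwk"),
    accuracy = file.path(out_dir, "accuracy.tsv"),
    log = file.path(out_dir, "run_log.txt"))
  out <- list()
  written <- character(0)

  log_lines <- c(paste0("phi6kp ",
                        as.character(utils::packageVersion("phi6kp"))),
                 paste0("seed\t", seed),
                 paste0("stages\t", paste(stages, collapse = ",")),
                 paste0("mu\t", params$mu),
                 paste0("burst\t", params$burst),
                 paste0("gens_per_plaque\t", params$gens_per_plaque),
                 paste0("replication\t", params$replication))

  if ("simulate" %in% stages) {
    ex <- simulate_experiment(design, params, seed)
    out$experiment <- ex
    write_clone_fasta(ex$clones, paths$clones)
    write_newick(ex$tree, paths$tree)
    write_mutation_table(ex$events, paths$events)
    written <- c(written, paths$clones, paths$tree, paths$events)
  }

  if (any(c("stats", "infer", "evaluate") %in% stages)) {
    if (!file.exists(paths$clones))
      stop("stage input missing: ", paths$clones,
           " (run simulate or provide clone FASTA)")
    clones <- read_clone_fasta(paths$clones)
  }

  if ("stats" %in% stages) {
    events <- read_mutation_table(paths$events)
    lens <- segment_lengths(clones[[1]])
    counts <- vapply(names(lens), function(s)
      sum(events$segment == s), 0)
    dens <- segment_density(counts, lens)
    utils::write.table(dens, paths$density, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    st <- substitution_table(events, design_regimes(design))
    kk <- kaks_by_regime(st)
    utils::write.table(kk, paths$kaks, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    tests <- if (sum(counts) > 0) {
      cu <- chisq_uniform_test(counts, lens)
      data.frame(test = "chisq_uniform", statistic = cu$statistic,
                 df = cu$df, p.value = cu$p.value)
    } else data.frame(test = character(0), statistic = numeric(0),
                      df = numeric(0), p.value = numeric(0))
    utils::write.table(tests, paths$tests, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    hp <- detect_homoplasy(design, events)
    utils::write.table(hp$reversions, paths$homoplasy, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$stats <- list(density = dens, kaks = kk, homoplasy = hp)
    written <- c(written, paths$density, paths$kaks, paths$tests,
                 paths$homoplasy)
  }

  if ("infer" %in% stages) {
    true_tree <- read_newick(paths$tree)
    tips <- true_tree$tip.label
    aln <- build_alignment(clones[tips])
    inferred <- if (infer_method == "mp") {
      res <- branch_and_bound_mp(aln)
      out$mp <- res
      res$trees[[1]]
    } else {
      neighbor_joining(alignment_distances(aln))
    }
    write_newick(inferred, paths$inferred)
    out$inferred <- inferred
    written <- c(written, paths$inferred)
  }

  if ("evaluate" %in% stages) {
    true_tree <- read_newick(paths$tree)
    inferred <- read_newick(paths$inferred)
    ce <- clade_errors(true_tree, inferred)
    acc <- data.frame(metric = c("rf", "false_positives", "false_negatives"),
                      value = c(ce$rf, length(ce$false_positives),
                                length(ce$false_negatives)))
    utils::write.table(acc, paths$accuracy, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$accuracy <- ce
    written <- c(written, paths$accuracy)
  }

  writeLines(log_lines, paths$log)
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  manifest_path <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  out$manifest <- manifest_path
  invisible(out)
}
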