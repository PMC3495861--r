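# The experiment design: a rooted bifurcating deme tree.  Each row describes
# one branch by its child clone label, its parent clone, the host regime
# (PP / ERA / ALT = daily alternation starting on PP), the bottleneck
# schedule, the branch duration in days, and generations per day.

ALLOWED_BOTTLENECKS <- c(1, 10, 100, 1000, 10000)

#' Read an experiment-design file
#'
#' Design files are tab-separated with header columns \code{branch},
#' \code{parent}, \code{host}, \code{schedule}, \code{days},
#' \code{gens_per_day}; lines starting with \code{#} are comments.  The
#' \code{schedule} field is a comma-separated list of bottleneck sizes (from
#' 1, 10, 100, 1000, 10000), each held for an equal share of the branch days.
#'
#' @param path Path to the design file.
#' @return An \code{experiment_design} data frame.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_design(d)
}

#' Validate an experiment design
#'
#' Checks that the branch table forms a rooted tree with strictly binary
#' bifurcations (the root clone may have a single descendant lineage, as in a
#' founding passage), that hosts and bottleneck sizes are from the allowed
#' sets, and that every schedule divides its branch days evenly.
#'
#' @param d Data frame of branches.
#' @return The design with class \code{experiment_design}.
#' @export
validate_design <- function(d) {
  need <- c("branch", "parent", "host", "schedule", "days", "gens_per_day")
  if (!all(need %in% names(d)))
    stop("design must have columns: ", paste(need, collapse = ", "))
  d$days <- as.integer(d$days)
  d$gens_per_day <- as.integer(d$gens_per_day)
  if (anyDuplicated(d$branch)) stop("duplicated branch labels")
  roots <- setdiff(d$parent, d$branch)
  if (length(unique(roots)) != 1L)
    stop("design must have exactly one root ancestor; found: ",
         paste(unique(roots), collapse = ", "))
  kids <- table(d$parent)
  internal <- intersect(d$parent, d$branch)
  if (any(kids[internal] != 2L))
    stop("internal nodes must bifurcate into exactly two branches: ",
         paste(names(kids[internal])[kids[internal] != 2L], collapse = ", "))
  if (kids[[unique(roots)]] > 2L) stop("root has more than two descendants")
  if (!all(d$host %in% c("PP", "ERA", "ALT")))
    stop("host must be PP, ERA or ALT")
  if (any(d$days < 1L) || any(d$gens_per_day < 1L))
    stop("days and gens_per_day must be positive")
  for (i in seq_len(nrow(d))) {
    ns <- schedule_sizes(d$schedule[i], d$days[i])
    if (!all(ns %in% ALLOWED_BOTTLENECKS))
      stop("branch ", d$branch[i], ": bottleneck sizes must be from {",
           paste(ALLOWED_BOTTLENECKS, collapse = ", "), "}")
  }
  class(d) <- c("experiment_design", "data.frame")
  d
}

# Expand a schedule string into the per-day bottleneck size vector.
schedule_sizes <- function(schedule, days) {
  ns <- as.numeric(strsplit(as.character(schedule), ",")[[1]])
  if (anyNA(ns)) stop("malformed schedule '", schedule, "'")
  if (days %% length(ns) != 0L)
    stop("schedule length ", length(ns), " does not divide ", days, " days")
  rep(ns, each = days %/% length(ns))
}

# Per-day host vector for a branch (ALT alternates daily, starting on PP).
day_hosts <- function(host, days) {
  if (host == "ALT") rep(c("PP", "ERA"), length.out = days) else rep(host, days)
}

#' The default 16-tip experiment design
#'
#' Reads the design shipped with the package
#' (\code{extdata/figure1_default.design}): five bifurcation levels with
#' durations 50, 50, 50, 100, 100 generations, a PP-propagated founding
#' lineage splitting into an ERA-shifted clade and a PP clade, single-plaque
#' (N = 1) bottleneck lineages on PP, ERA and alternating hosts, and
#' increasing- and decreasing-bottleneck treatments over
#' N in \{10, 100, 1000, 10000\}.  Regime generation totals are 500 (PP large),
#' 450 (ERA large), 200 each for the three N = 1 treatments, and 600 each for
#' the increasing and decreasing treatments; 2750 generations in total with
#' 350 from root to tip.
#'
#' @return An \code{experiment_design}.
#' @export
default_design <- function() {
  path <- system.file("extdata", "figure1_default.design",
                      package = "phi6kp", mustWork = TRUE)
  read_design(path)
}

#' Treatment-regime label of each design branch
#'
#' Branches are labelled \code{<host>_large} (constant bottleneck > 1),
#' \code{<host>_N1} (daily single-plaque transfer), or \code{increasing} /
#' \code{decreasing} for the ramped-bottleneck treatments.
#'
#' @param design An \code{experiment_design}.
#' @return Named character vector of regime labels, one per branch.
#' @export
design_regimes <- function(design) {
  lab <- vapply(seq_len(nrow(design)), function(i) {
    ns <- schedule_sizes(design$schedule[i], design$days[i])
    if (all(ns == 1)) paste0(design$host[i], "_N1")
    else if (length(unique(ns)) == 1L) paste0(design$host[i], "_large")
    else if (all(diff(ns) >= 0)) "increasing"
    else if (all(diff(ns) <= 0)) "decreasing"
    else "fluctuating"
  }, character(1))
  stats::setNames(lab, design$branch)
}

#' Generation totals of a design
#'
#' @param design An \code{experiment_design}.
#' @return List with \code{total} (generations summed over all branches) and
#'   \code{root_to_tip} (maximum root-to-tip path length in generations).
#' @export
design_generations <- function(design) {
  gens <- design$days * design$gens_per_day
  names(gens) <- design$branch
  depth <- function(b) {
    p <- design$parent[design$branch == b]
    g <- gens[[b]]
    if (p %in% design$branch) g + depth(p) else g
  }
  tips <- setdiff(design$branch, design$parent)
  list(total = sum(gens), root_to_tip = max(vapply(tips, depth, numeric(1))))
}

#' Convert a design to an ape phylogeny
#'
#' Builds the true rooted tree of the design, with internal node labels.  The
#' founding ancestor appears as a unary root node above the first bifurcation.
#'
#' @param design An \code{experiment_design}.
#' @return An object of class \code{phylo}.
#' @export
design_tree <- function(design) {
  root <- setdiff(design$parent, design$branch)
  nwk <- function(node) {
    ch <- design$branch[design$parent == node]
    if (!length(ch)) return(node)
    paste0("(", paste(vapply(ch, nwk, character(1)), collapse = ","), ")", node)
  }
  ape::read.tree(text = paste0(nwk(root), ";"))
}

# Parent lookup (child label -> parent label) including the root's parent NA.
design_parent_map <- function(design) {
  stats::setNames(design$parent, design$branch)
}
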