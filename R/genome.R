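#' Segment lengths of the phi6 genome
#'
#' Lengths in base pairs of the Large, Medium and Small genome segments.
#'
#' @return Named integer vector \code{c(L = 6374, M = 4063, S = 2948)}.
#' @export
default_segment_lengths <- function() {
  c(L = 6374L, M = 4063L, S = 2948L)
}

#' Construct a segmented genome
#'
#' A segmented genome is a named list of nucleotide strings, one per genome
#' segment (by default L, M and S).  The alphabet is strictly A/C/G/T and
#' segment lengths are immutable: substitutions never change the length of a
#' segment (no indels are modelled).
#'
#' @param segments Named character vector or list of sequences (one string per
#'   segment).  Names are the segment ids.
#' @return Object of class \code{segmented_genome}.
#' @export
segmented_genome <- function(segments) {
  segments <- lapply(segments, function(s) toupper(as.character(s)))
  if (is.null(names(segments)) || any(names(segments) == ""))
    stop("all segments must be named")
  for (id in names(segments)) {
    bad <- setdiff(unique(strsplit(segments[[id]], "")[[1]]), DNA_BASES)
    if (length(bad))
      stop("segment ", id, " contains characters outside A/C/G/T: ",
           paste(bad, collapse = ", "))
  }
  structure(segments, class = "segmented_genome")
}

#' @export
print.segmented_genome <- function(x, ...) {
  cat("segmented genome:",
      paste(sprintf("%s (%d bp)", names(x), segment_lengths(x)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Segment lengths of a genome
#' @param genome A \code{segmented_genome}.
#' @return Named integer vector of per-segment lengths.
#' @export
segment_lengths <- function(genome) {
  vapply(genome, nchar, integer(1))
}

#' Generate a random segmented genome
#'
#' Draws uniform random A/C/G/T sequences of the given segment lengths.  Used
#' to build synthetic ancestors; the caller's RNG state is untouched.
#'
#' @param seed Integer seed (the draw is deterministic given the seed).
#' @param lengths Named vector of segment lengths.
#' @return A \code{segmented_genome}.
#' @export
random_genome <- function(seed, lengths = default_segment_lengths()) {
  with_seed(seed, {
    segs <- lapply(lengths, function(n)
      paste(sample(DNA_BASES, n, replace = TRUE), collapse = ""))
    names(segs) <- names(lengths)
    segmented_genome(segs)
  })
}

#' The default synthetic phi6-like ancestor genome
#'
#' A fixed random genome with the canonical phi6 segment lengths, adjusted so
#' that three codons referenced throughout the package have their canonical
#' reference states: codon 144 of gene P3 (M) is AAA (Lys, so an A-to-G change
#' at its second position yields K144R), codon 176 of gene P12 (S) is TTT
#' (Phe, so a T-to-C change at its first position yields F176L - the
#' antagonistic-pleiotropy locus), and codon 8 of gene P9 (S) is CAA (Gln).
#' The sequence is synthetic: it shares segment lengths and gene-to-segment
#' assignments with phi6, not its actual sequence.
#'
#' @return A \code{segmented_genome}.
#' @export
default_genome <- function() {
  g <- random_genome(653121L)
  ann <- default_annotation()
  set_codon <- function(g, gene, codon, value) {
    r <- ann[ann$gene == gene, ]
    pos <- r$start + r$frame + (codon - 1L) * 3L
    substr(g[[r$segment]], pos, pos + 2L) <- value
    g
  }
  g <- unclass(g)
  g <- set_codon(g, "P3", 144L, "AAA")
  g <- set_codon(g, "P12", 176L, "TTT")
  g <- set_codon(g, "P9", 8L, "CAA")
  segmented_genome(g)
}

#' Apply substitutions to a genome
#'
#' Applies a table of substitutions, checking that each reference base matches
#' the current base at its position.  The input genome is not modified.
#'
#' @param genome A \code{segmented_genome}.
#' @param mutations Data frame with columns \code{segment}, \code{position},
#'   \code{ref}, \code{alt} (additional columns are ignored).
#' @return A new \code{segmented_genome} differing from the input at exactly
#'   the mutated positions.
#' @export
apply_mutations <- function(genome, mutations) {
  stopifnot(inherits(genome, "segmented_genome"))
  out <- unclass(genome)
  if (is.null(mutations) || nrow(mutations) == 0L)
    return(segmented_genome(out))
  lens <- segment_lengths(genome)
  for (i in seq_len(nrow(mutations))) {
    seg <- as.character(mutations$segment[i])
    pos <- as.integer(mutations$position[i])
    if (!seg %in% names(out))
      stop("unknown segment '", seg, "'")
    if (pos < 1L || pos > lens[[seg]])
      stop("position ", pos, " outside segment ", seg)
    cur <- substr(out[[seg]], pos, pos)
    if (cur != mutations$ref[i])
      stop("reference mismatch at ", seg, ":", pos, " (genome has ", cur,
           ", mutation expects ", mutations$ref[i], ")")
    if (mutations$ref[i] == mutations$alt[i])
      stop("ref equals alt at ", seg, ":", pos)
    substr(out[[seg]], pos, pos) <- as.character(mutations$alt[i])
  }
  segmented_genome(out)
}

#' Call substitutions between two genomes
#'
#' Compares two genomes position by position and returns one classified
#' substitution per differing site, sorted by (segment, position).  Both
#' genomes must have identical segment sets and lengths.  Classification and
#' labelling are relative to genome \code{a} (the predecessor).
#'
#' @param a,b \code{segmented_genome} objects (\code{a} is the reference /
#'   predecessor).
#' @param annotation A gene annotation (see \code{\link{read_annotation}}), or
#'   \code{NULL} for no annotation (all changes noncoding).
#' @return Data frame with columns \code{segment}, \code{position},
#'   \code{ref}, \code{alt}, \code{class}, \code{gene}, \code{label}.
#' @export
diff_genomes <- function(a, b, annotation = default_annotation()) {
  stopifnot(inherits(a, "segmented_genome"), inherits(b, "segmented_genome"))
  if (!identical(sort(names(a)), sort(names(b))))
    stop("segment sets differ")
  if (!identical(segment_lengths(a)[names(a)], segment_lengths(b)[names(a)]))
    stop("segment lengths differ")
  rows <- lapply(names(a), function(seg) {
    ra <- charToRaw(a[[seg]]); rb <- charToRaw(b[[seg]])
    idx <- which(ra != rb)
    if (!length(idx)) return(NULL)
    data.frame(segment = seg, position = idx,
               ref = strsplit(rawToChar(ra[idx]), "")[[1]],
               alt = strsplit(rawToChar(rb[idx]), "")[[1]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(empty_mutation_table())
  out <- out[order(out$segment, out$position), , drop = FALSE]
  rownames(out) <- NULL
  cls <- classify_mutations(a, annotation, out)
  cbind(out, cls)
}

empty_mutation_table <- function() {
  data.frame(segment = character(0), position = integer(0),
             ref = character(0), alt = character(0), class = character(0),
             gene = character(0), label = character(0),
             stringsAsFactors = FALSE)
}
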