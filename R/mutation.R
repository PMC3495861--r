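# Substitution classification through the standard genetic code.
#
# A substitution is nonsynonymous iff it changes the encoded amino acid in at
# least one overlapping CDS; the reported gene/label come from the first
# affected gene in annotation order (first overlapping gene for synonymous
# changes).  Coding labels follow the <refAA><codonIndex><altAA> convention
# (e.g. "K144R", or "Q8Q" for a synonymous change); noncoding changes are
# labelled "n.c. <position> <segment>".

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Classify a single substitution
#'
#' Translates the affected codon(s) of every CDS overlapping the site under
#' the standard genetic code, in the pre-mutation reference genome.
#'
#' @param genome The pre-mutation reference \code{segmented_genome}.
#' @param annotation A \code{gene_annotation} (or \code{NULL}).
#' @param segment Segment id.
#' @param position 1-based position within the segment.
#' @param alt Alternative base (A/C/G/T).
#' @param ref Optional expected reference base; checked against the genome
#'   when supplied.
#' @return List with elements \code{class} (one of \code{"synonymous"},
#'   \code{"nonsynonymous"}, \code{"noncoding"}), \code{gene} (name or
#'   \code{""}) and \code{label}.
#' @export
classify_mutation <- function(genome, annotation, segment, position, alt,
                              ref = NULL) {
  lens <- segment_lengths(genome)
  if (!segment %in% names(lens))
    stop("unknown segment '", segment, "'")
  position <- as.integer(position)
  if (position < 1L || position > lens[[segment]])
    stop("position ", position, " outside segment ", segment)
  cur <- substr(genome[[segment]], position, position)
  if (!is.null(ref) && !is.na(ref) && cur != ref)
    stop("reference mismatch at ", segment, ":", position)
  if (!alt %in% DNA_BASES) stop("alt base must be one of A/C/G/T")
  if (alt == cur) stop("alt equals the reference base")

  hits <- NULL
  if (!is.null(annotation) && nrow(annotation) > 0L) {
    cand <- annotation[annotation$segment == segment &
                         annotation$start + annotation$frame <= position &
                         annotation$end >= position, , drop = FALSE]
    if (nrow(cand)) {
      seq <- genome[[segment]]
      hits <- lapply(seq_len(nrow(cand)), function(i) {
        cds_start <- cand$start[i] + cand$frame[i]
        off <- position - cds_start            # 0-based offset into CDS
        codon_i <- off %/% 3L + 1L
        c0 <- cds_start + (codon_i - 1L) * 3L
        codon <- substr(seq, c0, c0 + 2L)
        codon_pos <- off %% 3L + 1L
        alt_codon <- codon
        substr(alt_codon, codon_pos, codon_pos) <- alt
        list(gene = cand$gene[i], codon_index = codon_i,
             aa_ref = translate_codon(codon), aa_alt = translate_codon(alt_codon))
      })
    }
  }
  if (is.null(hits) || !length(hits)) {
    return(list(class = "noncoding", gene = "",
                label = sprintf("n.c. %d %s", position, segment)))
  }
  changed <- vapply(hits, function(h) !identical(h$aa_ref, h$aa_alt), logical(1))
  use <- if (any(changed)) hits[[which(changed)[1]]] else hits[[1]]
  list(class = if (any(changed)) "nonsynonymous" else "synonymous",
       gene = use$gene,
       label = sprintf("%s%d%s", use$aa_ref, use$codon_index, use$aa_alt))
}

# Vectorised classification of a ref/alt table against one reference genome.
classify_mutations <- function(genome, annotation, muts) {
  if (nrow(muts) == 0L)
    return(data.frame(class = character(0), gene = character(0),
                      label = character(0), stringsAsFactors = FALSE))
  res <- lapply(seq_len(nrow(muts)), function(i)
    classify_mutation(genome, annotation, muts$segment[i], muts$position[i],
                      muts$alt[i], muts$ref[i]))
  data.frame(class = vapply(res, `[[`, "", "class"),
             gene = vapply(res, `[[`, "", "gene"),
             label = vapply(res, `[[`, "", "label"),
             stringsAsFactors = FALSE)
}

# --- global site indexing --------------------------------------------------
# Sites are numbered 1..sum(lengths) across segments in L,M,S order (the same
# order used for alignment concatenation).

site_offsets <- function(lengths) {
  cumsum(c(0L, unname(lengths)))[seq_along(lengths)]
}

# integer sites -> data.frame(segment, position)
site_to_segment <- function(sites, lengths = default_segment_lengths()) {
  off <- site_offsets(lengths)
  idx <- findInterval(sites, off + 1L)
  data.frame(segment = names(lengths)[idx],
             position = as.integer(sites - off[idx]),
             stringsAsFactors = FALSE)
}

segment_to_site <- function(segment, position, lengths = default_segment_lengths()) {
  off <- site_offsets(lengths)
  names(off) <- names(lengths)
  as.integer(off[segment] + position)
}
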