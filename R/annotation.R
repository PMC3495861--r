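#' Read a gene annotation table
#'
#' Annotations are tab-separated files with header columns \code{gene},
#' \code{segment}, \code{start}, \code{end}, \code{frame}: one CDS per row,
#' with 1-based inclusive coordinates on its segment and a reading-frame
#' offset (0-2) relative to \code{start}.  The coding span
#' (\code{end - start + 1 - frame}) must be a multiple of 3.  Genes may
#' overlap; each gene lies on exactly one segment.
#'
#' @param path Path to the TSV file.
#' @param segment_lengths Named vector of segment lengths used for bounds
#'   checking.
#' @return Data frame of class \code{gene_annotation}, ordered by
#'   (segment, start).
#' @export
read_annotation <- function(path, segment_lengths = default_segment_lengths()) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_annotation(ann, segment_lengths)
}

#' Validate and normalise a gene annotation
#'
#' @param ann Data frame with columns gene, segment, start, end, frame.
#' @param segment_lengths Named vector of segment lengths.
#' @return The validated annotation, ordered by (segment, start), with class
#'   \code{gene_annotation}.
#' @export
validate_annotation <- function(ann, segment_lengths = default_segment_lengths()) {
  need <- c("gene", "segment", "start", "end", "frame")
  if (!all(need %in% names(ann)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  if (nrow(ann) == 0L) {
    ann <- ann[, need, drop = FALSE]
    class(ann) <- c("gene_annotation", "data.frame")
    return(ann)
  }
  ann$start <- as.integer(ann$start)
  ann$end <- as.integer(ann$end)
  ann$frame <- as.integer(ann$frame)
  for (i in seq_len(nrow(ann))) {
    where <- paste0("annotation row ", i, " (gene ", ann$gene[i], ")")
    if (is.na(ann$start[i]) || is.na(ann$end[i]) || is.na(ann$frame[i]))
      stop(where, ": malformed numeric field")
    if (!ann$segment[i] %in% names(segment_lengths))
      stop(where, ": unknown segment '", ann$segment[i], "'")
    len <- segment_lengths[[ann$segment[i]]]
    if (ann$start[i] < 1L || ann$end[i] > len || ann$start[i] > ann$end[i])
      stop(where, ": CDS out of bounds for segment ", ann$segment[i])
    if (ann$frame[i] < 0L || ann$frame[i] > 2L)
      stop(where, ": frame must be 0, 1 or 2")
    if ((ann$end[i] - ann$start[i] + 1L - ann$frame[i]) %% 3L != 0L)
      stop(where, ": coding span not divisible by 3")
  }
  if (anyDuplicated(ann$gene))
    stop("duplicated gene name in annotation")
  ann <- ann[order(ann$segment, ann$start), need, drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' The default synthetic phi6 gene annotation
#'
#' Reads the annotation shipped with the package
#' (\code{extdata/phi6_synthetic_annotation.tsv}).  Gene-to-segment
#' assignments follow phi6 biology - the polymerase-complex genes (P1, P2,
#' P4, P7) on L, the host-attachment gene P3 (with P6, P10, P13) on M, and
#' P8, P12, P9, P5 on S - but the CDS coordinates are synthetic placeholders:
#' the true phi6 coordinates are not bundled, and any real-sequence analysis
#' should supply its own annotation via \code{\link{read_annotation}}.
#'
#' @return A \code{gene_annotation}.
#' @export
default_annotation <- function() {
  if (!is.null(.phi6kp_cache$default_annotation))
    return(.phi6kp_cache$default_annotation)
  path <- system.file("extdata", "phi6_synthetic_annotation.tsv",
                      package = "phi6kp", mustWork = TRUE)
  ann <- read_annotation(path)
  .phi6kp_cache$default_annotation <- ann
  ann
}

.phi6kp_cache <- new.env(parent = emptyenv())
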