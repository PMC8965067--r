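#' Fragment records
#'
#' A fragment is the unit of prediction: a fixed-length amino-acid string with
#' a label (`"dimer"`, `"non-dimer"`, or `"unknown"`) and an optional known
#' motif interval in 0-based half-open coordinates. Collections of fragments
#' are plain data frames with columns `id`, `sequence`, `label`,
#' `motif_start`, `motif_end` (the interval columns are `NA` when no motif is
#' annotated).
#'
#' @param id Fragment identifier.
#' @param sequence Amino-acid string over the 20 standard one-letter codes.
#' @param label One of `"dimer"`, `"non-dimer"`, `"unknown"`.
#' @param motif_start,motif_end Optional motif interval, 0-based half-open.
#' @return A one-row fragment data frame.
#' @examples
#' fragment("f1", strrep("L", 40), "non-dimer")
#' @export
fragment <- function(id, sequence, label = "unknown",
                     motif_start = NA_integer_, motif_end = NA_integer_) {
  sequence <- toupper(as.character(sequence))
  validate_sequence(sequence, id)
  label <- match.arg(label, c("dimer", "non-dimer", "unknown"))
  if (!is.na(motif_start) || !is.na(motif_end)) {
    if (is.na(motif_start) || is.na(motif_end))
      stop("motif interval needs both start and end (fragment '", id, "')")
    L <- nchar(sequence)
    if (motif_start < 0 || motif_end <= motif_start || motif_end > L)
      stop("invalid motif interval [", motif_start, ", ", motif_end,
           ") for fragment '", id, "' of length ", L)
  }
  data.frame(id = as.character(id), sequence = sequence, label = label,
             motif_start = as.integer(motif_start),
             motif_end = as.integer(motif_end),
             stringsAsFactors = FALSE)
}

validate_sequence <- function(sequence, id = "<sequence>") {
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) < 1L)
    stop("fragment '", id, "': sequence must be a non-empty string")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0L)
    stop("fragment '", id, "': non-standard residue letter '", chars[bad[1]],
         "' at position ", bad[1] - 1L, " (0-based)")
  invisible(sequence)
}

#' Known motif center of a fragment
#'
#' The motif center is the midpoint `(start + end) / 2` of the annotated
#' interval, possibly half-integral; it anchors the window position scores.
#'
#' @param frag A one-row fragment data frame.
#' @return Numeric center, or `NA` when the fragment has no annotated motif.
#' @export
motif_center <- function(frag) {
  stopifnot(nrow(frag) == 1L)
  if (is.na(frag$motif_start) || is.na(frag$motif_end)) return(NA_real_)
  (frag$motif_start + frag$motif_end) / 2
}

as_fragment_frame <- function(x) {
  needed <- c("id", "sequence", "label", "motif_start", "motif_end")
  if (!is.data.frame(x) || !all(needed %in% names(x)))
    stop("expected a fragment data frame with columns: ",
         paste(needed, collapse = ", "))
  x
}
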