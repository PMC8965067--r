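#' Read fragments from FASTA plus an optional annotation table
#'
#' Sequences come from a FASTA file; labels and motif intervals from a
#' tab-separated annotation table with columns
#' `fragment_id  label  motif_start  motif_end` (0-based half-open; empty
#' start/end for fragments without a known motif). Fragments absent from the
#' annotation table get label `"unknown"`.
#'
#' @param fasta_path Path to a FASTA file of amino-acid fragments.
#' @param annotation_path Optional path to the annotation TSV.
#' @return A fragment data frame (see [fragment()]).
#' @examples
#' fa <- system.file("extdata", "example_fragments.fa", package = "gltm")
#' ann <- system.file("extdata", "example_annotations.tsv", package = "gltm")
#' read_fragments(fa, ann)
#' @export
read_fragments <- function(fasta_path, annotation_path = NULL) {
  seqs <- tryCatch(Biostrings::readAAStringSet(fasta_path),
                   error = function(e) stop("malformed FASTA '", fasta_path,
                                            "': ", conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids in '", fasta_path, "': ",
         ids[duplicated(ids)][1])
  frames <- lapply(seq_along(seqs), function(i) {
    fragment(ids[i], as.character(seqs[[i]]))
  })
  frags <- do.call(rbind, frames)
  if (!is.null(annotation_path)) {
    ann <- read.delim(annotation_path, stringsAsFactors = FALSE,
                      colClasses = c(fragment_id = "character"))
    needed <- c("fragment_id", "label", "motif_start", "motif_end")
    if (!all(needed %in% names(ann)))
      stop("annotation table must have columns: ",
           paste(needed, collapse = ", "))
    missing <- setdiff(ann$fragment_id, frags$id)
    if (length(missing) > 0L)
      stop("annotation id(s) not found in FASTA: ",
           paste(utils::head(missing, 3), collapse = ", "))
    m <- match(frags$id, ann$fragment_id)
    hit <- !is.na(m)
    frags$label[hit] <- ann$label[m[hit]]
    frags$motif_start[hit] <- suppressWarnings(
      as.integer(ann$motif_start[m[hit]]))
    frags$motif_end[hit] <- suppressWarnings(
      as.integer(ann$motif_end[m[hit]]))
    bad <- !frags$label %in% c("dimer", "non-dimer", "unknown")
    if (any(bad))
      stop("unrecognized label '", frags$label[bad][1], "' for fragment '",
           frags$id[bad][1], "'")
    has <- !is.na(frags$motif_start)
    L <- nchar(frags$sequence)
    if (any(has & (is.na(frags$motif_end) | frags$motif_start < 0 |
                     frags$motif_end <= frags$motif_start |
                     frags$motif_end > L)))
      stop("invalid motif interval in annotation table")
  }
  frags
}

#' Write fragments to FASTA plus an annotation table
#'
#' @param frags Fragment data frame.
#' @param fasta_path Output FASTA path.
#' @param annotation_path Optional output TSV path (written for all fragments;
#'   motif columns empty when not annotated).
#' @return Invisibly, `frags`.
#' @export
write_fragments <- function(frags, fasta_path, annotation_path = NULL) {
  frags <- as_fragment_frame(frags)
  set <- Biostrings::AAStringSet(setNames(frags$sequence, frags$id))
  Biostrings::writeXStringSet(set, fasta_path)
  if (!is.null(annotation_path)) {
    ann <- data.frame(fragment_id = frags$id, label = frags$label,
                      motif_start = frags$motif_start,
                      motif_end = frags$motif_end)
    write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
  }
  invisible(frags)
}

#' Extract a fixed-length fragment around a TM interval
#'
#' Cuts a window of exactly `out_length` residues from a full protein
#' sequence, centered on the midpoint of the given transmembrane interval and
#' clamped to the sequence bounds, so the TM segment is contained whenever it
#' fits.
#'
#' @param full_sequence Amino-acid string.
#' @param tm_start,tm_end TM interval, 0-based half-open.
#' @param out_length Fragment length (default 40 residues).
#' @param id Identifier for the resulting fragment.
#' @return A one-row fragment data frame with label `"unknown"`.
#' @export
extract_fragment <- function(full_sequence, tm_start, tm_end,
                             out_length = 40L, id = "fragment") {
  full_sequence <- toupper(as.character(full_sequence))
  validate_sequence(full_sequence, id)
  L <- nchar(full_sequence)
  out_length <- as.integer(out_length)
  if (L < out_length)
    stop("sequence length ", L, " is shorter than requested fragment length ",
         out_length)
  if (tm_start < 0 || tm_end <= tm_start || tm_end > L)
    stop("invalid TM interval [", tm_start, ", ", tm_end, ")")
  mid <- (tm_start + tm_end) / 2
  start <- floor(mid - out_length / 2)
  start <- max(0L, min(as.integer(start), L - out_length))
  fragment(id, substr(full_sequence, start + 1L, start + out_length))
}

#' Write localization results to a tab-separated table
#'
#' One row per residue per fragment:
#' `fragment_id  predicted_label  true_times  residue_index  votes  tier`.
#' Residue indices are 0-based. Round-trips losslessly through
#' [read_localization()].
#'
#' @param results A list of localization results from [locate()].
#' @param path Output path.
#' @return Invisibly, the written data frame.
#' @export
write_localization <- function(results, path) {
  if (inherits(results, "gltm_localization")) results <- list(results)
  rows <- lapply(results, function(r) {
    L <- length(r$residue_votes)
    data.frame(fragment_id = r$fragment_id,
               predicted_label = r$predicted_label,
               true_times = if (is.na(r$true_times)) NA_integer_ else r$true_times,
               residue_index = seq_len(L) - 1L,
               votes = r$residue_votes,
               tier = r$tiers)
  })
  tab <- do.call(rbind, rows)
  ok <- tryCatch({
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("failed to write localization table to '", path, "': ",
         conditionMessage(ok))
  invisible(tab)
}

#' Read a localization table written by [write_localization()]
#'
#' @param path Input path.
#' @return A data frame with one row per residue per fragment.
#' @export
read_localization <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(fragment_id = "character"))
  needed <- c("fragment_id", "predicted_label", "true_times",
              "residue_index", "votes", "tier")
  if (!all(needed %in% names(tab)))
    stop("localization table '", path, "' must have columns: ",
         paste(needed, collapse = ", "))
  tab
}

#' Read or write a model/training configuration file
#'
#' Configuration files are YAML; keys mirror the arguments of
#' [model_config()] and [train_config()].
#'
#' @param path Config file path.
#' @return For `read_config`, a named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config Named list to serialize.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
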