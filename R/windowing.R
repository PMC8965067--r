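#' Random-step window segmentation of a fragment
#'
#' Splits a fragment of length `L` into `n` ordered windows of length `k`
#' with strictly increasing starts: the first window starts at 0, the last
#' ends at `L`, and the `n - 2` interior starts are drawn uniformly without
#' replacement from the interior positions and sorted. Every call draws fresh
#' interior starts, so repeated calls give distinct stochastic "views" of the
#' same fragment; this is the data-enhancement step the model trains on.
#'
#' @param fragment A one-row fragment data frame, or an integer length `L`.
#' @param n Number of windows (>= 2).
#' @param k Window length in residues (>= 1).
#' @return An object of class `gltm_windows` with fields `starts` (0-based),
#'   `k`, `n`, `L`, `centers` (`start + (k - 1) / 2`) and `fragment_id`.
#' @examples
#' set.seed(1)
#' ws <- segment_windows(40L, n = 12, k = 5)
#' ws$starts
#' @export
segment_windows <- function(fragment, n, k) {
  if (is.data.frame(fragment)) {
    frag <- as_fragment_frame(fragment)
    stopifnot(nrow(frag) == 1L)
    L <- nchar(frag$sequence)
    id <- frag$id
  } else {
    L <- as.integer(fragment)
    id <- NA_character_
  }
  n <- as.integer(n); k <- as.integer(k)
  if (n < 2L) stop("window count n must be >= 2 (got ", n, ")")
  if (k < 1L) stop("window length k must be >= 1 (got ", k, ")")
  if (L - k < n - 1L)
    stop("infeasible segmentation: need L - k >= n - 1 for strictly ",
         "increasing starts, but L = ", L, ", k = ", k, ", n = ", n)
  interior <- if (n > 2L) sort(sample.int(L - k - 1L, n - 2L)) else integer(0)
  starts <- c(0L, interior, L - k)
  structure(list(fragment_id = id, starts = starts, k = k, n = n, L = L,
                 centers = starts + (k - 1) / 2),
            class = "gltm_windows")
}

#' @export
print.gltm_windows <- function(x, ...) {
  cat(sprintf("<gltm_windows> %d windows of length %d over %d residues\n",
              x$n, x$k, x$L))
  cat("starts:", paste(x$starts, collapse = " "), "\n")
  invisible(x)
}

#' Encode one window with the overlap-aware one-hot scheme
#'
#' Produces the `(k + 2) x 22` model input for a single window. Rows
#' `0..k-1` are residue rows: channels 0-19 one-hot encode the amino acid,
#' channel 20 flags positions shared with the preceding window, channel 21
#' positions shared with the following window. Row `k` is the prev-overlap
#' state row (channel 20 = |overlap_prev| / k) and row `k + 1` the
#' next-overlap state row (channel 21 = |overlap_next| / k); their other
#' entries are zero. Channel indices here are 0-based; the returned matrix is
#' a plain R matrix.
#'
#' @param window_seq The window's `k`-residue string.
#' @param overlap_prev,overlap_next 0-based local residue indices shared with
#'   the neighbouring windows (empty for no overlap; the first window has no
#'   predecessor and the last no successor by convention).
#' @return A `(k + 2) x 22` numeric matrix.
#' @export
encode_window <- function(window_seq, overlap_prev = integer(0),
                          overlap_next = integer(0)) {
  window_seq <- toupper(as.character(window_seq))
  validate_sequence(window_seq)
  k <- nchar(window_seq)
  overlap_prev <- as.integer(overlap_prev)
  overlap_next <- as.integer(overlap_next)
  if (length(overlap_prev) > 0 &&
      (min(overlap_prev) < 0L || max(overlap_prev) >= k))
    stop("overlap_prev indices must lie in 0..k-1")
  if (length(overlap_next) > 0 &&
      (min(overlap_next) < 0L || max(overlap_next) >= k))
    stop("overlap_next indices must lie in 0..k-1")
  m <- matrix(0, nrow = k + 2L, ncol = 22L)
  aa_idx <- match(strsplit(window_seq, "", fixed = TRUE)[[1]], AA_ALPHABET)
  m[cbind(seq_len(k), aa_idx)] <- 1
  m[overlap_prev + 1L, 21L] <- 1
  m[overlap_next + 1L, 22L] <- 1
  m[k + 1L, 21L] <- length(overlap_prev) / k
  m[k + 2L, 22L] <- length(overlap_next) / k
  m
}

#' Encode all windows of a window set
#'
#' Computes the interval overlaps between consecutive windows and encodes
#' each window with [encode_window()]. Window `i`'s `overlap_prev` holds the
#' positions it shares with window `i - 1`, `overlap_next` those shared with
#' window `i + 1`, both as local (window-relative) indices.
#'
#' @param fragment One-row fragment data frame the window set belongs to.
#' @param ws A `gltm_windows` object from [segment_windows()].
#' @return A list of `n` encoded `(k + 2) x 22` matrices, in window order.
#' @export
encode_windowset <- function(fragment, ws) {
  frag <- as_fragment_frame(fragment)
  stopifnot(nrow(frag) == 1L, inherits(ws, "gltm_windows"))
  if (nchar(frag$sequence) != ws$L)
    stop("window set was built for length ", ws$L, " but fragment '",
         frag$id, "' has length ", nchar(frag$sequence))
  k <- ws$k
  starts <- ws$starts
  ends <- starts + k
  local_overlap <- function(i, j) {
    # positions of window i shared with window j, as local indices of i
    lo <- max(starts[i], starts[j])
    hi <- min(ends[i], ends[j])
    if (hi <= lo) integer(0) else seq.int(lo, hi - 1L) - starts[i]
  }
  lapply(seq_len(ws$n), function(i) {
    wseq <- substr(frag$sequence, starts[i] + 1L, ends[i])
    prev <- if (i > 1L) local_overlap(i, i - 1L) else integer(0)
    nxt <- if (i < ws$n) local_overlap(i, i + 1L) else integer(0)
    encode_window(wseq, prev, nxt)
  })
}

stack_encoded <- function(encoded) {
  do.call(rbind, encoded)
}

#' Window position scores for an annotated motif
#'
#' The supervision target for the position penalty: a softmax over windows of
#' the negative absolute distance (in residues) between each window center
#' and the known motif center `l`,
#' `s_i = exp(c - |cen_i - l|) / sum_j exp(c - |cen_j - l|)`.
#' The constant `c` cancels between numerator and denominator and is exposed
#' only for fidelity to the original GLTM formulation.
#'
#' @param ws A `gltm_windows` object.
#' @param center The motif center `l` in residue coordinates (e.g. from
#'   [motif_center()]); must be non-missing.
#' @param c Arbitrary constant (default 0; provably has no effect).
#' @return Numeric vector of length `n`, positive, summing to 1.
#' @export
position_scores <- function(ws, center, c = 0) {
  stopifnot(inherits(ws, "gltm_windows"))
  if (length(center) != 1L || is.na(center))
    stop("position score undefined for unannotated fragment (no motif center)")
  z <- c - abs(ws$centers - center)
  e <- exp(z - max(z))
  e / sum(e)
}
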