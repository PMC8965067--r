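# Internal fast path for building encoded fragment views. Produces exactly the
# same stacked matrix as segment_windows() + encode_windowset() (asserted by a
# property test) while avoiding per-window data frame and string overhead in
# the training and voting loops.

sequence_codes <- function(sequence) {
  match(strsplit(sequence, "", fixed = TRUE)[[1]], AA_ALPHABET)
}

# codes: integer residue codes; center: motif center or NA; y: 0/1/NA.
# Draws interior window starts from the current RNG stream (same draw as
# segment_windows).
fast_view <- function(codes, n, k, center, y) {
  L <- length(codes)
  interior <- if (n > 2L) sort(sample.int(L - k - 1L, n - 2L)) else integer(0)
  starts <- c(0L, interior, L - k)
  rp <- k + 2L
  base <- (seq_len(n) - 1L) * rp
  X <- matrix(0, n * rp, 22L)
  rows <- rep(base, each = k) + seq_len(k)
  X[cbind(rows, codes[rep(starts, each = k) + seq_len(k)])] <- 1
  ends <- starts + k
  ov <- pmax(0L, ends[-n] - starts[-1L])  # overlap of window i with i+1
  for (i in which(ov > 0L)) {
    o <- ov[i]
    X[base[i] + (k - o + 1L):k, 22L] <- 1      # suffix shared with next
    X[base[i + 1L] + 1L:o, 21L] <- 1           # prefix shared with previous
  }
  X[base + k + 1L, 21L] <- c(0L, ov) / k
  X[base + k + 2L, 22L] <- c(ov, 0L) / k
  S <- if (!is.na(center)) {
    z <- -abs(starts + (k - 1) / 2 - center)
    e <- exp(z - max(z))
    e / sum(e)
  } else NULL
  list(X = X, S = S, y = y, starts = starts)
}

# Precompute the per-fragment pieces the inner loops need.
view_source <- function(frags) {
  list(codes = lapply(frags$sequence, sequence_codes),
       center = ifelse(is.na(frags$motif_start), NA_real_,
                       (frags$motif_start + frags$motif_end) / 2),
       y = ifelse(frags$label == "dimer", 1,
                  ifelse(frags$label == "non-dimer", 0, NA_real_)),
       L = nchar(frags$sequence))
}
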