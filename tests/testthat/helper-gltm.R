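# Shared fixtures: everything is generated in code at test time.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_sequence <- function(L, letters = c("L", "I", "V", "A", "F", "G")) {
  paste(sample(letters, L, replace = TRUE), collapse = "")
}

toy_fragment <- function(id = "f1", L = 40L, label = "unknown",
                         motif_start = NA, motif_end = NA) {
  fragment(id, random_sequence(L), label, motif_start, motif_end)
}

# linearly separable toy set: positives carry a GGGGG block
separable_set <- function(n_pos = 30L, n_neg = 30L, L = 40L) {
  mk <- function(i, pos) {
    bg <- random_sequence(L, c("L", "I", "V", "A", "F"))
    if (pos) {
      at <- sample(0:(L - 5L), 1)
      substr(bg, at + 1, at + 5) <- "GGGGG"
      fragment(paste0("p", i), bg, "dimer", at, at + 5L)
    } else {
      fragment(paste0("n", i), bg, "non-dimer")
    }
  }
  do.call(rbind, c(lapply(seq_len(n_pos), mk, TRUE),
                   lapply(seq_len(n_neg), mk, FALSE)))
}

tiny_config <- function(...) {
  defaults <- list(k = 5L, n = 3L, u = 2L, d_a = 3L, alpha = 0.1, seed = 7L)
  args <- utils::modifyList(defaults, list(...))
  do.call(model_config, args)
}

# independent re-implementation of the window encoder, used as an oracle
oracle_encode_window <- function(window_seq, overlap_prev, overlap_next) {
  chars <- strsplit(window_seq, "", fixed = TRUE)[[1]]
  k <- length(chars)
  m <- matrix(0, k + 2, 22)
  for (j in seq_len(k)) {
    m[j, match(chars[j], AA20)] <- 1
    if ((j - 1) %in% overlap_prev) m[j, 21] <- 1
    if ((j - 1) %in% overlap_next) m[j, 22] <- 1
  }
  m[k + 1, 21] <- length(overlap_prev) / k
  m[k + 2, 22] <- length(overlap_next) / k
  m
}
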