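#' Motif templates
#'
#' A motif template is a short sequence pattern with fixed residues and `x`
#' wildcards, e.g. `"GxxxG"`. Wildcard positions are filled from the
#' background distribution when the motif is planted; fixed positions must be
#' standard amino-acid letters.
#'
#' @param name Template identifier.
#' @param pattern Pattern string: upper-case amino-acid letters for fixed
#'   positions, `"x"` for wildcards.
#' @return An object of class `motif_template` with fields `name`, `pattern`,
#'   `length`.
#' @examples
#' motif_template("gxxxg", "GxxxG")
#' @export
motif_template <- function(name, pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  fixed <- chars != "x"
  if (!any(fixed)) stop("template '", name, "' has no fixed positions")
  if (!all(chars[fixed] %in% AA_ALPHABET))
    stop("template '", name, "' has non-standard fixed residues")
  structure(list(name = as.character(name), pattern = pattern,
                 length = length(chars)),
            class = "motif_template")
}

#' @export
print.motif_template <- function(x, ...) {
  cat("<motif_template>", x$name, ":", x$pattern,
      sprintf("(%d residues)\n", x$length))
  invisible(x)
}

#' Default dimer motif templates
#'
#' Three families of TM dimerization motifs: the glycine-zipper pair
#' (`GxxxG`), a polar-residue pair one helix turn apart (`NxxxN`,
#' asparagine-mediated interhelical hydrogen bonding), and a leucine-zipper
#' heptad with leucine at every seventh position (`LxxxxxxLxxxxxxL`).
#'
#' @return A list of [motif_template()] objects.
#' @export
default_motif_templates <- function() {
  list(motif_template("gxxxg", "GxxxG"),
       motif_template("polar", "NxxxN"),
       motif_template("zipper", "LxxxxxxLxxxxxxL"))
}

#' Default hydrophobic background distribution
#'
#' Per-residue probabilities over the 20 standard amino acids, enriched for
#' the hydrophobic residues typical of TM helices (L, I, V, F, A, G carry
#' about 64% of the mass).
#'
#' @return A named numeric vector of probabilities summing to 1.
#' @export
default_background <- function() {
  c(A = 0.100, C = 0.020, D = 0.015, E = 0.015, F = 0.080,
    G = 0.080, H = 0.010, I = 0.115, K = 0.015, L = 0.150,
    M = 0.045, N = 0.020, P = 0.025, Q = 0.020, R = 0.015,
    S = 0.055, T = 0.045, V = 0.120, W = 0.025, Y = 0.030)
}

#' Simulation configuration
#'
#' Parameters of the synthetic planted-motif benchmark. The defaults emulate
#' the class balance of the reference TM-fragment benchmark: 524 dimer
#' fragments against 1,413 non-dimer fragments, each 40 residues long.
#'
#' @param n_positive Number of dimer fragments (each carries one planted
#'   motif).
#' @param n_negative Number of non-dimer background fragments.
#' @param fragment_length Fragment length in residues.
#' @param motif_templates List of [motif_template()] objects to plant.
#' @param background Named probability vector over the 20 amino acids.
#' @param seed Optional integer seed for reproducible generation.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_positive = 524L, n_negative = 1413L,
                       fragment_length = 40L,
                       motif_templates = default_motif_templates(),
                       background = default_background(),
                       seed = NULL) {
  n_positive <- as.integer(n_positive)
  n_negative <- as.integer(n_negative)
  fragment_length <- as.integer(fragment_length)
  if (n_positive < 0L || n_negative < 0L) stop("counts must be >= 0")
  if (!is.numeric(background) || length(background) != 20L ||
      !setequal(names(background), AA_ALPHABET))
    stop("background must be a named probability vector over the 20 amino acids")
  if (any(background < 0)) stop("background probabilities must be >= 0")
  if (abs(sum(background) - 1) > 1e-6)
    stop("background probabilities must sum to 1 (got ", sum(background), ")")
  if (length(motif_templates) > 0) {
    if (!all(vapply(motif_templates, inherits, logical(1), "motif_template")))
      stop("motif_templates must be motif_template objects")
    maxlen <- max(vapply(motif_templates, `[[`, integer(1), "length"))
    if (fragment_length < maxlen)
      stop("fragment_length (", fragment_length,
           ") must be >= longest template (", maxlen, ")")
  } else if (n_positive > 0L) {
    stop("n_positive > 0 requires at least one motif template")
  }
  structure(list(n_positive = n_positive, n_negative = n_negative,
                 fragment_length = fragment_length,
                 motif_templates = motif_templates,
                 background = background[AA_ALPHABET],
                 seed = seed),
            class = "sim_config")
}

#' Sample a background (non-dimer) fragment
#'
#' Draws residues i.i.d. from the configured background distribution. Uses
#' the current R random stream; seed with [set.seed()] or via
#' `config$seed`-driven callers for reproducibility.
#'
#' @param length Fragment length in residues (>= 1).
#' @param config A [sim_config()].
#' @param id Fragment identifier.
#' @return A one-row fragment data frame with label `"non-dimer"` and no
#'   motif interval.
#' @export
sample_background <- function(length, config = sim_config(), id = "bg") {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("length must be a positive integer")
  seq <- paste(sample(AA_ALPHABET, length, replace = TRUE,
                      prob = config$background), collapse = "")
  fragment(id, seq, label = "non-dimer")
}

#' Plant a motif into a fragment
#'
#' Instantiates the template at the given 0-based position: fixed pattern
#' positions overwrite the fragment, wildcards are redrawn from the background
#' (so the planted occurrence carries no composition signal beyond the fixed
#' residues). The motif interval is recorded and the label set to `"dimer"`.
#'
#' @param frag One-row fragment data frame.
#' @param template A [motif_template()].
#' @param position 0-based start of the motif.
#' @param config A [sim_config()] supplying the background for wildcards.
#' @return The modified one-row fragment data frame.
#' @export
plant_motif <- function(frag, template, position, config = sim_config()) {
  frag <- as_fragment_frame(frag)
  stopifnot(nrow(frag) == 1L, inherits(template, "motif_template"))
  position <- as.integer(position)
  L <- nchar(frag$sequence)
  if (is.na(position) || position < 0L || position + template$length > L)
    stop("motif position ", position, " with length ", template$length,
         " out of bounds for fragment of length ", L)
  chars <- strsplit(frag$sequence, "", fixed = TRUE)[[1]]
  patt <- strsplit(template$pattern, "", fixed = TRUE)[[1]]
  for (j in seq_along(patt)) {
    chars[position + j] <- if (patt[j] == "x") {
      sample(AA_ALPHABET, 1L, prob = config$background)
    } else patt[j]
  }
  out <- frag
  out$sequence <- paste(chars, collapse = "")
  out$label <- "dimer"
  out$motif_start <- position
  out$motif_end <- position + template$length
  out
}

template_regex <- function(template) {
  gsub("x", ".", template$pattern, fixed = TRUE)
}

#' Does a sequence contain a template's exact pattern?
#'
#' Fixed positions must match exactly; wildcards match anything. Used both to
#' reject accidental motifs in negatives and as a brute-force check in tests.
#'
#' @param sequence Amino-acid string.
#' @param template A [motif_template()].
#' @return Logical.
#' @export
matches_template <- function(sequence, template) {
  grepl(template_regex(template), sequence)
}

#' Simulate a planted-motif benchmark dataset
#'
#' Generates `n_positive` dimer fragments, each with exactly one motif
#' (template drawn uniformly, position uniform over admissible starts), and
#' `n_negative` background fragments. Negatives that happen to contain any
#' template's exact pattern are rejected and resampled, so the planted
#' patterns are fully class-separating; near-motifs (e.g. a lone polar
#' residue, GxxxA) are left in place, keeping the task non-trivial. Byte
#' identical across runs under the same `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A fragment data frame with `n_positive + n_negative` rows;
#'   positives first, with recorded motif intervals.
#' @examples
#' d <- simulate_dataset(sim_config(n_positive = 5, n_negative = 10, seed = 1))
#' table(d$label)
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    pos <- vector("list", config$n_positive)
    for (i in seq_len(config$n_positive)) {
      tpl <- config$motif_templates[[
        sample.int(length(config$motif_templates), 1L)]]
      at <- sample.int(config$fragment_length - tpl$length + 1L, 1L) - 1L
      frag <- sample_background(config$fragment_length, config,
                                id = sprintf("pos_%04d", i))
      pos[[i]] <- plant_motif(frag, tpl, at, config)
    }
    neg <- vector("list", config$n_negative)
    for (i in seq_len(config$n_negative)) {
      repeat {
        frag <- sample_background(config$fragment_length, config,
                                  id = sprintf("neg_%04d", i))
        hit <- any(vapply(config$motif_templates, matches_template,
                          logical(1), sequence = frag$sequence))
        if (!hit) break
      }
      neg[[i]] <- frag
    }
    do.call(rbind, c(pos, neg))
  })
}
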