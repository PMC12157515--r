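.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Hydrophobic / polar / fixed residue classification
#'
#' Used by [patterned_scramble()] to preserve the hydrophobic-polar
#' pattern of a sequence. The default hydrophobic set is
#' A, V, L, I, M, F, W, Y; G and P are held fixed in place; every other
#' standard residue is polar. The partition is configurable because no
#' single convention is universal; the set used is recorded in scramble
#' manifests.
#'
#' @param hydrophobic Character vector of one-letter codes.
#' @param fixed Character vector of codes kept fixed in place (default
#'   G and P).
#' @return Object of class `hp_classification` with `hydrophobic`,
#'   `fixed` and `polar` sets.
#' @export
hp_classification <- function(hydrophobic = c("A", "V", "L", "I", "M",
                                              "F", "W", "Y"),
                              fixed = c("G", "P")) {
  if (length(intersect(hydrophobic, fixed)))
    stop("hydrophobic and fixed sets must be disjoint")
  if (!all(c(hydrophobic, fixed) %in% .AA20))
    stop("codes must be standard amino acids")
  structure(list(hydrophobic = hydrophobic, fixed = fixed,
                 polar = setdiff(.AA20, c(hydrophobic, fixed))),
            class = "hp_classification")
}

check_standard <- function(chars) {
  bad <- setdiff(unique(chars), .AA20)
  if (length(bad)) stop("non-standard residue code: ", paste(bad, collapse = ", "))
}

#' Fully scrambled negative-control sequence
#'
#' Returns a seeded uniform permutation of the residues, so the output
#' has the same length and amino-acid composition as the input.
#'
#' @param seq Amino-acid string of standard one-letter codes.
#' @param seed Integer seed.
#' @return Scrambled amino-acid string.
#' @export
full_scramble <- function(seq, seed = 1L) {
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) == 0L) stop("sequence must be non-empty")
  check_standard(chars)
  rng <- local_rng(seed)
  paste(chars[rng$sample_int(length(chars))], collapse = "")
}

#' Patterned scrambled negative-control sequence
#'
#' Shuffles residue identities within the hydrophobic group and within
#' the polar group separately, keeping G and P (the `fixed` set) in
#' place, so the hydrophobic-polar pattern, the fixed positions and the
#' per-class composition are all preserved exactly.
#'
#' @param seq Amino-acid string of standard one-letter codes.
#' @param hp An `hp_classification`.
#' @param seed Integer seed.
#' @return Scrambled amino-acid string.
#' @export
patterned_scramble <- function(seq, hp = hp_classification(), seed = 1L) {
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) == 0L) stop("sequence must be non-empty")
  check_standard(chars)
  rng <- local_rng(seed)
  out <- chars
  for (cls in c("hydrophobic", "polar")) {
    pos <- which(chars %in% hp[[cls]])
    if (length(pos) > 1L) out[pos] <- chars[pos][rng$sample_int(length(pos))]
  }
  paste(out, collapse = "")
}

#' Sample scramble-control source designs per selection quadrant
#'
#' Draws, without replacement and per quadrant, the requested numbers of
#' source designs; each source later yields one full and one patterned
#' scramble control.
#'
#' @param quadrant_of Named character vector: design id -> quadrant
#'   label.
#' @param counts Named integer vector: quadrant label -> number of
#'   sources to sample.
#' @param seed Integer seed.
#' @return Character vector of selected design ids.
#' @export
allocate_control_sources <- function(quadrant_of, counts, seed = 1L) {
  rng <- local_rng(seed)
  out <- character(0)
  for (q in names(counts)) {
    pool <- names(quadrant_of)[quadrant_of == q]
    if (length(pool) < counts[[q]])
      stop("quadrant ", q, " has ", length(pool), " designs, need ",
           counts[[q]])
    if (counts[[q]] > 0L)
      out <- c(out, rng$sample(pool, counts[[q]]))
  }
  out
}
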