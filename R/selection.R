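#' Oligo-pool length arithmetic for orderable designs
#'
#' With an oligo cap of `oligo_max_nt` and identical `primer_nt`
#' nucleotides at each end, `variable_nt = oligo_max_nt - 2 * primer_nt`
#' nucleotides remain, encoding `floor(variable_nt / 3)` variable
#' residues; the reverse-primer region itself encodes the first
#' `fixed_cterm_in_primer` of the `fixed_cterm_residues` fixed
#' C-terminal residues (supplied downstream of the oligo), so designs of
#' up to `variable_aa + fixed_cterm_residues` residues are testable.
#'
#' @param oligo_max_nt Maximum oligo length (default 300 nt).
#' @param primer_nt Primer length at each end (default 21 nt).
#' @param fixed_cterm_residues Fixed C-terminal residues (default 17).
#' @param fixed_cterm_in_primer Fixed residues encoded in the reverse
#'   primer (default 7; must satisfy `3 * fixed_cterm_in_primer =
#'   primer_nt`).
#' @return Object of class `oligo_spec`.
#' @export
oligo_spec <- function(oligo_max_nt = 300L, primer_nt = 21L,
                       fixed_cterm_residues = 17L,
                       fixed_cterm_in_primer = 7L) {
  stopifnot(oligo_max_nt >= 2 * primer_nt,
            fixed_cterm_in_primer * 3L == primer_nt,
            fixed_cterm_in_primer <= fixed_cterm_residues)
  structure(list(oligo_max_nt = as.integer(oligo_max_nt),
                 primer_nt = as.integer(primer_nt),
                 fixed_cterm_residues = as.integer(fixed_cterm_residues),
                 fixed_cterm_in_primer = as.integer(fixed_cterm_in_primer)),
            class = "oligo_spec")
}

#' @rdname oligo_spec
#' @param spec An `oligo_spec`.
#' @return `max_lengths` returns a list with `variable_nt`,
#'   `variable_aa` and `total_aa` (defaults give 258, 86, 103).
#' @export
max_lengths <- function(spec = oligo_spec()) {
  variable_nt <- spec$oligo_max_nt - 2L * spec$primer_nt
  variable_aa <- variable_nt %/% 3L
  list(variable_nt = variable_nt, variable_aa = variable_aa,
       total_aa = variable_aa + spec$fixed_cterm_residues)
}

#' Orderability filter for a design sequence
#'
#' Passes sequences of at most `total_aa` residues (boundary inclusive)
#' containing none of the forbidden residues (cysteine by default, to
#' avoid disulfide artifacts in the display assay).
#'
#' @param seq Amino-acid string.
#' @param spec An `oligo_spec`.
#' @param forbid Character vector of forbidden residues.
#' @return List with `pass` (logical) and `reasons` (character vector of
#'   violated rules, empty when passing).
#' @export
orderability_filter <- function(seq, spec = oligo_spec(), forbid = "C") {
  chars <- strsplit(seq, "")[[1]]
  check_standard(chars)
  lim <- max_lengths(spec)$total_aa
  reasons <- character(0)
  if (length(chars) > lim)
    reasons <- c(reasons, sprintf("length %d exceeds %d residues",
                                  length(chars), lim))
  hit <- intersect(forbid, chars)
  if (length(hit))
    reasons <- c(reasons, paste0("contains forbidden residue: ",
                                 paste(hit, collapse = ", ")))
  list(pass = length(reasons) == 0L, reasons = reasons)
}

.DEFAULT_THRESHOLDS <- list(
  fragment_quality_A = 1.0,          # pass: < 1 A
  holes_shell2 = 0.0,                # pass: < 0
  helix_complementarity = 0.6,       # pass: > 0.6
  buried_unsat_count = 2L,           # pass: < 2
  oversaturated_hbonds = 0L,         # pass: == 0
  hydrophobic_sasa_ratio_shell2 = 0.58,  # pass: < 0.58
  best_plddt_reshaped = 85,          # pass: > 85
  min_lhl_rmsd_A = 1.5)              # pass: < 1.5 A

#' Assign a design to a Rosetta/AF2 pass-fail quadrant
#'
#' The Rosetta flag passes when all six physics metrics are strictly
#' inside their thresholds (fragment quality < 1 Angstrom, holes < 0,
#' helix complementarity > 0.6, buried unsatisfied H-bonds < 2,
#' oversaturated H-bonds = 0, hydrophobic SASA ratio < 0.58); the AF2
#' flag passes when the best reshaped-region pLDDT > 85 and the lowest
#' reshaped-LHL RMSD < 1.5 Angstrom. All comparisons are strict.
#'
#' @param record One-row data frame or named list with the eight metric
#'   fields (as produced by [simulate_metrics()]).
#' @param thresholds Named list overriding the defaults.
#' @return One of `"RP-AP"`, `"RP-AF"`, `"RF-AP"`, `"RF-AF"`.
#' @export
quadrant_assign <- function(record, thresholds = list()) {
  th <- utils::modifyList(.DEFAULT_THRESHOLDS, thresholds)
  get1 <- function(f) {
    v <- record[[f]]
    if (is.null(v) || length(v) != 1L || is.na(v)) stop("missing metric: ", f)
    v
  }
  rosetta_pass <- get1("fragment_quality_A") < th$fragment_quality_A &&
    get1("holes_shell2") < th$holes_shell2 &&
    get1("helix_complementarity") > th$helix_complementarity &&
    get1("buried_unsat_count") < th$buried_unsat_count &&
    get1("oversaturated_hbonds") == th$oversaturated_hbonds &&
    get1("hydrophobic_sasa_ratio_shell2") < th$hydrophobic_sasa_ratio_shell2
  af2_pass <- get1("best_plddt_reshaped") > th$best_plddt_reshaped &&
    get1("min_lhl_rmsd_A") < th$min_lhl_rmsd_A
  paste0(if (rosetta_pass) "RP" else "RF", "-", if (af2_pass) "AP" else "AF")
}

quadrants_of <- function(records, thresholds = list()) {
  vapply(seq_len(nrow(records)),
         function(i) quadrant_assign(records[i, , drop = FALSE], thresholds),
         "")
}

#' Populate selection quadrants with unique backbones
#'
#' Reduces a design table (multiple designs per backbone allowed) to at
#' most one design per backbone, using the Rosetta-Pass-first priority
#' order: (1) backbones with designs in both RP-AP and RP-AF are evenly
#' distributed between those two quadrants (seeded shuffle then
#' alternating assignment, so counts differ by at most one), discarding
#' their other designs; (2) remaining backbones with a design in one
#' Rosetta-Pass quadrant are assigned there; (3) remaining backbones
#' with an RF-AP design populate RF-AP; (4) everything left populates
#' RF-AF. When several designs of a backbone sit in its assigned
#' quadrant, one is drawn seeded.
#'
#' @param records Data frame with `design_id`, `backbone_id` and the
#'   eight metric columns.
#' @param seed Integer seed.
#' @param thresholds Threshold overrides for [quadrant_assign()].
#' @return Data frame with one row per backbone: `backbone_id`,
#'   `design_id`, `quadrant`.
#' @export
populate_quadrants <- function(records, seed = 1L, thresholds = list()) {
  records$quadrant <- quadrants_of(records, thresholds)
  rng <- local_rng(seed)
  remaining <- records
  out <- list()
  take <- function(backbone_ids, quadrant) {
    # pick one design per backbone inside `quadrant`, drop the backbones
    for (b in backbone_ids) {
      cand <- remaining[remaining$backbone_id == b &
                          remaining$quadrant == quadrant, "design_id"]
      pick <- if (length(cand) == 1L) cand else cand[rng$sample_int(length(cand), 1)]
      out[[length(out) + 1L]] <<- data.frame(backbone_id = b, design_id = pick,
                                             quadrant = quadrant,
                                             stringsAsFactors = FALSE)
    }
    remaining <<- remaining[!remaining$backbone_id %in% backbone_ids, ,
                            drop = FALSE]
  }
  has_q <- function(df, q) unique(df$backbone_id[df$quadrant == q])
  both <- intersect(has_q(remaining, "RP-AP"), has_q(remaining, "RP-AF"))
  if (length(both)) {
    both <- both[rng$sample_int(length(both))]
    to_ap <- both[seq_along(both) %% 2 == 1L]
    to_af <- setdiff(both, to_ap)
    take(to_ap, "RP-AP")
    take(to_af, "RP-AF")
  }
  take(has_q(remaining, "RP-AP"), "RP-AP")
  take(has_q(remaining, "RP-AF"), "RP-AF")
  take(has_q(remaining, "RF-AP"), "RF-AP")
  take(has_q(remaining, "RF-AF"), "RF-AF")
  do.call(rbind, out)
}

#' Randomly sample an equal number of designs per quadrant
#'
#' @param assignment Output of [populate_quadrants()].
#' @param per_quadrant Designs per quadrant (default 2500).
#' @param seed Integer seed.
#' @return The sampled subset of `assignment` (4 x per_quadrant rows).
#' @export
sample_quadrants <- function(assignment, per_quadrant = 2500L, seed = 1L) {
  rng <- local_rng(seed)
  out <- list()
  for (q in c("RP-AP", "RP-AF", "RF-AP", "RF-AF")) {
    rows <- which(assignment$quadrant == q)
    if (length(rows) < per_quadrant)
      stop("quadrant ", q, " holds ", length(rows),
           " backbones, need ", per_quadrant)
    out[[q]] <- assignment[rows[rng$sample_int(length(rows), per_quadrant)], ,
                           drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
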