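# Ideal backbone internal-coordinate constants (textbook values).
.BL <- c(N_CA = 1.458, CA_C = 1.525, C_N = 1.329, C_O = 1.231)
.BA <- c(N_CA_C = 111.2, CA_C_N = 116.2, C_N_CA = 121.7, CA_C_O = 120.5)

place_atom <- function(a, b, c, len, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180
  chi <- -torsion_deg * pi / 180  # sign matches the measured a-b-c-d dihedral
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- len * c(-cos(th), sin(th) * cos(chi), sin(th) * sin(chi))
  c + cbind(bc, m, n) %*% d2
}

#' Build an ideal-geometry backbone from phi/psi torsions
#'
#' Constructs a poly-alanine-like backbone chain with ideal bond lengths
#' and angles and the requested torsions (omega fixed at 180). Carbonyl
#' oxygens are placed anti to the following amide nitrogen. The first
#' phi and last psi are conventions only.
#'
#' @param phi,psi Numeric vectors of equal length n (degrees).
#' @param id Structure id.
#' @param aa Amino-acid letters (default all `"A"`).
#' @return A `backbone` of n residues.
#' @export
build_backbone <- function(phi, psi, id = "chain", aa = NULL) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2)
  if (is.null(aa)) aa <- rep("A", n)
  xyz <- array(NA_real_, c(n, 5, 3),
               dimnames = list(NULL, c("N", "CA", "C", "O", "CB"), NULL))
  xyz[1, "N", ] <- c(0, 0, 0)
  xyz[1, "CA", ] <- c(.BL["N_CA"], 0, 0)
  th <- .BA["N_CA_C"] * pi / 180
  xyz[1, "C", ] <- xyz[1, "CA", ] +
    .BL["CA_C"] * c(-cos(th), sin(th), 0)
  for (k in 2:n) {
    xyz[k, "N", ] <- place_atom(xyz[k - 1, "N", ], xyz[k - 1, "CA", ],
                                xyz[k - 1, "C", ], .BL["C_N"],
                                .BA["CA_C_N"], psi[k - 1])
    xyz[k, "CA", ] <- place_atom(xyz[k - 1, "CA", ], xyz[k - 1, "C", ],
                                 xyz[k, "N", ], .BL["N_CA"],
                                 .BA["C_N_CA"], 180)
    xyz[k, "C", ] <- place_atom(xyz[k - 1, "C", ], xyz[k, "N", ],
                                xyz[k, "CA", ], .BL["CA_C"],
                                .BA["N_CA_C"], phi[k])
    # O(k-1) anti to N(k) in the peptide plane
    xyz[k - 1, "O", ] <- place_atom(xyz[k, "N", ], xyz[k - 1, "CA", ],
                                    xyz[k - 1, "C", ], .BL["C_O"],
                                    .BA["CA_C_O"], 180)
  }
  xyz[n, "O", ] <- place_atom(xyz[n, "N", ], xyz[n, "CA", ], xyz[n, "C", ],
                              .BL["C_O"], .BA["CA_C_O"], psi[n] + 180)
  backbone(id, seq_len(n), aa, xyz)
}

#' Ideal alpha helix / extended strand builders
#'
#' `ideal_helix()` uses phi = -57, psi = -47 (about 1.5 Angstrom rise and
#' 100 degrees twist per residue, CA radius about 2.3 Angstrom);
#' `ideal_strand()` uses beta-region torsions phi = -139, psi = 135.
#'
#' @param n Number of residues.
#' @param id Structure id.
#' @return A `backbone`.
#' @export
ideal_helix <- function(n, id = "helix") {
  build_backbone(rep(-57, n), rep(-47, n), id = id)
}

#' @rdname ideal_helix
#' @export
ideal_strand <- function(n, id = "strand") {
  build_backbone(rep(-139, n), rep(135, n), id = id)
}

rotation_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

rotation_between <- function(from, to) {
  f <- from / sqrt(sum(from^2)); t_ <- to / sqrt(sum(to^2))
  v <- c(f[2] * t_[3] - f[3] * t_[2],
         f[3] * t_[1] - f[1] * t_[3],
         f[1] * t_[2] - f[2] * t_[1])
  s <- sqrt(sum(v^2)); cth <- sum(f * t_)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    p <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- c(f[2] * p[3] - f[3] * p[2],
              f[3] * p[1] - f[1] * p[3],
              f[1] * p[2] - f[2] * p[1])
    return(rotation_about(axis, pi))
  }
  rotation_about(v, atan2(s, cth))
}

ca_axis <- function(s, resi = NULL) {
  ca <- bb_coords(s, resi, atoms = "CA")
  cen <- colMeans(ca)
  sv <- svd(sweep(ca, 2, cen))
  ax <- sv$v[, 1]
  if (sum(ax * (ca[nrow(ca), ] - ca[1, ])) < 0) ax <- -ax
  list(centroid = cen, axis = ax)
}

#' Generate an idealized antiparallel beta-sheet scaffold
#'
#' Builds `n_strands` ideal extended strands of `strand_length` residues
#' in the xy plane (strand axis along x, strands 4.8 Angstrom apart in
#' y, alternating N-to-C direction). The scaffold stands in for the
#' fixed sheet against which LHL variants are placed; it carries no
#' connecting loops. Deterministic.
#'
#' @param n_strands Number of strands (>= 2).
#' @param strand_length Residues per strand.
#' @return List with `structure` (a `backbone`) and `annotation` (a
#'   `segment_annotation` whose `sheet_residues` cover all residues).
#' @export
make_scaffold <- function(n_strands, strand_length) {
  stopifnot(n_strands >= 2, strand_length >= 2)
  proto <- ideal_strand(strand_length)
  ax <- ca_axis(proto)
  R0 <- rotation_between(ax$axis, c(1, 0, 0))
  xyz_all <- NULL
  for (j in seq_len(n_strands)) {
    R <- R0
    if (j %% 2 == 0) R <- rotation_about(c(0, 0, 1), pi) %*% R0
    off <- c(0, 4.8 * (j - 1), 0)
    block <- proto$xyz
    for (k in seq_len(strand_length)) for (a in 1:5) {
      p <- block[k, a, ]
      if (all(is.finite(p)))
        block[k, a, ] <- drop(R %*% (p - ax$centroid)) + off
    }
    xyz_all <- if (is.null(xyz_all)) block else abind3(xyz_all, block)
  }
  n <- n_strands * strand_length
  s <- backbone(sprintf("scaffold_%dx%d", n_strands, strand_length),
                seq_len(n), rep("A", n), xyz_all)
  list(structure = s,
       annotation = segment_annotation(s$id, seq_len(n)),
       n_strands = n_strands, strand_length = strand_length)
}

abind3 <- function(a, b) {
  out <- array(NA_real_, c(dim(a)[1] + dim(b)[1], 5, 3),
               dimnames = dimnames(a))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

#' Specification of one LHL variant on a scaffold
#'
#' @param scaffold_id Id of the scaffold the variant is built on.
#' @param lhls List, one element per LHL unit, each a list with
#'   `helix_length` (>= 4), `centroid` (length-3, Angstrom), `axis`
#'   (length-3, normalized internally), `loop_lengths` (length-2
#'   integers >= 1).
#' @param seed Integer seed (reserved; construction is deterministic).
#' @return Object of class `lhl_variant_spec`.
#' @export
lhl_variant_spec <- function(scaffold_id, lhls, seed = 0L) {
  for (u in lhls) {
    stopifnot(u$helix_length >= 4, length(u$centroid) == 3,
              length(u$axis) == 3, all(u$loop_lengths >= 1))
  }
  structure(list(scaffold_id = scaffold_id, lhls = lhls,
                 seed = as.integer(seed)),
            class = "lhl_variant_spec")
}

loop_path <- function(p0, p1, n, bump = 2.5) {
  t <- seq(0, 1, length.out = n + 2)[2:(n + 1)]
  mid <- (p0 + p1) / 2 + c(0, 0, bump)
  # quadratic bezier CA trace; geometric, not physical
  outer(rep(1, n), p0) * (1 - t)^2 + outer(rep(1, n), mid) * 2 * t * (1 - t) +
    outer(rep(1, n), p1) * t^2
}

loop_atoms <- function(ca_path, sign0 = 1) {
  n <- nrow(ca_path)
  xyz <- array(NA_real_, c(n, 5, 3),
               dimnames = list(NULL, c("N", "CA", "C", "O", "CB"), NULL))
  for (k in seq_len(n)) {
    tang <- if (k < n) ca_path[min(k + 1, n), ] - ca_path[k, ]
            else ca_path[k, ] - ca_path[k - 1, ]
    tang <- tang / max(sqrt(sum(tang^2)), 1e-6)
    ref <- if (abs(tang[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    w <- c(tang[2] * ref[3] - tang[3] * ref[2],
           tang[3] * ref[1] - tang[1] * ref[3],
           tang[1] * ref[2] - tang[2] * ref[1])
    w <- w / sqrt(sum(w^2)) * sign0 * (-1)^k  # alternate to avoid helical runs
    ca <- ca_path[k, ]
    xyz[k, "N", ] <- ca - 1.2 * tang + 0.5 * w
    xyz[k, "CA", ] <- ca
    xyz[k, "C", ] <- ca + 1.2 * tang + 0.5 * w
    xyz[k, "O", ] <- xyz[k, "C", ] + 1.23 * w
  }
  xyz
}

linker_hash <- function(xyz) {
  v <- round(as.numeric(xyz[, c("N", "CA", "C", "O"), ]), 2)
  sprintf("%08x", sum(abs(v) * 1000) %% 4294967291)
}

#' Build one LHL variant on a scaffold with known ground truth
#'
#' Places, for each requested LHL unit, an ideal alpha helix at the
#' requested centroid and axis (N-to-C along the axis) and connects it
#' to the flanking strands with geometrically interpolated loops. The
#' chain order is strand 1, LHL 1, strand 2, LHL 2, strand 3, ..., so at
#' most `n_strands - 1` LHL units fit. Errors if any helix backbone atom
#' comes within 3 Angstrom (CA-CA) of the sheet.
#'
#' @param scaffold Result of [make_scaffold()].
#' @param spec An `lhl_variant_spec`.
#' @param id Structure id.
#' @return List with `structure`, `annotation` (sheet residues, helix
#'   ranges, reshaped LHL ranges, per-LHL `linker_ids`), and
#'   `ground_truth`: per LHL the requested centroid and unit axis.
#' @export
make_lhl_variant <- function(scaffold, spec, id = NULL) {
  sc <- scaffold$structure
  n_sheet <- length(sc$resi)
  n_lhl <- length(spec$lhls)
  n_strands <- scaffold$n_strands
  strand_len <- scaffold$strand_length
  if (n_lhl > n_strands - 1) stop("too many LHL units for this scaffold")
  if (is.null(id)) id <- sprintf("%s_var%d", spec$scaffold_id, spec$seed)

  sheet_ca <- bb_coords(sc, atoms = "CA")
  strand_idx <- split(seq_len(n_sheet),
                      rep(seq_len(n_strands), each = strand_len))

  xyz <- NULL; aa <- character(0)
  sheet_res <- integer(0); helices <- list(); lhls <- list(); linkers <- character(0)
  gt <- list()
  pos <- 0L
  append_block <- function(block, n) {
    xyz <<- if (is.null(xyz)) block else abind3(xyz, block)
    aa <<- c(aa, rep("A", n))
    pos <<- pos + n
  }
  for (j in seq_len(n_strands)) {
    idx <- strand_idx[[j]]
    append_block(sc$xyz[idx, , , drop = FALSE], length(idx))
    sheet_res <- c(sheet_res, (pos - length(idx) + 1L):pos)
    if (j <= n_lhl) {
      u <- spec$lhls[[j]]
      axis <- u$axis / sqrt(sum(u$axis^2))
      hel <- ideal_helix(u$helix_length)
      hax <- ca_axis(hel)
      # anchor on the backbone-atom centroid (the helix-vector convention)
      hcen <- colMeans(bb_coords(hel, atoms = c("N", "CA", "C", "O")))
      R <- rotation_between(hax$axis, axis)
      hx <- hel$xyz
      for (k in seq_len(u$helix_length)) for (a in 1:5) {
        p <- hx[k, a, ]
        if (all(is.finite(p)))
          hx[k, a, ] <- drop(R %*% (p - hcen)) + u$centroid
      }
      hel_ca <- hx[, "CA", , drop = TRUE]
      dmin <- min(vapply(seq_len(nrow(hel_ca)), function(k)
        min(sqrt(rowSums(sweep(sheet_ca, 2, hel_ca[k, ])^2))), numeric(1)))
      if (dmin < 3.0)
        stop("helix placement clashes with the sheet (min CA-CA ",
             sprintf("%.2f", dmin), " A)")
      anchor_in <- sc$xyz[idx[length(idx)], "CA", ]
      next_idx <- strand_idx[[j + 1]]
      anchor_out <- sc$xyz[next_idx[1], "CA", ]
      loop1 <- loop_atoms(loop_path(anchor_in, hx[1, "CA", ], u$loop_lengths[1]))
      loop2 <- loop_atoms(loop_path(hx[u$helix_length, "CA", ], anchor_out,
                                    u$loop_lengths[2]), sign0 = -1)
      lhl_start <- pos + 1L
      append_block(loop1, u$loop_lengths[1])
      h_start <- pos + 1L
      append_block(hx, u$helix_length)
      helices[[length(helices) + 1L]] <- c(h_start, pos)
      append_block(loop2, u$loop_lengths[2])
      lhls[[length(lhls) + 1L]] <- c(lhl_start, pos)
      linkers <- c(linkers, paste0("lnk_", u$loop_lengths[1], "x",
                                   u$loop_lengths[2], "_",
                                   linker_hash(loop1), linker_hash(loop2)))
      gt[[length(gt) + 1L]] <- list(centroid = u$centroid, axis = axis)
    }
  }
  s <- backbone(id, seq_len(pos), aa, xyz)
  ann <- segment_annotation(id, sheet_res, helices, lhls, linkers)
  list(structure = s, annotation = ann, ground_truth = gt)
}

#' Generate a prediction ensemble at controlled LHL RMSD
#'
#' Each member is the design with all reshaped-LHL atoms rigidly
#' translated along a seeded random direction so that its [lhl_rmsd()]
#' to the design equals the requested target (verified and rescaled, so
#' the achieved value is within 5 percent); non-reshaped atoms are
#' untouched.
#'
#' @param design A `backbone` design model.
#' @param annotation Its `segment_annotation`.
#' @param target_rmsds Numeric vector of target LHL RMSDs (>= 0).
#' @param plddts pLDDT per member, same length.
#' @param seed Integer seed.
#' @return A `prediction_ensemble`.
#' @export
make_prediction_ensemble <- function(design, annotation, target_rmsds,
                                     plddts, seed = 1L) {
  stopifnot(length(target_rmsds) == length(plddts))
  if (any(target_rmsds < 0)) stop("target RMSD must be non-negative")
  rng <- local_rng(seed)
  lhl <- lhl_residues(annotation)
  members <- lapply(seq_along(target_rmsds), function(i) {
    t0 <- target_rmsds[i]
    m <- design
    m$id <- sprintf("%s_pred%d", design$id, i)
    if (t0 > 0) {
      d <- rng$rnorm(3); d <- d / sqrt(sum(d^2))
      tf <- structure(list(rotation = diag(3), translation = t0 * d),
                      class = "rigid_transform")
      m <- transform_backbone(m, tf, resi = lhl)
      got <- lhl_rmsd(m, design, annotation)
      if (abs(got - t0) / t0 > 0.05) {  # rescale once; linear in shift
        tf2 <- structure(list(rotation = diag(3),
                              translation = (t0 / got - 1) * t0 * d),
                         class = "rigid_transform")
        m <- transform_backbone(m, tf2, resi = lhl)
      }
    }
    m
  })
  prediction_ensemble(design$id, members, plddts)
}

# Seeded RNG stream isolated from the global .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  wrap <- function(f) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    assign(".Random.seed", env$state, globalenv())
    out <- f(...)
    env$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    out
  }
  list(rnorm = wrap(stats::rnorm), runif = wrap(stats::runif),
       sample = wrap(base::sample), rbinom = wrap(stats::rbinom),
       rlnorm = wrap(stats::rlnorm), rgamma = wrap(stats::rgamma),
       rmultinom = wrap(stats::rmultinom), sample_int = wrap(base::sample.int))
}

.METRIC_NAMES <- c("fragment_quality_A", "holes_shell2", "helix_complementarity",
                   "buried_unsat_count", "oversaturated_hbonds",
                   "hydrophobic_sasa_ratio_shell2", "best_plddt_reshaped",
                   "min_lhl_rmsd_A")

#' Simulate a per-design metric table with planted pass rates
#'
#' Draws, independently per metric, a pass/fail flag with the given
#' probability and a value strictly inside or outside the corresponding
#' selection threshold (see [quadrant_assign()]), so realized quadrant
#' rates follow the products of the planted marginals.
#'
#' @param n Number of designs.
#' @param pass_rates Named numeric vector of per-metric pass
#'   probabilities (defaults 0.5); names among the eight metric columns.
#' @param seed Integer seed.
#' @param designs_per_backbone Designs sharing each backbone id
#'   (default 1).
#' @return Data frame: design_id, backbone_id, sequence and the eight
#'   metric columns.
#' @export
simulate_metrics <- function(n, pass_rates = NULL, seed = 1L,
                             designs_per_backbone = 1L) {
  rates <- stats::setNames(rep(0.5, length(.METRIC_NAMES)), .METRIC_NAMES)
  if (!is.null(pass_rates)) {
    bad <- setdiff(names(pass_rates), .METRIC_NAMES)
    if (length(bad)) stop("unknown metric: ", paste(bad, collapse = ", "))
    rates[names(pass_rates)] <- pass_rates
  }
  if (any(rates < 0 | rates > 1)) stop("pass rates must be in [0, 1]")
  rng <- local_rng(seed)
  nb <- ceiling(n / designs_per_backbone)
  backbone_id <- sprintf("bb%05d", rep(seq_len(nb),
                                       each = designs_per_backbone))[seq_len(n)]
  aa_pool <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "C")
  seqs <- vapply(seq_len(n), function(i)
    paste(aa_pool[rng$sample_int(length(aa_pool), 60, replace = TRUE)],
          collapse = ""), "")
  draw <- function(metric, pass) {
    switch(metric,
      fragment_quality_A = ifelse(pass, rng$runif(n, 0.2, 0.95),
                                  rng$runif(n, 1.05, 2.5)),
      holes_shell2 = ifelse(pass, rng$runif(n, -2, -0.05),
                            rng$runif(n, 0.05, 2)),
      helix_complementarity = ifelse(pass, rng$runif(n, 0.65, 0.95),
                                     rng$runif(n, 0.05, 0.55)),
      buried_unsat_count = ifelse(pass, rng$sample(0:1, n, replace = TRUE),
                                  rng$sample(2:5, n, replace = TRUE)),
      oversaturated_hbonds = ifelse(pass, 0L,
                                    rng$sample(1:3, n, replace = TRUE)),
      hydrophobic_sasa_ratio_shell2 = ifelse(pass, rng$runif(n, 0.30, 0.55),
                                             rng$runif(n, 0.60, 0.80)),
      best_plddt_reshaped = ifelse(pass, rng$runif(n, 86, 99),
                                   rng$runif(n, 50, 84)),
      min_lhl_rmsd_A = ifelse(pass, rng$runif(n, 0.2, 1.4),
                              rng$runif(n, 1.6, 6)))
  }
  out <- data.frame(design_id = sprintf("des%05d", seq_len(n)),
                    backbone_id = backbone_id, sequence = seqs,
                    stringsAsFactors = FALSE)
  for (m in .METRIC_NAMES) {
    pass <- rng$runif(n) < rates[m]
    out[[m]] <- draw(m, pass)
  }
  out
}

#' Specification for the protease-selection assay simulator
#'
#' Default protease concentration schedules follow the three-round
#' trypsin/chymotrypsin selection design (micromolar).
#'
#' @param n_designs Number of designs.
#' @param stable_fraction Planted fraction of stable designs.
#' @param stable_meanlog,stable_sdlog Log-normal parameters of stable
#'   design EC50s (micromolar scale).
#' @param unstable_meanlog,unstable_sdlog Same for unstable designs.
#' @param scramble_meanlog,scramble_sdlog Same for scramble controls.
#' @param ci_shape,ci_rate Gamma parameters of the 95 percent
#'   credible-interval widths (mean 1, so most records pass the < 2
#'   filter).
#' @param n_full_scrambles,n_patterned_scrambles Numbers of controls
#'   (default about 9.5 percent of `n_designs` each).
#' @param trypsin_conc,chymotrypsin_conc Cumulative concentration
#'   schedules (micromolar, increasing).
#' @param read_depth Reads per round for the optional read simulation
#'   (0 disables).
#' @param protein_length Residues per simulated design protein.
#' @param seed Integer seed.
#' @return Object of class `assay_sim_spec`.
#' @export
assay_sim_spec <- function(n_designs = 2000, stable_fraction = 0.6,
                           stable_meanlog = log(15), stable_sdlog = 0.4,
                           unstable_meanlog = log(0.3), unstable_sdlog = 0.5,
                           scramble_meanlog = log(0.25), scramble_sdlog = 0.5,
                           ci_shape = 4, ci_rate = 4,
                           n_full_scrambles = round(0.095 * n_designs),
                           n_patterned_scrambles = round(0.095 * n_designs),
                           trypsin_conc = c(0.07, 0.21, 0.64, 1.93, 5.78,
                                            17.33, 51.99),
                           chymotrypsin_conc = c(0.08, 0.25, 0.74, 2.22,
                                                 6.67, 20),
                           read_depth = 0L, protein_length = 40L, seed = 1L) {
  stopifnot(n_designs >= 1, stable_fraction >= 0, stable_fraction <= 1,
            all(diff(trypsin_conc) > 0), all(diff(chymotrypsin_conc) > 0))
  structure(as.list(environment()), class = "assay_sim_spec")
}

revtrans <- function(protein, rng) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), unname(gc))
  paste(vapply(strsplit(protein, "")[[1]], function(a) {
    cods <- by_aa[[a]]
    cods[rng$sample_int(length(cods), 1)]
  }, ""), collapse = "")
}

#' Simulate the stability selection assay
#'
#' Plants a true EC50 per sequence and protease (stable designs high,
#' unstable designs and scrambles low), reports EC50s with log-normal
#' multiplicative noise whose spread is tied to a drawn 95 percent
#' credible-interval width, and (optionally) simulates per-round
#' sequencing reads. Survival of one treatment at concentration c is
#' exp(-k c) with k = log(2) / EC50, i.e. pseudo-first-order kinetics
#' with half-survival at the planted EC50; population shares are
#' propagated across the rounds and sampled multinomially at the
#' requested read depth. Reads carry the design coding sequence between
#' the fixed TCAATG / CTCGAG flanking hexamers so they can be counted
#' with [count_reads()].
#'
#' @param spec An `assay_sim_spec`.
#' @return List with `ec50` (the reported table: design_id, category,
#'   trypsin_ec50, trypsin_ci95, chymotrypsin_ec50, chymotrypsin_ci95),
#'   `truth` (planted EC50s and stability flags), `designs` (design_id,
#'   protein, dna), and `reads` (per protease, per round character
#'   vectors of merged reads; empty when `read_depth = 0`).
#' @export
simulate_assay <- function(spec) {
  rng <- local_rng(spec$seed)
  n <- spec$n_designs
  n_stable <- round(n * spec$stable_fraction)
  stable <- c(rep(TRUE, n_stable), rep(FALSE, n - n_stable))
  ids <- c(sprintf("des%05d", seq_len(n)),
           sprintf("scrF%04d", seq_len(spec$n_full_scrambles)),
           sprintf("scrP%04d", seq_len(spec$n_patterned_scrambles)))
  category <- c(rep("design", n),
                rep("full_scramble", spec$n_full_scrambles),
                rep("patterned_scramble", spec$n_patterned_scrambles))
  ntot <- length(ids)
  draw_ec50 <- function() {
    out <- numeric(ntot)
    out[seq_len(n)] <- ifelse(stable,
      rng$rlnorm(n, spec$stable_meanlog, spec$stable_sdlog),
      rng$rlnorm(n, spec$unstable_meanlog, spec$unstable_sdlog))
    nscr <- ntot - n
    out[n + seq_len(nscr)] <- rng$rlnorm(nscr, spec$scramble_meanlog,
                                         spec$scramble_sdlog)
    out
  }
  true_t <- draw_ec50(); true_c <- draw_ec50()
  ci_t <- rng$rgamma(ntot, spec$ci_shape, spec$ci_rate)
  ci_c <- rng$rgamma(ntot, spec$ci_shape, spec$ci_rate)
  rep_t <- true_t * exp(rng$rnorm(ntot) * ci_t / 4)
  rep_c <- true_c * exp(rng$rnorm(ntot) * ci_c / 4)
  ec50 <- data.frame(design_id = ids, category = category,
                     trypsin_ec50 = rep_t, trypsin_ci95 = ci_t,
                     chymotrypsin_ec50 = rep_c, chymotrypsin_ci95 = ci_c,
                     stringsAsFactors = FALSE)
  truth <- data.frame(design_id = ids, category = category,
                      trypsin_ec50_true = true_t,
                      chymotrypsin_ec50_true = true_c,
                      stable = c(stable, rep(FALSE, ntot - n)),
                      stringsAsFactors = FALSE)
  aa_pool <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "C")
  proteins <- vapply(seq_len(ntot), function(i)
    paste(aa_pool[rng$sample_int(length(aa_pool), spec$protein_length,
                                 replace = TRUE)], collapse = ""), "")
  dna <- vapply(proteins, revtrans, "", rng = rng)
  designs <- data.frame(design_id = ids, protein = proteins, dna = unname(dna),
                        stringsAsFactors = FALSE)
  reads <- list()
  if (spec$read_depth > 0) {
    schedules <- list(trypsin = spec$trypsin_conc,
                      chymotrypsin = spec$chymotrypsin_conc)
    truths <- list(trypsin = true_t, chymotrypsin = true_c)
    for (p in names(schedules)) {
      share <- rep(1 / ntot, ntot)
      rounds <- list()
      for (r in seq_along(schedules[[p]])) {
        surv <- exp(-log(2) / truths[[p]] * schedules[[p]][r])
        share <- share * surv
        if (sum(share) == 0) share <- rep(1e-12, ntot)
        cnt <- drop(rng$rmultinom(1, spec$read_depth, share / sum(share)))
        rounds[[r]] <- paste0("TCAATG",
                              rep(designs$dna, cnt), "CTCGAG")
      }
      reads[[p]] <- rounds
    }
  }
  list(ec50 = ec50, truth = truth, designs = designs, reads = reads)
}
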