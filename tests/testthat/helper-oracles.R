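# Independent oracles used to cross-check the geometry implementation.
# These deliberately avoid the package's own Kabsch/trimming code paths:
# the superposition oracle minimizes RMSD numerically over Euler angles,
# and the trimming oracle selects the kept window by enumeration.

euler_rot <- function(a) {
  ca <- cos(a[1]); sa <- sin(a[1])
  cb <- cos(a[2]); sb <- sin(a[2])
  cc <- cos(a[3]); sc <- sin(a[3])
  Rz <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cc, sc, 0, -sc, cc), 3, 3)
  Rz %*% Ry %*% Rx
}

# Brute-force least-squares superposition: numeric optimization over
# rotations with multiple starts (translation handled by centering).
oracle_superpose <- function(mobile, target, n_starts = 12) {
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(as.matrix(mobile), 2, cm)
  B <- sweep(as.matrix(target), 2, ct)
  obj <- function(a) {
    R <- euler_rot(a)
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  starts <- rbind(c(0, 0, 0),
                  as.matrix(expand.grid(c(-2, 1), c(-1, 2), c(0, 3))),
                  matrix(stats::runif(3 * (n_starts - 9), -pi, pi),
                         ncol = 3))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], obj, method = "BFGS",
                        control = list(reltol = 1e-16, maxit = 500))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  R <- euler_rot(best$par)
  list(rotation = R, translation = drop(ct - R %*% cm), rmsd = best$value)
}

# Enumerative trimming oracle: among all equal-length windows of the
# longer range, keep the most central one, preferring the window that
# keeps the extra N-terminal residue when the trim is odd.
oracle_trim <- function(range_a, range_b) {
  la <- range_a[2] - range_a[1] + 1L
  lb <- range_b[2] - range_b[1] + 1L
  keep <- min(la, lb)
  windows <- function(r) {
    len <- r[2] - r[1] + 1L
    starts <- r[1]:(r[2] - keep + 1L)
    left <- starts - r[1]
    right <- (len - keep) - left
    # centrality: minimize |left - right|; N-bias: smaller left wins ties
    ord <- order(abs(left - right), left)
    c(starts[ord[1]], starts[ord[1]] + keep - 1L)
  }
  list(a = windows(range_a), b = windows(range_b))
}

# Direct-path pairwise helix RMSD: oracle superposition on the sheet,
# enumerative trimming, explicit concatenated RMSD.
oracle_pairwise_helix_rmsd <- function(a, b, ann_a, ann_b) {
  fit <- oracle_superpose(bb_coords(b, ann_b$sheet_residues),
                          bb_coords(a, ann_a$sheet_residues))
  pa <- pb <- NULL
  for (h in seq_along(ann_a$helices)) {
    tr <- oracle_trim(ann_a$helices[[h]], ann_b$helices[[h]])
    pa <- rbind(pa, bb_coords(a, tr$a[1]:tr$a[2]))
    pb <- rbind(pb, bb_coords(b, tr$b[1]:tr$b[2]))
  }
  moved <- sweep(pb %*% t(fit$rotation), 2, fit$translation, `+`)
  sqrt(mean(rowSums((moved - pa)^2)))
}

oracle_lhl_rmsd <- function(prediction, design, annotation) {
  lhl <- lhl_residues(annotation)
  fixed <- setdiff(design$resi, lhl)
  fit <- oracle_superpose(bb_coords(prediction, fixed),
                          bb_coords(design, fixed))
  p <- bb_coords(prediction, lhl)
  moved <- sweep(p %*% t(fit$rotation), 2, fit$translation, `+`)
  sqrt(mean(rowSums((moved - bb_coords(design, lhl))^2)))
}

# A pair of comparable annotated structures on a shared scaffold, with
# configurable helix lengths so the trimming rule is exercised.
make_variant_pair <- function(seed, len_a = c(10L, 12L), len_b = c(12L, 9L)) {
  sc <- make_scaffold(4, 6)
  rng_shift <- function(s) {
    set.seed(s)
    c(stats::runif(1, -2, 2), stats::runif(1, -2, 2), stats::runif(1, 0, 2))
  }
  mk <- function(lens, shift, sd) {
    spec <- lhl_variant_spec(sc$structure$id, list(
      list(helix_length = lens[1], centroid = c(6, 5, 10) + shift,
           axis = c(1, 0.2 * sd, 0.1), loop_lengths = c(3, 3)),
      list(helix_length = lens[2], centroid = c(14, 12, 10) - shift,
           axis = c(0.9, -0.2, 0.15 * sd), loop_lengths = c(2, 4))))
    make_lhl_variant(sc, spec)
  }
  list(a = mk(len_a, rng_shift(seed), 1),
       b = mk(len_b, rng_shift(seed + 1000), -1))
}
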