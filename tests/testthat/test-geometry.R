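random_points <- function(n, seed) {
  set.seed(seed)
  matrix(stats::rnorm(3 * n, sd = 4), ncol = 3)
}

test_that("superposition recovers planted rigid motions exactly", {
  A <- random_points(12, 1)
  fit0 <- superpose(A, A)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-10)

  set.seed(2)
  ang <- stats::runif(3, -pi, pi)
  R <- euler_rot(ang)
  t0 <- c(3, -7, 2)
  B <- sweep(A %*% t(R), 2, t0, `+`)
  fit <- superpose(A, B)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  expect_equal(fit$rotation, R, tolerance = 1e-8)
  expect_equal(fit$translation, t0, tolerance = 1e-8)
  expect_equal(apply_transform(A, fit), B, tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
})

test_that("superposition RMSD is invariant under joint rigid motions and matches the numeric oracle", {
  A <- random_points(10, 3)
  B <- A + matrix(stats::rnorm(30, sd = 0.8), ncol = 3)
  r1 <- superpose(A, B)$rmsd
  R <- euler_rot(c(0.4, -1.1, 2.0))
  r2 <- superpose(sweep(A %*% t(R), 2, c(1, 2, 3), `+`),
                  sweep(B %*% t(R), 2, c(1, 2, 3), `+`))$rmsd
  expect_equal(r1, r2, tolerance = 1e-10)
  expect_equal(r1, oracle_superpose(A, B)$rmsd, tolerance = 1e-8)

  expect_error(superpose(A[1:3, ], B), "differ in size")
  expect_error(superpose(A[1:2, ], B[1:2, ]), "at least 3 points")
})

test_that("helix vectors are rigid-motion equivariant and track the helix axis", {
  h <- ideal_helix(12)
  v <- helix_vector(h, c(2, 11))
  expect_equal(sqrt(sum(v$direction^2)), 1, tolerance = 1e-12)

  # direction points N-to-C along the CA axis of an ideal helix
  axis <- lhldesign:::ca_axis(h, 2:11)$axis
  expect_gt(sum(v$direction * axis), cos(15 * pi / 180))

  R <- euler_rot(c(1.2, 0.3, -0.7)); t0 <- c(5, -2, 9)
  tf <- structure(list(rotation = R, translation = t0, rmsd = 0),
                  class = "rigid_transform")
  v2 <- helix_vector(transform_backbone(h, tf), c(2, 11))
  expect_equal(v2$centroid, drop(R %*% v$centroid) + t0, tolerance = 1e-9)
  expect_equal(v2$direction, drop(R %*% v$direction), tolerance = 1e-9)
})

test_that("common-length trimming keeps the central window with N-terminal bias", {
  expect_equal(trim_to_common(c(1, 10), c(1, 10)), list(a = c(1L, 10L), b = c(1L, 10L)))
  expect_equal(trim_to_common(c(1, 12), c(1, 10))$a, c(2L, 11L))
  expect_equal(trim_to_common(c(1, 11), c(1, 10))$a, c(1L, 10L))  # odd trim: extra N-side kept
  expect_equal(trim_to_common(c(1, 10), c(1, 11))$b, c(1L, 10L))
  expect_equal(trim_to_common(c(5, 5), c(1, 9))$b, c(5L, 5L))
  expect_error(trim_to_common(c(4, 3), c(1, 5)), "non-empty")

  set.seed(10)
  for (i in 1:200) {
    a0 <- sample(-20:20, 1); a1 <- a0 + sample(0:15, 1)
    b0 <- sample(-20:20, 1); b1 <- b0 + sample(0:15, 1)
    got <- trim_to_common(c(a0, a1), c(b0, b1))
    expect_equal(got$a[2] - got$a[1], got$b[2] - got$b[1])
    expect_identical(got, oracle_trim(c(a0, a1), c(b0, b1)))
  }
})

test_that("sheet-aligned helix RMSD has the expected metric behavior", {
  pair <- make_variant_pair(1)
  a <- pair$a; b <- pair$b
  expect_equal(pairwise_helix_rmsd(a$structure, a$structure,
                                   a$annotation, a$annotation),
               0, tolerance = 1e-9)
  dab <- pairwise_helix_rmsd(a$structure, b$structure,
                             a$annotation, b$annotation)
  dba <- pairwise_helix_rmsd(b$structure, a$structure,
                             b$annotation, a$annotation)
  expect_gt(dab, 0)
  expect_equal(dab, dba, tolerance = 1e-6)

  # rigid 3 A displacement of every helix (sheet fixed) reads back exactly 3
  moved <- a$structure
  for (h in a$annotation$helices) {
    idx <- match(h[1]:h[2], moved$resi)
    moved$xyz[idx, , 1] <- moved$xyz[idx, , 1] + 3
  }
  expect_equal(pairwise_helix_rmsd(a$structure, moved,
                                   a$annotation, a$annotation),
               3, tolerance = 1e-6)

  # CA-only variant is a valid RMSD too, and differs in general
  dca <- pairwise_helix_rmsd(a$structure, b$structure,
                             a$annotation, b$annotation, atoms = "CA")
  expect_gt(dca, 0)
})

test_that("LHL RMSD aligns on the fixed region and scores only reshaped residues", {
  co <- simulate_variant_cohort(1, seed = 7)
  s <- co$structures[[1]]; ann <- co$annotations[[1]]
  expect_equal(lhl_rmsd(s, s, ann), 0, tolerance = 1e-10)

  lhl <- lhl_residues(ann)
  pred <- s
  idx <- match(lhl, pred$resi)
  pred$xyz[idx, , 3] <- pred$xyz[idx, , 3] + 2
  expect_equal(lhl_rmsd(pred, s, ann), 2, tolerance = 1e-6)

  # moving the whole structure rigidly changes nothing
  tf <- structure(list(rotation = euler_rot(c(0.3, 0.9, -0.2)),
                       translation = c(4, 4, 4), rmsd = 0),
                  class = "rigid_transform")
  expect_equal(lhl_rmsd(transform_backbone(pred, tf), s, ann), 2,
               tolerance = 1e-6)
  expect_equal(lhl_rmsd(pred, s, ann),
               oracle_lhl_rmsd(pred, s, ann), tolerance = 1e-6)
})

test_that("ensemble selectors implement lowest-RMSD and top-pLDDT conventions", {
  co <- simulate_variant_cohort(1, seed = 11)
  s <- co$structures[[1]]; ann <- co$annotations[[1]]
  ens <- make_prediction_ensemble(s, ann, target_rmsds = c(2, 1, 3),
                                  plddts = c(90, 70, 80), seed = 5)
  low <- ensemble_lhl_rmsd(ens, s, ann, selector = "lowest")
  expect_equal(low, 1, tolerance = 0.05)
  r1 <- ensemble_lhl_rmsd(ens, s, ann, selector = "rank1")
  expect_equal(r1, 2, tolerance = 0.10)  # member with pLDDT 90
  expect_gte(r1, low)
  expect_error(ensemble_lhl_rmsd(ens, s, ann, selector = "best"))
  expect_error(prediction_ensemble("d", list(s), c(80, 90)), "per structure")
})

test_that("bias fractions hit 0 and 1 in the unbiased and fully biased limits", {
  co <- simulate_variant_cohort(3, seed = 13)
  ref <- simulate_variant_cohort(1, seed = 99)
  designs <- co$structures; anns <- co$annotations
  # predictions identical to designs: never strictly closer to the reference
  unbiased <- bias_statistics(designs, designs, ref$structures[[1]],
                              anns, anns, ref$annotations[[1]])
  expect_equal(unbiased$frac_closer_to_ref, 0)
  expect_equal(unbiased$frac_margin_closer, 0)
  # predictions identical to the reference: always closer (RMSD 0)
  preds <- rep(ref$structures, 3)
  biased <- bias_statistics(designs, preds, ref$structures[[1]],
                            anns, rep(ref$annotations, 3),
                            ref$annotations[[1]])
  expect_equal(biased$frac_closer_to_ref, 1)
  expect_lte(biased$frac_margin_closer, biased$frac_closer_to_ref)
  expect_equal(biased$d_ref, rep(0, 3), tolerance = 1e-8)
})

test_that("6D binning uses 2 A floor cubes and sign octants", {
  v <- structure(list(centroid = c(3.1, -0.5, 0), direction = c(0.6, -0.8, 0)),
                 class = "helix_vector")
  b <- bin_index(v)
  expect_equal(b$cube, c(1L, -1L, 0L))
  expect_equal(b$octant, c("+", "-", "+"))  # zero component counts as "+"
  expect_equal(b$key, "1:-1:0:+-+")

  b2 <- bin_index(v, bin_spec(cube_edge = 4))
  expect_equal(b2$cube, c(0L, -1L, 0L))

  mk <- function(cen, dir) structure(list(centroid = cen, direction = dir),
                                     class = "helix_vector")
  uni <- list(mk(c(1, 1, 1), c(1, 1, 1)),
              mk(c(5, 1, 1), c(1, 1, 1)),
              mk(c(1, 1, 1), c(-1, 1, 1)))   # 3 distinct bins
  expect_equal(bin_occupancy(uni[1:2], uni), 2 / 3)
  expect_equal(bin_occupancy(uni, uni), 1)
  expect_equal(bin_occupancy(list(), uni), 0)
  # duplicates in the subset do not inflate occupancy
  expect_equal(bin_occupancy(c(uni[1], uni[1]), uni), 1 / 3)
})

test_that("sheet face flips under mirror reflection and is +1 in-plane", {
  co <- simulate_variant_cohort(1, seed = 17)
  s <- co$structures[[1]]; ann <- co$annotations[[1]]
  h1 <- ann$helices[[1]]
  f <- sheet_face(s, h1, ann$sheet_residues)
  expect_true(f %in% c(-1, 1))

  mirror <- s
  mirror$xyz[, , 3] <- -mirror$xyz[, , 3]  # reflect through z = 0
  expect_equal(sheet_face(mirror, h1, ann$sheet_residues), -f)

  # helix centroid projected into the sheet plane => +1 by convention
  flat <- make_scaffold(4, 6)$structure
  expect_equal(sheet_face(flat, c(1, 4), flat$resi), 1)
  expect_error(sheet_face(s, h1, ann$sheet_residues[1:3]), "at least 4")
})

test_that("shell residues grow outward from the reshaped elements", {
  co <- simulate_variant_cohort(1, seed = 19)
  s <- co$structures[[1]]; ann <- co$annotations[[1]]
  lhl <- lhl_residues(ann)
  s1 <- shell_residues(s, ann, shell = 1)
  s2 <- shell_residues(s, ann, shell = 2)
  expect_true(all(lhl %in% s1))
  expect_true(all(s1 %in% s2))
  expect_true(all(s2 %in% s$resi))
  # a tight first-shell radius reduces to the LHL itself
  expect_equal(shell_residues(s, ann, shell = 1, shell1_distance = 0.1),
               sort(lhl))
  expect_error(shell_residues(s, ann, shell = 3), "shell")
})

test_that("orientation gating admits pointed-toward residues and rejects pointed-away ones", {
  # residue 1 is the reshaped element; residues 2 and 3 sit 8 A away,
  # with CB vectors pointing toward and away from residue 1.
  xyz <- array(NA_real_, c(3, 5, 3),
               dimnames = list(NULL, c("N", "CA", "C", "O", "CB"), NULL))
  put <- function(i, ca, cb) {
    xyz[i, "CA", ] <<- ca
    xyz[i, "CB", ] <<- cb
    xyz[i, "N", ] <<- ca + c(0, 0, 1)
    xyz[i, "C", ] <<- ca + c(0, 1, 0)
    xyz[i, "O", ] <<- ca + c(0, 2, 0)
  }
  put(1, c(0, 0, 0), c(-1, 0, 0))
  put(2, c(8, 0, 0), c(7, 0, 0))    # CB toward residue 1
  put(3, c(0, 8, 0), c(0, 9, 0))    # CB away from residue 1
  s <- backbone("toy", 1:3, rep("A", 3), xyz)
  ann <- segment_annotation("toy", integer(0), list(),
                            reshaped_lhls = list(c(1, 1)),
                            linker_ids = "l1")
  expect_equal(shell_residues(s, ann, shell = 1), c(1L, 2L))
})

test_that("minimum helix length filtering is strict at the boundary", {
  mk <- function(l1, l2) segment_annotation(
    "x", 1:4,
    helices = list(c(10, 10 + l1 - 1), c(30, 30 + l2 - 1)),
    reshaped_lhls = list(c(9, 10 + l1), c(29, 31 + l2)),
    linker_ids = c("la", "lb"))
  expect_true(min_helix_length_filter(mk(7, 7)))
  expect_false(min_helix_length_filter(mk(6, 12)))
  expect_false(min_helix_length_filter(mk(12, 6)))
  expect_true(min_helix_length_filter(mk(8, 9), min_len = 8))
})
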