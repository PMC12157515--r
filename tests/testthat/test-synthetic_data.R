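test_that("ideal secondary structures reproduce their target dihedrals", {
  h <- ideal_helix(10)
  dh <- backbone_dihedrals(h)
  expect_equal(stats::median(dh$phi, na.rm = TRUE), -57, tolerance = 1)
  expect_equal(stats::median(dh$psi, na.rm = TRUE), -47, tolerance = 1)

  e <- ideal_strand(8)
  de <- backbone_dihedrals(e)
  expect_equal(stats::median(de$phi, na.rm = TRUE), -139, tolerance = 1)
  expect_equal(stats::median(de$psi, na.rm = TRUE), 135, tolerance = 1)

  # consecutive CA-CA distances near the canonical 3.8 A
  ca <- bb_coords(h, atoms = "CA")
  d <- sqrt(rowSums((ca[-1, ] - ca[-nrow(ca), ])^2))
  expect_true(all(abs(d - 3.8) < 0.2))
})

test_that("scaffolds lay out parallel strands with fixed spacing, deterministically", {
  sc <- make_scaffold(4, 6)
  expect_equal(length(sc$structure$resi), 24L)
  expect_equal(sc$annotation$sheet_residues, 1:24)
  expect_equal(sc$n_strands, 4L)
  ca <- bb_coords(sc$structure, atoms = "CA")
  # strand j sits at y ~ 4.8 (j - 1)
  ymeans <- vapply(1:4, function(j) mean(ca[(j - 1) * 6 + 1:6, 2]), 0)
  expect_equal(diff(ymeans), rep(4.8, 3), tolerance = 0.2)
  expect_identical(make_scaffold(4, 6)$structure$xyz, sc$structure$xyz)
  expect_error(make_scaffold(1, 6))
})

test_that("LHL variants carry their planted helix placement as ground truth", {
  sc <- make_scaffold(4, 6)
  spec <- lhl_variant_spec(sc$structure$id, list(
    list(helix_length = 10, centroid = c(6, 5, 10), axis = c(1, 0.3, 0),
         loop_lengths = c(3, 2)),
    list(helix_length = 12, centroid = c(14, 12, 11), axis = c(1, -0.2, 0.1),
         loop_lengths = c(2, 4))))
  var <- make_lhl_variant(sc, spec)
  ann <- var$annotation
  expect_length(ann$helices, 2)
  expect_length(ann$reshaped_lhls, 2)
  expect_length(ann$linker_ids, 2)
  # helix ranges sit inside their LHL ranges
  for (i in 1:2) {
    expect_gte(ann$helices[[i]][1], ann$reshaped_lhls[[i]][1])
    expect_lte(ann$helices[[i]][2], ann$reshaped_lhls[[i]][2])
  }
  # planted placements are recovered by the 6D helix vector
  for (i in 1:2) {
    v <- helix_vector(var$structure, ann$helices[[i]])
    gt <- var$ground_truth[[i]]
    expect_lt(sqrt(sum((v$centroid - gt$centroid)^2)), 0.5)
    ang <- acos(min(1, sum(v$direction * gt$axis))) * 180 / pi
    expect_lt(ang, 10)
  }
  # identical specs give identical linker ids; different loops differ
  var2 <- make_lhl_variant(sc, spec)
  expect_identical(var2$annotation$linker_ids, ann$linker_ids)
  spec3 <- spec; spec3$lhls[[1]]$loop_lengths <- c(4, 2)
  var3 <- make_lhl_variant(sc, spec3)
  expect_false(var3$annotation$linker_ids[1] == ann$linker_ids[1])

  # a helix through the sheet plane is rejected as a clash
  bad <- lhl_variant_spec(sc$structure$id, list(
    list(helix_length = 10, centroid = c(6, 5, 0.5), axis = c(1, 0, 0),
         loop_lengths = c(3, 3))))
  expect_error(make_lhl_variant(sc, bad), "clash")
})

test_that("variants on opposite sheet faces are told apart", {
  sc <- make_scaffold(4, 6)
  mk <- function(z) make_lhl_variant(sc, lhl_variant_spec(sc$structure$id,
    list(list(helix_length = 10, centroid = c(6, 5, z), axis = c(1, 0, 0),
              loop_lengths = c(3, 3)))))
  up <- mk(10); dn <- mk(-10)
  f_up <- sheet_face(up$structure, up$annotation$helices[[1]],
                     up$annotation$sheet_residues)
  f_dn <- sheet_face(dn$structure, dn$annotation$helices[[1]],
                     dn$annotation$sheet_residues)
  expect_equal(f_up * f_dn, -1)
})

test_that("random variant cohorts are reproducible and clash-free", {
  co <- simulate_variant_cohort(5, seed = 42)
  expect_length(co$structures, 5)
  expect_length(co$annotations, 5)
  co2 <- simulate_variant_cohort(5, seed = 42)
  expect_identical(co$structures[[3]]$xyz, co2$structures[[3]]$xyz)
  co3 <- simulate_variant_cohort(5, seed = 43)
  expect_false(identical(co$structures[[1]]$xyz, co3$structures[[1]]$xyz))
  # each variant has two annotated helices of the allowed lengths
  for (a in co$annotations) {
    lens <- vapply(a$helices, function(h) h[2] - h[1] + 1L, 1L)
    expect_true(all(lens %in% 8:14))
  }
})

test_that("prediction ensembles hit their target LHL RMSDs", {
  co <- simulate_variant_cohort(1, seed = 3)
  s <- co$structures[[1]]; ann <- co$annotations[[1]]
  ens <- make_prediction_ensemble(s, ann, target_rmsds = c(0, 1.5, 4),
                                  plddts = c(95, 90, 60), seed = 2)
  got <- vapply(ens$members, function(m) lhl_rmsd(m$structure, s, ann), 0)
  expect_equal(got[1], 0, tolerance = 1e-9)
  expect_lt(abs(got[2] - 1.5) / 1.5, 0.05)
  expect_lt(abs(got[3] - 4) / 4, 0.05)
  # non-reshaped atoms untouched
  fixed <- setdiff(s$resi, lhl_residues(ann))
  expect_equal(bb_coords(ens$members[[3]]$structure, fixed),
               bb_coords(s, fixed), tolerance = 1e-12)
  expect_error(make_prediction_ensemble(s, ann, -1, 90), "non-negative")
})

test_that("assay simulation plants the requested cohort composition", {
  spec <- assay_sim_spec(n_designs = 200, stable_fraction = 0.6,
                         read_depth = 0, seed = 4)
  sim <- simulate_assay(spec)
  expect_equal(sum(sim$truth$category == "design"), 200)
  expect_equal(sum(sim$truth$stable), 120)
  expect_equal(sum(sim$ec50$category == "full_scramble"), round(0.095 * 200))
  expect_equal(sum(sim$ec50$category == "patterned_scramble"),
               round(0.095 * 200))
  # stable designs are planted well above unstable ones
  med_stable <- stats::median(
    sim$truth$trypsin_ec50_true[sim$truth$stable])
  med_unstable <- stats::median(
    sim$truth$trypsin_ec50_true[!sim$truth$stable &
                                  sim$truth$category == "design"])
  expect_gt(med_stable, 10 * med_unstable)
  # deterministic
  sim2 <- simulate_assay(spec)
  expect_identical(sim$ec50, sim2$ec50)
})

test_that("simulated reads deplete low-EC50 designs across selection rounds", {
  spec <- assay_sim_spec(n_designs = 40, stable_fraction = 0.5,
                         read_depth = 2000, protein_length = 12, seed = 6)
  sim <- simulate_assay(spec)
  expect_length(sim$reads$trypsin, length(spec$trypsin_conc))
  expect_length(sim$reads$chymotrypsin, length(spec$chymotrypsin_conc))

  first <- count_reads(sim$reads$trypsin[[1]], sim$designs)
  last <- count_reads(sim$reads$trypsin[[length(spec$trypsin_conc)]],
                      sim$designs)
  # a few reads carry a flank hexamer inside the coding region and are
  # (correctly) rejected as ambiguous, so recovery is near-total, not exact
  expect_gt(sum(first), 0.9 * 2000)
  stable_ids <- sim$truth$design_id[sim$truth$stable]
  frac_stable <- function(cnt)
    sum(cnt[names(cnt) %in% stable_ids]) / sum(cnt)
  # stringent rounds enrich the stable designs
  expect_gt(frac_stable(last), frac_stable(first))
  expect_gt(frac_stable(last), 0.95)
})

test_that("the isolated RNG stream leaves global reproducibility intact", {
  set.seed(500)
  a <- stats::rnorm(1)
  set.seed(500)
  invisible(simulate_variant_cohort(1, seed = 77))
  b <- stats::rnorm(1)
  expect_identical(a, b)
})
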