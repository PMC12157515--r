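passing_record <- function(...) {
  rec <- list(fragment_quality_A = 0.5, holes_shell2 = -0.4,
              helix_complementarity = 0.7, buried_unsat_count = 1L,
              oversaturated_hbonds = 0L,
              hydrophobic_sasa_ratio_shell2 = 0.5,
              best_plddt_reshaped = 92, min_lhl_rmsd_A = 0.8)
  utils::modifyList(rec, list(...))
}

test_that("oligo arithmetic yields 258 variable nt, 86 variable and 103 total residues", {
  ml <- max_lengths()
  expect_equal(ml$variable_nt, 258L)
  expect_equal(ml$variable_aa, 86L)
  expect_equal(ml$total_aa, 103L)

  ml2 <- max_lengths(oligo_spec(150, 21, 17, 7))
  expect_equal(ml2$variable_nt, 108L)
  expect_equal(ml2$variable_aa, 36L)
  expect_equal(ml2$total_aa, 53L)

  # the reverse primer must encode exactly its share of fixed residues
  expect_error(oligo_spec(primer_nt = 20L))
  expect_error(oligo_spec(oligo_max_nt = 30L, primer_nt = 21L))
})

test_that("the orderability filter is strict at 103 residues and rejects cysteine", {
  ok103 <- paste(rep("A", 103), collapse = "")
  too104 <- paste(rep("A", 104), collapse = "")
  expect_true(orderability_filter(ok103)$pass)
  f <- orderability_filter(too104)
  expect_false(f$pass)
  expect_match(f$reasons, "104 exceeds 103")

  fc <- orderability_filter("MKVCLAE")
  expect_false(fc$pass)
  expect_match(fc$reasons, "forbidden residue: C")
  expect_true(orderability_filter("MKVCLAE", forbid = character(0))$pass)

  both <- orderability_filter(paste0(too104, "C"))
  expect_length(both$reasons, 2)
})

test_that("every quadrant threshold uses the documented strict comparison", {
  qa <- function(...) quadrant_assign(passing_record(...))
  expect_equal(qa(), "RP-AP")

  # Rosetta metrics: value at the threshold must fail
  expect_equal(qa(fragment_quality_A = 1.0), "RF-AP")
  expect_equal(qa(fragment_quality_A = 0.999), "RP-AP")
  expect_equal(qa(holes_shell2 = 0), "RF-AP")
  expect_equal(qa(holes_shell2 = -1e-6), "RP-AP")
  expect_equal(qa(helix_complementarity = 0.6), "RF-AP")
  expect_equal(qa(helix_complementarity = 0.601), "RP-AP")
  expect_equal(qa(buried_unsat_count = 2L), "RF-AP")
  expect_equal(qa(buried_unsat_count = 1L), "RP-AP")
  expect_equal(qa(oversaturated_hbonds = 1L), "RF-AP")
  expect_equal(qa(hydrophobic_sasa_ratio_shell2 = 0.58), "RF-AP")
  expect_equal(qa(hydrophobic_sasa_ratio_shell2 = 0.579), "RP-AP")

  # AF2 metrics
  expect_equal(qa(best_plddt_reshaped = 85), "RP-AF")
  expect_equal(qa(best_plddt_reshaped = 85.01), "RP-AP")
  expect_equal(qa(min_lhl_rmsd_A = 1.5), "RP-AF")
  expect_equal(qa(min_lhl_rmsd_A = 1.499), "RP-AP")

  # double failure
  expect_equal(qa(fragment_quality_A = 2, min_lhl_rmsd_A = 3), "RF-AF")
  expect_error(quadrant_assign(passing_record(holes_shell2 = NULL)),
               "missing metric: holes_shell2")
})

test_that("threshold overrides shift the quadrant boundary", {
  rec <- passing_record(best_plddt_reshaped = 80)
  expect_equal(quadrant_assign(rec), "RP-AF")
  expect_equal(quadrant_assign(rec, list(best_plddt_reshaped = 75)), "RP-AP")
})

test_that("quadrant population keeps one design per backbone with RP-first priority", {
  rec_row <- function(d, b, ...) {
    cbind(data.frame(design_id = d, backbone_id = b,
                     stringsAsFactors = FALSE),
          as.data.frame(passing_record(...)))
  }
  records <- rbind(
    rec_row("d1", "b1"),                                    # RP-AP
    rec_row("d2", "b1", best_plddt_reshaped = 60),          # RP-AF
    rec_row("d3", "b2", fragment_quality_A = 2),            # RF-AP
    rec_row("d4", "b2"),                                    # RP-AP
    rec_row("d5", "b3", fragment_quality_A = 2,
            min_lhl_rmsd_A = 3))                            # RF-AF
  out <- populate_quadrants(records, seed = 4)
  expect_equal(sort(out$backbone_id), c("b1", "b2", "b3"))
  expect_false(any(duplicated(out$backbone_id)))
  # b2 has an RP design, so its RF-AP design is discarded
  expect_equal(out$quadrant[out$backbone_id == "b2"], "RP-AP")
  expect_equal(out$quadrant[out$backbone_id == "b3"], "RF-AF")
  # b1 (both RP quadrants) lands in one of them
  expect_true(out$quadrant[out$backbone_id == "b1"] %in% c("RP-AP", "RP-AF"))

  # backbones with designs in both RP quadrants split evenly
  many <- do.call(rbind, lapply(1:10, function(i) rbind(
    rec_row(sprintf("a%d", i), sprintf("bb%d", i)),
    rec_row(sprintf("f%d", i), sprintf("bb%d", i),
            best_plddt_reshaped = 60))))
  pop <- populate_quadrants(many, seed = 9)
  expect_equal(sum(pop$quadrant == "RP-AP"), 5)
  expect_equal(sum(pop$quadrant == "RP-AF"), 5)
  expect_identical(populate_quadrants(many, seed = 9), pop)
})

test_that("equal-depth quadrant sampling enforces availability and reproducibility", {
  set.seed(6)
  assignment <- data.frame(
    backbone_id = sprintf("b%03d", 1:120),
    design_id = sprintf("d%03d", 1:120),
    quadrant = rep(c("RP-AP", "RP-AF", "RF-AP", "RF-AF"), each = 30),
    stringsAsFactors = FALSE)
  got <- sample_quadrants(assignment, per_quadrant = 10, seed = 2)
  expect_equal(nrow(got), 40)
  expect_equal(unname(table(got$quadrant)[c("RP-AP", "RP-AF", "RF-AP",
                                            "RF-AF")]),
               rep(10L, 4), ignore_attr = TRUE)
  expect_false(any(duplicated(got$design_id)))
  expect_identical(sample_quadrants(assignment, per_quadrant = 10, seed = 2),
                   got)
  expect_error(sample_quadrants(assignment, per_quadrant = 31, seed = 2),
               "RP-AP")
})

test_that("simulated metric cohorts realize the planted quadrant rates", {
  rosetta6 <- c("fragment_quality_A", "holes_shell2", "helix_complementarity",
                "buried_unsat_count", "oversaturated_hbonds",
                "hydrophobic_sasa_ratio_shell2")
  af2 <- c("best_plddt_reshaped", "min_lhl_rmsd_A")
  mk_rates <- function(r, a) as.list(stats::setNames(c(rep(r, 6), rep(a, 2)),
                                                     c(rosetta6, af2)))
  n <- 4000
  rec <- simulate_metrics(n, pass_rates = mk_rates(0.9, 0.7), seed = 3)
  expect_equal(nrow(rec), n)
  q <- lhldesign:::quadrants_of(rec)
  p_rp <- 0.9^6; p_ap <- 0.7^2
  se <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(q %in% c("RP-AP", "RP-AF")) - p_rp), 3 * se(p_rp))
  expect_lt(abs(mean(q %in% c("RP-AP", "RF-AP")) - p_ap), 3 * se(p_ap))
  expect_identical(simulate_metrics(n, pass_rates = mk_rates(0.9, 0.7),
                                    seed = 3), rec)

  all_pass <- simulate_metrics(200, pass_rates = mk_rates(1, 1), seed = 4)
  expect_true(all(lhldesign:::quadrants_of(all_pass) == "RP-AP"))
  none <- simulate_metrics(200, pass_rates = mk_rates(0, 0), seed = 5)
  expect_true(all(lhldesign:::quadrants_of(none) == "RF-AF"))
  expect_error(simulate_metrics(10, pass_rates = list(bogus = 1)),
               "unknown metric")

  # designs sharing a backbone are grouped under one backbone id
  grp <- simulate_metrics(10, seed = 6, designs_per_backbone = 2L)
  expect_equal(length(unique(grp$backbone_id)), 5L)
})
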