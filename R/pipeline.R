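write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Run a configured analysis pipeline
#'
#' Executes the configured stages in order inside one output directory
#' and writes a machine-readable JSON manifest recording the
#' configuration, package version, seeds and the md5 checksum of every
#' output file; re-running the same configuration reproduces identical
#' outputs and an identical manifest. Stage parameters mirror the
#' underlying functions.
#'
#' Supported stages and their main outputs:
#' \describe{
#'   \item{simulate_metrics}{[simulate_metrics()] -> `metrics.tsv`}
#'   \item{select}{[populate_quadrants()] + [sample_quadrants()] on
#'     `metrics.tsv` -> `selection.tsv`}
#'   \item{scramble}{[allocate_control_sources()] + both scramble
#'     generators on `selection.tsv` -> `controls.tsv`}
#'   \item{simulate_assay}{[simulate_assay()] -> `ec50.tsv`}
#'   \item{classify}{[stability_pipeline()] on `ec50.tsv` ->
#'     `stability_calls.tsv`}
#'   \item{simulate_variants}{[make_lhl_variant()] cohort ->
#'     `rmsd_overall.tsv`, `rmsd_helix1.tsv`, `rmsd_helix2.tsv`,
#'     `linkers.json`}
#'   \item{diversity}{[summarize_group()] on `rmsd_overall.tsv` ->
#'     `diversity_summary.tsv`}
#'   \item{split}{[search_split()] on the three matrices ->
#'     `split.json`}
#' }
#'
#' @param config A named list, or a path to a YAML file, with fields
#'   `output_dir`, `master_seed`, and `stages` (list of
#'   `list(stage = <name>, <params>)`).
#' @return The manifest list, invisibly; also written as
#'   `manifest.json`. A failing stage raises an error naming it.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$output_dir), !is.null(config$stages))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$master_seed)) 1L else as.integer(config$master_seed)
  manifest <- list(config = config, package_version =
                     as.character(utils::packageVersion("lhldesign")),
                   stages = list())
  p <- function(f) file.path(out, f)
  for (st in config$stages) {
    name <- st$stage
    files <- tryCatch(run_stage(name, st, p, seed),
                      error = function(e)
                        stop("stage '", name, "' failed: ",
                             conditionMessage(e), call. = FALSE))
    manifest$stages[[length(manifest$stages) + 1L]] <-
      list(stage = name,
           outputs = stats::setNames(as.list(unname(tools::md5sum(files))),
                                     basename(files)))
  }
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

run_stage <- function(name, st, p, master_seed) {
  g <- function(field, default) if (is.null(st[[field]])) default else st[[field]]
  seed <- as.integer(g("seed", master_seed))
  switch(name,
    simulate_metrics = {
      m <- simulate_metrics(g("n", 1000L), g("pass_rates", NULL), seed,
                            g("designs_per_backbone", 1L))
      write_tsv(m, p("metrics.tsv"))
    },
    select = {
      m <- read_tsv(p("metrics.tsv"))
      assign_ <- populate_quadrants(m, seed)
      sel <- sample_quadrants(assign_, g("per_quadrant", 250L), seed + 1L)
      write_tsv(sel, p("selection.tsv"))
    },
    scramble = {
      sel <- read_tsv(p("selection.tsv"))
      m <- read_tsv(p("metrics.tsv"))
      counts <- unlist(g("counts", list(`RP-AF` = 24, `RF-AP` = 24,
                                        `RP-AP` = 23, `RF-AF` = 23)))
      quad <- stats::setNames(sel$quadrant, sel$design_id)
      src <- allocate_control_sources(quad, counts, seed)
      seqs <- stats::setNames(m$sequence, m$design_id)[src]
      hp <- hp_classification()
      rows <- lapply(seq_along(src), function(i) {
        data.frame(source_id = src[i],
                   control_type = c("full_scramble", "patterned_scramble"),
                   sequence = c(full_scramble(seqs[i], seed + i),
                                patterned_scramble(seqs[i], hp, seed + i)),
                   seed = seed + i,
                   hp_set = paste(hp$hydrophobic, collapse = ""),
                   stringsAsFactors = FALSE)
      })
      write_tsv(do.call(rbind, rows), p("controls.tsv"))
    },
    simulate_assay = {
      args <- st[setdiff(names(st), c("stage", "seed"))]
      spec <- do.call(assay_sim_spec, c(args, list(seed = seed)))
      sim <- simulate_assay(spec)
      write_tsv(sim$ec50, p("ec50.tsv"))
    },
    classify = {
      res <- stability_pipeline(read_tsv(p("ec50.tsv")),
                                g("max_ci", 2.0), g("percentile", 95))
      write_tsv(res$calls, p("stability_calls.tsv"))
    },
    simulate_variants = {
      cohort <- simulate_variant_cohort(g("n", 20L), seed,
                                        g("spread", 6))
      files <- c(
        write_rmsd_matrix(pairwise_matrix(cohort$structures,
                                          cohort$annotations, "overall"),
                          p("rmsd_overall.tsv")),
        write_rmsd_matrix(pairwise_matrix(cohort$structures,
                                          cohort$annotations, "helix1"),
                          p("rmsd_helix1.tsv")),
        write_rmsd_matrix(pairwise_matrix(cohort$structures,
                                          cohort$annotations, "helix2"),
                          p("rmsd_helix2.tsv")))
      jsonlite::write_json(lapply(cohort$annotations, `[[`, "linker_ids"),
                           p("linkers.json"))
      c(files, p("linkers.json"))
    },
    diversity = {
      m <- read_rmsd_matrix(p("rmsd_overall.tsv"))
      write_tsv(summarize_group(m, g("label", "cohort")),
                p("diversity_summary.tsv"))
    },
    split = {
      mo <- read_rmsd_matrix(p("rmsd_overall.tsv"))
      m1 <- read_rmsd_matrix(p("rmsd_helix1.tsv"))
      m2 <- read_rmsd_matrix(p("rmsd_helix2.tsv"))
      linkers <- jsonlite::fromJSON(p("linkers.json"), simplifyVector = FALSE)
      linkers <- lapply(linkers, unlist)
      sp <- split_spec(n_clusters = g("n_clusters", 5L),
                       n_cluster_seeds = g("n_cluster_seeds", 5L),
                       n_bipartitions_per_seed =
                         g("n_bipartitions_per_seed", 5L),
                       leakage_threshold = g("leakage_threshold", 2.0),
                       target_train_fraction =
                         g("target_train_fraction", 0.9),
                       master_seed = seed)
      res <- search_split(mo$ids, m1, m2, mo, sp, linkers)
      write_split(res, p("split.json"))
    },
    stop("unknown stage: ", name))
}

#' Generate a cohort of LHL variants with randomized helix placements
#'
#' Convenience generator used by the pipeline and the test suite: one
#' shared scaffold, `n` two-LHL variants whose helix centroids and axes
#' are drawn seeded around the two sheet faces' standard positions, with
#' `spread` controlling the centroid scatter (Angstrom).
#'
#' @param n Number of variants.
#' @param seed Integer seed.
#' @param spread Centroid scatter in Angstrom.
#' @param helix_lengths Range of helix lengths to draw from.
#' @param loop_length_range Range of loop lengths to draw from.
#' @param n_strands,strand_length Scaffold size.
#' @return List with `structures`, `annotations`, `ground_truth`,
#'   `specs` and the shared `scaffold`.
#' @export
simulate_variant_cohort <- function(n, seed = 1L, spread = 6,
                                    helix_lengths = 8:14,
                                    loop_length_range = 2:5,
                                    n_strands = 4L, strand_length = 6L) {
  scaffold <- make_scaffold(n_strands, strand_length)
  rng <- local_rng(seed)
  base_centroids <- list(c(6, 5, 10), c(14, 12, 10))
  structures <- list(); annotations <- list(); gt <- list(); specs <- list()
  made <- 0L; tries <- 0L
  while (made < n && tries < 50L * n) {
    tries <- tries + 1L
    lhls <- lapply(base_centroids, function(b) {
      ax <- c(rng$rnorm(1, 1, 0.4), rng$rnorm(1, 0, 0.4), rng$rnorm(1, 0, 0.3))
      list(helix_length = helix_lengths[rng$sample_int(length(helix_lengths), 1)],
           centroid = b + c(rng$runif(1, -spread, spread),
                            rng$runif(1, -spread, spread),
                            rng$runif(1, 0, spread / 2)),
           axis = ax / sqrt(sum(ax^2)),
           loop_lengths = loop_length_range[rng$sample_int(
             length(loop_length_range), 2, replace = TRUE)])
    })
    spec <- lhl_variant_spec(scaffold$structure$id, lhls, seed = made + 1L)
    v <- tryCatch(make_lhl_variant(scaffold, spec,
                                   id = sprintf("var%04d", made + 1L)),
                  error = function(e) NULL)  # rejected clash, redraw
    if (is.null(v)) next
    made <- made + 1L
    structures[[made]] <- v$structure
    annotations[[made]] <- v$annotation
    gt[[made]] <- v$ground_truth
    specs[[made]] <- spec
  }
  if (made < n) stop("could not place ", n, " clash-free variants")
  list(structures = structures, annotations = annotations,
       ground_truth = gt, specs = specs, scaffold = scaffold)
}
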