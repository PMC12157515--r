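with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Gaussian affinity matrix from an RMSD matrix
#'
#' `A_ij = exp(-d_ij^2 / (2 sigma^2))` with zero diagonal. With
#' `sigma = "median"` the bandwidth is the median off-diagonal distance,
#' a scale-free default.
#'
#' @param m An `rmsd_matrix`.
#' @param sigma Positive bandwidth in Angstrom, or `"median"`.
#' @return Symmetric affinity matrix with ids as dimnames.
#' @export
affinity_from_rmsd <- function(m, sigma = "median") {
  d <- m$values
  if (identical(sigma, "median")) sigma <- stats::median(d[upper.tri(d)])
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  a <- exp(-d^2 / (2 * sigma^2))
  diag(a) <- 0
  a
}

spectral_embed <- function(affinity, k) {
  n <- nrow(affinity)
  deg <- rowSums(affinity)
  dhalf <- 1 / sqrt(pmax(deg, 1e-12))
  lap <- diag(n) - t(affinity * dhalf) * dhalf  # symmetric normalized Laplacian
  eg <- eigen(lap, symmetric = TRUE)
  n_zero <- sum(eg$values < 1e-10)
  if (n_zero > 1)
    warning("affinity graph appears disconnected (", n_zero,
            " near-zero Laplacian eigenvalues)")
  U <- eg$vectors[, n - seq_len(k) + 1, drop = FALSE]  # k smallest eigenvalues
  norms <- sqrt(rowSums(U^2))
  U / pmax(norms, 1e-12)  # row normalization before k-means
}

#' Spectral clustering of an affinity matrix
#'
#' Embeds the points using the eigenvectors of the k smallest
#' eigenvalues of the symmetric normalized graph Laplacian
#' (row-normalized) and clusters the embedding with seeded k-means.
#' Deterministic for a fixed seed; a disconnected affinity graph is
#' reported by a warning.
#'
#' @param affinity Symmetric non-negative matrix.
#' @param k Number of clusters (<= n).
#' @param seed Integer seed for the k-means initialization.
#' @return Integer cluster labels in 1..k, named by the matrix dimnames
#'   when present.
#' @export
spectral_cluster <- function(affinity, k, seed = 1L) {
  n <- nrow(affinity)
  if (k > n) stop("k exceeds the number of points")
  emb <- spectral_embed(affinity, k)
  labels_from_embedding(emb, k, seed, rownames(affinity))
}

labels_from_embedding <- function(emb, k, seed, ids = NULL) {
  if (k == nrow(emb)) {
    lab <- seq_len(k)
  } else {
    km <- with_seed(seed, suppressWarnings(
      stats::kmeans(emb, centers = k, nstart = 10, iter.max = 100)))
    lab <- km$cluster
  }
  if (!is.null(ids)) names(lab) <- ids
  lab
}

#' Parameters of the structure-based train/test split search
#'
#' Defaults mirror the full-scale search: 25 spectral clusters, 1,000
#' clustering seeds x 1,000 random cluster bipartitions each, a 2
#' Angstrom per-helix leakage threshold and a 9:1 train:test target.
#'
#' @param n_clusters Number of spectral clusters.
#' @param n_cluster_seeds Clustering seeds tried.
#' @param n_bipartitions_per_seed Random cluster bipartitions per seed.
#' @param leakage_threshold Minimum allowed cross-split per-helix RMSD
#'   (Angstrom).
#' @param target_train_fraction Target train fraction in (0, 1).
#' @param lambda Size-balance penalty (Angstrom per unit fraction) in
#'   the candidate score.
#' @param master_seed Integer; all randomness derives from it
#'   (clustering seed i is `master_seed + i`, the bipartitions of seed i
#'   use stream `master_seed + n_cluster_seeds + i`).
#' @return Object of class `split_spec`.
#' @export
split_spec <- function(n_clusters = 25L, n_cluster_seeds = 1000L,
                       n_bipartitions_per_seed = 1000L,
                       leakage_threshold = 2.0,
                       target_train_fraction = 0.9,
                       lambda = 10, master_seed = 1L) {
  stopifnot(n_clusters >= 1, n_cluster_seeds >= 1,
            n_bipartitions_per_seed >= 1, leakage_threshold > 0,
            target_train_fraction > 0, target_train_fraction < 1)
  structure(as.list(environment()), class = "split_spec")
}

cross_violations <- function(train, test, h1, h2, thr) {
  sub1 <- h1[train, test, drop = FALSE]
  sub2 <- h2[train, test, drop = FALSE]
  which(sub1 < thr | sub2 < thr, arr.ind = TRUE)
}

#' Structure-similarity-aware train/test split search
#'
#' Searches `n_cluster_seeds` spectral clusterings of the overall helix
#' RMSD matrix times `n_bipartitions_per_seed` random bipartitions of
#' the clusters; each candidate is scored as the minimum cross-split
#' `min(helix1, helix2)` RMSD minus `lambda` times the deviation of the
#' train fraction from its target, and the best candidate is kept. The
#' winning split is then pruned: while any cross-split pair has helix 1
#' or helix 2 RMSD below the leakage threshold, the example in the most
#' violating pairs is removed (preferring the removal that best
#' approaches the target train fraction, ties toward the smaller side,
#' then lexicographic id). Finally, cross-split pairs sharing a linker
#' id are removed by the same rule, so no identical loop backbone spans
#' the split.
#'
#' @param ids Character design ids.
#' @param helix1_m,helix2_m,overall_m `rmsd_matrix` objects aligned with
#'   `ids`.
#' @param spec A `split_spec`.
#' @param linker_ids Optional list (per id) of character linker ids.
#' @return A `split_result`: `train_ids`, `test_ids`, `removed_ids`, and
#'   `provenance` (winning seed, bipartition, score, and the exact
#'   number of candidates scored). Errors with class
#'   `lhldesign_infeasible_split` when pruning empties a side.
#' @export
search_split <- function(ids, helix1_m, helix2_m, overall_m, spec,
                         linker_ids = NULL) {
  stopifnot(identical(ids, overall_m$ids), identical(ids, helix1_m$ids),
            identical(ids, helix2_m$ids))
  n <- length(ids)
  h1 <- helix1_m$values; h2 <- helix2_m$values
  dimnames(h1) <- dimnames(h2) <- list(ids, ids)
  aff <- affinity_from_rmsd(overall_m)
  emb <- spectral_embed(aff, spec$n_clusters)
  target <- spec$target_train_fraction
  best <- list(score = -Inf)
  n_cand <- 0L
  for (i in seq_len(spec$n_cluster_seeds)) {
    lab <- labels_from_embedding(emb, spec$n_clusters, spec$master_seed + i)
    rng <- local_rng(spec$master_seed + spec$n_cluster_seeds + i)
    for (j in seq_len(spec$n_bipartitions_per_seed)) {
      side <- rng$runif(spec$n_clusters) < 0.5
      n_cand <- n_cand + 1L
      in_a <- side[lab]
      na <- sum(in_a)
      if (na == 0L || na == n) next  # degenerate candidate, scored as -Inf
      # train = the side closer to the target fraction
      train_a <- abs(na / n - target) <= abs((n - na) / n - target)
      train <- if (train_a) which(in_a) else which(!in_a)
      test <- setdiff(seq_len(n), train)
      cross_min <- min(pmin(h1[train, test, drop = FALSE],
                            h2[train, test, drop = FALSE]))
      score <- cross_min - spec$lambda * abs(length(train) / n - target)
      if (score > best$score)
        best <- list(score = score, seed = i, bipartition = j,
                     train = ids[train], test = ids[test])
    }
  }
  if (!is.finite(best$score))
    stop_infeasible("no non-degenerate cluster bipartition found")
  train <- best$train; test <- best$test
  removed <- character(0)
  prune <- function(viol_fun) {
    repeat {
      if (length(train) == 0L || length(test) == 0L)
        stop_infeasible("pruning removed an entire split side")
      v <- viol_fun(train, test)
      if (nrow(v) == 0L) break
      members <- c(train[v[, 1]], test[v[, 2]])
      deg <- table(members)
      cand <- names(deg)[deg == max(deg)]
      after_frac <- vapply(cand, function(id) {
        tr <- length(train) - (id %in% train)
        te <- length(test) - (id %in% test)
        abs(tr / max(tr + te, 1) - target)
      }, numeric(1))
      cand <- cand[after_frac == min(after_frac)]
      if (length(cand) > 1L) {
        smaller <- if (length(train) <= length(test)) train else test
        in_small <- cand %in% smaller
        if (any(in_small)) cand <- cand[in_small]
      }
      drop_id <- sort(cand)[1]
      train <<- setdiff(train, drop_id)
      test <<- setdiff(test, drop_id)
      removed <<- c(removed, drop_id)
    }
  }
  prune(function(tr, te)
    cross_violations(tr, te, h1, h2, spec$leakage_threshold))
  if (!is.null(linker_ids)) {
    lk <- linker_ids
    names(lk) <- ids
    prune(function(tr, te) {
      out <- NULL
      for (a in seq_along(tr)) for (b in seq_along(te)) {
        if (length(intersect(lk[[tr[a]]], lk[[te[b]]])) > 0)
          out <- rbind(out, c(a, b))
      }
      if (is.null(out)) matrix(integer(0), 0, 2) else out
    })
  }
  structure(list(train_ids = train, test_ids = test, removed_ids = removed,
                 provenance = list(seed = best$seed,
                                   bipartition = best$bipartition,
                                   score = best$score,
                                   n_candidates = n_cand,
                                   master_seed = spec$master_seed)),
            class = "split_result")
}

stop_infeasible <- function(msg) {
  stop(structure(class = c("lhldesign_infeasible_split", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Independent validity checker for a split result
#'
#' Re-scans the per-helix RMSD matrices and linker ids and verifies the
#' split invariants: the three id sets partition the input, no
#' cross-split pair falls below the leakage threshold in either helix,
#' and no cross-split pair shares a linker id.
#'
#' @param result A `split_result`.
#' @param ids,helix1_m,helix2_m As given to [search_split()].
#' @param threshold Leakage threshold (Angstrom).
#' @param linker_ids Optional list of linker ids per design.
#' @return `TRUE`, or an error describing the first violation.
#' @export
check_split <- function(result, ids, helix1_m, helix2_m, threshold = 2.0,
                        linker_ids = NULL) {
  all_ids <- sort(c(result$train_ids, result$test_ids, result$removed_ids))
  if (!identical(all_ids, sort(ids))) stop("split does not partition the ids")
  if (length(intersect(result$train_ids, result$test_ids)))
    stop("train and test overlap")
  h1 <- helix1_m$values; h2 <- helix2_m$values
  dimnames(h1) <- dimnames(h2) <- list(ids, ids)
  v <- cross_violations(result$train_ids, result$test_ids, h1, h2, threshold)
  if (nrow(v)) stop("leakage: cross-split pair below threshold")
  if (!is.null(linker_ids)) {
    lk <- linker_ids; names(lk) <- ids
    for (a in result$train_ids) for (b in result$test_ids)
      if (length(intersect(lk[[a]], lk[[b]])))
        stop("cross-split pair shares a linker id")
  }
  TRUE
}

#' Random validation split of a training set
#'
#' The validation size is `n * fraction` rounded half up (at least 1);
#' membership is drawn by seeded uniform sampling without replacement.
#'
#' @param ids Character ids (n >= 2).
#' @param fraction Validation fraction in (0, 1), default 0.1.
#' @param seed Integer seed.
#' @return List with `train_ids` and `validation_ids`.
#' @export
validation_split <- function(ids, fraction = 0.1, seed = 1L) {
  n <- length(ids)
  stopifnot(n >= 2, fraction > 0, fraction < 1)
  n_val <- max(1L, as.integer(floor(n * fraction + 0.5)))
  rng <- local_rng(seed)
  val <- sort(rng$sample(ids, n_val))
  list(train_ids = setdiff(ids, val), validation_ids = val)
}

#' Write a split result as JSON
#'
#' @param result A `split_result`.
#' @param path Output path.
#' @export
write_split <- function(result, path) {
  jsonlite::write_json(list(train = result$train_ids,
                            test = result$test_ids,
                            removed = result$removed_ids,
                            provenance = result$provenance),
                       path, auto_unbox = TRUE)
  invisible(path)
}
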