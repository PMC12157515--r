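restrict_to_helix <- function(ann, h) {
  segment_annotation(ann$structure_id, ann$sheet_residues,
                     ann$helices[h], ann$reshaped_lhls[seq_len(0)])
}

#' All-by-all pairwise helix RMSD matrix for a group of structures
#'
#' Computes [pairwise_helix_rmsd()] for every unordered pair. `metric`
#' selects the concatenated two-helix RMSD (`"overall"`) or restricts to
#' one matched helix (`"helix1"`, `"helix2"`).
#'
#' @param structures List of `backbone`s (>= 2).
#' @param annotations Index-aligned list of `segment_annotation`s with
#'   position-matched sheets and equal helix counts.
#' @param metric `"overall"`, `"helix1"` or `"helix2"`.
#' @param ids Design ids (default structure ids).
#' @return An `rmsd_matrix`: list with `ids` and symmetric `values`
#'   matrix (Angstrom, zero diagonal).
#' @export
pairwise_matrix <- function(structures, annotations,
                            metric = c("overall", "helix1", "helix2"),
                            ids = NULL) {
  metric <- match.arg(metric)
  n <- length(structures)
  if (n < 2L) stop("need at least 2 structures")
  if (length(annotations) != n) stop("one annotation per structure required")
  if (is.null(ids)) ids <- vapply(structures, `[[`, "", "id")
  anns <- switch(metric,
                 overall = annotations,
                 helix1 = lapply(annotations, restrict_to_helix, h = 1L),
                 helix2 = lapply(annotations, restrict_to_helix, h = 2L))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- pairwise_helix_rmsd(structures[[i]], structures[[j]],
                                              anns[[i]], anns[[j]])
  }
  rmsd_matrix(ids, m)
}

#' Construct / validate an RMSD matrix container
#'
#' @param ids Ordered character ids.
#' @param values Symmetric non-negative matrix with zero diagonal.
#' @return Object of class `rmsd_matrix`.
#' @export
rmsd_matrix <- function(ids, values) {
  values <- as.matrix(values)
  if (nrow(values) != length(ids) || ncol(values) != length(ids))
    stop("matrix dimensions do not match ids")
  if (max(abs(values - t(values))) > 1e-6) stop("matrix must be symmetric")
  if (any(values < 0)) stop("distances must be non-negative")
  if (any(abs(diag(values)) > 1e-9)) stop("diagonal must be zero")
  dimnames(values) <- list(ids, ids)
  structure(list(ids = as.character(ids), values = values),
            class = "rmsd_matrix")
}

upper_vals <- function(m) m$values[upper.tri(m$values)]

#' Summary statistics of a group's pairwise RMSD distribution
#'
#' Statistics are over the n(n-1)/2 distinct pairs. Quartiles use linear
#' interpolation between order statistics (type 7); whiskers extend to
#' the most extreme values within 1.5 interquartile ranges of the
#' quartiles.
#'
#' @param m An `rmsd_matrix`.
#' @param label Group label.
#' @return One-row data frame: group, n_pairs, mean, median, q1, q3,
#'   whisker_lo, whisker_hi (Angstrom).
#' @export
summarize_group <- function(m, label = "group") {
  v <- upper_vals(m)
  if (length(v) < 1L) stop("need at least 2 structures")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- min(v[v >= q[1] - 1.5 * iqr])
  hi <- max(v[v <= q[3] + 1.5 * iqr])
  data.frame(group = label, n_pairs = length(v), mean = mean(v),
             median = q[2], q1 = q[1], q3 = q[3],
             whisker_lo = lo, whisker_hi = hi, stringsAsFactors = FALSE)
}

#' Sample structures at even intervals of RMSD to a reference
#'
#' Sorts the structures by their pairwise helix RMSD to the reference
#' and picks indices `round(j (n-1)/(k-1)) + 1` for j = 0..k-1 (the
#' median element when k = 1), so the minimum and maximum are always
#' included for k >= 2.
#'
#' @param structures,annotations Index-aligned lists.
#' @param reference,ann_reference The reference structure and its
#'   helix-matched annotation.
#' @param k Number of structures to pick (1 <= k <= n).
#' @return Integer vector of selected positions into `structures`, in
#'   ascending reference-RMSD order, with the RMSDs as names.
#' @export
even_interval_sample <- function(structures, annotations, reference,
                                 ann_reference, k) {
  n <- length(structures)
  if (k > n) stop("k exceeds the number of structures")
  if (k < 1) stop("k must be at least 1")
  d <- vapply(seq_len(n), function(i)
    pairwise_helix_rmsd(reference, structures[[i]],
                        ann_reference, annotations[[i]]), numeric(1))
  ord <- order(d)
  pick <- if (k == 1) ord[floor((n + 1) / 2)]
          else ord[round((seq_len(k) - 1) * (n - 1) / (k - 1)) + 1]
  stats::setNames(pick, sprintf("%.3f", d[pick]))
}

#' Negative pseudo-log-likelihood over selected positions
#'
#' Sums `-log(p_i)` (natural log) over the requested residue positions,
#' consuming externally computed per-position probabilities of the
#' designed residue given the structure.
#'
#' @param per_position_probs Named numeric vector, names are residue
#'   indices, values in (0, 1\].
#' @param positions Integer positions to aggregate over.
#' @return Score in nats (>= 0).
#' @export
neg_pll <- function(per_position_probs, positions) {
  key <- as.character(positions)
  miss <- setdiff(key, names(per_position_probs))
  if (length(miss)) stop("missing positions: ", paste(miss, collapse = ", "))
  p <- unname(per_position_probs[key])
  if (any(p <= 0 | p > 1)) stop("probabilities must be in (0, 1]")
  sum(-log(p))
}

#' Bin scores by an aligned RMSD value
#'
#' Bins are half-open `[e_k, e_{k+1})` over the strictly increasing
#' `edges`, plus a final overflow bin `[e_last, Inf)`. Values below the
#' first edge are excluded (their count is reported).
#'
#' @param scores,rmsds Index-aligned numeric vectors.
#' @param edges Strictly increasing breakpoints (Angstrom).
#' @return Data frame with one row per bin: bin label, n, median, q1,
#'   q3; attribute `n_below` counts values below the first edge.
#' @export
bin_scores_by_rmsd <- function(scores, rmsds, edges) {
  if (length(scores) != length(rmsds)) stop("scores and rmsds differ in length")
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  lows <- edges
  highs <- c(edges[-1], Inf)
  rows <- lapply(seq_along(lows), function(b) {
    sel <- rmsds >= lows[b] & rmsds < highs[b]
    v <- scores[sel]
    q <- if (length(v)) stats::quantile(v, c(0.25, 0.5, 0.75), type = 7,
                                        names = FALSE) else rep(NA_real_, 3)
    data.frame(bin = if (is.finite(highs[b]))
                 sprintf("[%g,%g)", lows[b], highs[b])
               else sprintf("[%g,Inf)", lows[b]),
               n = length(v), median = q[2], q1 = q[1], q3 = q[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_below") <- sum(rmsds < edges[1])
  out
}

#' Two-sample two-sided t-test helper for group comparisons
#'
#' Thin wrapper over [stats::t.test()] used when comparing helix-RMSD
#' distributions between design subsets.
#'
#' @param x,y Numeric samples.
#' @return The `htest` object.
#' @export
compare_groups_ttest <- function(x, y) {
  stats::t.test(x, y, alternative = "two.sided")
}

#' Read or write a square RMSD matrix as TSV
#'
#' The TSV is square with an id header row and a leading id column.
#'
#' @param m An `rmsd_matrix` (for writing).
#' @param path File path.
#' @return `read_rmsd_matrix` returns an `rmsd_matrix`.
#' @export
write_rmsd_matrix <- function(m, path) {
  df <- data.frame(id = m$ids, m$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rmsd_matrix
#' @export
read_rmsd_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  rmsd_matrix(ids, as.matrix(df[, -1, drop = FALSE]))
}
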