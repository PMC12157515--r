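#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `mobile` onto `target`. Reflections are excluded by correcting the
#' sign of the smallest singular direction, so the result is always a
#' rigid motion.
#'
#' @param mobile,target m x 3 coordinate matrices, m >= 3, position
#'   matched.
#' @return A list of class `rigid_transform` with elements `rotation`
#'   (3 x 3), `translation` (length 3) and `rmsd` (Angstrom). The motion
#'   maps a point `x` to `rotation %*% x + translation`.
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target))) stop("point sets differ in size")
  if (nrow(mobile) < 3L) stop("need at least 3 points")
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  structure(list(rotation = R, translation = drop(ct - R %*% cm),
                 rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to a point matrix
#' @param points m x 3 matrix.
#' @param tf A `rigid_transform`.
#' @return Transformed m x 3 matrix.
#' @export
apply_transform <- function(points, tf) {
  sweep(as.matrix(points) %*% t(tf$rotation), 2, tf$translation, `+`)
}

rmsd_points <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' 6D helix vector: centroid plus N-to-C direction
#'
#' The centroid is the mean over all N, CA, C, O atoms of the helix
#' residues. The direction is the normalized mean of the per-residue unit
#' carbonyl C-to-O vectors, sign-flipped when needed so that it points
#' from the helix N terminus to the C terminus (positive dot product with
#' CA_last - CA_first); in a regular alpha helix the carbonyls align with
#' the axis, so this mean is a robust axis estimate.
#'
#' @param s A `backbone`.
#' @param helix_range Inclusive residue range `c(from, to)`.
#' @return List of class `helix_vector` with `centroid`, `direction`
#'   (unit), `helix_range`, `n_residues`.
#' @export
helix_vector <- function(s, helix_range) {
  resi <- range_seq(helix_range)
  pts <- bb_coords(s, resi, atoms = c("N", "CA", "C", "O"))
  centroid <- colMeans(pts)
  idx <- match(resi, s$resi)
  co <- t(vapply(idx, function(k) {
    v <- s$xyz[k, "O", ] - s$xyz[k, "C", ]
    v / sqrt(sum(v^2))
  }, numeric(3)))
  dir <- colMeans(co)
  dir <- dir / sqrt(sum(dir^2))
  nc <- s$xyz[idx[length(idx)], "CA", ] - s$xyz[idx[1], "CA", ]
  if (sum(dir * nc) < 0) dir <- -dir
  structure(list(centroid = centroid, direction = dir,
                 helix_range = as.integer(helix_range[1:2]),
                 n_residues = length(resi)),
            class = "helix_vector")
}

#' Trim two helix ranges to their longest common length
#'
#' The shorter range is unchanged; the longer is reduced to the central
#' window of the shorter's length. When the total trim is odd, the extra
#' kept residue is N-terminal: floor(d/2) residues are trimmed from the N
#' side and ceiling(d/2) from the C side.
#'
#' @param range_a,range_b Inclusive integer ranges.
#' @return List with elements `a` and `b`, equal-length ranges.
#' @export
trim_to_common <- function(range_a, range_b) {
  la <- range_a[2] - range_a[1] + 1L
  lb <- range_b[2] - range_b[1] + 1L
  if (la <= 0 || lb <= 0) stop("ranges must be non-empty")
  trim <- function(r, keep) {
    d <- (r[2] - r[1] + 1L) - keep
    c(r[1] + floor(d / 2), r[2] - ceiling(d / 2))
  }
  keep <- min(la, lb)
  list(a = as.integer(trim(range_a, keep)), b = as.integer(trim(range_b, keep)))
}

#' Sheet-aligned pairwise helix RMSD
#'
#' Aligns structure `b` onto structure `a` using the backbone atoms of
#' their position-matched sheet residues, trims each matched helix pair
#' to the longest common length ([trim_to_common()]), and reports one
#' RMSD over the concatenated backbone atoms of all matched trimmed
#' helices, without re-superposing on the helices. This measures how
#' differently two structures place their helices relative to the shared
#' sheet.
#'
#' @param a,b `backbone` structures.
#' @param ann_a,ann_b Their `segment_annotation`s; must carry
#'   equally many sheet residues (position matched) and equally many
#'   helices. The `helices` slot is used; pass a restricted annotation to
#'   compare a single helix.
#' @param atoms Atom set for all RMSDs: `"backbone"` (N, CA, C, O;
#'   default) or `"CA"`.
#' @return RMSD in Angstrom.
#' @export
pairwise_helix_rmsd <- function(a, b, ann_a, ann_b, atoms = c("backbone", "CA")) {
  atoms <- match.arg(atoms)
  aset <- if (atoms == "backbone") c("N", "CA", "C", "O") else "CA"
  if (length(ann_a$sheet_residues) != length(ann_b$sheet_residues))
    stop("sheet residue counts differ")
  if (length(ann_a$helices) != length(ann_b$helices))
    stop("helix counts differ")
  tf <- superpose(bb_coords(b, ann_b$sheet_residues, aset),
                  bb_coords(a, ann_a$sheet_residues, aset))
  pa <- pb <- NULL
  for (h in seq_along(ann_a$helices)) {
    tr <- trim_to_common(ann_a$helices[[h]], ann_b$helices[[h]])
    pa <- rbind(pa, bb_coords(a, range_seq(tr$a), aset))
    pb <- rbind(pb, bb_coords(b, range_seq(tr$b), aset))
  }
  rmsd_points(pa, apply_transform(pb, tf))
}

#' Reshaped-LHL RMSD between a prediction and its design model
#'
#' Superposes the prediction onto the design using the backbone atoms of
#' all residues outside every reshaped LHL range, then computes the RMSD
#' over the backbone atoms of the reshaped LHL residues. Both structures
#' must have the same residue count.
#'
#' @param prediction,design `backbone` structures of equal length.
#' @param annotation A `segment_annotation` with `reshaped_lhls`.
#' @param atoms `"backbone"` or `"CA"`.
#' @return RMSD in Angstrom.
#' @export
lhl_rmsd <- function(prediction, design, annotation, atoms = c("backbone", "CA")) {
  atoms <- match.arg(atoms)
  aset <- if (atoms == "backbone") c("N", "CA", "C", "O") else "CA"
  if (length(prediction$resi) != length(design$resi))
    stop("structures differ in residue count")
  lhl <- lhl_residues(annotation)
  fixed <- setdiff(design$resi, lhl)
  tf <- superpose(bb_coords(prediction, fixed, aset),
                  bb_coords(design, fixed, aset))
  rmsd_points(apply_transform(bb_coords(prediction, lhl, aset), tf),
              bb_coords(design, lhl, aset))
}

#' LHL RMSD of a prediction ensemble
#'
#' `selector = "lowest"` returns the minimum [lhl_rmsd()] over members
#' (the convention for filtering); `"rank1"` returns the LHL RMSD of the
#' member with the highest pLDDT, ties broken toward the first member.
#'
#' @param ensemble A `prediction_ensemble` (see
#'   [prediction_ensemble()]).
#' @param design,annotation As in [lhl_rmsd()].
#' @param selector `"lowest"` or `"rank1"`.
#' @return RMSD in Angstrom.
#' @export
ensemble_lhl_rmsd <- function(ensemble, design, annotation,
                              selector = c("lowest", "rank1")) {
  selector <- match.arg(selector)
  rmsds <- vapply(ensemble$members,
                  function(m) lhl_rmsd(m$structure, design, annotation),
                  numeric(1))
  if (selector == "lowest") return(min(rmsds))
  rmsds[[which.max(vapply(ensemble$members, `[[`, numeric(1), "plddt"))]]
}

#' Bundle predicted models with their pLDDT confidences
#'
#' @param design_id Character id.
#' @param structures List of `backbone` objects.
#' @param plddts Numeric vector in \[0, 100\], one per structure.
#' @return Object of class `prediction_ensemble` with a `members` list of
#'   `(structure, plddt)` pairs.
#' @export
prediction_ensemble <- function(design_id, structures, plddts) {
  if (length(structures) < 1L) stop("ensemble needs at least one member")
  if (length(structures) != length(plddts)) stop("plddt per structure required")
  if (any(!is.finite(plddts))) stop("plddt must be finite")
  structure(list(design_id = as.character(design_id),
                 members = Map(function(s, p) list(structure = s, plddt = p),
                               structures, as.numeric(plddts))),
            class = "prediction_ensemble")
}

#' Idealization-bias statistics of predictions
#'
#' For each (design, prediction) pair, compares the sheet-aligned helix
#' RMSD of the prediction to an idealized reference structure
#' (`d_ref`) with its RMSD to its own design model (`d_design`).
#' Predictions systematically landing nearer the idealized reference
#' than the model they were predicted from reveal a bias toward
#' idealized geometries.
#'
#' @param designs,predictions Lists of `backbone`s, index aligned.
#' @param reference The idealized reference `backbone`.
#' @param ann_designs,ann_predictions Lists of `segment_annotation`s,
#'   index aligned with the structures.
#' @param ann_reference Annotation of the reference, helix-matched.
#' @param margin Margin in Angstrom for the strong-bias fraction
#'   (default 1.0).
#' @return List with `frac_closer_to_ref` (fraction with
#'   `d_ref < d_design`; ties count as not closer) and
#'   `frac_margin_closer` (fraction with `d_design - d_ref > margin`),
#'   plus the per-item distances `d_ref`, `d_design`.
#' @export
bias_statistics <- function(designs, predictions, reference,
                            ann_designs, ann_predictions, ann_reference,
                            margin = 1.0) {
  n <- length(designs)
  if (length(predictions) != n || length(ann_designs) != n ||
      length(ann_predictions) != n)
    stop("designs, predictions and annotations must be index aligned")
  d_ref <- d_design <- numeric(n)
  for (i in seq_len(n)) {
    d_ref[i] <- pairwise_helix_rmsd(reference, predictions[[i]],
                                    ann_reference, ann_predictions[[i]])
    d_design[i] <- pairwise_helix_rmsd(designs[[i]], predictions[[i]],
                                       ann_designs[[i]], ann_predictions[[i]])
  }
  list(frac_closer_to_ref = mean(d_ref < d_design),
       frac_margin_closer = mean(d_design - d_ref > margin),
       d_ref = d_ref, d_design = d_design)
}

#' Specification of the 6D geometry binning
#'
#' Position space is divided into cubes of edge `cube_edge` (default
#' 2 Angstrom) anchored at `origin`; direction space is divided into 8
#' sign octants within each cube, giving 6-dimensional bins.
#'
#' @param cube_edge Cube edge length in Angstrom (> 0).
#' @param origin Length-3 origin of the grid.
#' @return Object of class `bin_spec`.
#' @export
bin_spec <- function(cube_edge = 2.0, origin = c(0, 0, 0)) {
  if (cube_edge <= 0) stop("cube_edge must be positive")
  structure(list(cube_edge = cube_edge, origin = as.numeric(origin)),
            class = "bin_spec")
}

#' 6D bin index of a helix vector
#'
#' Cube indices are `floor((centroid - origin)/cube_edge)` per axis; the
#' octant signs are `"+"` when the direction component is >= 0 (a zero
#' component counts as `"+"`). Octants are taken in the global frame in
#' which the structures were mutually aligned.
#'
#' @param v A `helix_vector`.
#' @param spec A `bin_spec`.
#' @return List with integer `cube` (ix, iy, iz), character `octant`
#'   (three signs) and a single string `key`.
#' @export
bin_index <- function(v, spec = bin_spec()) {
  i <- as.integer(floor((v$centroid - spec$origin) / spec$cube_edge))
  s <- ifelse(v$direction >= 0, "+", "-")
  list(cube = i, octant = s,
       key = paste0(i[1], ":", i[2], ":", i[3], ":", paste(s, collapse = "")))
}

#' Fraction of geometry bins occupied by a subset of helix vectors
#'
#' @param subset,universe Lists of `helix_vector`s; the subset should
#'   come from a subset of the universe's designs.
#' @param spec A `bin_spec`.
#' @return `|bins(subset)| / |bins(universe)|` in \[0, 1\].
#' @export
bin_occupancy <- function(subset, universe, spec = bin_spec()) {
  if (length(universe) == 0L) stop("universe must be non-empty")
  keys <- function(vs) unique(vapply(vs, function(v) bin_index(v, spec)$key, ""))
  length(keys(subset)) / length(keys(universe))
}

#' Which face of the beta sheet a helix sits on
#'
#' Fits a plane to the sheet CA atoms and reports the sign of the dot
#' product between the plane normal and the vector from the sheet CA
#' centroid to the helix centroid. The normal's orientation is fixed
#' reproducibly: it must have positive dot product with the cross
#' product of the first two non-collinear inter-CA sheet vectors, so the
#' sign is stable for a given sheet residue ordering. A helix centroid
#' exactly in the plane returns +1.
#'
#' @param s A `backbone`.
#' @param helix_range Inclusive residue range of the helix.
#' @param sheet_residues Integer vector (>= 4) of sheet residues.
#' @return `+1` or `-1`.
#' @export
sheet_face <- function(s, helix_range, sheet_residues) {
  if (length(sheet_residues) < 4L) stop("need at least 4 sheet residues")
  ca <- bb_coords(s, sheet_residues, atoms = "CA")
  cen <- colMeans(ca)
  M <- sweep(ca, 2, cen)
  sv <- svd(M)
  if (sv$d[2] < 1e-8) stop("degenerate (collinear) sheet geometry")
  normal <- sv$v[, 3]
  ref <- NULL
  v1 <- ca[2, ] - ca[1, ]
  for (k in 3:nrow(ca)) {
    v2 <- ca[k, ] - ca[1, ]
    cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
            v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
    if (sqrt(sum(cr^2)) > 1e-8) { ref <- cr; break }
  }
  if (is.null(ref)) stop("degenerate (collinear) sheet geometry")
  if (sum(normal * ref) < 0) normal <- -normal
  h <- helix_vector(s, helix_range)$centroid
  if (sum(normal * (h - cen)) >= 0) 1L else -1L
}

virtual_cb <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  a <- c(b[2] * cc[3] - b[3] * cc[2],
         b[3] * cc[1] - b[1] * cc[3],
         b[1] * cc[2] - b[2] * cc[1])
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + ca
}

cb_or_virtual <- function(s, k) {
  p <- s$xyz[k, "CB", ]
  if (all(is.finite(p))) return(p)
  virtual_cb(s$xyz[k, "N", ], s$xyz[k, "CA", ], s$xyz[k, "C", ])
}

#' Shell residues around the reshaped LHL elements
#'
#' Shell 1 contains all reshaped LHL residues plus any residue that is
#' (i) within `shell1_distance` (CA-CA, default 10 Angstrom) of any LHL
#' residue and (ii) pointed toward any LHL residue. Shell 2 contains all
#' shell 1 residues plus any residue within `shell2_distance` (default
#' 8 Angstrom) of any shell 1 residue and pointed toward a shell 1
#' residue. Residue i "points toward" residue j when the angle between
#' (CB_i - CA_i) and (CA_j - CA_i) is below 90 degrees; glycines (and
#' any residue lacking CB) use a virtual CB built from ideal tetrahedral
#' geometry.
#'
#' @param s A `backbone`.
#' @param annotation A `segment_annotation` with `reshaped_lhls`.
#' @param shell 1 or 2.
#' @param shell1_distance,shell2_distance Cutoffs in Angstrom.
#' @return Sorted integer vector of residue numbers.
#' @export
shell_residues <- function(s, annotation, shell = 1,
                           shell1_distance = 10.0, shell2_distance = 8.0) {
  if (!shell %in% c(1, 2)) stop("shell must be 1 or 2")
  if (shell1_distance <= 0 || shell2_distance <= 0)
    stop("shell distances must be positive")
  ca <- bb_coords(s, atoms = "CA")
  cb <- t(vapply(seq_along(s$resi), function(k) cb_or_virtual(s, k), numeric(3)))
  grow <- function(core, cutoff) {
    core_idx <- match(core, s$resi)
    add <- logical(length(s$resi))
    for (k in seq_along(s$resi)) {
      if (s$resi[k] %in% core) next
      d <- sqrt(rowSums(sweep(ca[core_idx, , drop = FALSE], 2, ca[k, ])^2))
      if (min(d) > cutoff) next
      u <- cb[k, ] - ca[k, ]
      toward <- any(apply(ca[core_idx, , drop = FALSE], 1,
                          function(p) sum(u * (p - ca[k, ])) > 0))
      add[k] <- toward
    }
    sort(unique(c(core, s$resi[add])))
  }
  s1 <- grow(lhl_residues(annotation), shell1_distance)
  if (shell == 1) return(s1)
  grow(s1, shell2_distance)
}

#' Minimum-helical-length filter for reshaped LHL units
#'
#' Passes only when every reshaped LHL contains at least `min_len`
#' helical residues (helix ranges intersected with the LHL range); an
#' LHL with no assigned helix fails.
#'
#' @param annotation A `segment_annotation` with both `helices` and
#'   `reshaped_lhls`.
#' @param min_len Minimum helical residue count (default 7, boundary
#'   inclusive).
#' @return Logical flag.
#' @export
min_helix_length_filter <- function(annotation, min_len = 7L) {
  for (lhl in annotation$reshaped_lhls) {
    n_hel <- 0L
    for (h in annotation$helices)
      n_hel <- n_hel + length(intersect(range_seq(h), range_seq(lhl)))
    if (n_hel < min_len) return(FALSE)
  }
  TRUE
}
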