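#' Construct a backbone structure
#'
#' A `backbone` holds the ordered residues of one protein chain with the
#' four backbone heavy atoms (N, CA, C, O) and, optionally, CB. It is the
#' unit of all geometric analysis in the package.
#'
#' @param id Character identifier for the structure.
#' @param resi Integer vector of 1-based residue numbers, strictly
#'   increasing.
#' @param aa Character vector of one-letter amino-acid codes (`"X"` for
#'   non-standard residues), same length as `resi`.
#' @param xyz Numeric array of dimension `c(n, 5, 3)` with second
#'   dimension named `N, CA, C, O, CB` (CB rows may be `NA`) holding
#'   coordinates in Angstrom.
#' @return An object of class `backbone`.
#' @export
backbone <- function(id, resi, aa, xyz) {
  s <- structure(list(id = as.character(id),
                      resi = as.integer(resi),
                      aa = as.character(aa),
                      xyz = xyz),
                 class = "backbone")
  validate_backbone(s)
  s
}

#' Validate a backbone structure
#'
#' Checks the class invariants: strictly increasing residue numbers, all
#' four backbone atoms present with finite coordinates, and consistent
#' dimensions.
#'
#' @param s A `backbone` object.
#' @return `s`, invisibly. Errors describe the first violated invariant.
#' @export
validate_backbone <- function(s) {
  stopifnot(inherits(s, "backbone"))
  n <- length(s$resi)
  if (n < 1L) stop("backbone has no residues")
  if (any(diff(s$resi) <= 0L)) stop("residue indices must be strictly increasing")
  if (length(s$aa) != n) stop("aa and resi lengths differ")
  d <- dim(s$xyz)
  if (length(d) != 3L || d[1] != n || d[2] != 5L || d[3] != 3L)
    stop("xyz must be an n x 5 x 3 array")
  atoms <- dimnames(s$xyz)[[2]]
  if (!identical(atoms, c("N", "CA", "C", "O", "CB")))
    stop("xyz atom dimension must be N, CA, C, O, CB")
  core <- s$xyz[, c("N", "CA", "C", "O"), , drop = FALSE]
  bad <- which(apply(core, 1, function(m) any(!is.finite(m))))
  if (length(bad))
    stop("missing or non-finite backbone atom at residue ", s$resi[bad[1]])
  invisible(s)
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("<backbone> %s: %d residues (%d-%d), CB present for %d\n",
              x$id, length(x$resi), min(x$resi), max(x$resi),
              sum(stats::complete.cases(x$xyz[, "CB", , drop = TRUE]))))
  invisible(x)
}

#' Extract backbone coordinates as a point matrix
#'
#' Stacks the requested atoms of the requested residues, residue-major,
#' into an m x 3 coordinate matrix. This ordering convention is shared by
#' every RMSD in the package, so that position-matched structures produce
#' position-matched point sets.
#'
#' @param s A `backbone`.
#' @param resi Residue numbers to extract (default: all). Order is kept.
#' @param atoms Atom names among N, CA, C, O, CB (default backbone four).
#' @return Numeric matrix with 3 columns.
#' @export
bb_coords <- function(s, resi = NULL, atoms = c("N", "CA", "C", "O")) {
  if (is.null(resi)) resi <- s$resi
  idx <- match(resi, s$resi)
  if (anyNA(idx)) stop("residues not in structure: ",
                       paste(resi[is.na(idx)], collapse = ", "))
  out <- matrix(NA_real_, length(idx) * length(atoms), 3)
  for (k in seq_along(idx)) {
    out[((k - 1) * length(atoms) + 1):(k * length(atoms)), ] <-
      s$xyz[idx[k], atoms, , drop = TRUE]
  }
  if (any(!is.finite(out))) stop("requested atoms missing for some residues")
  out
}

#' Apply a rigid transform to whole or part of a backbone
#'
#' @param s A `backbone`.
#' @param tf A `rigid_transform` (see [superpose()]).
#' @param resi Residues to move (default all).
#' @return The transformed `backbone`.
#' @export
transform_backbone <- function(s, tf, resi = NULL) {
  if (is.null(resi)) resi <- s$resi
  idx <- match(resi, s$resi)
  for (k in idx) {
    for (a in c("N", "CA", "C", "O", "CB")) {
      p <- s$xyz[k, a, ]
      if (all(is.finite(p)))
        s$xyz[k, a, ] <- drop(tf$rotation %*% p) + tf$translation
    }
  }
  s
}

#' Read a backbone from PDB text or file
#'
#' Parses ATOM records (via bio3d) for one chain, keeping the first
#' alternate location (blank or `"A"`) and rejecting insertion codes,
#' which do not occur in designed or predicted models. Every residue must
#' carry N, CA, C and O; CB is kept when present. Non-standard residues
#' get the one-letter code `"X"`.
#'
#' @param pdb Either a file path or a character scalar/vector of PDB text.
#' @param chain Optional chain identifier; default: first chain in file.
#' @param id Structure id; defaults to the file name or `"structure"`.
#' @return A `backbone`.
#' @export
read_backbone <- function(pdb, chain = NULL, id = NULL) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    path <- pdb
    if (is.null(id)) id <- sub("\\.pdb$", "", basename(path))
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(paste(pdb, collapse = "\n"), "\n")), path)
    if (is.null(id)) id <- "structure"
  }
  p <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- p$atom[p$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records found")
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[is.na(at$chain) | at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("empty chain: ", chain)
  if (any(!is.na(at$insert))) stop("insertion codes are not supported")
  at <- at[is.na(at$alt) | at$alt == "A", , drop = FALSE]
  resno <- unique(at$resno)
  n <- length(resno)
  xyz <- array(NA_real_, c(n, 5, 3),
               dimnames = list(NULL, c("N", "CA", "C", "O", "CB"), NULL))
  aa <- character(n)
  for (k in seq_len(n)) {
    rows <- at[at$resno == resno[k], , drop = FALSE]
    aa[k] <- suppressWarnings(bio3d::aa321(rows$resid[1]))
    if (is.na(aa[k]) || !aa[k] %in% c(LETTERS)) aa[k] <- "X"
    for (a in c("N", "CA", "C", "O", "CB")) {
      hit <- which(rows$elety == a)
      if (length(hit)) xyz[k, a, ] <- as.numeric(rows[hit[1], c("x", "y", "z")])
    }
    if (any(!is.finite(xyz[k, c("N", "CA", "C", "O"), ])))
      stop("missing backbone atom (N/CA/C/O) at residue ", resno[k])
  }
  backbone(id, resno, aa, xyz)
}

aa123_safe <- function(aa1) {
  out <- suppressWarnings(bio3d::aa123(aa1))
  out[is.na(out) | aa1 == "X"] <- "UNK"
  out
}

#' Write a backbone as PDB-format text
#'
#' Emits standard fixed-width ATOM records with 3-decimal coordinates in
#' residue order (N, CA, C, O, then CB when present) and a final TER/END.
#'
#' @param s A `backbone`.
#' @param file Optional path; when given the text is also written there.
#' @return Character vector of PDB lines, invisibly when `file` is given.
#' @export
write_backbone <- function(s, file = NULL) {
  validate_backbone(s)
  res3 <- aa123_safe(s$aa)
  lines <- character(0)
  serial <- 0L
  for (k in seq_along(s$resi)) {
    for (a in c("N", "CA", "C", "O", "CB")) {
      p <- s$xyz[k, a, ]
      if (any(!is.finite(p))) next
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, paste0(" ", a), res3[k], "A", s$resi[k],
        p[1], p[2], p[3], 1, 0, substr(a, 1, 1)))
    }
  }
  lines <- c(lines, sprintf("TER   %5d      %3s %s%4d",
                            serial + 1L, res3[length(res3)], "A",
                            s$resi[length(s$resi)]),
             "END")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Construct a segment annotation
#'
#' Carries, for one structure: the beta-sheet residues (a position-matched
#' list across comparable structures), the helix ranges, the reshaped
#' loop-helix-loop (LHL) ranges, and optionally one opaque linker
#' identifier per reshaped LHL (two structures sharing a linker id carry
#' an identical loop backbone).
#'
#' @param structure_id Character id of the annotated structure.
#' @param sheet_residues Integer vector of sheet residue numbers.
#' @param helices List of length-2 integer vectors `c(from, to)`,
#'   inclusive, sorted, non-overlapping.
#' @param reshaped_lhls List of length-2 integer vectors, inclusive.
#' @param linker_ids Optional character vector, one per reshaped LHL.
#' @return An object of class `segment_annotation`.
#' @export
segment_annotation <- function(structure_id, sheet_residues,
                               helices = list(), reshaped_lhls = list(),
                               linker_ids = NULL) {
  norm_ranges <- function(x) lapply(x, function(r) as.integer(r[1:2]))
  ann <- structure(list(structure_id = as.character(structure_id),
                        sheet_residues = as.integer(sheet_residues),
                        helices = norm_ranges(helices),
                        reshaped_lhls = norm_ranges(reshaped_lhls),
                        linker_ids = if (!is.null(linker_ids)) as.character(linker_ids)),
                   class = "segment_annotation")
  for (r in c(ann$helices, ann$reshaped_lhls))
    if (r[2] < r[1]) stop("empty range: ", r[1], "-", r[2])
  ov <- function(rs) {
    if (length(rs) < 2) return(FALSE)
    m <- do.call(rbind, rs)[order(vapply(rs, `[`, 1L, 1)), , drop = FALSE]
    any(m[-1, 1] <= m[-nrow(m), 2])
  }
  if (ov(ann$helices)) stop("helix ranges overlap")
  if (ov(ann$reshaped_lhls)) stop("reshaped LHL ranges overlap")
  if (!is.null(ann$linker_ids) && length(ann$linker_ids) != length(ann$reshaped_lhls))
    stop("need one linker_id per reshaped LHL")
  ann
}

range_seq <- function(r) seq.int(r[1], r[2])

#' Residues covered by the reshaped LHL ranges of an annotation
#' @param ann A `segment_annotation`.
#' @return Sorted integer vector.
#' @export
lhl_residues <- function(ann) {
  sort(unique(unlist(lapply(ann$reshaped_lhls, range_seq))))
}

#' Read or write segment annotations as JSON
#'
#' The JSON layout is
#' `{"structure_id":..., "sheet_residues":[...], "helices":[[a,b],...],
#'   "reshaped_lhls":[[a,b],...], "linker_ids":[...]}`.
#'
#' @param path File path.
#' @return `read_annotation` returns a `segment_annotation`.
#' @export
read_annotation <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  to_ranges <- function(x) {
    if (is.null(x) || length(x) == 0) return(list())
    if (is.matrix(x)) return(lapply(seq_len(nrow(x)), function(i) x[i, ]))
    x
  }
  segment_annotation(j$structure_id, j$sheet_residues,
                     to_ranges(j$helices), to_ranges(j$reshaped_lhls),
                     j$linker_ids)
}

#' @rdname read_annotation
#' @param ann A `segment_annotation` to serialize.
#' @export
write_annotation <- function(ann, path) {
  x <- list(structure_id = ann$structure_id,
            sheet_residues = ann$sheet_residues,
            helices = lapply(ann$helices, as.integer),
            reshaped_lhls = lapply(ann$reshaped_lhls, as.integer))
  if (!is.null(ann$linker_ids)) x$linker_ids <- ann$linker_ids
  jsonlite::write_json(x, path, auto_unbox = TRUE)
  invisible(path)
}

dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Backbone phi/psi dihedral angles
#'
#' @param s A `backbone`.
#' @return Data frame with columns `resi`, `phi`, `psi` in degrees;
#'   terminal angles are `NA`.
#' @export
backbone_dihedrals <- function(s) {
  n <- length(s$resi)
  phi <- psi <- rep(NA_real_, n)
  consec <- c(FALSE, diff(s$resi) == 1L)
  for (k in seq_len(n)) {
    if (k > 1 && consec[k])
      phi[k] <- dihedral(s$xyz[k - 1, "C", ], s$xyz[k, "N", ],
                         s$xyz[k, "CA", ], s$xyz[k, "C", ])
    if (k < n && consec[k + 1])
      psi[k] <- dihedral(s$xyz[k, "N", ], s$xyz[k, "CA", ],
                         s$xyz[k, "C", ], s$xyz[k + 1, "N", ])
  }
  data.frame(resi = s$resi, phi = phi, psi = psi)
}

#' Assign helices from backbone dihedrals
#'
#' Labels a residue helical when its (phi, psi) falls in the alpha-helical
#' window phi in \[-100, -30\] and psi in \[-80, +5\] degrees, and reports
#' maximal runs of at least `min_length` consecutive helical residues.
#' Annotation-supplied helix ranges, when available, take precedence over
#' this assigner throughout the package.
#'
#' @param s A `backbone` with at least 3 residues.
#' @param min_length Minimum run length (default 4).
#' @return List of inclusive residue ranges `c(from, to)`, sorted,
#'   non-overlapping; empty list when no helix is found.
#' @export
assign_helices <- function(s, min_length = 4L) {
  if (length(s$resi) < 3L) stop("need at least 3 residues")
  dh <- backbone_dihedrals(s)
  hel <- !is.na(dh$phi) & !is.na(dh$psi) &
    dh$phi >= -100 & dh$phi <= -30 & dh$psi >= -80 & dh$psi <= 5
  ranges <- list()
  k <- 1L
  n <- length(hel)
  while (k <= n) {
    if (hel[k]) {
      j <- k
      while (j < n && hel[j + 1] && s$resi[j + 1] == s$resi[j] + 1L) j <- j + 1L
      if (j - k + 1L >= min_length)
        ranges[[length(ranges) + 1L]] <- c(s$resi[k], s$resi[j])
      k <- j + 1L
    } else k <- k + 1L
  }
  ranges
}
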