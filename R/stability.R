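#' Count merged sequencing reads per design
#'
#' A read counts for a design when it contains the six bases immediately
#' preceding the coding sequence (`flank5`, default TCAATG), later
#' followed by the six bases immediately following it (`flank3`, default
#' CTCGAG), and the enclosed region translates to exactly the design's
#' full protein sequence. Matching is by protein identity, so synonymous
#' nucleotide changes still count; a read matches at most one design.
#' Both strands of each read are scanned. Designs with identical
#' proteins are reported once and counted under the lexicographically
#' smallest id.
#'
#' @param reads Character vector of merged read sequences, a
#'   `DNAStringSet`, or a path to a FASTQ/FASTA file.
#' @param designs Data frame with `design_id`, `protein` and optionally
#'   `dna` columns (coding regions must translate cleanly).
#' @param flank5,flank3 Flanking hexamers.
#' @return Named integer vector of counts, one per (canonical) design
#'   id.
#' @export
count_reads <- function(reads, designs, flank5 = "TCAATG",
                        flank3 = "CTCGAG") {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads)) "fastq" else "fasta"
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = fmt))
  } else if (inherits(reads, "DNAStringSet")) {
    reads <- as.character(reads)
  }
  if (!is.null(designs$dna)) {
    bad <- nchar(designs$dna) %% 3 != 0
    if (any(bad)) stop("coding region length not a multiple of 3 for ",
                       designs$design_id[which(bad)[1]])
  }
  # collapse designs with identical proteins onto a canonical id
  canon <- vapply(split(designs$design_id, designs$protein),
                  function(x) sort(x)[1], "")
  dup <- names(canon)[vapply(split(designs$design_id, designs$protein),
                             length, 1L) > 1]
  if (length(dup))
    warning(length(dup), " protein sequence(s) shared by multiple designs; ",
            "counts merged under the lexicographically smallest id")
  counts <- stats::setNames(integer(length(canon)), unname(canon))
  translate1 <- function(dna) {
    if (nchar(dna) == 0L || nchar(dna) %% 3 != 0) return(NA_character_)
    p <- tryCatch(as.character(Biostrings::translate(
      Biostrings::DNAString(dna), if.fuzzy.codon = "error")),
      error = function(e) NA_character_)
    if (!is.na(p) && grepl("\\*", p)) return(NA_character_)
    p
  }
  extract <- function(read) {
    i5 <- regexpr(flank5, read, fixed = TRUE)
    if (i5 < 0) return(NA_character_)
    rest <- substr(read, i5 + nchar(flank5), nchar(read))
    i3 <- regexpr(flank3, rest, fixed = TRUE)
    if (i3 < 0) return(NA_character_)
    substr(rest, 1, i3 - 1)
  }
  for (r in reads) {
    hit <- NA_character_
    for (strand in c(r, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(r))))) {
      coding <- extract(strand)
      if (is.na(coding)) next
      p <- translate1(coding)
      if (!is.na(p) && p %in% names(canon)) { hit <- canon[[p]]; break }
    }
    if (!is.na(hit)) counts[hit] <- counts[hit] + 1L
  }
  counts
}

required_ec50_cols <- c("design_id", "category", "trypsin_ec50",
                        "trypsin_ci95", "chymotrypsin_ec50",
                        "chymotrypsin_ci95")

check_ec50_table <- function(records) {
  miss <- setdiff(required_ec50_cols, names(records))
  if (length(miss)) stop("EC50 table lacks columns: ",
                         paste(miss, collapse = ", "))
  invisible(records)
}

#' Filter EC50 records by credible-interval width
#'
#' Retains records whose 95 percent credible-interval width is strictly
#' below `max_ci` for both proteases; wide intervals indicate EC50s not
#' pinned down by the selection rounds.
#'
#' @param records EC50 data frame (columns `design_id`, `category`,
#'   `trypsin_ec50`, `trypsin_ci95`, `chymotrypsin_ec50`,
#'   `chymotrypsin_ci95`).
#' @param max_ci Width cutoff (default 2.0, strict).
#' @return The retained subset.
#' @export
credible_filter <- function(records, max_ci = 2.0) {
  check_ec50_table(records)
  records[records$trypsin_ci95 < max_ci & records$chymotrypsin_ci95 < max_ci, ,
          drop = FALSE]
}

#' Per-protease stability thresholds from patterned scramble controls
#'
#' The threshold for each protease is the given percentile (default
#' 95th, linear interpolation) of the EC50s of the patterned scramble
#' controls; full scrambles are excluded by default (set
#' `pool_scrambles = TRUE` to pool both control types).
#'
#' @param records EC50 data frame.
#' @param percentile Percentile in (0, 100).
#' @param pool_scrambles Include full scrambles too.
#' @return Named numeric vector `c(trypsin = ..., chymotrypsin = ...)`.
#' @export
scramble_thresholds <- function(records, percentile = 95,
                                pool_scrambles = FALSE) {
  check_ec50_table(records)
  keep <- if (pool_scrambles)
    records$category %in% c("patterned_scramble", "full_scramble")
  else records$category == "patterned_scramble"
  scr <- records[keep, , drop = FALSE]
  if (nrow(scr) < 2L) stop("need at least 2 patterned scramble records")
  c(trypsin = stats::quantile(scr$trypsin_ec50, percentile / 100,
                              type = 7, names = FALSE),
    chymotrypsin = stats::quantile(scr$chymotrypsin_ec50, percentile / 100,
                                   type = 7, names = FALSE))
}

#' Classify designs as stable or unstable
#'
#' A design is stable when its EC50 is strictly greater than the
#' scramble-derived threshold for both proteases. Records should have
#' passed [credible_filter()] first.
#'
#' @param records EC50 data frame (designs and/or controls).
#' @param thresholds Output of [scramble_thresholds()].
#' @return Data frame `design_id`, `category`, `stable` plus the
#'   thresholds used as attributes `thresholds`.
#' @export
classify_stable <- function(records, thresholds) {
  check_ec50_table(records)
  if (!all(c("trypsin", "chymotrypsin") %in% names(thresholds)))
    stop("thresholds must name both proteases")
  out <- data.frame(design_id = records$design_id,
                    category = records$category,
                    stable = records$trypsin_ec50 > thresholds[["trypsin"]] &
                      records$chymotrypsin_ec50 > thresholds[["chymotrypsin"]],
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thresholds
  out
}

#' Full stability-classification pipeline on an EC50 table
#'
#' Applies the credible-interval filter, derives patterned-scramble
#' thresholds from the retained controls, and classifies the retained
#' designs.
#'
#' @param records EC50 data frame.
#' @param max_ci Credible-interval cutoff (default 2.0).
#' @param percentile Scramble percentile (default 95).
#' @return List with `calls` (design rows only), `thresholds` and
#'   `n_filtered` (records dropped by the credible filter).
#' @export
stability_pipeline <- function(records, max_ci = 2.0, percentile = 95) {
  kept <- credible_filter(records, max_ci)
  thr <- scramble_thresholds(kept, percentile)
  calls <- classify_stable(kept[kept$category == "design", , drop = FALSE],
                           thr)
  list(calls = calls, thresholds = thr,
       n_filtered = nrow(records) - nrow(kept))
}
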