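# Recombination detection across mutually aligned reference genomes.
#
# Reads are mapped separately against every reference (all references must
# be equal length: the mutual alignment is the identity column map; align
# unequal genomes externally and supply the gapped FASTA). Each read is
# attributed to the reference(s) achieving its best identity — ties count
# toward every tied reference, so indistinguishable references produce
# identical coverage rows and no spurious dominance. Windows where one
# reference's coverage dominates are merged into segments; breakpoints
# fall between segments with different dominant references.

#' Map reads separately against each reference
#'
#' @param reads read data frame.
#' @param refs reference data frame (equal lengths).
#' @param params [map_params()].
#' @return named list (by ref id) of alignment lists, one per reference.
#' @export
map_per_ref <- function(reads, refs, params = map_params()) {
  out <- list()
  for (r in seq_len(nrow(refs))) {
    out[[refs$id[r]]] <- map_all(reads, refs[r, , drop = FALSE], params)
  }
  out
}

#' Per-reference coverage along mutual-alignment columns
#'
#' Entry `(r, c)` counts the reads whose best placement(s) include
#' reference `r` and whose alignment covers column `c`. A read tied
#' between several references (identical best identity) counts toward all
#' of them.
#'
#' @param per_ref_alignments named list from [map_per_ref()].
#' @param refs reference data frame (equal lengths).
#' @return integer matrix, rows = references, columns = alignment columns.
#' @export
coverage_matrix <- function(per_ref_alignments, refs) {
  lens <- nchar(refs$seq)
  if (length(unique(lens)) != 1L) {
    stop("references differ in length; supply a mutual alignment ",
         "(externally aligned, gap-columned FASTA)")
  }
  L <- lens[[1]]
  ids <- refs$id
  mat <- matrix(0L, nrow = length(ids), ncol = L,
                dimnames = list(ids, NULL))
  # best identity per read across references
  best <- new.env(hash = TRUE, parent = emptyenv())
  for (rid in ids) {
    for (a in per_ref_alignments[[rid]]) {
      cur <- get0(a$read_id, envir = best)
      if (is.null(cur) || a$identity > cur) {
        assign(a$read_id, a$identity, envir = best)
      }
    }
  }
  for (rid in ids) {
    for (a in per_ref_alignments[[rid]]) {
      if (a$identity >= get(a$read_id, envir = best) - 1e-9) {
        cols <- a$pairs[, "ref"]
        cols <- cols[!is.na(cols)] + 1L
        mat[rid, cols] <- mat[rid, cols] + 1L
      }
    }
  }
  mat
}

#' Find segments dominated by a single reference
#'
#' The column range is cut into non-overlapping windows of `window`
#' columns; in each, the reference with the highest mean coverage is
#' dominant provided its mean is at least `min_cov` and at least
#' `min_ratio` times the runner-up's. Consecutive windows with the same
#' valid dominant are merged; ambiguous windows join no segment.
#'
#' @param matrix coverage matrix from [coverage_matrix()].
#' @param window window width in columns.
#' @param min_ratio minimum dominant / runner-up coverage ratio (> 1).
#' @param min_cov minimum mean dominant coverage.
#' @return data frame `start`, `end` (0-based half-open columns),
#'   `dominant_ref`, `mean_dominant_coverage`, `dominance_ratio`; sorted,
#'   disjoint.
#' @export
dominant_segments <- function(matrix, window = 200L, min_ratio = 2,
                              min_cov = 5) {
  stopifnot(window >= 1L, min_ratio > 1, min_cov >= 0)
  L <- ncol(matrix)
  ids <- rownames(matrix)
  starts <- seq.int(0L, L - 1L, by = window)
  win_dom <- character(length(starts))
  for (w in seq_along(starts)) {
    cols <- (starts[w] + 1L):min(starts[w] + window, L)
    means <- rowMeans(matrix[, cols, drop = FALSE])
    ord <- order(-means, ids)
    top <- means[ord[1L]]
    runner <- if (length(means) > 1L) means[ord[2L]] else 0
    ratio <- if (runner == 0) Inf else top / runner
    win_dom[w] <- if (top >= min_cov && ratio >= min_ratio) {
      ids[ord[1L]]
    } else {
      NA_character_
    }
  }
  # merge consecutive windows with the same valid dominant
  segs <- list()
  i <- 1L
  while (i <= length(starts)) {
    if (is.na(win_dom[i])) {
      i <- i + 1L
      next
    }
    j <- i
    while (j < length(starts) && identical(win_dom[j + 1L], win_dom[i])) {
      j <- j + 1L
    }
    seg_start <- starts[i]
    seg_end <- min(starts[j] + window, L)
    cols <- (seg_start + 1L):seg_end
    means <- rowMeans(matrix[, cols, drop = FALSE])
    dom <- win_dom[i]
    others <- means[setdiff(ids, dom)]
    runner <- if (length(others) > 0L) max(others) else 0
    segs[[length(segs) + 1L]] <- data.frame(
      start = seg_start, end = seg_end, dominant_ref = dom,
      mean_dominant_coverage = unname(means[dom]),
      dominance_ratio = if (runner == 0) Inf else
        unname(means[dom]) / runner,
      stringsAsFactors = FALSE)
    i <- j + 1L
  }
  if (length(segs) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      dominant_ref = character(0),
                      mean_dominant_coverage = numeric(0),
                      dominance_ratio = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, segs)
}

#' Candidate recombination breakpoints between dominant segments
#'
#' One breakpoint per adjacent segment pair with different dominant
#' references; the column is the shared boundary, or the midpoint of the
#' ambiguous gap between the segments.
#'
#' @param segments data frame from [dominant_segments()].
#' @return data frame `column`, `ref_from`, `ref_to`.
#' @export
breakpoints <- function(segments) {
  out <- list()
  if (nrow(segments) >= 2L) {
    for (i in seq_len(nrow(segments) - 1L)) {
      if (segments$dominant_ref[i] == segments$dominant_ref[i + 1L]) next
      col <- if (segments$end[i] == segments$start[i + 1L]) {
        segments$end[i]
      } else {
        floor((segments$end[i] + segments$start[i + 1L]) / 2)
      }
      out[[length(out) + 1L]] <- data.frame(
        column = col, ref_from = segments$dominant_ref[i],
        ref_to = segments$dominant_ref[i + 1L], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(column = integer(0), ref_from = character(0),
                      ref_to = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
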