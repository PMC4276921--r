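# SNV-based phylogenetics: binary presence matrices over (position, allele)
# variant keys, Hamming-distance trees, and "shrunk genome" construction —
# concatenated reference windows around variant sites with per-sample
# alleles substituted, closely occurring variants sharing merged windows.

#' Build a binary sample-by-variant presence matrix
#'
#' The variant key is the (position, alternate allele) pair: two samples
#' carrying different alternate bases at one site differ in two columns.
#'
#' @param per_sample_snvs named list (>= 2 samples) of SNV data frames with
#'   `pos` (0-based) and `alt_base`.
#' @return binary integer matrix, rows = samples, columns labelled
#'   `"pos:alt"` sorted by (pos, alt).
#' @export
build_snv_matrix <- function(per_sample_snvs) {
  if (length(per_sample_snvs) < 2L) stop("need at least 2 samples")
  labels <- names(per_sample_snvs)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop("sample labels must be present and unique")
  }
  keys <- unique(do.call(rbind, lapply(per_sample_snvs, function(s) {
    data.frame(pos = s$pos, alt = s$alt_base, stringsAsFactors = FALSE)
  })))
  keys <- keys[order(keys$pos, keys$alt), , drop = FALSE]
  key_ids <- paste0(keys$pos, ":", keys$alt)
  m <- matrix(0L, nrow = length(labels), ncol = length(key_ids),
              dimnames = list(labels, key_ids))
  for (s in labels) {
    snvs <- per_sample_snvs[[s]]
    if (nrow(snvs) > 0L) {
      m[s, paste0(snvs$pos, ":", snvs$alt_base)] <- 1L
    }
  }
  m
}

#' Build a tree from an SNV presence matrix
#'
#' Pairwise distance is the Hamming distance between binary rows (number of
#' discordant variant keys); the tree comes from
#' [hierarchical_cluster()]. Optionally an all-zero `reference` outgroup
#' row is added.
#'
#' @param matrix binary matrix from [build_snv_matrix()].
#' @param linkage linkage passed to [hierarchical_cluster()].
#' @param add_reference add an all-zero outgroup row labelled
#'   `"reference"`.
#' @return tree (nested list).
#' @export
snv_tree <- function(matrix, linkage = "average", add_reference = FALSE) {
  if (add_reference) {
    matrix <- rbind(matrix, reference = 0L)
  }
  d <- snv_hamming(matrix)
  hierarchical_cluster(d, linkage)
}

#' Pairwise Hamming distances between binary matrix rows
#' @param matrix binary matrix.
#' @return symmetric numeric matrix.
#' @export
snv_hamming <- function(matrix) {
  n <- nrow(matrix)
  d <- base::matrix(0, n, n, dimnames = list(rownames(matrix),
                                             rownames(matrix)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      h <- sum(matrix[i, ] != matrix[j, ])
      d[i, j] <- h
      d[j, i] <- h
    }
  }
  d
}

#' Merge flanking windows around variant positions
#'
#' Each variant contributes the window
#' `[max(0, p - flank), min(ref_length, p + flank + 1))`; overlapping or
#' adjacent windows are merged, so closely occurring variants share one
#' window.
#'
#' @param snv_positions 0-based variant positions.
#' @param flank flank width in bp (>= 0).
#' @param ref_length reference length.
#' @return data frame `start`, `end` (0-based half-open), sorted, disjoint.
#' @export
shrink_windows <- function(snv_positions, flank, ref_length) {
  stopifnot(flank >= 0)
  if (length(snv_positions) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  if (any(snv_positions < 0L | snv_positions >= ref_length)) {
    stop("variant positions must lie within the reference")
  }
  pos <- sort(unique(as.integer(snv_positions)))
  start <- pmax(0L, pos - as.integer(flank))
  end <- pmin(as.integer(ref_length), pos + as.integer(flank) + 1L)
  # sort + sweep merge of overlapping/adjacent intervals
  ms <- start[1L]; me <- end[1L]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  data.frame(start = out_s, end = out_e)
}

#' Build shrunk genomes: concatenated variant windows per sample
#'
#' Windows are computed on the union of all samples' variant positions, so
#' every output sequence (including the reference row) has identical
#' length — the output is an alignment.
#'
#' @param ref one-row reference data frame.
#' @param per_sample_snvs named list of SNV data frames (`pos`,
#'   `alt_base`).
#' @param flank flank width in bp.
#' @return named character vector of equal-length sequences; first element
#'   is `reference`. The window table is attached as attribute
#'   `"windows"`.
#' @export
shrunk_genomes <- function(ref, per_sample_snvs, flank = 10L) {
  L <- nchar(ref$seq[[1]])
  all_pos <- sort(unique(unlist(lapply(per_sample_snvs, `[[`, "pos"))))
  windows <- shrink_windows(all_pos, flank, L)
  extract <- function(seq_chars) {
    if (nrow(windows) == 0L) return("")
    paste(unlist(lapply(seq_len(nrow(windows)), function(i) {
      seq_chars[(windows$start[i] + 1L):windows$end[i]]
    })), collapse = "")
  }
  ref_chars <- strsplit(ref$seq[[1]], "", fixed = TRUE)[[1]]
  out <- c(reference = extract(ref_chars))
  for (s in names(per_sample_snvs)) {
    snvs <- per_sample_snvs[[s]]
    chars <- ref_chars
    if (nrow(snvs) > 0L) chars[snvs$pos + 1L] <- snvs$alt_base
    out[[s]] <- extract(chars)
  }
  attr(out, "windows") <- windows
  out
}
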