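# Per-position pileup profiling, SNV calling, consensus extraction, and
# conversion to sparse SNV-frequency profiles.
#
# Every call is traceable: the position profile stores the raw base counts
# that support it. Deletions are counted in depth but never yield calls and
# are excluded from frequency denominators (substitution-centric design).

PROFILE_ROWS <- c("A", "C", "G", "T", "del")

#' Pile up aligned reads against one reference
#'
#' Each aligned read base increments exactly one base counter at its
#' reference position; deletions (a reference offset with no read base)
#' increment the `del` counter; read N bases and insertions are ignored.
#'
#' @param alignments list of [alignment_record()] on `ref`.
#' @param reads read data frame containing every aligned read.
#' @param ref one-row reference data frame.
#' @return object of class `position_profile`: list with `ref_id`, `counts`
#'   (5 x L integer matrix, rows A/C/G/T/del), `depth` (length-L integer
#'   vector).
#' @export
pileup <- function(alignments, reads, ref) {
  L <- nchar(ref$seq[[1]])
  counts <- matrix(0L, nrow = 5L, ncol = L,
                   dimnames = list(PROFILE_ROWS, NULL))
  seq_map <- stats::setNames(reads$seq, reads$id)
  for (a in alignments) {
    if (a$ref_id != ref$id[[1]]) {
      stop("alignment to '", a$ref_id, "' passed to pileup on '",
           ref$id[[1]], "'")
    }
    p <- a$pairs
    refcol <- p[, "ref"]
    if (any(refcol >= L, na.rm = TRUE)) {
      stop("alignment of read '", a$read_id, "' runs past the reference end")
    }
    aligned <- !is.na(refcol)
    dels <- aligned & is.na(p[, "read"])
    both <- aligned & !is.na(p[, "read"])
    if (any(both)) {
      rc <- strsplit(seq_map[[a$read_id]], "", fixed = TRUE)[[1]]
      bases <- rc[p[both, "read"] + 1L]
      pos <- refcol[both] + 1L
      keep <- bases != "N"
      if (any(keep)) {
        idx <- cbind(match(bases[keep], PROFILE_ROWS), pos[keep])
        counts[idx] <- counts[idx] + 1L
      }
    }
    if (any(dels)) {
      dpos <- refcol[dels] + 1L
      counts[cbind(rep(5L, length(dpos)), dpos)] <-
        counts[cbind(rep(5L, length(dpos)), dpos)] + 1L
    }
  }
  structure(list(ref_id = ref$id[[1]], counts = counts,
                 depth = as.integer(colSums(counts))),
            class = "position_profile")
}

#' Call substitution variants from a position profile
#'
#' At every position with `depth >= min_depth`, each non-reference base with
#' `count / depth >= min_freq` yields one call; deletions never do.
#'
#' @param profile a `position_profile`.
#' @param ref one-row reference data frame.
#' @param min_depth minimum total depth (including deletions).
#' @param min_freq minimum alternate-allele frequency in `(0, 1]`.
#' @return data frame `ref_id`, `pos` (0-based), `ref_base`, `alt_base`,
#'   `depth`, `alt_count`, `alt_freq`, sorted by position then allele.
#' @export
call_snvs <- function(profile, ref, min_depth = 10L, min_freq = 0.05) {
  stopifnot(min_depth >= 1L, min_freq > 0, min_freq <= 1)
  ref_chars <- strsplit(ref$seq[[1]], "", fixed = TRUE)[[1]]
  depth <- profile$depth
  out <- list()
  eligible <- which(depth >= min_depth)
  for (p in eligible) {
    rb <- ref_chars[p]
    for (b in DNA_BASES) {
      if (b == rb) next
      cnt <- profile$counts[b, p]
      if (cnt > 0L && cnt / depth[p] >= min_freq) {
        out[[length(out) + 1L]] <- data.frame(
          ref_id = profile$ref_id, pos = p - 1L, ref_base = rb,
          alt_base = b, depth = depth[p], alt_count = cnt,
          alt_freq = cnt / depth[p], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(ref_id = character(0), pos = integer(0),
                      ref_base = character(0), alt_base = character(0),
                      depth = integer(0), alt_count = integer(0),
                      alt_freq = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$pos, res$alt_base), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract a consensus sequence from a position profile
#'
#' Per position, the majority base among A/C/G/T wins; ties break toward
#' the reference base, then alphabetically. Positions below `min_depth`
#' emit the reference base. Deletions never shorten the consensus.
#'
#' @param profile a `position_profile`.
#' @param ref one-row reference data frame.
#' @param min_depth minimum depth to override the reference.
#' @param id identifier for the consensus sequence.
#' @return one-row reference data frame.
#' @export
consensus_seq <- function(profile, ref, min_depth = 1L, id = NULL) {
  stopifnot(min_depth >= 1L)
  ref_chars <- strsplit(ref$seq[[1]], "", fixed = TRUE)[[1]]
  acgt <- profile$counts[DNA_BASES, , drop = FALSE]
  maxv <- apply(acgt, 2L, max)
  # alphabetically first base achieving the max
  winner <- DNA_BASES[max.col(t(acgt), ties.method = "first")]
  ref_idx <- cbind(match(ref_chars, DNA_BASES), seq_along(ref_chars))
  ref_count <- ifelse(is.na(ref_idx[, 1L]), -1L, acgt[ref_idx])
  out <- ifelse(profile$depth < min_depth | maxv == 0L, ref_chars,
                ifelse(ref_count == maxv, ref_chars, winner))
  ref_df(id %||% paste0(ref$id[[1]], "_consensus"),
         paste(out, collapse = ""))
}

#' Convert a position profile to a sparse SNV-frequency profile
#'
#' Positions with `depth >= min_depth` and at least one non-reference base
#' map to the total non-reference frequency
#' `(A+C+G+T - count(ref_base)) / (A+C+G+T)`; deletions are excluded from
#' the denominator so frequencies stay comparable across samples with
#' different deletion rates.
#'
#' @param profile a `position_profile`.
#' @param ref one-row reference data frame.
#' @param min_depth minimum total depth for a position to be considered.
#' @return object of class `snv_profile`: list with `ref_id`, `pos`
#'   (0-based integer vector), `freq`, `depth` (at those positions), and
#'   `depth_vector` (dense per-position depth over the whole reference).
#' @export
to_snv_profile <- function(profile, ref, min_depth = 10L) {
  stopifnot(min_depth >= 1L)
  ref_chars <- strsplit(ref$seq[[1]], "", fixed = TRUE)[[1]]
  acgt_sum <- colSums(profile$counts[DNA_BASES, , drop = FALSE])
  ref_idx <- cbind(match(ref_chars, DNA_BASES), seq_along(ref_chars))
  ref_count <- ifelse(is.na(ref_idx[, 1L]), 0L, profile$counts[ref_idx])
  nonref <- acgt_sum - ref_count
  keep <- profile$depth >= min_depth & nonref > 0L
  pos <- which(keep) - 1L
  structure(list(ref_id = profile$ref_id,
                 pos = pos,
                 freq = unname(nonref[keep] / acgt_sum[keep]),
                 depth = profile$depth[keep],
                 depth_vector = profile$depth),
            class = "snv_profile")
}

#' Write a position profile as a TSV table (1-based positions)
#' @param profile a `position_profile`.
#' @param ref one-row reference data frame.
#' @param path output file.
#' @export
write_profile_tsv <- function(profile, ref, path) {
  ref_chars <- strsplit(ref$seq[[1]], "", fixed = TRUE)[[1]]
  df <- data.frame(pos_1based = seq_along(ref_chars),
                   ref_base = ref_chars,
                   A = profile$counts["A", ], C = profile$counts["C", ],
                   G = profile$counts["G", ], T = profile$counts["T", ],
                   del = profile$counts["del", ],
                   depth = profile$depth, stringsAsFactors = FALSE)
  write_tsv_table(df, path)
}

#' Read a position profile from its TSV representation
#' @param path TSV written by [write_profile_tsv()].
#' @param ref_id reference identifier to attach.
#' @return a `position_profile`.
#' @export
read_profile_tsv <- function(path, ref_id = "ref") {
  df <- read_tsv_table(path)
  counts <- t(as.matrix(df[, c("A", "C", "G", "T", "del")]))
  dimnames(counts) <- list(PROFILE_ROWS, NULL)
  storage.mode(counts) <- "integer"
  structure(list(ref_id = ref_id, counts = counts,
                 depth = as.integer(colSums(counts))),
            class = "position_profile")
}

#' Write SNV calls as a TSV table (1-based positions)
#' @param calls data frame from [call_snvs()].
#' @param path output file.
#' @export
write_snv_tsv <- function(calls, path) {
  df <- data.frame(ref_id = calls$ref_id, pos_1based = calls$pos + 1L,
                   ref_base = calls$ref_base, alt_base = calls$alt_base,
                   depth = calls$depth, alt_freq = calls$alt_freq,
                   stringsAsFactors = FALSE)
  write_tsv_table(df, path)
}

#' Read SNV calls from their TSV representation (to 0-based positions)
#' @param path TSV written by [write_snv_tsv()].
#' @return data frame in [call_snvs()] layout (without `alt_count`).
#' @export
read_snv_tsv <- function(path) {
  df <- read_tsv_table(path)
  data.frame(ref_id = df$ref_id, pos = df$pos_1based - 1L,
             ref_base = df$ref_base, alt_base = df$alt_base,
             depth = df$depth, alt_freq = df$alt_freq,
             stringsAsFactors = FALSE)
}
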