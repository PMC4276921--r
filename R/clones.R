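# Quasispecies clone discovery by mutation co-occurrence linkage.
#
# For every pair of called variants close enough to be spanned by reads,
# reads covering both positions are tallied into a 2x2 table of
# (alt, alt) / (alt, ref) / (ref, alt) / (ref, ref) observations. The
# support statistic n11 / (n11 + n10 + n01) — Jaccard over alt-carrying
# reads — links variants into clones via connected components; it stays
# informative at the low coverages where count-based association tests
# lose power.

#' Pairwise linkage statistics between called variants
#'
#' For every variant pair with `q - p <= max_span`, counts reads covering
#' both positions with an unambiguous base at each (reads showing N, or a
#' base that is neither the reference nor the called alternate, are
#' skipped for that pair).
#'
#' @param alignments list of [alignment_record()] on the calls' reference.
#' @param reads read data frame.
#' @param snv_calls data frame from [call_snvs()].
#' @param max_span maximum position separation considered (bp).
#' @return data frame `pos_a`, `alt_a`, `pos_b`, `alt_b`, `n11`, `n10`,
#'   `n01`, `n00`, `support` (one row per covered pair; pairs never
#'   co-covered are absent).
#' @export
link_stats <- function(alignments, reads, snv_calls, max_span = 500L) {
  stopifnot(max_span >= 1L)
  empty <- data.frame(pos_a = integer(0), alt_a = character(0),
                      pos_b = integer(0), alt_b = character(0),
                      n11 = integer(0), n10 = integer(0),
                      n01 = integer(0), n00 = integer(0),
                      support = numeric(0), stringsAsFactors = FALSE)
  if (nrow(snv_calls) < 2L) return(empty)
  seq_map <- stats::setNames(reads$seq, reads$id)
  # per-variant-position map: read_id -> observed base
  positions <- sort(unique(snv_calls$pos))
  base_at <- lapply(positions, function(p) character(0))
  names(base_at) <- as.character(positions)
  for (a in alignments) {
    p <- a$pairs
    both <- !is.na(p[, "read"]) & !is.na(p[, "ref"])
    hit <- both & p[, "ref"] %in% positions
    if (!any(hit)) next
    rc <- strsplit(seq_map[[a$read_id]], "", fixed = TRUE)[[1]]
    bases <- rc[p[hit, "read"] + 1L]
    at <- as.character(p[hit, "ref"])
    for (m in seq_along(at)) {
      base_at[[at[m]]][[a$read_id]] <- bases[m]
    }
  }
  out <- list()
  calls <- snv_calls[order(snv_calls$pos, snv_calls$alt_base), , drop = FALSE]
  for (i in seq_len(nrow(calls) - 1L)) {
    for (j in (i + 1L):nrow(calls)) {
      pa <- calls$pos[i]; pb <- calls$pos[j]
      if (pa == pb) next
      if (pb - pa > max_span) break
      ba <- base_at[[as.character(pa)]]
      bb <- base_at[[as.character(pb)]]
      common <- intersect(names(ba), names(bb))
      if (length(common) == 0L) next
      xa <- ba[common]; xb <- bb[common]
      ok <- xa %in% c(calls$ref_base[i], calls$alt_base[i]) &
        xb %in% c(calls$ref_base[j], calls$alt_base[j])
      if (!any(ok)) next
      aa <- xa[ok] == calls$alt_base[i]
      bbb <- xb[ok] == calls$alt_base[j]
      n11 <- sum(aa & bbb); n10 <- sum(aa & !bbb)
      n01 <- sum(!aa & bbb); n00 <- sum(!aa & !bbb)
      den <- n11 + n10 + n01
      out[[length(out) + 1L]] <- data.frame(
        pos_a = pa, alt_a = calls$alt_base[i],
        pos_b = pb, alt_b = calls$alt_base[j],
        n11 = n11, n10 = n10, n01 = n01, n00 = n00,
        support = if (den > 0L) n11 / den else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Assemble clones from linked variants
#'
#' Variants become nodes; an edge joins a pair when its support reaches
#' `min_support` with at least `min_reads` co-occurring alt reads.
#' Connected components are clones (singletons included). Each clone's
#' consensus is the reference with its alternate bases substituted; its
#' frequency estimate is the mean alternate-allele frequency of its
#' members. A variant-free reference clone closes the frequency budget
#' (`1 - sum of clone frequencies`, floored at 0).
#'
#' @param snv_calls data frame from [call_snvs()].
#' @param links data frame from [link_stats()].
#' @param min_support minimum support in `(0, 1]`.
#' @param min_reads minimum `n11`.
#' @param ref one-row reference data frame.
#' @return data frame of class `clone_set`: `id`, `n_variants`,
#'   `variants` (comma-joined `pos:alt`, 0-based), `freq`, `mean_depth`,
#'   `consensus`.
#' @export
build_clones <- function(snv_calls, links, min_support = 0.8,
                         min_reads = 5L, ref = NULL) {
  stopifnot(min_support > 0, min_support <= 1, min_reads >= 1L)
  key <- function(pos, alt) paste0(pos, ":", alt)
  ref_seq <- if (!is.null(ref)) ref$seq[[1]] else NULL
  make_consensus <- function(snvs) {
    if (is.null(ref_seq)) return(NA_character_)
    chars <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
    if (nrow(snvs) > 0L) chars[snvs$pos + 1L] <- snvs$alt_base
    paste(chars, collapse = "")
  }
  if (nrow(snv_calls) == 0L) {
    return(structure(data.frame(
      id = "reference", n_variants = 0L, variants = "", freq = 1,
      mean_depth = NA_real_, consensus = make_consensus(snv_calls),
      stringsAsFactors = FALSE), class = c("clone_set", "data.frame")))
  }
  keys <- key(snv_calls$pos, snv_calls$alt_base)
  # union-find over variant keys
  parent <- stats::setNames(seq_along(keys), keys)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nrow(links) > 0L) {
    linked <- links$support >= min_support & !is.na(links$support) &
      links$n11 >= min_reads
    for (e in which(linked)) {
      ka <- key(links$pos_a[e], links$alt_a[e])
      kb <- key(links$pos_b[e], links$alt_b[e])
      if (!(ka %in% keys) || !(kb %in% keys)) next
      ra <- find(match(ka, keys)); rb <- find(match(kb, keys))
      if (ra != rb) parent[rb] <- ra
    }
  }
  comp <- vapply(seq_along(keys), find, numeric(1))
  groups <- split(seq_along(keys), comp)
  # order clones by smallest member position
  ord <- order(vapply(groups, function(g) min(snv_calls$pos[g]), numeric(1)))
  groups <- groups[ord]
  rows <- lapply(seq_along(groups), function(ci) {
    g <- groups[[ci]]
    snvs <- snv_calls[g, , drop = FALSE]
    snvs <- snvs[order(snvs$pos), , drop = FALSE]
    data.frame(
      id = sprintf("clone%d", ci),
      n_variants = nrow(snvs),
      variants = paste(key(snvs$pos, snvs$alt_base), collapse = ","),
      freq = mean(snvs$alt_freq),
      mean_depth = mean(snvs$depth),
      consensus = make_consensus(snvs),
      stringsAsFactors = FALSE)
  })
  clones <- do.call(rbind, rows)
  ref_clone <- data.frame(
    id = "reference", n_variants = 0L, variants = "",
    freq = max(0, 1 - sum(clones$freq)), mean_depth = NA_real_,
    consensus = make_consensus(snv_calls[0, , drop = FALSE]),
    stringsAsFactors = FALSE)
  structure(rbind(clones, ref_clone),
            class = c("clone_set", "data.frame"))
}

#' Sankey-ready link table for a clone set
#'
#' One row per adjacent (by position) variant pair within each clone,
#' carrying that pair's co-occurrence count and support.
#'
#' @param clones `clone_set` from [build_clones()].
#' @param links data frame from [link_stats()].
#' @return data frame `clone_id`, `pos_from`, `pos_to`, `n11`, `support`,
#'   sorted by clone then position.
#' @export
sankey_table <- function(clones, links) {
  out <- list()
  for (ci in seq_len(nrow(clones))) {
    if (clones$n_variants[ci] < 2L) next
    kv <- strsplit(clones$variants[ci], ",", fixed = TRUE)[[1]]
    parts <- strsplit(kv, ":", fixed = TRUE)
    pos <- as.integer(vapply(parts, `[[`, character(1), 1L))
    alt <- vapply(parts, `[[`, character(1), 2L)
    ord <- order(pos)
    pos <- pos[ord]; alt <- alt[ord]
    for (i in seq_len(length(pos) - 1L)) {
      hit <- which(links$pos_a == pos[i] & links$alt_a == alt[i] &
                     links$pos_b == pos[i + 1L] &
                     links$alt_b == alt[i + 1L])
      out[[length(out) + 1L]] <- data.frame(
        clone_id = clones$id[ci], pos_from = pos[i], pos_to = pos[i + 1L],
        n11 = if (length(hit) == 1L) links$n11[hit] else NA_integer_,
        support = if (length(hit) == 1L) links$support[hit] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(clone_id = character(0), pos_from = integer(0),
                      pos_to = integer(0), n11 = integer(0),
                      support = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$clone_id, res$pos_from), , drop = FALSE]
}
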