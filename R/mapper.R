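# Minimal deterministic seed-and-extend read mapper.
#
# Exact k-mer seeds propose candidate placements; each candidate is scored by
# ungapped identity over the read/reference overlap; the best placement wins,
# with ties broken by (ref_id, position). Intended for the indel-free reads
# the simulator produces; gapped external alignments enter via read_sam().

#' Mapping parameters
#'
#' @param k seed length in bp.
#' @param min_identity minimum ungapped identity for a placement to be
#'   reported.
#' @param max_candidates cap on the number of candidate placements scored
#'   per read.
#' @return list of class `map_params`.
#' @export
map_params <- function(k = 11L, min_identity = 0.8, max_candidates = 50L) {
  stopifnot(k >= 1L, min_identity >= 0, min_identity <= 1,
            max_candidates >= 1L)
  structure(list(k = as.integer(k), min_identity = min_identity,
                 max_candidates = as.integer(max_candidates)),
            class = "map_params")
}

#' Build an exact k-mer index over a reference set
#'
#' Every k-mer at every position is indexed; k-mers containing N are skipped.
#'
#' @param refs reference data frame.
#' @param k seed length; must not exceed the shortest reference.
#' @return a `kmer_index` object.
#' @export
build_index <- function(refs, k = 11L) {
  k <- as.integer(k)
  if (k > min(nchar(refs$seq))) {
    stop("k exceeds the shortest reference length")
  }
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(nrow(refs))) {
    seq <- refs$seq[[r]]
    L <- nchar(seq)
    starts <- seq_len(L - k + 1L)
    kmers <- substring(seq, starts, starts + k - 1L)
    ok <- !grepl("N", kmers, fixed = TRUE)
    if (!any(ok)) next
    hits <- split(starts[ok] - 1L, kmers[ok])
    for (km in names(hits)) {
      entry <- get0(km, envir = env)
      add <- cbind(ref = r, pos = hits[[km]])
      assign(km, if (is.null(entry)) add else rbind(entry, add), envir = env)
    }
  }
  structure(list(k = k, env = env, ref_ids = refs$id,
                 ref_chars = lapply(refs$seq, function(s)
                   strsplit(s, "", fixed = TRUE)[[1]]),
                 ref_lens = nchar(refs$seq)),
            class = "kmer_index")
}

#' Number of (k-mer, position) entries in an index
#' @param index a `kmer_index`.
#' @return integer entry count.
#' @export
index_size <- function(index) {
  keys <- ls(index$env)
  if (length(keys) == 0L) return(0L)
  sum(vapply(keys, function(km) nrow(get(km, envir = index$env)),
             integer(1)))
}

#' Map a single read
#'
#' Seed k-mers are taken at every `k`-th read offset (plus the final
#' offset); each hit proposes the placement `hit_pos - offset`. Candidates
#' are scored by ungapped identity over the read/reference overlap, N bases
#' excluded from the denominator. Returns `NULL` when no placement reaches
#' `min_identity`.
#'
#' @param read one-row read data frame, or a list/row with `id` and `seq`.
#' @param index a `kmer_index`.
#' @param params [map_params()].
#' @return an [alignment_record()] or `NULL`.
#' @export
map_read <- function(read, index, params = map_params()) {
  seq <- read$seq[[1]]
  id <- read$id[[1]]
  k <- index$k
  rl <- nchar(seq)
  if (k > rl) stop("seed length k exceeds read length")
  offsets <- unique(c(seq.int(0L, rl - k, by = k), rl - k))
  seeds <- substring(seq, offsets + 1L, offsets + k)
  cand <- list()
  for (i in seq_along(seeds)) {
    hits <- get0(seeds[[i]], envir = index$env)
    if (is.null(hits)) next
    cand[[length(cand) + 1L]] <-
      cbind(ref = hits[, "ref"], start = hits[, "pos"] - offsets[i])
  }
  if (length(cand) == 0L) return(NULL)
  cand <- unique(do.call(rbind, cand))
  # deterministic candidate order: (ref_id, start)
  ord <- order(index$ref_ids[cand[, "ref"]], cand[, "start"])
  cand <- cand[ord, , drop = FALSE]
  if (nrow(cand) > params$max_candidates) {
    cand <- cand[seq_len(params$max_candidates), , drop = FALSE]
  }
  read_chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, "ref"]; s <- cand[i, "start"]
    L <- index$ref_lens[r]
    ro <- max(0L, -s)                      # first aligned read offset
    re <- min(rl - 1L, L - 1L - s)         # last aligned read offset
    if (re - ro + 1L < k) next
    rb <- read_chars[(ro:re) + 1L]
    fb <- index$ref_chars[[r]][(s + ro):(s + re) + 1L]
    keep <- rb != "N" & fb != "N"
    if (!any(keep)) next
    ident <- sum(rb[keep] == fb[keep]) / sum(keep)
    if (is.null(best) || ident > best$identity + 1e-15) {
      best <- list(ref = r, start = s, ro = ro, re = re, identity = ident)
    }
  }
  if (is.null(best) || best$identity < params$min_identity) return(NULL)
  pairs <- cbind(read = best$ro:best$re,
                 ref = (best$start + best$ro):(best$start + best$re))
  alignment_record(id, index$ref_ids[best$ref], best$start + best$ro,
                   pairs, "+", best$identity)
}

#' Map a set of reads against a reference set
#'
#' @param reads read data frame.
#' @param refs reference data frame (or a pre-built `kmer_index`).
#' @param params [map_params()].
#' @return list of [alignment_record()] (input order preserved, unmapped
#'   reads omitted) with a `summary` attribute
#'   `(n_reads, n_mapped, n_unmapped)`.
#' @export
map_all <- function(reads, refs, params = map_params()) {
  index <- if (inherits(refs, "kmer_index")) refs else {
    build_index(refs, params$k)
  }
  out <- vector("list", nrow(reads))
  n <- 0L
  for (i in seq_len(nrow(reads))) {
    a <- map_read(reads[i, ], index, params)
    if (!is.null(a)) {
      n <- n + 1L
      out[[n]] <- a
    }
  }
  out <- out[seq_len(n)]
  attr(out, "summary") <- c(n_reads = nrow(reads), n_mapped = n,
                            n_unmapped = nrow(reads) - n)
  out
}
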