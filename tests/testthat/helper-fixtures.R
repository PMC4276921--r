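# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; nothing is stored on disk.

# leaf labels of a newick string (labels here are plain word characters)
tree_leaves_from_newick <- function(nwk) {
  regmatches(nwk, gregexpr("[A-Za-z0-9_.-]+(?=:)", nwk, perl = TRUE))[[1]]
}

ref_df_for_tests <- function(id, seq) {
  data.frame(id = id, seq = seq, taxon = NA_character_,
             stringsAsFactors = FALSE)
}

# hand-built sparse SNV profile with a uniform dense depth vector
make_snv_profile <- function(pos, freq, ref_length, depth = 100L,
                             ref_id = "ref1", depth_vector = NULL) {
  structure(list(
    ref_id = ref_id,
    pos = as.integer(pos),
    freq = as.numeric(freq),
    depth = rep_len(as.integer(depth), length(pos)),
    depth_vector = depth_vector %||%
      rep(as.integer(depth), ref_length)),
    class = "snv_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-taxon panel plus error-free reads with truth labels
fixture_two_taxa <- function(genome_length = 5000L, n_reads = 800L,
                             read_length = 100L, error_rate = 0,
                             weights = c(0.5, 0.5), seed = 101L) {
  panel <- sim_taxon_panel(2L, genome_length, 0.1, seed = seed)
  reads <- make_reads(panel$refs, weights, n_reads, read_length,
                      error_rate, seed = seed + 1L)
  list(panel = panel, reads = reads)
}

# reads guaranteed unmappable against any A/C/G/T reference
unmappable_reads <- function(n, read_length = 60L) {
  data.frame(id = sprintf("junk%03d", seq_len(n)),
             seq = strrep("N", read_length),
             qual = strrep("I", read_length),
             stringsAsFactors = FALSE)
}

# naive per-position recount of a pileup from alignments + reads:
# independent oracle for the profile module
naive_pileup_counts <- function(alignments, reads, ref) {
  L <- nchar(ref$seq[[1]])
  counts <- matrix(0L, nrow = 5L, ncol = L,
                   dimnames = list(c("A", "C", "G", "T", "del"), NULL))
  seq_map <- stats::setNames(reads$seq, reads$id)
  for (a in alignments) {
    rc <- strsplit(seq_map[[a$read_id]], "", fixed = TRUE)[[1]]
    for (i in seq_len(nrow(a$pairs))) {
      ro <- a$pairs[i, 1L]; fo <- a$pairs[i, 2L]
      if (is.na(fo)) next
      if (is.na(ro)) {
        counts["del", fo + 1L] <- counts["del", fo + 1L] + 1L
      } else if (rc[ro + 1L] != "N") {
        counts[rc[ro + 1L], fo + 1L] <- counts[rc[ro + 1L], fo + 1L] + 1L
      }
    }
  }
  counts
}

# leaf-set/height merge list from one of our trees (for hclust comparison)
tree_merges <- function(tree) {
  out <- list()
  walk <- function(node, depth_above) {
    if (!is.null(node$label)) return(0)
    child_heights <- vapply(node$children, function(ch) {
      walk(ch, 0) + (ch$branch %||% 0)
    }, numeric(1))
    h <- child_heights[1L]
    out[[length(out) + 1L]] <<-
      list(leaves = sort(tree_leaves(node)), height = h)
    h
  }
  walk(tree, 0)
  out
}

# merge list from an hclust object (heights halved to match our node
# heights, which sit at d/2)
hclust_merges <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  out <- list()
  for (i in seq_len(nrow(hc$merge))) {
    get_set <- function(x) {
      if (x < 0) hc$labels[-x] else sets[[x]]
    }
    sets[[i]] <- sort(c(get_set(hc$merge[i, 1L]),
                        get_set(hc$merge[i, 2L])))
    out[[i]] <- list(leaves = sets[[i]], height = hc$height[i] / 2)
  }
  out
}
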