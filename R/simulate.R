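# Deterministic synthetic-data generators: reference genomes, diverged and
# recombinant variants, and error-bearing short reads with truth labels.
#
# All generators take an explicit integer seed and restore the caller's RNG
# state, so outputs are byte-identical across runs and independent of
# surrounding code.

#' Simulate a random genome
#'
#' Bases are drawn i.i.d. with `P(G) = P(C) = gc_content / 2` and
#' `P(A) = P(T) = (1 - gc_content) / 2`.
#'
#' @param length genome length in bp.
#' @param gc_content target GC fraction in `[0, 1]`.
#' @param seed integer seed.
#' @param id sequence identifier.
#' @return one-row data frame with `id`, `seq`, `taxon`.
#' @export
make_genome <- function(length, gc_content = 0.5, seed = 1L, id = "genome1") {
  stopifnot(length >= 1L, gc_content >= 0, gc_content <= 1)
  probs <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
             G = gc_content / 2, T = (1 - gc_content) / 2)
  seq <- with_seed(seed, {
    paste(sample(names(probs), length, replace = TRUE, prob = probs),
          collapse = "")
  })
  ref_df(id, seq)
}

#' Plant substitution variants into a genome
#'
#' Positions are sampled uniformly without replacement (optionally within a
#' restricted region); the alternate base is uniform over the three
#' non-reference bases. The truth table records every planted variant.
#'
#' @param genome one-row reference data frame (or a single sequence string).
#' @param snv_rate per-base substitution probability; used to derive
#'   `n_snvs = round(rate * length)` when `n_snvs` is not given.
#' @param n_snvs explicit number of variants to plant.
#' @param seed integer seed.
#' @param id identifier for the mutated sequence.
#' @param region optional 0-based half-open `c(start, end)` window to plant
#'   variants in (default: whole genome).
#' @return list with `genome` (one-row data frame) and `truth` (data frame
#'   `pos` 0-based, `ref_base`, `alt_base`, sorted by position).
#' @export
mutate_genome <- function(genome, snv_rate = NULL, n_snvs = NULL, seed = 1L,
                          id = NULL, region = NULL) {
  seq <- if (is.data.frame(genome)) genome$seq[[1]] else genome
  L <- nchar(seq)
  if (is.null(n_snvs)) {
    stopifnot(!is.null(snv_rate), snv_rate >= 0, snv_rate < 1)
    n_snvs <- round(snv_rate * L)
  }
  region <- region %||% c(0L, L)
  candidates <- seq.int(region[1L], region[2L] - 1L)
  if (n_snvs > length(candidates)) {
    stop("n_snvs exceeds the number of available positions")
  }
  id <- id %||% paste0(if (is.data.frame(genome)) genome$id[[1]] else "genome",
                       "_mut")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  truth <- with_seed(seed, {
    pos <- sort(sample(candidates, n_snvs))
    ref_base <- chars[pos + 1L]
    alt_base <- vapply(ref_base, function(b) {
      sample(setdiff(DNA_BASES, b), 1L)
    }, character(1), USE.NAMES = FALSE)
    data.frame(pos = pos, ref_base = ref_base, alt_base = alt_base,
               stringsAsFactors = FALSE)
  })
  chars[truth$pos + 1L] <- truth$alt_base
  list(genome = ref_df(id, paste(chars, collapse = "")), truth = truth)
}

#' Splice a recombinant genome from equal-length parents
#'
#' Segments between successive breakpoints are taken from the parents in the
#' given order, cycling if there are more segments than parents. Parents must
#' be equal length (the mutual alignment is the identity here; align unequal
#' genomes externally first).
#'
#' @param parents reference data frame, one row per parent.
#' @param breakpoints strictly increasing 0-based columns in `(0, length)`.
#' @param id identifier for the recombinant.
#' @return list with `genome` (one-row data frame) and `segments` (data frame
#'   `parent_id`, `start`, `end`; 0-based half-open).
#' @export
recombine <- function(parents, breakpoints = integer(0), id = "recombinant") {
  lens <- nchar(parents$seq)
  if (length(unique(lens)) != 1L) {
    stop("parents must be equal length (supply a mutual alignment)")
  }
  L <- lens[[1]]
  breakpoints <- as.integer(breakpoints)
  if (length(breakpoints) > 0L) {
    if (is.unsorted(breakpoints, strictly = TRUE) ||
        min(breakpoints) <= 0L || max(breakpoints) >= L) {
      stop("breakpoints must be strictly increasing within (0, length)")
    }
  }
  bounds <- c(0L, breakpoints, L)
  n_seg <- length(bounds) - 1L
  parent_idx <- ((seq_len(n_seg) - 1L) %% nrow(parents)) + 1L
  pieces <- vapply(seq_len(n_seg), function(i) {
    substr(parents$seq[[parent_idx[i]]], bounds[i] + 1L, bounds[i + 1L])
  }, character(1))
  segments <- data.frame(parent_id = parents$id[parent_idx],
                         start = bounds[-length(bounds)],
                         end = bounds[-1L], stringsAsFactors = FALSE)
  list(genome = ref_df(id, paste(pieces, collapse = "")),
       segments = segments)
}

#' Simulate error-bearing short reads from a genome mixture
#'
#' Each read's source genome is drawn from `weights`; its start is uniform
#' over valid positions; each base is flipped to a uniform different base
#' with probability `error_rate`. Reads are single-end, fixed-length,
#' forward-strand. Truth columns (`truth_source`, `truth_start`) record the
#' source genome and 0-based start of every read.
#'
#' @param genomes reference data frame, one row per source genome.
#' @param weights mixture weights, non-negative, summing to 1.
#' @param n_reads number of reads.
#' @param read_length read length in bp (at most the shortest genome).
#' @param error_rate per-base substitution error probability in `[0, 1)`.
#' @param seed integer seed.
#' @return read data frame with columns `id`, `seq`, `qual`,
#'   `truth_source`, `truth_start`.
#' @export
make_reads <- function(genomes, weights, n_reads, read_length,
                       error_rate = 0, seed = 1L) {
  stopifnot(nrow(genomes) == length(weights), all(weights >= 0),
            abs(sum(weights) - 1) < 1e-9,
            error_rate >= 0, error_rate < 1, n_reads >= 1)
  if (read_length > min(nchar(genomes$seq))) {
    stop("read_length exceeds the shortest genome")
  }
  with_seed(seed, {
    src <- sample.int(nrow(genomes), n_reads, replace = TRUE, prob = weights)
    lens <- nchar(genomes$seq)
    starts <- vapply(src, function(s) {
      sample.int(lens[s] - read_length + 1L, 1L) - 1L
    }, integer(1))
    seqs <- substring(genomes$seq[src], starts + 1L, starts + read_length)
    if (error_rate > 0) {
      chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)),
                      nrow = read_length)
      err <- which(stats::runif(length(chars)) < error_rate)
      if (length(err) > 0L) {
        # uniform over the three non-current bases
        shift <- sample.int(3L, length(err), replace = TRUE)
        cur <- match(chars[err], DNA_BASES)
        chars[err] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
      }
      seqs <- apply(chars, 2L, paste, collapse = "")
    }
    data.frame(id = sprintf("read%06d", seq_len(n_reads)),
               seq = seqs,
               qual = strrep("I", read_length),
               truth_source = genomes$id[src],
               truth_start = starts,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a panel of diverged taxon genomes
#'
#' Generates a common ancestor and `n_taxa` descendants, each carrying
#' independent substitutions at rate `divergence / 2`, so that the expected
#' pairwise divergence is close to `divergence`.
#'
#' @param n_taxa number of taxa.
#' @param length genome length in bp.
#' @param divergence target pairwise divergence (fraction of sites).
#' @param seed integer seed.
#' @param gc_content ancestor GC fraction.
#' @return list with `refs` (reference data frame, `taxon` filled) and
#'   `truth` (named list of per-taxon variant tables).
#' @export
sim_taxon_panel <- function(n_taxa, length, divergence = 0.1, seed = 1L,
                            gc_content = 0.5) {
  anc <- make_genome(length, gc_content, seed = derive_seed(seed, 0L),
                     id = "ancestor")
  n_snvs <- round(divergence / 2 * length)
  refs <- NULL
  truth <- list()
  for (i in seq_len(n_taxa)) {
    m <- mutate_genome(anc, n_snvs = n_snvs, seed = derive_seed(seed, i),
                       id = sprintf("taxon%d", i))
    m$genome$taxon <- sprintf("taxon%d", i)
    refs <- rbind(refs, m$genome)
    truth[[m$genome$id]] <- m$truth
  }
  list(refs = refs, truth = truth)
}

#' Simulate a quasispecies haplotype mixture
#'
#' Builds a backbone genome and `n_haplotypes` haplotypes, each carrying
#' `n_snvs_each` private substitutions at interleaved, evenly spaced
#' positions (spacing `spacing` bp), so that adjacent same-haplotype
#' variants can be spanned by reads longer than `spacing`.
#'
#' @param n_haplotypes number of haplotypes.
#' @param n_snvs_each private variants per haplotype.
#' @param length backbone length in bp.
#' @param spacing distance between consecutive same-haplotype variants.
#' @param seed integer seed.
#' @param first_pos 0-based position of the first variant.
#' @return list with `backbone` (one-row data frame), `haplotypes`
#'   (reference data frame) and `truth` (named list of variant tables).
#' @export
sim_quasispecies <- function(n_haplotypes = 2L, n_snvs_each = 3L,
                             length = 1000L, spacing = 120L, seed = 1L,
                             first_pos = 100L) {
  backbone <- make_genome(length, seed = derive_seed(seed, 0L),
                          id = "backbone")
  offset <- floor(spacing / (n_haplotypes + 1L))
  chars0 <- strsplit(backbone$seq[[1]], "", fixed = TRUE)[[1]]
  haps <- NULL
  truth <- list()
  for (h in seq_len(n_haplotypes)) {
    pos <- first_pos + (seq_len(n_snvs_each) - 1L) * spacing +
      (h - 1L) * offset
    if (max(pos) >= length) stop("variant positions exceed backbone length")
    ref_base <- chars0[pos + 1L]
    alt_base <- with_seed(derive_seed(seed, h), {
      vapply(ref_base, function(b) sample(setdiff(DNA_BASES, b), 1L),
             character(1), USE.NAMES = FALSE)
    })
    chars <- chars0
    chars[pos + 1L] <- alt_base
    hid <- sprintf("hap%d", h)
    haps <- rbind(haps, ref_df(hid, paste(chars, collapse = "")))
    truth[[hid]] <- data.frame(pos = pos, ref_base = ref_base,
                               alt_base = alt_base, stringsAsFactors = FALSE)
  }
  list(backbone = backbone, haplotypes = haps, truth = truth)
}
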