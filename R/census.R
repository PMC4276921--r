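# Subsampling-based taxonomic census.
#
# Rather than classifying every read, small random samples of reads are
# drawn repeatedly ("random picking"), classified against a reference panel
# with a taxon label per reference, and the per-iteration taxon proportions
# aggregated into a mean with a percentile confidence interval. An
# "unaligned" pseudo-taxon absorbs reads with no acceptable placement.

#' Census parameters
#'
#' @param n_per_iteration reads sampled per iteration.
#' @param n_iterations number of independent iterations.
#' @param seed integer seed; iteration `i` uses `seed + i`.
#' @param map_params mapper settings used for classification.
#' @return list of class `census_params`.
#' @export
census_params <- function(n_per_iteration = 250L, n_iterations = 20L,
                          seed = 1L, map_params = ngsdesk::map_params()) {
  stopifnot(n_per_iteration >= 1L, n_iterations >= 1L)
  structure(list(n_per_iteration = as.integer(n_per_iteration),
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), map_params = map_params),
            class = "census_params")
}

#' Randomly pick reads without replacement
#'
#' Samples `min(n, nrow(reads))` reads uniformly without replacement;
#' deterministic under `seed`. The returned order is the sampled order.
#'
#' @param reads read data frame.
#' @param n sample size.
#' @param seed integer seed.
#' @return read data frame subset.
#' @export
random_pick <- function(reads, n, seed = 1L) {
  if (nrow(reads) == 0L) stop("cannot pick from an empty read set")
  stopifnot(n >= 1L)
  idx <- with_seed(seed, sample.int(nrow(reads), min(n, nrow(reads))))
  reads[idx, , drop = FALSE]
}

#' Classify a read sample against a taxon-labelled reference panel
#'
#' Each read contributes exactly one count: to the taxon of its best-hit
#' reference, or to the unaligned tally.
#'
#' @param sample read data frame (typically from [random_pick()]).
#' @param refs reference data frame, or a pre-built `kmer_index`.
#' @param taxon_map data frame with `ref_id`, `taxon` covering every
#'   reference.
#' @param map_params mapper settings.
#' @return list with `counts` (named integer vector per taxon) and
#'   `unaligned` (integer).
#' @export
classify_sample <- function(sample, refs, taxon_map,
                            map_params = ngsdesk::map_params()) {
  ref_ids <- if (inherits(refs, "kmer_index")) refs$ref_ids else refs$id
  missing <- setdiff(ref_ids, taxon_map$ref_id)
  if (length(missing) > 0L) {
    stop("references without a taxon entry: ", paste(missing, collapse = ", "))
  }
  tax <- stats::setNames(taxon_map$taxon, taxon_map$ref_id)
  alns <- map_all(sample, refs, map_params)
  hit_taxa <- vapply(alns, function(a) tax[[a$ref_id]], character(1))
  counts <- table(factor(hit_taxa, levels = sort(unique(taxon_map$taxon))))
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       unaligned = nrow(sample) - length(alns))
}

#' Run a subsampling census
#'
#' Runs `n_iterations` independent pick-and-classify passes and aggregates
#' per-taxon proportions: mean, standard deviation and a 2.5/97.5 percentile
#' interval across iterations. Taxa never observed in any iteration are
#' absent from the output; an `unaligned` row is always present.
#'
#' @param reads read data frame.
#' @param refs reference data frame.
#' @param taxon_map data frame with `ref_id`, `taxon`.
#' @param params [census_params()].
#' @return object of class `census_result`: list with `summary` (data frame
#'   `taxon`, `mean`, `sd`, `ci_low`, `ci_high`) and `iterations` (matrix of
#'   proportions, taxa x iterations).
#' @export
run_census <- function(reads, refs, taxon_map, params = census_params()) {
  index <- build_index(refs, params$map_params$k)
  per_iter <- vector("list", params$n_iterations)
  for (i in seq_len(params$n_iterations)) {
    smp <- random_pick(reads, params$n_per_iteration,
                       seed = derive_seed(params$seed, i))
    cl <- classify_sample(smp, index, taxon_map, params$map_params)
    n <- sum(cl$counts) + cl$unaligned
    per_iter[[i]] <- c(cl$counts, unaligned = cl$unaligned) / n
  }
  taxa <- names(per_iter[[1]])
  mat <- do.call(cbind, per_iter)
  colnames(mat) <- paste0("iter", seq_len(params$n_iterations))
  observed <- rowSums(mat) > 0 | rownames(mat) == "unaligned"
  mat <- mat[observed, , drop = FALSE]
  summary <- data.frame(
    taxon = rownames(mat),
    mean = rowMeans(mat),
    sd = apply(mat, 1L, stats::sd),
    ci_low = apply(mat, 1L, stats::quantile, probs = 0.025),
    ci_high = apply(mat, 1L, stats::quantile, probs = 0.975),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(summary = summary, iterations = mat),
            class = "census_result")
}

#' @export
print.census_result <- function(x, ...) {
  cat("Subsampling census over", ncol(x$iterations), "iterations\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
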