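# SNV-profile clustering: position/frequency filtering, pairwise profile
# distances under pluggable metrics, agglomerative and neighbor-joining
# tree construction, Newick-ready output.
#
# Pair comparison vectorizes profiles over the union of their variant
# positions: a position absent from one profile contributes frequency 0
# when that sample covers it at adequate depth, and is dropped from the
# pair entirely when either sample lacks coverage there. This keeps
# absence-of-coverage from masquerading as absence-of-variant.

CLUSTER_METRICS <- c("euclidean", "manhattan", "canberra", "pearson")
CLUSTER_LINKAGES <- c("single", "complete", "average", "neighbor_joining")

#' Clustering parameters
#'
#' @param metric one of `euclidean`, `manhattan`, `canberra`, `pearson`
#'   (Pearson distance is `1 - r`, with `r := 0` for constant vectors).
#' @param linkage one of `single`, `complete`, `average` (UPGMA),
#'   `neighbor_joining`.
#' @param min_depth positions below this depth are dropped.
#' @param min_freq frequencies below this are removed.
#' @param whitelist,blacklist optional lists of 0-based half-open
#'   `c(start, end)` intervals; contradictory overlap raises an error.
#' @return list of class `cluster_params`.
#' @export
cluster_params <- function(metric = "euclidean", linkage = "average",
                           min_depth = 10L, min_freq = 0,
                           whitelist = NULL, blacklist = NULL) {
  metric <- match.arg(metric, CLUSTER_METRICS)
  linkage <- match.arg(linkage, CLUSTER_LINKAGES)
  stopifnot(min_freq >= 0, min_freq <= 1)
  structure(list(metric = metric, linkage = linkage,
                 min_depth = as.integer(min_depth), min_freq = min_freq,
                 whitelist = whitelist, blacklist = blacklist),
            class = "cluster_params")
}

in_intervals <- function(pos, intervals) {
  if (is.null(intervals) || length(intervals) == 0L) {
    return(rep(FALSE, length(pos)))
  }
  hit <- rep(FALSE, length(pos))
  for (iv in intervals) hit <- hit | (pos >= iv[1L] & pos < iv[2L])
  hit
}

#' Filter an SNV profile by depth, position and frequency
#'
#' @param snv_profile an `snv_profile`.
#' @param params [cluster_params()].
#' @return filtered `snv_profile`.
#' @export
filter_profile <- function(snv_profile, params = cluster_params()) {
  if (!is.null(params$whitelist) && !is.null(params$blacklist)) {
    for (w in params$whitelist) {
      for (b in params$blacklist) {
        if (max(w[1L], b[1L]) < min(w[2L], b[2L])) {
          stop("whitelist and blacklist intervals overlap: [",
               w[1L], ",", w[2L], ") vs [", b[1L], ",", b[2L], ")")
        }
      }
    }
  }
  keep <- snv_profile$depth >= params$min_depth &
    snv_profile$freq >= params$min_freq
  if (!is.null(params$whitelist)) {
    keep <- keep & in_intervals(snv_profile$pos, params$whitelist)
  }
  if (!is.null(params$blacklist)) {
    keep <- keep & !in_intervals(snv_profile$pos, params$blacklist)
  }
  out <- snv_profile
  out$pos <- snv_profile$pos[keep]
  out$freq <- snv_profile$freq[keep]
  out$depth <- snv_profile$depth[keep]
  out
}

#' Distance between two SNV profiles
#'
#' Vectors are built over the union of variant positions; a position absent
#' from a profile contributes 0 when that sample covers it at
#' `min_depth`, and the position is dropped for the pair when either
#' sample does not.
#'
#' @param a,b `snv_profile` objects on the same reference.
#' @param metric distance metric name.
#' @param min_depth coverage gate for implicit zeros.
#' @return non-negative scalar distance.
#' @export
profile_distance <- function(a, b, metric = "euclidean", min_depth = 10L) {
  metric <- match.arg(metric, CLUSTER_METRICS)
  if (a$ref_id != b$ref_id) {
    stop("profiles on different references: ", a$ref_id, " vs ", b$ref_id)
  }
  pos <- sort(union(a$pos, b$pos))
  if (length(pos) == 0L) return(0)
  cov_a <- a$depth_vector[pos + 1L] >= min_depth
  cov_b <- b$depth_vector[pos + 1L] >= min_depth
  pos <- pos[cov_a & cov_b]
  va <- ifelse(pos %in% a$pos, a$freq[match(pos, a$pos)], 0)
  vb <- ifelse(pos %in% b$pos, b$freq[match(pos, b$pos)], 0)
  metric_distance(va, vb, metric)
}

metric_distance <- function(va, vb, metric) {
  if (length(va) == 0L) return(0)
  switch(metric,
    euclidean = sqrt(sum((va - vb)^2)),
    manhattan = sum(abs(va - vb)),
    canberra = {
      s <- va + vb
      ok <- s > 0
      if (!any(ok)) 0 else sum(abs(va[ok] - vb[ok]) / s[ok])
    },
    pearson = {
      if (length(va) < 2L || stats::sd(va) == 0 || stats::sd(vb) == 0) {
        r <- if (isTRUE(all.equal(va, vb))) 1 else 0
      } else {
        r <- stats::cor(va, vb)
      }
      1 - r
    })
}

#' Pairwise distance matrix over a set of SNV profiles
#'
#' Profiles are filtered with [filter_profile()] first.
#'
#' @param profiles named list of `snv_profile` objects (>= 2, shared
#'   reference).
#' @param params [cluster_params()].
#' @return symmetric numeric matrix with zero diagonal, labelled by
#'   profile names.
#' @export
distance_matrix <- function(profiles, params = cluster_params()) {
  if (length(profiles) < 2L) stop("need at least 2 profiles")
  labels <- names(profiles) %||% paste0("sample", seq_along(profiles))
  if (anyDuplicated(labels)) stop("profile labels must be unique")
  filtered <- lapply(profiles, filter_profile, params = params)
  n <- length(filtered)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- profile_distance(filtered[[i]], filtered[[j]], params$metric,
                            params$min_depth)
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  m
}

leaf_node <- function(label, branch = 0) {
  list(label = label, branch = branch)
}

#' Hierarchical clustering of a distance matrix into a phylogram
#'
#' `single`/`complete`/`average` perform standard agglomerative merging
#' with node height equal to half the merge distance, so branch lengths are
#' height differences and UPGMA output is ultrametric. `neighbor_joining`
#' is standard NJ with negative branch lengths clamped to 0 and the final
#' two nodes joined under the root. Ties are broken deterministically by
#' the lexicographically smallest (label, label) pair, where a cluster is
#' labelled by its smallest member.
#'
#' @param matrix symmetric distance matrix with unique labels.
#' @param linkage linkage name.
#' @return tree (nested list) serializable with [write_newick()].
#' @export
hierarchical_cluster <- function(matrix, linkage = "average") {
  linkage <- match.arg(linkage, CLUSTER_LINKAGES)
  if (any(is.na(matrix)) || any(matrix < 0)) {
    stop("distance matrix must be non-negative and free of NA/NaN")
  }
  labels <- rownames(matrix)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop("distance matrix must carry unique labels")
  }
  n <- nrow(matrix)
  if (n < 2L) stop("need at least 2 samples")
  if (linkage == "neighbor_joining") {
    return(nj_tree(matrix))
  }
  # active cluster state
  nodes <- lapply(labels, leaf_node)
  members <- as.list(labels)
  heights <- rep(0, n)
  sizes <- rep(1L, n)
  d <- matrix
  repr <- labels   # smallest member label per cluster
  while (length(nodes) > 1L) {
    k <- length(nodes)
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        pair <- sort(c(repr[i], repr[j]))
        if (is.null(best) || d[i, j] < best$d - 1e-15 ||
            (abs(d[i, j] - best$d) <= 1e-15 &&
             (pair[1L] < best$pair[1L] ||
              (pair[1L] == best$pair[1L] && pair[2L] < best$pair[2L])))) {
          best <- list(i = i, j = j, d = d[i, j], pair = pair)
        }
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    node_i <- nodes[[i]]; node_i$branch <- h - heights[i]
    node_j <- nodes[[j]]; node_j$branch <- h - heights[j]
    kids <- if (repr[i] <= repr[j]) list(node_i, node_j) else
      list(node_j, node_i)
    merged <- list(children = kids, branch = NA_real_)
    new_d <- vapply(seq_len(k), function(m) {
      if (m == i || m == j) return(NA_real_)
      switch(linkage,
        single = min(d[i, m], d[j, m]),
        complete = max(d[i, m], d[j, m]),
        average = (sizes[i] * d[i, m] + sizes[j] * d[j, m]) /
          (sizes[i] + sizes[j]))
    }, numeric(1))
    keep <- setdiff(seq_len(k), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], new_d[keep]),
               c(new_d[keep], 0))
    nodes <- c(nodes[keep], list(merged))
    members <- c(members[keep],
                 list(c(members[[i]], members[[j]])))
    heights <- c(heights[keep], h)
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
    repr <- c(repr[keep], min(best$pair))
  }
  root <- nodes[[1L]]
  root$branch <- NULL
  root
}

# Standard neighbor joining on a labelled distance matrix.
nj_tree <- function(d) {
  labels <- rownames(d)
  n <- nrow(d)
  nodes <- lapply(labels, leaf_node)
  repr <- labels
  active <- seq_len(n)
  dm <- d
  while (length(active) > 2L) {
    k <- length(active)
    r <- rowSums(dm)
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        q <- (k - 2) * dm[i, j] - r[i] - r[j]
        pair <- sort(c(repr[i], repr[j]))
        if (is.null(best) || q < best$q - 1e-12 ||
            (abs(q - best$q) <= 1e-12 &&
             (pair[1L] < best$pair[1L] ||
              (pair[1L] == best$pair[1L] && pair[2L] < best$pair[2L])))) {
          best <- list(i = i, j = j, q = q, pair = pair)
        }
      }
    }
    i <- best$i; j <- best$j
    bi <- 0.5 * dm[i, j] + (r[i] - r[j]) / (2 * (k - 2))
    bj <- dm[i, j] - bi
    bi <- max(bi, 0); bj <- max(bj, 0)
    node_i <- nodes[[i]]; node_i$branch <- bi
    node_j <- nodes[[j]]; node_j$branch <- bj
    kids <- if (repr[i] <= repr[j]) list(node_i, node_j) else
      list(node_j, node_i)
    merged <- list(children = kids, branch = NA_real_)
    new_d <- vapply(seq_len(k), function(m) {
      if (m == i || m == j) return(NA_real_)
      0.5 * (dm[i, m] + dm[j, m] - dm[i, j])
    }, numeric(1))
    keep <- setdiff(seq_len(k), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], pmax(new_d[keep], 0)),
                c(pmax(new_d[keep], 0), 0))
    nodes <- c(nodes[keep], list(merged))
    repr <- c(repr[keep], min(best$pair))
    active <- seq_len(k - 1L)
  }
  b <- max(dm[1L, 2L], 0) / 2
  a1 <- nodes[[1L]]; a1$branch <- b
  a2 <- nodes[[2L]]; a2$branch <- b
  kids <- if (repr[1L] <= repr[2L]) list(a1, a2) else list(a2, a1)
  list(children = kids, branch = NULL)
}

#' All leaf labels of a tree
#' @param tree tree node.
#' @return character vector.
#' @export
tree_leaves <- function(tree) {
  if (!is.null(tree$label)) return(tree$label)
  unlist(lapply(tree$children, tree_leaves))
}

#' Root-to-leaf depth per leaf (for ultrametricity checks)
#' @param tree tree node.
#' @return named numeric vector of root-to-leaf path lengths.
#' @export
tree_depths <- function(tree) {
  walk <- function(node, acc) {
    b <- node$branch
    if (is.null(b) || is.na(b)) b <- 0
    if (!is.null(node$label)) {
      return(stats::setNames(acc + b, node$label))
    }
    unlist(lapply(node$children, walk, acc = acc + b))
  }
  walk(tree, 0)
}
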