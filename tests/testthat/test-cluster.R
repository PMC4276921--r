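# Clustering contracts: filtering as a per-position predicate, the four
# metrics against brute-force recomputation, agglomerative linkages against
# stats::hclust, NJ against ape, ultrametricity and tie-break determinism.

test_that("filter_profile applies depth/frequency/interval predicates", {
  sp <- make_snv_profile(c(10, 20, 30, 40), c(0.1, 0.5, 1.0, 0.9), 100)

  same <- filter_profile(sp, cluster_params(min_depth = 1, min_freq = 0))
  expect_equal(same$pos, sp$pos)

  fixed <- filter_profile(sp, cluster_params(min_depth = 1, min_freq = 1))
  expect_equal(fixed$pos, 30L)

  expect_error(
    filter_profile(sp, cluster_params(whitelist = list(c(0, 50)),
                                      blacklist = list(c(40, 60)))),
    "overlap")

  # predicate oracle on a random profile with random interval filters
  set.seed(7)
  pos <- sort(sample(0:499, 60))
  freq <- runif(60)
  depth_vec <- sample(5:50, 500, replace = TRUE)
  spr <- make_snv_profile(pos, freq, 500, depth = 10L,
                          depth_vector = depth_vec)
  spr$depth <- depth_vec[pos + 1L]
  params <- cluster_params(min_depth = 15, min_freq = 0.3,
                           whitelist = list(c(0, 200), c(300, 450)),
                           blacklist = list(c(220, 260)))
  got <- filter_profile(spr, params)
  keep <- vapply(seq_along(pos), function(i) {
    p <- pos[i]
    depth_vec[p + 1L] >= 15 && freq[i] >= 0.3 &&
      ((p >= 0 && p < 200) || (p >= 300 && p < 450)) &&
      !(p >= 220 && p < 260)
  }, logical(1))
  expect_equal(got$pos, pos[keep])
  expect_equal(got$freq, freq[keep])
})

test_that("profile distances satisfy identity and single-coordinate cases", {
  sp <- make_snv_profile(c(5, 9), c(0.4, 0.8), 50)
  for (m in c("euclidean", "manhattan", "canberra", "pearson")) {
    expect_equal(profile_distance(sp, sp, m), 0)
  }

  a <- make_snv_profile(7, 1.0, 50)
  b <- make_snv_profile(integer(0), numeric(0), 50)
  expect_equal(profile_distance(a, b, "manhattan"), 1)
  expect_equal(profile_distance(a, b, "euclidean"), 1)
  expect_equal(profile_distance(a, b, "canberra"), 1)

  other <- make_snv_profile(7, 1.0, 50, ref_id = "other")
  expect_error(profile_distance(a, other, "euclidean"), "different")
})

test_that("metrics equal a direct loop recomputation on random profiles", {
  set.seed(11)
  mk <- function() {
    pos <- sort(sample(0:999, 200))
    make_snv_profile(pos, runif(200), 1000)
  }
  a <- mk(); b <- mk()
  pos_u <- sort(union(a$pos, b$pos))
  va <- vb <- numeric(length(pos_u))
  for (i in seq_along(pos_u)) {
    if (pos_u[i] %in% a$pos) va[i] <- a$freq[match(pos_u[i], a$pos)]
    if (pos_u[i] %in% b$pos) vb[i] <- b$freq[match(pos_u[i], b$pos)]
  }
  expect_equal(profile_distance(a, b, "euclidean"),
               sqrt(sum((va - vb)^2)), tolerance = 1e-12)
  expect_equal(profile_distance(a, b, "manhattan"),
               sum(abs(va - vb)), tolerance = 1e-12)
  can <- 0
  for (i in seq_along(va)) {
    if (va[i] + vb[i] > 0) can <- can + abs(va[i] - vb[i]) / (va[i] + vb[i])
  }
  expect_equal(profile_distance(a, b, "canberra"), can, tolerance = 1e-12)
  expect_equal(profile_distance(a, b, "pearson"),
               1 - stats::cor(va, vb), tolerance = 1e-12)
})

test_that("distance_matrix is symmetric and consistent with pairs", {
  set.seed(13)
  profiles <- lapply(1:4, function(i) {
    pos <- sort(sample(0:199, 30))
    make_snv_profile(pos, runif(30), 200)
  })
  names(profiles) <- paste0("s", 1:4)
  params <- cluster_params(min_depth = 1)
  m <- distance_matrix(profiles, params)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
  expect_equal(m["s1", "s3"],
               profile_distance(profiles[[1]], profiles[[3]],
                                "euclidean", 1))
  expect_error(distance_matrix(profiles[1], params), "at least 2")

  ident <- distance_matrix(list(a = profiles[[1]], b = profiles[[1]],
                                c = profiles[[1]]), params)
  expect_true(all(ident == 0))
})

test_that("forced merges behave and 2-sample UPGMA is exact", {
  d <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(write_newick(hierarchical_cluster(d, "average")),
               "(A:1.0,B:1.0);")

  d3 <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  for (lk in c("single", "complete", "average")) {
    tr <- hierarchical_cluster(d3, lk)
    # A and B merge first: the root has C as a direct child
    kid_labels <- vapply(tr$children, function(ch) {
      if (!is.null(ch$label)) ch$label else ""
    }, character(1))
    expect_true("C" %in% kid_labels)
  }
  bad <- d3; bad[1, 2] <- NA
  expect_error(hierarchical_cluster(bad, "average"), "NA")
})

test_that("agglomerative linkages match stats::hclust merge-for-merge", {
  set.seed(17)
  for (rep in 1:3) {
    pts <- matrix(runif(16), 8)
    rownames(pts) <- paste0("s", 1:8)
    d <- as.matrix(dist(pts))
    for (lk in c("single", "complete", "average")) {
      ours <- tree_merges(hierarchical_cluster(d, lk))
      hc_method <- if (lk == "average") "average" else lk
      ref <- hclust_merges(stats::hclust(stats::as.dist(d), hc_method))
      expect_equal(length(ours), length(ref))
      key <- function(ms) {
        ms[order(vapply(ms, `[[`, numeric(1), "height"))]
      }
      ours <- key(ours); ref <- key(ref)
      for (i in seq_along(ours)) {
        expect_equal(ours[[i]]$leaves, ref[[i]]$leaves)
        expect_equal(ours[[i]]$height, ref[[i]]$height, tolerance = 1e-9)
      }
    }
  }
})

test_that("neighbor joining recovers random additive topologies", {
  skip_if_not_installed("ape")
  skip_if_not_installed("phangorn")
  set.seed(19)
  for (rep in 1:3) {
    truth <- ape::rtree(8)
    d <- ape::cophenetic.phylo(truth)
    d <- d[sort(rownames(d)), sort(rownames(d))]
    ours <- ape::read.tree(
      text = write_newick(hierarchical_cluster(d, "neighbor_joining")))
    expect_equal(phangorn::RF.dist(ape::unroot(ours), ape::unroot(truth)),
                 0)
  }
})

test_that("UPGMA output is ultrametric and leaf-complete", {
  set.seed(23)
  pts <- matrix(runif(20), 10)
  rownames(pts) <- paste0("x", 1:10)
  d <- as.matrix(dist(pts))
  tr <- hierarchical_cluster(d, "average")
  depths <- tree_depths(tr)
  expect_setequal(names(depths), rownames(d))
  expect_lt(max(depths) - min(depths), 1e-9)
})

test_that("permuting input order changes nothing in the output tree", {
  set.seed(29)
  pts <- matrix(runif(12), 6)
  rownames(pts) <- paste0("s", 1:6)
  d <- as.matrix(dist(pts))
  perm <- sample(6)
  dp <- d[perm, perm]
  for (lk in c("single", "complete", "average", "neighbor_joining")) {
    expect_identical(write_newick(hierarchical_cluster(d, lk)),
                     write_newick(hierarchical_cluster(dp, lk)))
  }
})
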