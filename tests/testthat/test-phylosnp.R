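# SNV-matrix phylogenetics and shrunk-genome window arithmetic.

test_that("build_snv_matrix keys variants by (position, allele)", {
  s1 <- data.frame(pos = c(100L, 200L), alt_base = c("G", "T"))
  s2 <- data.frame(pos = 100L, alt_base = "G")
  m <- build_snv_matrix(list(a = s1, b = s2))
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(unname(m["a", ]), c(1L, 1L))
  expect_equal(unname(m["b", ]), c(1L, 0L))

  # same position, different allele -> two distinct columns
  m2 <- build_snv_matrix(list(
    a = data.frame(pos = 100L, alt_base = "G"),
    b = data.frame(pos = 100L, alt_base = "T")))
  expect_equal(ncol(m2), 2L)
  expect_equal(sum(m2), 2L)

  ident <- build_snv_matrix(list(a = s1, b = s1))
  expect_equal(unname(ident["a", ]), unname(ident["b", ]))

  expect_error(build_snv_matrix(stats::setNames(list(s1, s2), c("a", "a"))),
               "unique")

  # row sums equal per-sample variant counts on simulated truth
  g <- make_genome(2000, seed = 101)
  truths <- lapply(1:4, function(i) {
    mutate_genome(g, n_snvs = 5 + i, seed = 110 + i)$truth
  })
  names(truths) <- paste0("t", 1:4)
  mm <- build_snv_matrix(truths)
  expect_equal(unname(rowSums(mm)), vapply(truths, nrow, integer(1),
                                           USE.NAMES = FALSE))
})

test_that("snv_tree distances are Hamming counts with documented ties", {
  rows <- list(
    A = data.frame(pos = c(1L, 2L), alt_base = c("G", "G")),
    B = data.frame(pos = 1L, alt_base = "G"),
    C = data.frame(pos = integer(0), alt_base = character(0)))
  m <- build_snv_matrix(rows)
  d <- snv_hamming(m)
  expect_equal(d["A", "B"], 1)
  expect_equal(d["A", "C"], 2)
  expect_equal(d["B", "C"], 1)
  # d(A,B) == d(B,C) == 1: tie broken to the lexicographically
  # smallest pair (A,B)
  tr <- snv_tree(m, "average")
  inner <- Filter(function(ch) is.null(ch$label), tr$children)[[1]]
  expect_setequal(tree_leaves(inner), c("A", "B"))

  zero <- build_snv_matrix(list(A = rows$A, B = rows$A))
  trz <- snv_tree(zero)
  expect_equal(unname(tree_depths(trz)), c(0, 0))
})

test_that("two simulated clades separate in the SNV tree", {
  g <- make_genome(3000, seed = 121)
  shared1 <- mutate_genome(g, n_snvs = 10, seed = 122)$truth
  shared2 <- mutate_genome(g, n_snvs = 10, seed = 123)$truth
  private <- function(s) mutate_genome(g, n_snvs = 3, seed = s)$truth
  clade1 <- lapply(1:2, function(i) rbind(shared1, private(130 + i)))
  clade2 <- lapply(1:2, function(i) rbind(shared2, private(140 + i)))
  samples <- c(stats::setNames(clade1, c("c1a", "c1b")),
               stats::setNames(clade2, c("c2a", "c2b")))
  tr <- snv_tree(build_snv_matrix(samples), "average")
  for (ch in tr$children) {
    leaves <- sort(tree_leaves(ch))
    expect_true(identical(leaves, c("c1a", "c1b")) ||
                  identical(leaves, c("c2a", "c2b")))
  }
})

test_that("shrink_windows merges flanks like an interval union", {
  w <- shrink_windows(100L, 5L, 1000L)
  expect_equal(w$start, 95L)
  expect_equal(w$end, 106L)
  expect_equal(sum(w$end - w$start), 11L)

  w2 <- shrink_windows(c(100L, 104L), 5L, 1000L)
  expect_equal(nrow(w2), 1L)
  expect_equal(c(w2$start, w2$end), c(95L, 110L))
  expect_equal(sum(w2$end - w2$start), 15L)

  # clipping at reference bounds
  w3 <- shrink_windows(c(2L, 998L), 5L, 1000L)
  expect_equal(w3$start, c(0L, 993L))
  expect_equal(w3$end, c(8L, 1000L))

  skip_if_not_installed("IRanges")
  set.seed(31)
  pos <- sample(0:9999, 200)
  flank <- 25L
  w4 <- shrink_windows(pos, flank, 10000L)
  ir <- IRanges::reduce(IRanges::IRanges(
    start = pmax(0L, pos - flank) + 1L,
    end = pmin(10000L, pos + flank + 1L)))
  expect_equal(sum(w4$end - w4$start), sum(IRanges::width(ir)))
  expect_equal(w4$start, IRanges::start(ir) - 1L)
  expect_equal(w4$end, IRanges::end(ir))
})

test_that("shrunk genomes are equal-length with alleles substituted", {
  ref <- make_genome(500, seed = 151, id = "ref1")
  none <- shrunk_genomes(ref, list(a = data.frame(pos = integer(0),
                                                  alt_base = character(0)),
                                   b = data.frame(pos = integer(0),
                                                  alt_base = character(0))),
                         flank = 5)
  expect_true(all(nchar(none) == 0L))

  rb <- substr(ref$seq, 101, 101)
  alt <- setdiff(c("A", "C", "G", "T"), rb)[1]
  one <- shrunk_genomes(ref,
                        list(s = data.frame(pos = 100L, alt_base = alt)),
                        flank = 2)
  expect_equal(unique(nchar(one)), 5L)
  diffs <- which(strsplit(one[["s"]], "")[[1]] !=
                   strsplit(one[["reference"]], "")[[1]])
  expect_equal(diffs, 3L)
})

test_that("shrunk-genome Hamming equals variant symmetric difference", {
  ref <- make_genome(5000, seed = 161, id = "ref1")
  # positions far apart relative to flank: windows never share two variants
  mk <- function(seed) {
    m <- mutate_genome(ref, n_snvs = 6, seed = seed)
    m$truth[, c("pos", "alt_base")]
  }
  samples <- list(a = mk(162), b = mk(163), c = mk(164))
  all_pos <- sort(unique(unlist(lapply(samples, `[[`, "pos"))))
  if (min(diff(all_pos)) > 9) {       # guard the premise, flank 4 below
    sg <- shrunk_genomes(ref, samples, flank = 4)
    key <- function(s) paste0(s$pos, ":", s$alt_base)
    for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
      h <- sum(strsplit(sg[[pair[1]]], "")[[1]] !=
                 strsplit(sg[[pair[2]]], "")[[1]])
      sym <- length(union(setdiff(key(samples[[pair[1]]]),
                                  key(samples[[pair[2]]])),
                          setdiff(key(samples[[pair[2]]]),
                                  key(samples[[pair[1]]]))))
      expect_equal(h, sym)
    }
    # tree from shrunk alignment matches tree from the SNV matrix
    labs <- names(samples)
    dH <- matrix(0, 3, 3, dimnames = list(labs, labs))
    for (i in 1:2) for (j in (i + 1):3) {
      dH[i, j] <- dH[j, i] <-
        sum(strsplit(sg[[labs[i]]], "")[[1]] !=
              strsplit(sg[[labs[j]]], "")[[1]])
    }
    t1 <- write_newick(hierarchical_cluster(dH, "average"))
    t2 <- write_newick(snv_tree(build_snv_matrix(samples), "average"))
    expect_identical(t1, t2)
  } else {
    succeed("random positions collided; premise of the fixture not met")
  }
})
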