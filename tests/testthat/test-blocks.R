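test_that("greedy segmentation follows the span, chromosome and homogeneity rules", {
  # 8 CpGs in 200 bp, homogeneous -> one block of 8
  m8 <- uniform_map(8, spacing = 25)
  b <- segment_genome(matrix(0.9, 8, 3), m8, min_cpg = 4, max_bp = 5000)
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_cpgs, 8L)
  expect_equal(b$start_cpg, 0L)
  expect_equal(b$end_cpg, 8L)

  # CpGs 6000 bp apart: span rule forces singletons, all dropped
  far <- uniform_map(8, spacing = 6000)
  expect_equal(nrow(segment_genome(matrix(0.9, 8, 2), far,
                                   min_cpg = 4, max_bp = 5000)), 0L)

  # 4 CpGs at 0.0 then 4 at 1.0: boundary exactly at the jump
  jump <- segment_genome(matrix(rep(c(0, 1), each = 4), ncol = 1),
                         uniform_map(8), min_cpg = 4, max_bp = 5000,
                         homogeneity_tol = 0.25)
  expect_equal(nrow(jump), 2L)
  expect_equal(jump$start_cpg, c(0L, 4L))
  expect_equal(jump$end_cpg, c(4L, 8L))

  # blocks never span chromosomes; output disjoint and sorted
  map2 <- cpg_map(rep(c("chr1", "chr2"), each = 6),
                  rep(seq(1000, by = 30, length.out = 6), 2))
  b2 <- segment_genome(matrix(0.5, 12, 2), map2, min_cpg = 4)
  expect_equal(nrow(b2), 2L)
  expect_equal(b2$chrom, c("chr1", "chr2"))
  expect_true(all(diff(b2$start_cpg) > 0))
  expect_true(all(b2$start_cpg[-1] >= b2$end_cpg[-nrow(b2)]))

  fake <- structure(data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                               index = c(2L, 0L, 1L)),
                    class = c("cpg_map", "data.frame"))
  expect_error(segment_genome(matrix(0.5, 3, 1), fake, min_cpg = 1),
               "unsorted")
})

test_that("block table cells equal the brute-force per-CpG tally ratio", {
  blocks <- segment_genome(matrix(0.5, 20, 1), uniform_map(20), min_cpg = 4)
  x <- fc(c(0, "CCTT"), c(2, "TTTT", 2), c(10, "C.CC"), c(15, "TCTCT"),
          n_cpgs = 20)
  tab <- block_methylation_table(blocks, list(s1 = x), min_depth = 1)
  oracle <- brute_tally(x, 20)
  for (i in seq_len(nrow(blocks))) {
    idx <- (blocks$start_cpg[i] + 1):blocks$end_cpg[i]
    expect_equal(unname(tab$meth[i, 1]),
                 sum(oracle$meth[idx]) / sum(oracle$total[idx]))
  }
  # 3 methylated of 10 calls -> 0.3
  one <- block_methylation_table(
    structure(data.frame(chrom = "chr1", start_bp = 1000, end_bp = 1250,
                         start_cpg = 0L, end_cpg = 10L, n_cpgs = 10L),
              class = c("block_set", "data.frame")),
    list(s = fc(c(0, "CCCTTTTTTT"), n_cpgs = 10)), min_depth = 1)
  expect_equal(unname(one$meth[1, 1]), 0.3)
})

test_that("cells with coverage below min_depth are missing", {
  blocks <- structure(data.frame(chrom = "chr1", start_bp = 1000,
                                 end_bp = 1250, start_cpg = 0L, end_cpg = 10L,
                                 n_cpgs = 10L),
                      class = c("block_set", "data.frame"))
  four <- fc(c(0, "CCTT"), n_cpgs = 10)          # 4 calls < 5
  tab <- block_methylation_table(blocks, list(s = four), min_depth = 5)
  expect_true(is.na(tab$meth[1, 1]))
  expect_equal(unname(tab$coverage[1, 1]), 4)
  # zero calls: missing regardless of min_depth
  none <- fragment_collection(as.data.frame(four)[0, ], n_cpgs = 10)
  tab0 <- block_methylation_table(blocks, list(s = none), n_cpgs = 10,
                                  min_depth = 0)
  expect_true(is.na(tab0$meth[1, 1]))
})

test_that("top-variance selection excludes incomplete blocks and breaks ties genomically", {
  set.seed(1)
  meth <- matrix(runif(200 * 4), 200, 4)
  blocks <- structure(data.frame(chrom = "chr1",
                                 start_bp = seq(1, by = 300, length.out = 200),
                                 end_bp = seq(251, by = 300, length.out = 200),
                                 start_cpg = seq(0, by = 5, length.out = 200),
                                 end_cpg = seq(5, by = 5, length.out = 200),
                                 n_cpgs = 5L),
                      class = c("block_set", "data.frame"))
  tab <- structure(list(meth = meth, coverage = matrix(50, 200, 4),
                        blocks = blocks, min_depth = 10),
                   class = "block_table")
  top <- top_variance_blocks(tab, 0.01)
  expect_equal(nrow(top$meth), 2L)          # 1% of 200
  v <- apply(meth, 1, var)
  expect_setequal(top$blocks$start_cpg,
                  blocks$start_cpg[order(-v)[1:2]])

  # a block missing in one sample is never selected
  meth2 <- meth; meth2[which.max(v), 2] <- NA
  tab2 <- tab; tab2$meth <- meth2
  top2 <- top_variance_blocks(tab2, 0.01)
  expect_false(blocks$start_cpg[which.max(v)] %in% top2$blocks$start_cpg)

  # constant table: ties resolved by genomic order, size still ceil(f*n)
  tab3 <- tab; tab3$meth <- matrix(0.5, 200, 4)
  top3 <- top_variance_blocks(tab3, 0.01)
  expect_equal(top3$blocks$start_cpg, blocks$start_cpg[1:2])
})

test_that("average-linkage clustering matches hand computation and brute force", {
  # engineered distances: d(A,B) = 1, d(A,C) = d(B,C) = 10
  m <- cbind(A = rep(0, 20), B = rep(0.05, 20), C = rep(c(1, 0), each = 10))
  tab <- structure(list(meth = m, coverage = matrix(99, 20, 3),
                        blocks = NULL, min_depth = 10), class = "block_table")
  h <- cluster_samples(tab)
  expect_equal(h$height, c(1, 10))
  expect_equal(sort(h$merge[1, ]), c(-2, -1))  # A and B merge first

  # duplicated sample: first merge at height 0
  set.seed(5)
  m2 <- cbind(a = runif(10), b = runif(10))
  m2 <- cbind(m2, a2 = m2[, "a"])
  tab2 <- tab; tab2$meth <- m2; tab2$coverage <- matrix(99, 10, 3)
  expect_equal(min(cluster_samples(tab2)$height), 0)

  # permutation invariance of merge heights
  set.seed(7)
  m3 <- matrix(runif(8 * 30), 30, 8, dimnames = list(NULL, letters[1:8]))
  tabA <- tab; tabA$meth <- m3; tabA$coverage <- matrix(99, 30, 8)
  perm <- sample(8)
  tabB <- tab; tabB$meth <- m3[, perm]; tabB$coverage <- matrix(99, 30, 8)
  expect_equal(cluster_samples(tabA)$height, cluster_samples(tabB)$height)

  # brute-force O(n^3) agglomeration oracle, n <= 8
  expect_equal(cluster_samples(tabA)$height, brute_average_linkage(m3))

  # missing cells are the caller's problem
  m4 <- m3; m4[1, 1] <- NA
  tabC <- tab; tabC$meth <- m4; tabC$coverage <- matrix(99, 30, 8)
  expect_error(cluster_samples(tabC), "missing")
})

test_that("block sets round-trip through the 5-column BED dialect", {
  w <- small_world(seed = 3, n_cell_types = 2, n_cpgs = 600,
                   blocks_per_cell_type = 4, n_reps = 1)
  beta <- with(cfdecon:::per_cpg_tally(w$samples$ct01_r1, 600),
               ifelse(total > 0, meth / total, NA))
  blocks <- segment_genome(matrix(beta, ncol = 1), w$map)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_blocks(blocks, p)
  back <- read_blocks(p)
  expect_equal(as.data.frame(back), as.data.frame(blocks)[names(back)])
})
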