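mini_table <- function(meth, coverage = NULL) {
  nb <- nrow(meth)
  blocks <- structure(
    data.frame(chrom = "chr1",
               start_bp = seq(1000, by = 500, length.out = nb),
               end_bp = seq(1250, by = 500, length.out = nb),
               start_cpg = seq(0L, by = 10L, length.out = nb),
               end_cpg = seq(10L, by = 10L, length.out = nb),
               n_cpgs = 10L),
    class = c("block_set", "data.frame"))
  structure(list(meth = meth,
                 coverage = coverage %||% matrix(50, nb, ncol(meth)),
                 blocks = blocks, min_depth = 5),
            class = "block_table")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("candidate screening reproduces the Welch t-test and margin arithmetic", {
  tgt <- c(0.10, 0.15, 0.20)
  bgv <- c(0.80, 0.85, 0.90, 0.75, 0.95)
  meth <- rbind(c(tgt, bgv),                 # clean hypomethylated marker
                rep(0.5, 8))                 # no separation at all
  colnames(meth) <- c(paste0("t", 1:3), paste0("b", 1:5))
  tab <- mini_table(meth)
  cand <- find_markers(tab, paste0("t", 1:3), paste0("b", 1:5), marker_config())
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$diff, 0.70)
  # independent oracle: stats::t.test on the same values
  tt <- t.test(bgv, tgt)
  expect_equal(cand$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(abs((mean(bgv) - mean(tgt)) /
                     sqrt(var(tgt) / 3 + var(bgv) / 5)), 15.34, tolerance = 1e-3)
  # margin = background 2.5th centile - target 75th centile (type-7 quantiles)
  expect_equal(cand$margin,
               quantile(bgv, 0.025, names = FALSE) -
                 quantile(tgt, 0.75, names = FALSE))
  expect_equal(cand$margin, 0.755 - 0.175)

  # identical groups: diff 0 < 0.3, rejected
  same <- mini_table(matrix(c(0.4, 0.5, 0.6, 0.4, 0.5, 0.6), nrow = 1,
                            dimnames = list(NULL, c(paste0("t", 1:3),
                                                    paste0("b", 1:3)))))
  expect_equal(nrow(find_markers(same, paste0("t", 1:3), paste0("b", 1:3))), 0L)
})

test_that("blocks too missing in either group are dropped before testing", {
  meth <- rbind(c(0.1, NA, NA, 0.9, 0.85, 0.8),   # 2/3 target NA -> dropped
                c(0.1, 0.12, 0.15, 0.9, 0.85, 0.8))
  colnames(meth) <- c(paste0("t", 1:3), paste0("b", 1:3))
  cand <- find_markers(mini_table(meth), paste0("t", 1:3), paste0("b", 1:3))
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$start_cpg, 10L)  # only the complete block survives

  # a group with < 2 usable values is skipped even under a lax NA rule
  cfglax <- marker_config(max_na_frac = 0.9)
  cand2 <- find_markers(mini_table(meth[1, , drop = FALSE]),
                        paste0("t", 1:3), paste0("b", 1:3), cfglax)
  expect_equal(nrow(cand2), 0L)

  expect_error(find_markers(mini_table(meth), c("t1", "b1"), c("b1", "b2")),
               "disjoint")
})

test_that("Welch p-values agree with the exact permutation oracle on small fixtures", {
  set.seed(31)
  diffs <- numeric(30)
  for (i in 1:30) {
    x <- rnorm(4, 0.3, 0.1)
    y <- rnorm(4, 0.3 + runif(1, 0, 0.3), 0.1)
    pw <- cfdecon:::welch_rows(matrix(x, 1), matrix(y, 1))$p
    pp <- perm_welch_p(x, y)
    diffs[i] <- pw - pp
  }
  # exact permutation granularity is 1/35 for 4v4; agreement is approximate
  expect_lt(mean(abs(diffs)), 0.05)
  expect_lt(max(abs(diffs)), 0.15)
})

test_that("ranking orders by margin with p-value then genomic tie-breaks", {
  cand <- data.frame(chrom = "chr1", start_bp = c(3000, 1000, 2000),
                     end_bp = c(3200, 1200, 2200),
                     start_cpg = c(30L, 10L, 20L), end_cpg = c(35L, 15L, 25L),
                     n_cpgs = 5L, target_mean = 0.1, background_mean = 0.9,
                     diff = 0.8, p_value = c(1e-4, 1e-3, 1e-3),
                     margin = c(0.5, 0.3, 0.3))
  expect_equal(rank_and_select(cand, 1)$margin, 0.5)
  # saturation: k >= n returns everything, margin order
  expect_equal(rank_and_select(cand, 10)$start_cpg, c(30L, 10L, 20L))
  # equal margins and p: genomic order, stable across runs
  cand$p_value <- 1e-3; cand$margin <- 0.3
  expect_equal(rank_and_select(cand, 3)$start_cpg, c(10L, 20L, 30L))
  expect_identical(rank_and_select(cand, 3), rank_and_select(cand, 3))
  expect_warning(out <- rank_and_select(cand[0, ], 5), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("hypermethylated selection equals hypomethylated selection on the flipped table", {
  set.seed(13)
  meth <- matrix(runif(40 * 8), 40, 8,
                 dimnames = list(NULL, c(paste0("t", 1:3), paste0("b", 1:5))))
  meth[1:5, 1:3] <- meth[1:5, 1:3] * 0.1 + 0.88   # target-hypermethylated rows
  tabA <- mini_table(meth)
  tabB <- mini_table(1 - meth)
  hyper <- find_markers(tabA, paste0("t", 1:3), paste0("b", 1:5),
                        marker_config(direction = "hypermethylated"))
  hypo <- find_markers(tabB, paste0("t", 1:3), paste0("b", 1:5),
                       marker_config(direction = "hypomethylated"))
  expect_equal(hyper$start_cpg, hypo$start_cpg)
  expect_equal(hyper$diff, hypo$diff)
  expect_equal(hyper$p_value, hypo$p_value)
  expect_equal(hyper$margin, hypo$margin)
})

test_that("planted markers are recovered with no false positives on synthetic data", {
  hits <- 0; planted <- 0; fp <- 0
  for (seed in 1:5) {
    w <- small_world(seed = 600 + seed)
    n <- nrow(w$map)
    blocks <- segment_genome(
      vapply(w$samples, function(s) {
        t <- cfdecon:::per_cpg_tally(s, n)
        ifelse(t$total > 0, t$meth / t$total, NA)
      }, numeric(n)), w$map)
    tab <- block_methylation_table(blocks, w$samples, n_cpgs = n, min_depth = 5)
    sel <- select_all_markers(tab, w$groups, marker_config(k = 50))
    led <- w$refs$ledger
    planted <- planted + nrow(led)
    # a marker counts as a planted hit when it overlaps a planted block of
    # the same cell type (segmentation may trim a boundary CpG)
    overlaps_planted <- vapply(seq_len(nrow(sel)), function(i) {
      own <- led[led$cell_type == sel$cell_type[i], ]
      any(sel$start_cpg[i] < own$end_cpg & sel$end_cpg[i] > own$start_cpg)
    }, logical(1))
    hit_planted <- vapply(seq_len(nrow(led)), function(i) {
      own <- sel[sel$cell_type == led$cell_type[i], ]
      any(led$start_cpg[i] < own$end_cpg & led$end_cpg[i] > own$start_cpg)
    }, logical(1))
    hits <- hits + sum(hit_planted)
    fp <- fp + sum(!overlaps_planted)
  }
  expect_gte(hits / planted, 0.95)
  expect_lte(fp / planted, 0.02)
})

test_that("marker sets round-trip through their TSV dialect", {
  cand <- data.frame(chrom = "chr1", start_bp = 1000L, end_bp = 1200L,
                     start_cpg = 10L, end_cpg = 15L, n_cpgs = 5L,
                     target_mean = 0.1, background_mean = 0.9, diff = 0.8,
                     p_value = 1e-4, margin = 0.5)
  sel <- rank_and_select(cand, 1, cell_type = "ct01")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_markers(sel, p)
  back <- read_markers(p)
  expect_equal(back$start_cpg, 10L)
  expect_equal(back$end_cpg, 15L)
  expect_equal(back$cell_type, "ct01")
  expect_equal(back$margin, 0.5)
})
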