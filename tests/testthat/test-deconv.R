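one_marker <- function(start = 0L, end = 20L) {
  structure(data.frame(chrom = "chr1", start_bp = 1000L,
                       end_bp = 1000L + (end - start) * 25L,
                       start_cpg = start, end_cpg = end,
                       n_cpgs = end - start, cell_type = "ct01"),
            class = c("marker_set", "data.frame"))
}

test_that("fragments classify as U/X/M by their in-marker methylated fraction", {
  mk <- list(start_cpg = 0L, end_cpg = 10L)
  expect_equal(classify_fragment(list(start_cpg = 0L, pattern = "TTTT"), mk), "U")
  expect_equal(classify_fragment(list(start_cpg = 0L, pattern = "CCC"), mk), "M")
  expect_equal(classify_fragment(list(start_cpg = 0L, pattern = "CT"), mk),
               "excluded")
  expect_equal(classify_fragment(list(start_cpg = 0L, pattern = "CCTT"), mk), "X")
  # only in-marker, non-missing calls count
  expect_equal(classify_fragment(list(start_cpg = 8L, pattern = "TT.CCCC"), mk),
               "excluded")  # 2 observed calls inside [0,10)
  expect_equal(classify_fragment(list(start_cpg = 7L, pattern = "TTTCCCC"), mk),
               "U")         # calls at 7,8,9 inside; the Cs fall outside
})

test_that("atlas entries are the U-fraction of classified reference fragments", {
  mk <- one_marker()
  all_u <- fc(c(0, "TTTT", 50), c(5, "TTTTT", 50), n_cpgs = 30)
  all_m <- fc(c(0, "CCCC", 50), c(5, "CCCCC", 50), n_cpgs = 30)
  atlas <- build_atlas(list(ct01 = all_u, ct02 = all_m), mk)
  expect_equal(unname(atlas$A[1, ]), c(1, 0))

  # propensity 0.5, 4-call fragments: exact closed form P(Binom(4, .5) <= 1)
  set.seed(77)
  n <- 60000
  pats <- vapply(seq_len(n), function(i) {
    paste(ifelse(rbinom(4, 1, 0.5) == 1, "C", "T"), collapse = "")
  }, character(1))
  half <- fragment_collection(
    data.frame(chrom = "chr1", start_cpg = sample(0:16, n, replace = TRUE),
               pattern = pats, count = 1L), n_cpgs = 30)
  a2 <- build_atlas(list(ct01 = half, ct02 = all_m), mk)
  p_exact <- 5 / 16  # P(0 or 1 methylated of 4) at the 0.25 threshold
  expect_lt(abs(a2$A[1, "ct01"] - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / n))

  # a cell type with no classifiable fragments is a named error
  expect_error(build_atlas(list(ct01 = all_u,
                                ctXX = fc(c(25, "CT"), n_cpgs = 30)), mk),
               "ctXX")
})

test_that("deconvolution recovers pure and engineered mixtures", {
  w <- small_world(seed = 55, n_cell_types = 3, n_cpgs = 3000,
                   blocks_per_cell_type = 12, coverage = 30)
  n <- nrow(w$map)
  blocks <- segment_genome(
    vapply(w$samples, function(s) {
      t <- cfdecon:::per_cpg_tally(s, n)
      ifelse(t$total > 0, t$meth / t$total, NA)
    }, numeric(n)), w$map)
  tab <- block_methylation_table(blocks, w$samples, n_cpgs = n, min_depth = 5)
  sel <- select_all_markers(tab, w$groups, marker_config(k = 12))
  pool <- function(ct) {
    fragment_collection(do.call(rbind, lapply(w$samples[w$groups[[ct]]],
                                              as.data.frame)),
                        n_cpgs = n, provenance = ct)
  }
  atlas <- build_atlas(lapply(setNames(nm = names(w$groups)), pool), sel)

  # pure mixture: proportion ~1 for the source cell type
  pure <- sample_fragments(w$refs, cell_type = "ct02", coverage = 30, seed = 999)
  fit <- deconvolve(pure, atlas)
  expect_gt(fit$proportions["ct02"], 0.98)
  expect_equal(sum(fit$proportions), 1)
  expect_true(all(fit$proportions >= 0))

  # methods behave like a model fit
  expect_equal(coef(fit), fit$proportions)
  expect_equal(length(residuals(fit)), fit$n_markers_used)
  expect_equal(fitted(fit) + residuals(fit), fit$b)

  # engineered three-way mixture recovered within 0.02 at 30x
  mix1 <- mix_fragments(pool("ct01"), pool("ct02"), 0.5, 20, seed = 5)
  mix2 <- mix_fragments(mix1, pool("ct03"), 0.5, 20, seed = 6)
  fit2 <- deconvolve(mix2, atlas)
  expect_lt(max(abs(fit2$proportions - c(0.25, 0.25, 0.5))), 0.05)
})

test_that("NNLS proportions match identity algebra and the grid-search oracle", {
  mk <- rbind(one_marker(0L, 10L), one_marker(10L, 20L))
  atlas <- structure(list(A = diag(2), markers = mk,
                          support = matrix(99, 2, 2), config = deconv_config()),
                     class = "uxm_atlas")
  colnames(atlas$A) <- c("ct01", "ct02"); rownames(atlas$A) <- c("m1", "m2")
  # mixture whose U-fractions are exactly (0.3, 0.7) over the two markers
  mix <- fc(c(0, "TTT", 30), c(0, "CCC", 70), c(10, "TTT", 70), c(10, "CCC", 30),
            n_cpgs = 20)
  fit <- deconvolve(mix, atlas)
  expect_equal(unname(fit$proportions), c(0.3, 0.7), tolerance = 1e-9)

  # grid oracle on a random well-conditioned 2-type problem
  set.seed(11)
  A <- matrix(runif(12, 0.05, 0.95), 6, 2)
  b <- as.numeric(A %*% c(0.26, 0.74)) + rnorm(6, 0, 0.01)
  x_nnls <- pracma::lsqnonneg(A, b)$x
  x_grid <- grid_nnls_2(A, b)
  expect_lt(max(abs(x_nnls - x_grid)), 0.011)  # within one 0.01 grid step

  # noiseless pure column: proportion 1 +- 1e-6
  b2 <- A[, 1]
  x2 <- pracma::lsqnonneg(A, b2)$x
  expect_equal(x2 / sum(x2), c(1, 0), tolerance = 1e-6)

  expect_error(deconvolve(fc(c(0, "CT"), n_cpgs = 20), atlas),
               "no informative markers")
})

test_that("estimation error does not grow with coverage", {
  w <- small_world(seed = 91, n_cell_types = 3, n_cpgs = 3000,
                   blocks_per_cell_type = 12, coverage = 30)
  n <- nrow(w$map)
  blocks <- segment_genome(
    vapply(w$samples, function(s) {
      t <- cfdecon:::per_cpg_tally(s, n)
      ifelse(t$total > 0, t$meth / t$total, NA)
    }, numeric(n)), w$map)
  tab <- block_methylation_table(blocks, w$samples, n_cpgs = n, min_depth = 5)
  sel <- select_all_markers(tab, w$groups, marker_config(k = 12))
  pool <- function(ct) {
    fragment_collection(do.call(rbind, lapply(w$samples[w$groups[[ct]]],
                                              as.data.frame)),
                        n_cpgs = n, provenance = ct)
  }
  atlas <- build_atlas(lapply(setNames(nm = names(w$groups)), pool), sel)
  spike <- sample_fragments(w$refs, cell_type = "ct01", coverage = 20, seed = 321)
  bg <- mix_fragments(pool("ct02"), pool("ct03"), 0.5, 20, seed = 322)
  err <- function(cov, seed) {
    mx <- mix_fragments(bg, spike, 0.10, cov, seed = seed)
    abs(deconvolve(mx, atlas)$proportions["ct01"] - 0.10)
  }
  lo <- mean(vapply(1:8, function(s) err(2.5, 1000 + s), numeric(1)))
  hi <- mean(vapply(1:8, function(s) err(30, 2000 + s), numeric(1)))
  expect_lte(hi, lo + 0.01)
})
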