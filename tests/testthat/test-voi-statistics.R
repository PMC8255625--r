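make_maps <- function(dims, seed = 1) {
  set.seed(seed)
  setNames(lapply(mp_contrasts(), function(cc) {
    array(rnorm(prod(dims)), dims)
  }), mp_contrasts())
}

test_that("extract_voi returns the labeled voxels in canonical order", {
  dims <- c(4, 5, 3)
  maps <- make_maps(dims)
  labels <- array(0L, dims)
  set.seed(2)
  vox <- sample(prod(dims), 12)
  labels[vox] <- 1L

  block <- extract_voi(maps, labels, 1)
  expect_equal(block$n, 12)

  # brute-force scan: visit voxels slice-by-slice, row, column
  oracle <- c()
  for (k in 1:dims[3]) for (i in 1:dims[1]) for (j in 1:dims[2]) {
    if (labels[i, j, k] == 1L) oracle <- c(oracle, maps$t1[i, j, k])
  }
  expect_equal(block$values$t1, oracle)

  # single-voxel label
  labels2 <- array(0L, dims); labels2[2, 3, 1] <- 7L
  b1 <- extract_voi(maps, labels2, 7)
  expect_equal(b1$n, 1)
  expect_equal(b1$values$qsm, maps$qsm[2, 3, 1])

  expect_error(extract_voi(maps, labels, 99), "absent")
  bad <- maps; bad$qsm <- array(0, c(2, 2, 2))
  expect_error(extract_voi(bad, labels, 1), "shape")
})

test_that("summaries match a naive two-pass oracle and pool correctly", {
  const <- toy_block(setNames(rep(list(rep(3.5, 6)), 4), mp_contrasts()))
  s <- summarize_voi(const)
  expect_equal(s$qsm_mean, 3.5)
  expect_equal(s$qsm_sd, 0)

  set.seed(3)
  vals <- setNames(lapply(1:4, function(i) rnorm(25)), mp_contrasts())
  blk <- toy_block(vals)
  s2 <- summarize_voi(blk)
  two_pass <- function(x) {
    m <- sum(x) / length(x)
    list(mean = m, sd = sqrt(sum((x - m)^2) / (length(x) - 1)))
  }
  for (cc in mp_contrasts()) {
    expect_equal(s2[[paste0(cc, "_mean")]], two_pass(vals[[cc]])$mean)
    expect_equal(s2[[paste0(cc, "_sd")]], two_pass(vals[[cc]])$sd)
  }

  # pooling equals summarizing the concatenation
  vals_b <- setNames(lapply(1:4, function(i) rnorm(10)), mp_contrasts())
  blk_b <- toy_block(vals_b, subject_id = "s2")
  pooled <- pool_and_summarize(list(blk, blk_b))
  concat <- toy_block(setNames(lapply(mp_contrasts(), function(cc) {
    c(vals[[cc]], vals_b[[cc]])
  }), mp_contrasts()))
  direct <- summarize_voi(concat)
  expect_equal(pooled$qsm_sd, direct$qsm_sd)
  expect_equal(pooled$n_voxels, 35)
  expect_equal(pooled$scope, "pooled")

  one <- toy_block(setNames(rep(list(1), 4), mp_contrasts()))
  expect_warning(s3 <- summarize_voi(one), "single-voxel")
  expect_equal(s3$t1_sd, 0)
})

test_that("ranking is ascending with alphabetical tie-break", {
  specs <- load_reference_params()
  ranked <- rank_structures(specs, "qsm")
  expect_equal(ranked$structure[1], "CP")       # lowest susceptibility
  expect_equal(ranked$structure[21], "VP")      # highest susceptibility
  expect_true(all(diff(ranked$qsm_mean) >= 0))
  expect_setequal(ranked$structure, specs$structure)

  tied <- data.frame(structure = c("b", "a"), qsm_mean = c(1, 1))
  expect_equal(rank_structures(tied, "qsm")$structure, c("a", "b"))
})

test_that("grand means reproduce the published cross-structure statistics", {
  specs <- load_reference_params()
  gm <- grand_means(specs, "nuclei")
  expect_equal(gm$n_structures, rep(19, 4))
  expect_lt(abs(gm$mean[gm$contrast == "na"] - 51.0) / 51.0, 0.005)
  expect_lt(abs(gm$mean[gm$contrast == "t1"] - 1448.5) / 1448.5, 0.005)
  expect_lt(abs(gm$sd[gm$contrast == "na"] - 14.4) / 14.4, 0.02)
  expect_lt(abs(gm$sd[gm$contrast == "t1"] - 179) / 179, 0.02)

  ft <- grand_means(specs, "fiber_tracts")
  expect_equal(ft$n_structures, rep(2, 4))
  expect_lt(abs(ft$mean[ft$contrast == "t1"] - 1231) / 1231, 0.005)

  # single-structure subset degenerates to (mean, 0)
  cp_only <- specs[specs$structure == "CP", ]
  gm1 <- grand_means(cp_only, "fiber_tracts", specs = cp_only)
  expect_equal(gm1$mean[gm1$contrast == "na"], 40.0)
  expect_equal(gm1$sd, rep(0, 4))

  expect_error(grand_means(specs[-1, ], "nuclei"), "missing structure")
})

test_that("pooled correlation matches the closed-form oracle and cor.test", {
  x <- rnorm(10)
  blk <- toy_block(list(qsm = x, na = 2 * x + 1, mtr = rnorm(10),
                        t1 = rnorm(10)))
  res <- pooled_correlation(list(blk), c("qsm", "na"))
  expect_equal(res$r, 1)
  expect_lt(res$p, 1e-12)

  # direct covariance-formula oracle on a toy block
  set.seed(4)
  blk2 <- toy_block(setNames(lapply(1:4, function(i) rnorm(10)),
                             mp_contrasts()))
  res2 <- pooled_correlation(list(blk2), c("t1", "na"))
  a <- blk2$values$t1; b <- blk2$values$na
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(res2$r, r_oracle)
  ct <- cor.test(a, b)
  expect_equal(res2$p, ct$p.value)

  # symmetry and affine invariance
  res_sym <- pooled_correlation(list(blk2), c("na", "t1"))
  expect_equal(res_sym$r, res2$r)
  blk3 <- blk2; blk3$values$na <- -3 * blk3$values$na + 7
  expect_equal(pooled_correlation(list(blk3), c("t1", "na"))$r, -res2$r)

  zero <- toy_block(list(qsm = rep(1, 5), na = rnorm(5), mtr = rnorm(5),
                         t1 = rnorm(5)))
  expect_error(pooled_correlation(list(zero), c("qsm", "na")),
               "zero variance")
})

test_that("summaries are invariant under voxel permutation of the label volume", {
  dims <- c(5, 5, 4)
  maps <- make_maps(dims, seed = 6)
  labels <- array(0L, dims)
  labels[sample(prod(dims), 20)] <- 1L
  s_a <- summarize_voi(extract_voi(maps, labels, 1))

  # move the same multiset of values to different voxel positions
  vox_vals <- lapply(maps, function(m) m[labels == 1L])
  labels_b <- array(0L, dims)
  labels_b[sample(prod(dims), 20)] <- 1L
  maps_b <- maps
  for (cc in mp_contrasts()) maps_b[[cc]][labels_b == 1L] <- vox_vals[[cc]]
  s_b <- summarize_voi(extract_voi(maps_b, labels_b, 1))
  expect_equal(s_a$t1_mean, s_b$t1_mean)
  expect_equal(s_a$t1_sd, s_b$t1_sd)
})
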