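test_that("ellipsoid construction takes means as center and SDs as axes", {
  specs <- load_reference_params()
  pal <- make_ellipsoid(specs[specs$structure == "Pal", ])
  expect_equal(unname(pal$center), c(0.0851, 23.0, 1237))
  expect_equal(unname(pal$semi_axes), c(0.0095, 1.7, 15))
  expect_equal(pal$color_value, 38.8)

  # all 21 published structures yield valid (positive-axis) ellipsoids
  for (i in seq_len(nrow(specs))) {
    expect_s3_class(make_ellipsoid(specs[i, ]), "ellipsoid")
  }
  degenerate <- toy_summary(axes = c(qsm = 0, mtr = 1, t1 = 1))
  expect_error(make_ellipsoid(degenerate), "degenerate")
})

test_that("overlap decision matches closed-form sphere cases", {
  unit <- make_ellipsoid(toy_summary())
  self <- ellipsoid_overlap(unit, unit)
  expect_true(self$overlaps)
  expect_equal(self$margin, -1)

  far <- make_ellipsoid(toy_summary(center = c(qsm = 3, mtr = 0, t1 = 0)))
  res <- ellipsoid_overlap(unit, far)
  expect_false(res$overlaps)
  expect_equal(res$margin, 3, tolerance = 1e-6)  # min Q2 = (3-1)^2 = 4

  touching <- make_ellipsoid(toy_summary(center = c(qsm = 2, mtr = 0, t1 = 0)))
  expect_true(ellipsoid_overlap(unit, touching)$overlaps)  # tangency counts
})

test_that("overlap decision agrees with a dense sampling oracle", {
  set.seed(42)
  n_pairs <- 500
  checked <- 0
  agree <- 0
  for (i in seq_len(n_pairs)) {
    e1 <- random_ellipsoid()
    e2 <- random_ellipsoid()
    res <- ellipsoid_overlap(e1, e2)
    if (abs(res$margin) < 1e-3) next  # boundary cases excluded
    checked <- checked + 1
    oracle <- overlap_sampling_oracle(e1, e2)
    if (!oracle && res$overlaps) {
      # sampling can miss thin intersections; refine before disagreeing
      oracle <- overlap_sampling_oracle(e1, e2, n_points = 400000)
    }
    if (res$overlaps) {
      # the minimizer must be a witness inside both ellipsoids
      w <- res$point
      q <- function(e) sum(((w - e$center) / e$semi_axes)^2)
      expect_lt(q(e1), 1 + 1e-6)
      expect_lt(q(e2), 1 + 1e-6)
    }
    agree <- agree + (oracle == res$overlaps)
  }
  expect_gt(checked, 400)
  expect_gte(agree / checked, 0.99)
})

test_that("overlap is symmetric and monotone under axis inflation", {
  set.seed(17)
  for (i in 1:40) {
    e1 <- random_ellipsoid()
    e2 <- random_ellipsoid()
    r12 <- ellipsoid_overlap(e1, e2)
    r21 <- ellipsoid_overlap(e2, e1)
    expect_equal(r12$overlaps, r21$overlaps)
    if (r12$overlaps) {
      for (t in c(1.5, 3)) {
        g1 <- e1; g1$semi_axes <- e1$semi_axes * t
        g2 <- e2; g2$semi_axes <- e2$semi_axes * t
        expect_true(ellipsoid_overlap(g1, g2)$overlaps)
      }
    }
  }
})

test_that("overlap matrix is symmetric and consistent with pair calls", {
  specs <- load_reference_params()
  extra <- specs[specs$group == "extrapyramidal", ]
  ov <- overlap_matrix(extra)
  mg <- attr(ov, "margins")
  expect_true(all(diag(ov)))
  expect_true(all(ov == t(ov)))
  expect_true(all(mg == t(mg)))
  for (i in 1:5) for (j in (i + 1):6) {
    res <- ellipsoid_overlap(make_ellipsoid(extra[i, ]),
                             make_ellipsoid(extra[j, ]))
    res_rev <- ellipsoid_overlap(make_ellipsoid(extra[j, ]),
                                 make_ellipsoid(extra[i, ]))
    expect_equal(ov[i, j], res$overlaps || res_rev$overlaps)
  }
  # qualitative claims that are numerically unambiguous from the reference
  # table: RN and SN ellipsoids are disjoint; NC and Put are by far the
  # closest extrapyramidal pair (and overlap once the axes are doubled)
  expect_false(ov["RN", "SN"])
  off_diag <- mg[upper.tri(mg)]
  expect_equal(min(off_diag[off_diag > 0]), mg["NC", "Put"])
  doubled <- extra
  for (cc in paste0(mp_contrasts(), "_sd")) doubled[[cc]] <- 2 * doubled[[cc]]
  expect_true(overlap_matrix(doubled)["NC", "Put"])

  # among the epi-thalamic nuclei, LGB, Pul and HB are mutually disjoint
  epi <- overlap_matrix(specs[specs$group == "epi_thalamic", ])
  trio <- c("LGB", "Pul", "HB")
  expect_false(any(epi[trio, trio] & !diag(3)))

  one <- overlap_matrix(extra[1, , drop = FALSE])
  expect_equal(dim(one), c(1, 1))
  expect_true(one[1, 1])
})
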