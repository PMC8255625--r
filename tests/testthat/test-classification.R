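# Synthetic feature table: n_subj subjects x the structures of `specs`,
# feature values drawn around per-structure centers `sep` SDs apart.
fake_features <- function(specs, n_subj = 5, sep = 0, seed = 1) {
  set.seed(seed)
  rows <- expand.grid(subject_id = sprintf("s%02d", seq_len(n_subj)),
                      structure = specs$structure,
                      stringsAsFactors = FALSE)
  rows$group <- specs$group[match(rows$structure, specs$structure)]
  x <- matrix(rnorm(nrow(rows) * 32), nrow(rows), 32,
              dimnames = list(NULL, feature_names()))
  x <- x + sep * as.integer(factor(rows$structure))
  out <- cbind(rows, as.data.frame(x, check.names = FALSE))
  class(out) <- c("feature_table", "data.frame")
  out
}

test_that("datasets have the documented sizes for the three tasks", {
  specs <- load_reference_params()
  feats <- fake_features(specs)

  ds1 <- build_dataset(feats, "all_structures")
  expect_equal(dim(ds1$x), c(90, 32))
  expect_equal(nlevels(ds1$y), 18)
  expect_false(any(default_excluded_structures() %in% ds1$sample_info$structure))

  ds2 <- build_dataset(feats, "functional_groups")
  expect_equal(nlevels(ds2$y), 5)

  ds3 <- build_dataset(feats, "within_group", group = "aras")
  expect_equal(nrow(ds3$x), 15)
  expect_setequal(levels(ds3$y), c("DRN", "PPN", "VTA"))  # LC excluded

  expect_error(build_dataset(feats[-3, ], "all_structures"), "incomplete")
  expect_error(build_dataset(feats, "within_group", group = "nope"), "group")
})

test_that("widely separated classes are classified perfectly", {
  specs <- mini_specs()
  feats <- fake_features(specs, n_subj = 4, sep = 10, seed = 2)
  ds <- build_dataset(feats, "all_structures", exclude = character(0))
  rep <- run_task(ds, n_runs = 2, cv = "loo", seed = 3)
  expect_equal(rep$mean_accuracy, 1.0)
  expect_equal(unname(diag(rep$confusion)), rep(1, 4))
  expect_true(all(rep$confusion[upper.tri(rep$confusion)] == 0))
})

test_that("permuted labels score at chance level", {
  specs <- mini_specs()
  feats <- fake_features(specs, n_subj = 6, sep = 10, seed = 4)
  set.seed(8)
  # break the label link, permuting within subject to keep the table complete
  feats$structure <- ave(feats$structure, feats$subject_id, FUN = sample)
  ds <- build_dataset(feats, "all_structures", exclude = character(0))
  rep <- run_task(ds, n_runs = 5, cv = "kfold", k = 4, seed = 5)
  # chance for 4 balanced classes is 0.25; allow generous stochastic slack
  expect_lt(abs(rep$mean_accuracy - 0.25), 0.2)
})

test_that("report invariants hold: stochastic rows, importances, accuracy identity", {
  specs <- mini_specs()
  feats <- fake_features(specs, n_subj = 5, sep = 1.5, seed = 6)
  ds <- build_dataset(feats, "all_structures", exclude = character(0))
  rep <- run_task(ds, n_runs = 3, cv = "loo", seed = 7)

  expect_equal(unname(rowSums(rep$confusion)), rep(1, 4), tolerance = 1e-9)
  expect_true(all(rep$importances >= 0))
  expect_equal(sum(rep$importances), 1, tolerance = 1e-9)
  expect_equal(sum(rep$contrast_importance), 1, tolerance = 1e-9)

  # mean accuracy equals the class-count-weighted mean of per-class recall
  counts <- table(ds$y)
  weighted <- sum(rep$per_class_accuracy * counts) / sum(counts)
  expect_equal(rep$mean_accuracy, unname(weighted), tolerance = 1e-12)

  # full report is reproducible bit for bit under the same master seed
  rep2 <- run_task(ds, n_runs = 3, cv = "loo", seed = 7)
  expect_identical(rep, rep2)
  rep3 <- run_task(ds, n_runs = 3, cv = "loo", seed = 8)
  expect_false(identical(rep$accuracy_per_run, rep3$accuracy_per_run))

  single <- ds; single$y <- factor(rep("a", nrow(ds$x)))
  expect_error(run_task(single, n_runs = 1), "2 classes")
})

test_that("confusion normalization is element-wise division by row sums", {
  expect_equal(normalize_confusion(diag(3)), diag(3))
  expect_equal(normalize_confusion(matrix(c(3, 0, 1, 2), 2, 2)),
               matrix(c(0.75, 0, 0.25, 1), 2, 2))
  set.seed(9)
  for (i in 1:10) {
    m <- matrix(rpois(16, 3), 4, 4)
    got <- normalize_confusion(m)
    for (r in 1:4) {
      if (sum(m[r, ]) > 0) {
        expect_equal(got[r, ], m[r, ] / sum(m[r, ]))
      } else {
        expect_equal(got[r, ], rep(0, 4))
      }
    }
  }
  expect_error(normalize_confusion(matrix(c(-1, 1, 1, 1), 2, 2)), "negative")
})

test_that("ablation is seed-consistent and ordered by subset size", {
  specs <- mini_specs()
  feats <- fake_features(specs, n_subj = 4, sep = 2, seed = 10)
  ab <- contrast_ablation(feats,
                          subsets = list(na = "na", all = mp_contrasts(),
                                         `qsm+t1` = c("qsm", "t1")),
                          exclude = character(0), n_runs = 2, seed = 11)
  expect_equal(ab$n_contrasts, c(1, 2, 4))
  expect_equal(ab$n_features, c(8, 16, 32))

  # the full-contrast subset reproduces run_task with the same protocol
  ds <- build_dataset(feats, "all_structures", exclude = character(0))
  direct <- run_task(ds, n_runs = 2, cv = "kfold", k = 5, seed = 11)
  expect_equal(ab$mean_accuracy[ab$subset == "all"], direct$mean_accuracy)

  expect_error(contrast_ablation(feats, subsets = list(character(0))),
               "non-empty")
})
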