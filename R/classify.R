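#' Assemble a classification dataset from a feature table
#'
#' Builds the design matrix and target labels for one of the three
#' prediction tasks: classify every structure (`"all_structures"`), predict
#' the functional group of each sample (`"functional_groups"`), or classify
#' structures within one functional group (`"within_group"`). Very small
#' structures adjacent to CSF (default MB, LC, HB) are excluded.
#'
#' @param features A `feature_table` from [extract_features()].
#' @param task One of `"all_structures"`, `"functional_groups"`,
#'   `"within_group"`.
#' @param group Functional group for `task = "within_group"`.
#' @param exclude Structures to drop (default
#'   [default_excluded_structures()]).
#' @param contrasts Contrasts whose features are active (default all four).
#' @return List of class `task_dataset` with `x` (numeric matrix, samples x
#'   features), `y` (factor of targets), `sample_info` (subject/structure of
#'   each row), `task`, `group`, `contrasts`.
#' @export
build_dataset <- function(features,
                          task = c("all_structures", "functional_groups",
                                   "within_group"),
                          group = NULL,
                          exclude = default_excluded_structures(),
                          contrasts = mp_contrasts()) {
  task <- match.arg(task)
  rows <- features[!(features$structure %in% exclude), , drop = FALSE]
  if (task == "within_group") {
    if (is.null(group) || !(group %in% functional_groups())) {
      stop("within_group task needs a valid functional group", call. = FALSE)
    }
    rows <- rows[rows$group == group, , drop = FALSE]
  }
  if (nrow(rows) == 0) stop("no samples left after filtering", call. = FALSE)
  # every subject must contribute every retained structure
  tab <- table(rows$subject_id, rows$structure)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)
    stop("incomplete feature table: missing or duplicated (subject, ",
         "structure) rows, e.g. ", rownames(tab)[bad[1, 1]], "/",
         colnames(tab)[bad[1, 2]], call. = FALSE)
  }
  cols <- feature_names(contrasts)
  x <- as.matrix(rows[, cols, drop = FALSE])
  y <- switch(task,
              all_structures = factor(rows$structure),
              functional_groups = factor(rows$group),
              within_group = factor(rows$structure))
  structure(list(x = x, y = droplevels(y),
                 sample_info = rows[, c("subject_id", "structure", "group")],
                 task = task, group = group, contrasts = contrasts),
            class = "task_dataset")
}

# Stratified fold assignment: samples of each class are spread over folds.
assign_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(sample(k), length(idx)))
  }
  folds
}

#' Run one classification task
#'
#' Repeats cross-validated random-forest classification (100 trees per
#' forest, refit in every fold) `n_runs` times with run seeds derived from
#' the master seed, and aggregates: mean accuracy over runs, confusion
#' counts summed over folds and runs then row-normalized, per-class accuracy
#' (the confusion diagonal), and impurity-decrease feature importances from
#' forests refit on the full data in each run, normalized to sum 1.
#' Per-contrast importance is the sum of that contrast's feature
#' importances.
#'
#' @param dataset A `task_dataset` from [build_dataset()].
#' @param n_runs Number of repeated runs (default 100).
#' @param cv `"loo"` (leave-one-out) or `"kfold"`.
#' @param k Number of folds for `cv = "kfold"` (default 5).
#' @param ntree Trees per forest (default 100).
#' @param seed Master seed; run `r` uses `seed + r`.
#' @return List of class `task_report`: `task`, `group`, `contrasts`,
#'   `mean_accuracy`, `accuracy_per_run`, `per_class_accuracy`, `confusion`
#'   (row-normalized), `confusion_counts`, `importances`,
#'   `contrast_importance`, `n_runs`, `cv`, `n_samples`, `seed`.
#' @export
run_task <- function(dataset, n_runs = 100, cv = c("loo", "kfold"), k = 5,
                     ntree = 100, seed = 1) {
  cv <- match.arg(cv)
  x <- dataset$x
  y <- dataset$y
  n <- nrow(x)
  if (nlevels(y) < 2) {
    stop("degenerate task: fewer than 2 classes", call. = FALSE)
  }
  if (any(table(y) < 2)) {
    warning("class(es) with a single sample: ",
            paste(names(which(table(y) < 2)), collapse = ", "),
            call. = FALSE)
  }
  classes <- levels(y)
  counts <- matrix(0, nlevels(y), nlevels(y),
                   dimnames = list(true = classes, predicted = classes))
  acc <- numeric(n_runs)
  imp <- setNames(numeric(ncol(x)), colnames(x))
  for (r in seq_len(n_runs)) {
    set.seed(as.integer(seed) + r)
    folds <- if (cv == "loo") seq_len(n) else assign_folds(y, k)
    pred <- factor(rep(NA_character_, n), levels = classes)
    for (fold in sort(unique(folds))) {
      test <- folds == fold
      fit <- randomForest::randomForest(x[!test, , drop = FALSE],
                                        droplevels(y[!test]),
                                        ntree = ntree)
      p <- predict(fit, x[test, , drop = FALSE])
      pred[test] <- factor(as.character(p), levels = classes)
    }
    acc[r] <- mean(pred == y)
    counts <- counts + table(y, pred)
    full <- randomForest::randomForest(x, y, ntree = ntree)
    imp <- imp + randomForest::importance(full)[, "MeanDecreaseGini"]
  }
  imp <- imp / n_runs
  if (sum(imp) > 0) imp <- imp / sum(imp)
  contrast_imp <- vapply(dataset$contrasts, function(cc) {
    sum(imp[feature_names(cc)])
  }, numeric(1))
  confusion <- normalize_confusion(counts)
  structure(list(task = dataset$task, group = dataset$group,
                 contrasts = dataset$contrasts,
                 mean_accuracy = mean(acc), accuracy_per_run = acc,
                 per_class_accuracy = setNames(diag(confusion), classes),
                 confusion = confusion, confusion_counts = counts,
                 importances = imp, contrast_importance = contrast_imp,
                 n_runs = n_runs, cv = cv, k = if (cv == "kfold") k else NA,
                 n_samples = n, seed = seed),
            class = "task_report")
}

#' @export
print.task_report <- function(x, ...) {
  cat("Task:", x$task,
      if (!is.null(x$group)) paste0("(", x$group, ")"), "\n")
  cat(sprintf("Mean accuracy over %d runs (%s CV): %.1f%%\n",
              x$n_runs, x$cv, 100 * x$mean_accuracy))
  cat("Per-class accuracy:\n")
  print(round(x$per_class_accuracy, 3))
  invisible(x)
}

#' Row-normalize a confusion count matrix
#'
#' @param counts Nonnegative count matrix (rows = true class).
#' @return Row-stochastic matrix; all-zero rows are left zero.
#' @export
#' @examples
#' normalize_confusion(matrix(c(3, 0, 1, 2), 2, 2))
normalize_confusion <- function(counts) {
  counts <- as.matrix(unclass(counts))
  if (any(counts < 0)) stop("negative confusion counts", call. = FALSE)
  rs <- rowSums(counts)
  out <- counts
  nz <- rs > 0
  out[nz, ] <- counts[nz, , drop = FALSE] / rs[nz]
  out
}

#' Default contrast subsets for the ablation
#'
#' @return Named list of contrast subsets in reporting order: the four
#'   singletons, the six pairs, the four triples, then all four contrasts.
#' @export
contrast_subsets <- function() {
  cn <- mp_contrasts()
  subsets <- list()
  for (m in 1:4) {
    for (s in as.data.frame(combn(cn, m), stringsAsFactors = FALSE)) {
      subsets[[paste(s, collapse = "+")]] <- as.character(s)
    }
  }
  subsets
}

#' Contrast-subset ablation
#'
#' Re-runs a classification task restricted to the features of each contrast
#' subset, with identical seeds across subsets, to measure how accuracy
#' depends on the available contrasts.
#'
#' @param features A `feature_table`.
#' @param subsets List of contrast subsets (default [contrast_subsets()]).
#' @param task,group,exclude Passed to [build_dataset()].
#' @param n_runs,cv,k,ntree,seed Passed to [run_task()]; the ablation uses
#'   5-fold CV by default.
#' @param keep_reports If TRUE, attach the full `task_report`s as attribute
#'   `reports`.
#' @return Data frame with columns `subset`, `n_contrasts`, `n_features`,
#'   `mean_accuracy`, in subset-size order.
#' @export
contrast_ablation <- function(features, subsets = contrast_subsets(),
                              task = "all_structures", group = NULL,
                              exclude = default_excluded_structures(),
                              n_runs = 100, cv = "kfold", k = 5, ntree = 100,
                              seed = 1, keep_reports = FALSE) {
  if (length(subsets) == 0 || any(lengths(subsets) == 0)) {
    stop("contrast subsets must be non-empty", call. = FALSE)
  }
  if (is.null(names(subsets))) {
    names(subsets) <- vapply(subsets, paste, "", collapse = "+")
  }
  subsets <- subsets[order(lengths(subsets))]
  reports <- lapply(subsets, function(s) {
    ds <- build_dataset(features, task = task, group = group,
                        exclude = exclude, contrasts = s)
    run_task(ds, n_runs = n_runs, cv = cv, k = k, ntree = ntree, seed = seed)
  })
  out <- data.frame(subset = names(subsets),
                    n_contrasts = lengths(subsets),
                    n_features = 8L * lengths(subsets),
                    mean_accuracy = vapply(reports, `[[`, 0, "mean_accuracy"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (keep_reports) attr(out, "reports") <- reports
  out
}
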