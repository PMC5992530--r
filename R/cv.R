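#' Stratified fold assignment
#'
#' Within each class, records are shuffled by a seeded generator and dealt
#' round-robin to the `k` folds, so per-class fold counts differ by at
#' most one (and are exactly equal when the class size is divisible by
#' `k`). For the 225-grain, 3-taxon design with `k = 5`, every fold holds
#' 45 grains, 15 per taxon.
#'
#' @param tab a [feature_table()].
#' @param k number of folds (>= 2).
#' @param seed integer seed; the same seed always yields the same
#'   assignment.
#' @return object of class `fold_assignment`: list with `k`, `fold`
#'   (integer fold index per record) and `seed`.
#' @export
stratified_folds <- function(tab, k = 5, seed = 1) {
  stopifnot(inherits(tab, "feature_table"), k >= 2)
  y <- tab$data[[tab$schema$class_name]]
  sizes <- table(y)
  if (any(sizes < k))
    stop("every class needs at least k records; smallest has ",
         min(sizes))
  fold <- integer(n_records(tab))
  with_seed(seed, {
    for (cl in levels(y)) {
      ix <- which(y == cl)
      ix <- ix[sample.int(length(ix))]
      fold[ix] <- rep_len(seq_len(k), length(ix))
    }
  })
  structure(list(k = as.integer(k), fold = fold, seed = as.integer(seed)),
            class = "fold_assignment")
}

#' Single k-fold cross-validation run
#'
#' For each fold, a tree is built on the other `k - 1` folds and evaluated
#' on the held-out fold; the fold accuracy, confusion matrix and the fold
#' tree's split attributes are recorded. The run mean is the unweighted
#' arithmetic mean of the fold accuracies (folds are equal-sized by
#' design, so this equals pooled accuracy).
#'
#' @param tab a [feature_table()].
#' @param attrs attribute subset (default all).
#' @param params an [induction_params()].
#' @param k folds (ignored when `folds` is supplied).
#' @param seed fold-assignment seed (ignored when `folds` is supplied).
#' @param folds optional precomputed [stratified_folds()] assignment.
#' @return object of class `cv_result`: list with `fold_accuracy`,
#'   `mean_accuracy`, `confusion` (summed over folds), `split_attrs`
#'   (list per fold) and `folds`.
#' @export
run_cv <- function(tab, attrs = NULL, params = induction_params(),
                   k = 5, seed = 1, folds = NULL) {
  folds <- folds %||% stratified_folds(tab, k, seed)
  stopifnot(inherits(folds, "fold_assignment"))
  prep <- prep_c45(tab, attrs)
  n <- n_records(tab)
  acc <- numeric(folds$k)
  split_attrs <- vector("list", folds$k)
  classes <- prep$classes
  confusion <- matrix(0, prep$k, prep$k,
                      dimnames = list(true = classes, predicted = classes))
  for (f in seq_len(folds$k)) {
    train <- which(folds$fold != f)
    test <- which(folds$fold == f)
    root <- grow_c45(prep, train, tab$weights[train], params)
    if (params$pruning) root <- prune_node(root, params$confidence)
    tree <- structure(list(root = root, classes = classes,
                           attrs = prep$attrs, params = params,
                           schema = prep$schema), class = "c45_tree")
    D <- tree_distributions(tree, prep, test, tab$weights[test])
    pred <- max.col(D, ties.method = "first")
    truth <- prep$y[test]
    w <- tab$weights[test]
    acc[f] <- 100 * sum(w[pred == truth]) / sum(w)
    for (i in seq_along(test))
      confusion[truth[i], pred[i]] <- confusion[truth[i], pred[i]] + w[i]
    split_attrs[[f]] <- split_attributes(tree)
  }
  structure(list(fold_accuracy = acc, mean_accuracy = mean(acc),
                 confusion = confusion, split_attrs = split_attrs,
                 folds = folds),
            class = "cv_result")
}

#' Repeated stratified cross-validation
#'
#' Repeats [run_cv()] `R` times with independent seeded fold assignments
#' (sub-seeds derived from `seed` via [derive_seeds()]), aggregating the
#' overall mean accuracy (mean of repetition means) and, across all
#' `R * k` fold trees, the number of trees in which each attribute
#' appears as a split attribute.
#'
#' @param tab a [feature_table()].
#' @param attrs attribute subset (default all).
#' @param params an [induction_params()].
#' @param k folds.
#' @param R repetitions (>= 1).
#' @param seed master seed.
#' @return object of class `repeated_cv_result`: list with `R`, `k`,
#'   `rep_means`, `mean_accuracy`, `attribute_frequency` (named integer
#'   vector) and `runs` (list of `cv_result`).
#' @export
repeat_cv <- function(tab, attrs = NULL, params = induction_params(),
                      k = 5, R = 1000, seed = 1) {
  stopifnot(R >= 1)
  seeds <- derive_seeds(seed, R)
  runs <- vector("list", R)
  for (r in seq_len(R))
    runs[[r]] <- run_cv(tab, attrs, params, k = k, seed = seeds[r])
  rep_means <- vapply(runs, `[[`, 0, "mean_accuracy")
  all_sets <- unlist(lapply(runs, `[[`, "split_attrs"), recursive = FALSE)
  prep_attrs <- if (is.null(attrs)) schema_attribute_names(tab$schema)
                else intersect(schema_attribute_names(tab$schema), attrs)
  freq <- vapply(prep_attrs, function(a)
    sum(vapply(all_sets, function(s) a %in% s, TRUE)), 0L)
  structure(list(R = R, k = k, rep_means = rep_means,
                 mean_accuracy = mean(rep_means),
                 attribute_frequency = freq, runs = runs),
            class = "repeated_cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result:", length(x$fold_accuracy), "folds, mean",
      sprintf("%.2f%%", x$mean_accuracy), "\n")
  cat("  fold accuracies:",
      paste(sprintf("%.2f", x$fold_accuracy), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.repeated_cv_result <- function(x, ...) {
  cat("repeated_cv_result:", x$R, "x", x$k, "-fold CV, overall mean",
      sprintf("%.2f%%", x$mean_accuracy), "\n")
  f <- sort(x$attribute_frequency[x$attribute_frequency > 0],
            decreasing = TRUE)
  if (length(f)) {
    cat("  split-attribute frequency (trees):\n")
    for (a in names(f)) cat(sprintf("    %-18s %d\n", a, f[[a]]))
  }
  invisible(x)
}
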