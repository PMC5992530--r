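test_that("stratified folds reproduce the 225-grain design exactly", {
  tab <- generate_dataset(default_config(seed = 8))
  folds <- stratified_folds(tab, k = 5, seed = 3)
  expect_equal(unname(table(folds$fold)), rep(45L, 5), ignore_attr = TRUE)
  y <- tab$data$taxon
  for (f in 1:5) {
    expect_equal(unname(table(y[folds$fold == f])), rep(15L, 3),
                 ignore_attr = TRUE)
    expect_equal(sum(folds$fold != f), 180)
    expect_equal(unname(table(y[folds$fold != f])), rep(60L, 3),
                 ignore_attr = TRUE)
  }
})

test_that("folds partition exactly and balance within one per class", {
  tab <- generate_dataset(default_config(n_per_taxon = 11, seed = 2))
  for (k in c(2, 3, 5)) {
    folds <- stratified_folds(tab, k = k, seed = k)
    expect_equal(sort(unique(folds$fold)), 1:k)
    expect_length(folds$fold, n_records(tab))
    per_class <- table(tab$data$taxon, folds$fold)
    expect_lte(max(apply(per_class, 1, function(r) diff(range(r)))), 1)
  }
  small <- generate_dataset(default_config(n_per_taxon = 4, seed = 2))
  expect_error(stratified_folds(small, k = 5), "at least k")
})

test_that("fold assignment is deterministic per seed", {
  tab <- generate_dataset(default_config(seed = 8))
  expect_identical(stratified_folds(tab, 5, seed = 77)$fold,
                   stratified_folds(tab, 5, seed = 77)$fold)
  expect_false(identical(stratified_folds(tab, 5, seed = 77)$fold,
                         stratified_folds(tab, 5, seed = 78)$fold))
})

test_that("run_cv scores each held-out fold and records split attributes", {
  tab <- generate_dataset(default_config(seed = 13))
  res <- run_cv(tab, k = 5, seed = 4)
  expect_length(res$fold_accuracy, 5)
  expect_equal(res$mean_accuracy, mean(res$fold_accuracy), tolerance = 1e-9)
  expect_equal(sum(res$confusion), 225, tolerance = 1e-9)
  expect_length(res$split_attrs, 5)
  expect_true(all(vapply(res$split_attrs, function(s)
    all(s %in% schema_attribute_names(tab$schema)), TRUE)))
  expect_gt(res$mean_accuracy, 85)
})

test_that("separable data scores 100% and constant data the majority rate", {
  sch <- default_schema()
  sch$attributes <- sch$attributes[c("min_axis", "n_pores")]
  sch$class_levels <- c("Betula", "Corylus")
  d <- data.frame(min_axis = c(rep(10, 20), rep(20, 20)),
                  n_pores = 3,
                  taxon = rep(c("Betula", "Corylus"), each = 20))
  sep <- feature_table(d, schema = sch)
  expect_equal(run_cv(sep, k = 5, seed = 1)$mean_accuracy, 100)

  d2 <- data.frame(min_axis = 10, n_pores = 3,
                   taxon = rep(c("Betula", "Corylus"), times = c(15, 10)))
  const <- feature_table(d2, schema = sch)
  expect_equal(run_cv(const, k = 5, seed = 1)$mean_accuracy, 60,
               tolerance = 1e-9)
})

test_that("repeat_cv aggregates means of means and attribute frequencies", {
  tab <- generate_dataset(default_config(seed = 14))
  rep3 <- repeat_cv(tab, k = 5, R = 3, seed = 6)
  expect_length(rep3$rep_means, 3)
  expect_equal(rep3$mean_accuracy, mean(rep3$rep_means), tolerance = 1e-9)
  expect_gte(min(rep3$rep_means), min(rep3$rep_means))
  expect_true(rep3$mean_accuracy >= min(rep3$rep_means) &&
                rep3$mean_accuracy <= max(rep3$rep_means))
  expect_true(all(rep3$attribute_frequency <= 3 * 5))
  # R = 1 reduces to a single run with the derived seed
  rep1 <- repeat_cv(tab, k = 5, R = 1, seed = 6)
  one <- run_cv(tab, k = 5, seed = derive_seeds(6, 1)[1])
  expect_equal(rep1$mean_accuracy, one$mean_accuracy, tolerance = 1e-12)
})
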