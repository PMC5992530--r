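best6 <- c("min_axis", "max_axis", "axes_diff", "n_lateral_pores",
           "n_pores", "oncus_width_max")

test_that("split-attribute ranking counts tree appearances", {
  sets <- list(c("max_axis", "n_pores"), c("max_axis", "wall"),
               c("max_axis", "n_pores"))
  r <- collect_split_attributes(sets)
  expect_identical(names(r), c("max_axis", "n_pores", "wall"))
  expect_identical(unname(r), c(3L, 2L, 1L))
  expect_length(collect_split_attributes(list(character(0), character(0))),
                0)
})

test_that("core selection supports union and min-frequency rules", {
  r <- c(max_axis = 3L, n_pores = 2L, wall = 1L)
  expect_setequal(select_core(r), c("max_axis", "n_pores", "wall"))
  expect_setequal(select_core(r, rule = "min_freq", m = 2),
                  c("max_axis", "n_pores"))
  expect_length(select_core(r[0]), 0)
})

test_that("low-cost augmentation closes over groups and derivations", {
  aug <- augment_low_cost(best6)
  expect_setequal(aug, c(best6, "n_top_pores", "n_oblique_pores",
                         "oncus_width_min"))
  expect_length(aug, 9)
  # idempotent and monotone
  expect_identical(augment_low_cost(aug), aug)
  expect_true(all(best6 %in% aug))
  expect_length(augment_low_cost(character(0)), 0)
  expect_identical(augment_low_cost("wall"), "wall")
  expect_error(augment_low_cost("sporopollenin"), "unknown")
})

test_that("compare_subsets pairs fold assignments across subsets", {
  tab <- generate_dataset(default_config(seed = 19))
  cmp <- compare_subsets(tab,
                         list(one = best6, two = best6,
                              easy = easiest4_attributes()),
                         R = 2, seed = 5)
  # identical subsets: identical per-repetition results, zero difference
  expect_equal(cmp$rep_means[, "one"], cmp$rep_means[, "two"],
               tolerance = 1e-12)
  expect_equal(cmp$diff_pp["one", "two"], 0, tolerance = 1e-12)
  expect_equal(cmp$diff_pp["one", "easy"],
               cmp$mean_accuracy[["one"]] - cmp$mean_accuracy[["easy"]],
               tolerance = 1e-9)
  expect_error(compare_subsets(tab, list(bad = "sporopollenin")),
               "unknown")
})

test_that("the full procedure produces a complete selection report", {
  tab <- generate_dataset(default_config(seed = 20))
  rep <- run_full_procedure(tab, R = 2, seed = 20)
  expect_s3_class(rep, "selection_report")
  expect_true(all(rep$core %in% names(rep$ranking)))
  expect_true(all(rep$core %in% rep$augmented))
  expect_setequal(names(rep$comparison$mean_accuracy),
                  c("full", "core", "augmented", "easiest"))
  expect_equal(dim(rep$diff_pp), c(4, 4))
  expect_identical(rep$easiest, easiest4_attributes())
  # deterministic per seed
  rep2 <- run_full_procedure(tab, R = 2, seed = 20)
  expect_identical(rep$core, rep2$core)
  expect_equal(rep$comparison$mean_accuracy, rep2$comparison$mean_accuracy,
               tolerance = 1e-12)
})
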