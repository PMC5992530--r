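# small two-attribute table builder for split/tree unit tests
tiny_table <- function(x, classes, x2 = NULL, weights = 1) {
  sch <- default_schema()
  attrs <- c("min_axis", "wall")[seq_len(1 + !is.null(x2))]
  sch$attributes <- sch$attributes[attrs]
  sch$class_levels <- unique(c("Betula", "Corylus", "Alnus"))[
    seq_len(length(unique(classes)))]
  map <- setNames(sch$class_levels, sort(unique(classes)))
  d <- data.frame(min_axis = x)
  if (!is.null(x2)) d$wall <- x2
  d$taxon <- unname(map[classes])
  feature_table(d, schema = sch, weights = weights)
}

test_that("class entropy matches closed forms", {
  expect_equal(class_entropy(c(5, 0, 0)), 0, tolerance = 1e-9)
  expect_equal(class_entropy(c(2, 2)), 1, tolerance = 1e-9)
  expect_equal(class_entropy(c(1, 3)),
               -(0.25 * log2(0.25) + 0.75 * log2(0.75)), tolerance = 1e-9)
  expect_equal(class_entropy(c(1, 3)), 0.811278, tolerance = 1e-6)
  expect_error(class_entropy(c(0, 0)), "positive")
  expect_error(class_entropy(c(-1, 2)), "nonnegative")
})

test_that("evaluate_split reproduces hand-computed gain bookkeeping", {
  tab <- tiny_table(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  ev <- evaluate_split(tab, split_test("min_axis", threshold = 1))
  expect_equal(ev$known_fraction, 1, tolerance = 1e-9)
  expect_equal(ev$gain, 1, tolerance = 1e-9)
  expect_equal(ev$split_info, 1, tolerance = 1e-9)
  expect_equal(ev$gain_ratio, 1, tolerance = 1e-9)
  expect_true(ev$admissible)

  # all records in one branch: no partition, zero gain, inadmissible
  ev0 <- evaluate_split(tab, split_test("min_axis", threshold = 5))
  expect_equal(ev0$gain, 0, tolerance = 1e-9)
  expect_false(ev0$admissible)
  expect_true(is.na(ev0$gain_ratio))
})

test_that("missing values scale gain by the known fraction", {
  tab <- tiny_table(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  tab$data$min_axis[4] <- NA
  ev <- evaluate_split(tab, split_test("min_axis", threshold = 1))
  expect_equal(ev$known_fraction, 0.75, tolerance = 1e-9)
  # gain on known subset ({1,1}->a,a | {2}->b), scaled by F = 0.75
  gain_known <- class_entropy(c(2, 1)) - 0
  expect_equal(ev$gain, 0.75 * gain_known, tolerance = 1e-9)
  # split info over branch proportions incl. the missing-weight group
  expect_equal(ev$split_info, class_entropy(c(2, 1, 1)), tolerance = 1e-9)
})

test_that("best_split_for_attribute picks data-valued thresholds", {
  tab <- tiny_table(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  best <- best_split_for_attribute(tab, "min_axis")
  expect_equal(best$test$threshold, 2)  # largest value <= best midpoint 2.5
  expect_equal(best$gain_ratio, 1, tolerance = 1e-9)
  # constant attribute admits no split
  expect_null(best_split_for_attribute(tiny_table(rep(1, 4),
                                                  c("a", "a", "b", "b")),
                                       "min_axis"))
})

test_that("single-class and perfectly-separating tables build trivially", {
  tab <- tiny_table(c(1, 2, 3, 4), c("a", "a", "a", "a"))
  tree <- build_tree(tab)
  expect_true(tree$root$leaf)
  expect_identical(split_attributes(tree), character(0))

  tab <- tiny_table(c(1, 1, 2, 2, 1.5, 2.5), c("a", "a", "b", "b", "a", "b"),
                    x2 = rep(1, 6))
  tree <- build_tree(tab, params = induction_params(pruning = FALSE))
  expect_identical(split_attributes(tree), "min_axis")
  expect_equal(evaluate_tree(tree, tab)$percent_correct, 100)
})

test_that("a pore-count signal yields the expected root test", {
  # taxon Alnus has pore counts {4,5,6}; the others {2,3}; remaining
  # attributes carry noise
  sch <- default_schema()
  sch$attributes <- sch$attributes[c("wall", "n_pores")]
  set.seed(99)
  n <- 30
  d <- data.frame(
    wall = runif(3 * n, 1, 2),
    n_pores = c(sample(2:3, 2 * n, TRUE), sample(4:6, n, TRUE)),
    taxon = rep(c("Betula", "Corylus", "Alnus"), each = n)
  )
  tab <- feature_table(d, schema = sch)
  tree <- build_tree(tab)
  expect_identical(tree$root$attr, "n_pores")
  expect_equal(tree$root$threshold, 3)
  right <- tree$root$children[[2]]
  expect_true(right$leaf)
  expect_identical(tree$classes[right$class], "Alnus")
})

test_that("identical data and params give identical trees", {
  tab <- generate_dataset(default_config(seed = 21))
  t1 <- build_tree(tab)
  t2 <- build_tree(tab)
  expect_identical(tree_shape(t1), tree_shape(t2))
  expect_identical(export_rules(t1), export_rules(t2))
})

test_that("fractional routing conserves weight at every node", {
  tab <- generate_dataset(default_config(seed = 4))  # has missing onci
  tree <- build_tree(tab, params = induction_params(pruning = FALSE))
  check <- function(node) {
    if (node$leaf) return(invisible())
    child_w <- sum(vapply(node$children, function(ch) sum(ch$dist), 0))
    expect_equal(child_w, sum(node$dist), tolerance = 1e-9)
    expect_equal(sum(node$props), 1, tolerance = 1e-9)
    for (ch in node$children) check(ch)
  }
  check(tree$root)
})

test_that("classification routes missing values by branch proportions", {
  # 6 'a' records below the cut, 2 'b' above: branch proportions 0.75/0.25
  tab <- tiny_table(c(1, 1, 1, 1, 1, 1, 2, 2),
                    c("a", "a", "a", "a", "a", "a", "b", "b"))
  tree <- build_tree(tab, params = induction_params(pruning = FALSE))
  expect_false(tree$root$leaf)
  res <- classify(tree, data.frame(min_axis = NA_real_))
  expect_equal(unname(res$distribution), c(0.75, 0.25), tolerance = 1e-9)
  expect_identical(res$class, "Betula")
  # known value reduces to plain path descent
  res2 <- classify(tree, data.frame(min_axis = 2.5))
  expect_equal(unname(res2$distribution), c(0, 1), tolerance = 1e-9)
})

test_that("evaluate_tree scores weighted accuracy and a full confusion", {
  tab <- generate_dataset(default_config(seed = 12))
  tree <- build_tree(tab)
  ev <- evaluate_tree(tree, tab)
  expect_gt(ev$percent_correct, 90)
  expect_equal(sum(ev$confusion), sum(tab$weights), tolerance = 1e-9)
  expect_equal(rownames(ev$confusion), tab$schema$class_levels)
  # single-leaf tree on a 60/40 table scores the majority rate
  maj <- tiny_table(c(rep(1, 10)), c(rep("a", 6), rep("b", 4)))
  leafy <- build_tree(maj)
  expect_true(leafy$root$leaf)
  expect_equal(evaluate_tree(leafy, maj)$percent_correct, 60)
})

test_that("pessimistic error bound behaves like the J4.8 estimate", {
  # zero observed errors still get a positive pessimistic surcharge
  expect_gt(pollentree:::add_errs(10, 0, 0.25), 0)
  expect_lt(pollentree:::add_errs(10, 0, 0.25), 10)
  # surcharge shrinks with confidence and grows with error count
  expect_gt(pollentree:::add_errs(20, 5, 0.1),
            pollentree:::add_errs(20, 5, 0.4))
  expect_gt(pollentree:::add_errs(20, 8, 0.25),
            pollentree:::add_errs(20, 2, 0.25))
})

test_that("pruning collapses chance structure on label noise", {
  sch <- default_schema()
  sch$attributes <- sch$attributes["wall"]
  set.seed(5)
  d <- data.frame(wall = runif(60, 1, 2),
                  taxon = sample(c("Betula", "Corylus"), 60, TRUE))
  tab <- feature_table(d, schema = sch)
  pruned <- build_tree(tab)
  unpruned <- build_tree(tab, params = induction_params(pruning = FALSE))
  n_nodes <- function(node) if (node$leaf) 1 else
    1 + sum(vapply(node$children, n_nodes, 0))
  expect_lte(n_nodes(pruned$root), n_nodes(unpruned$root))
})
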