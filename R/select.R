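#' Rank attributes by how many trees split on them
#'
#' Counts, per attribute, the number of trees whose internal nodes test
#' it, over the full-data tree plus the fold trees of a cross-validation
#' run. Descending order; ties broken by schema order.
#'
#' @param attr_sets list of character vectors (one per tree), e.g. the
#'   full-data tree's [split_attributes()] plus a `cv_result`'s
#'   `split_attrs`.
#' @param schema a `pollen_schema` supplying attribute order.
#' @return named integer vector (attributes appearing in >= 1 tree).
#' @export
collect_split_attributes <- function(attr_sets, schema = default_schema()) {
  stopifnot(length(attr_sets) >= 1)
  an <- schema_attribute_names(schema)
  counts <- vapply(an, function(a)
    sum(vapply(attr_sets, function(s) a %in% s, TRUE)), 0L)
  counts <- counts[counts > 0]
  counts[order(-counts, match(names(counts), an))]
}

#' Select the core discriminative subset from a ranking
#'
#' Default rule: the union of split attributes (every attribute appearing
#' in at least one tree). The `min_freq` rule instead keeps attributes
#' appearing in at least `m` trees.
#'
#' @param ranking named counts from [collect_split_attributes()].
#' @param rule `"union"` or `"min_freq"`.
#' @param m minimum tree count for `rule = "min_freq"`.
#' @param schema a `pollen_schema` for ordering the result.
#' @return character vector of attribute names in schema order.
#' @export
select_core <- function(ranking, rule = c("union", "min_freq"), m = 2,
                        schema = default_schema()) {
  rule <- match.arg(rule)
  keep <- if (rule == "union") names(ranking)
          else names(ranking)[ranking >= m]
  intersect(schema_attribute_names(schema), keep)
}

#' Augment a subset with low-cost co-measured attributes
#'
#' Measuring one attribute often yields others for free: a derived
#' attribute requires its constituents (number of pores requires the top,
#' lateral and oblique counts), and attributes in the same measurement
#' group come from the same measurement act (determining the maximum
#' oncus width means all onci were measured, so the minimum is also
#' known). This closure adds, for each attribute in `core`, its
#' derivation inputs and its measurement-group companions, repeatedly
#' until stable; it is idempotent and never removes attributes.
#'
#' @param core character vector of attribute names.
#' @param schema a `pollen_schema`.
#' @return character vector in schema order, superset of `core`.
#' @export
#' @examples
#' best6 <- c("n_pores", "max_axis", "min_axis", "axes_diff",
#'            "oncus_width_max", "n_lateral_pores")
#' augment_low_cost(best6)  # adds top/oblique pore counts + min oncus width
augment_low_cost <- function(core, schema = default_schema()) {
  an <- schema_attribute_names(schema)
  unknown <- setdiff(core, an)
  if (length(unknown))
    stop("unknown attribute(s): ", paste(unknown, collapse = ", "))
  out <- core
  repeat {
    added <- character(0)
    for (a in out) {
      spec <- schema$attributes[[a]]
      added <- c(added, spec$derived_from,
                 an[vapply(schema$attributes, function(s)
                   s$group == spec$group, TRUE)])
    }
    new <- union(out, added)
    if (setequal(new, out)) break
    out <- new
  }
  intersect(an, out)
}

#' Compare attribute subsets by paired repeated cross-validation
#'
#' Runs repeated `k`-fold CV for every named subset using *identical*
#' fold assignments per repetition across subsets (the same derived seed
#' sequence), so subset accuracy differences are paired comparisons not
#' confounded by fold randomness.
#'
#' @param tab a [feature_table()].
#' @param subsets named list of attribute-name vectors.
#' @param params an [induction_params()].
#' @param k folds.
#' @param R repetitions.
#' @param seed master seed (drives the shared fold assignments).
#' @return object of class `subset_comparison`: list with `mean_accuracy`
#'   (named), `rep_means` (R x subsets matrix), `diff_pp` (pairwise
#'   matrix, row minus column, percentage points) and `fold_seeds`.
#' @export
compare_subsets <- function(tab, subsets, params = induction_params(),
                            k = 5, R = 100, seed = 1) {
  stopifnot(is.list(subsets), length(subsets) >= 1,
            !is.null(names(subsets)), all(nzchar(names(subsets))))
  an <- schema_attribute_names(tab$schema)
  for (nm in names(subsets)) {
    unknown <- setdiff(subsets[[nm]], an)
    if (length(unknown))
      stop("subset '", nm, "' has unknown attribute(s): ",
           paste(unknown, collapse = ", "))
  }
  fold_seeds <- derive_seeds(seed, R)
  rep_means <- matrix(NA_real_, R, length(subsets),
                      dimnames = list(NULL, names(subsets)))
  for (nm in names(subsets)) {
    for (r in seq_len(R)) {
      res <- run_cv(tab, subsets[[nm]], params, k = k, seed = fold_seeds[r])
      rep_means[r, nm] <- res$mean_accuracy
    }
  }
  means <- colMeans(rep_means)
  diff_pp <- outer(means, means, `-`)
  structure(list(mean_accuracy = means, rep_means = rep_means,
                 diff_pp = diff_pp, fold_seeds = fold_seeds, k = k, R = R),
            class = "subset_comparison")
}

#' Default names of the four easiest-to-automate features
#'
#' Number of lateral pores plus the two axes and their difference — the
#' features easiest to identify automatically in a microscope image.
#' @return character vector of four attribute names.
#' @export
easiest4_attributes <- function() {
  c("min_axis", "max_axis", "axes_diff", "n_lateral_pores")
}

#' Full split-attribute feature-selection procedure
#'
#' The end-to-end pipeline: (1) build the full-data tree; (2) run one
#' stratified `k`-fold CV on the full feature set, recording each fold
#' tree's split attributes; (3) rank attributes by tree appearances and
#' select the core subset (union rule by default); (4) augment the core
#' with low-cost co-measured features; (5) compare the full set, core,
#' augmented and easiest subsets by paired repeated CV.
#'
#' @param tab a [feature_table()].
#' @param params an [induction_params()].
#' @param k folds.
#' @param R repetitions for the subset comparison.
#' @param seed master seed; stage sub-seeds are derived from it.
#' @param easiest named easiest subset (default [easiest4_attributes()]).
#' @param rule,m core-selection rule, see [select_core()].
#' @return object of class `selection_report`: list with `full_tree`,
#'   `cv` (the stage-2 `cv_result`), `ranking`, `core`, `augmented`,
#'   `easiest`, `comparison` (a `subset_comparison`) and `diff_pp`.
#' @export
#' @examples
#' \donttest{
#' tab <- generate_dataset(default_config(seed = 7))
#' rep <- run_full_procedure(tab, R = 5, seed = 7)
#' rep$core
#' }
run_full_procedure <- function(tab, params = induction_params(), k = 5,
                               R = 100, seed = 1,
                               easiest = easiest4_attributes(),
                               rule = "union", m = 2) {
  sub_seeds <- derive_seeds(seed, 2)
  full_tree <- build_tree(tab, params = params)
  cv <- run_cv(tab, params = params, k = k, seed = sub_seeds[1])
  ranking <- collect_split_attributes(
    c(list(split_attributes(full_tree)), cv$split_attrs),
    schema = tab$schema)
  core <- select_core(ranking, rule = rule, m = m, schema = tab$schema)
  augmented <- augment_low_cost(core, schema = tab$schema)
  subsets <- list(full = schema_attribute_names(tab$schema),
                  core = core, augmented = augmented, easiest = easiest)
  comparison <- compare_subsets(tab, subsets, params, k = k, R = R,
                                seed = sub_seeds[2])
  structure(list(full_tree = full_tree, cv = cv, ranking = ranking,
                 core = core, augmented = augmented, easiest = easiest,
                 comparison = comparison, diff_pp = comparison$diff_pp),
            class = "selection_report")
}

#' @export
print.subset_comparison <- function(x, ...) {
  cat("subset_comparison:", x$R, "x", x$k, "-fold paired CV\n")
  for (nm in names(x$mean_accuracy))
    cat(sprintf("  %-10s %.2f%%\n", nm, x$mean_accuracy[[nm]]))
  invisible(x)
}

#' @export
print.selection_report <- function(x, ...) {
  cat("selection_report\n")
  cat("  ranking:", paste(sprintf("%s:%d", names(x$ranking), x$ranking),
                          collapse = ", "), "\n")
  cat("  core     (", length(x$core), "):",
      paste(x$core, collapse = ", "), "\n")
  cat("  augmented(", length(x$augmented), "):",
      paste(x$augmented, collapse = ", "), "\n")
  cat("  easiest  (", length(x$easiest), "):",
      paste(x$easiest, collapse = ", "), "\n")
  print(x$comparison)
  invisible(x)
}
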