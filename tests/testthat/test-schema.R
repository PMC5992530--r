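test_that("default schema lists the 13 morphological attributes", {
  sch <- default_schema()
  expect_length(sch$attributes, 13)
  expect_identical(sch$class_name, "taxon")
  expect_identical(sch$class_levels, c("Betula", "Corylus", "Alnus"))
  expect_length(sch$attributes$position$categories, 5)
  expect_identical(sch$attributes$position$kind, "nominal")
})

test_that("measurement groups and derivations encode co-measurement", {
  sch <- default_schema()
  expect_identical(sch$attributes$oncus_width_max$group,
                   sch$attributes$oncus_width_min$group)
  expect_identical(sch$attributes$min_axis$group,
                   sch$attributes$max_axis$group)
  expect_setequal(sch$attributes$n_pores$derived_from,
                  c("n_top_pores", "n_lateral_pores", "n_oblique_pores"))
  expect_setequal(sch$attributes$axes_diff$derived_from,
                  c("max_axis", "min_axis"))
  for (a in sch$attributes)
    expect_true(all(a$derived_from %in% names(sch$attributes)))
})

test_that("feature tables validate values and warn on derived mismatch", {
  tab <- generate_dataset(default_config(seed = 2))
  d <- tab$data
  d$max_axis[1] <- d$min_axis[1] - 1  # max below min, diff stale too
  expect_warning(expect_warning(feature_table(d), "max axis smaller"),
                 "axes difference")
  d <- tab$data
  d$n_pores[3] <- d$n_pores[3] + 1
  expect_warning(feature_table(d), "number of pores")
  d <- tab$data
  d$wall[2] <- -0.5
  expect_error(suppressWarnings(feature_table(d)), "wall")
  expect_error(feature_table(tab$data, weights = c(0, rep(1, 224))),
               "positive")
})

test_that("subset_table restricts attributes in schema order", {
  tab <- generate_dataset(default_config(seed = 2))
  sub <- subset_table(tab, rows = 1:10,
                      attrs = c("n_pores", "max_axis"))
  expect_equal(n_records(sub), 10)
  # schema order preserved regardless of request order
  expect_identical(schema_attribute_names(sub$schema),
                   c("max_axis", "n_pores"))
  expect_error(subset_table(tab, attrs = "exine_sculpture"), "unknown")
})
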