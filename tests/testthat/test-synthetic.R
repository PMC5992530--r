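test_that("default config has three calibrated profiles of 75 grains", {
  cfg <- default_config()
  expect_s3_class(cfg, "synthetic_config")
  expect_length(cfg$profiles, 3)
  expect_setequal(names(cfg$profiles), c("Betula", "Corylus", "Alnus"))
  expect_identical(cfg$n_per_taxon, 75L)
  for (pr in cfg$profiles) {
    expect_equal(sum(pr$pore_probs), 1, tolerance = 1e-9)
    expect_equal(sum(pr$position_probs), 1, tolerance = 1e-9)
    expect_true(all(rowSums(pr$pore_tuples) >= 2))
    expect_equal(pr$oncus_missing_prob, 0.1)
  }
})

test_that("generated dataset has the study's size and derived structure", {
  tab <- generate_dataset(default_config(seed = 11))
  expect_equal(n_records(tab), 225)
  expect_equal(unname(table(tab$data$taxon)), rep(75L, 3),
               ignore_attr = TRUE)
  d <- tab$data
  expect_equal(d$axes_diff, d$max_axis - d$min_axis, tolerance = 1e-12)
  expect_equal(d$n_pores,
               d$n_top_pores + d$n_lateral_pores + d$n_oblique_pores)
  num_cols <- c("min_axis", "max_axis", "axes_diff", "wall",
                "oncus_height_min", "oncus_height_max",
                "oncus_width_min", "oncus_width_max")
  for (cn in num_cols) expect_true(all(d[[cn]] > 0, na.rm = TRUE))
  ok <- !is.na(d$oncus_width_max)
  expect_true(all(d$oncus_width_min[ok] <= d$oncus_width_max[ok]))
  expect_true(all(d$oncus_height_min[ok] <= d$oncus_height_max[ok]))
})

test_that("oncus fields are missing jointly", {
  tab <- generate_dataset(default_config(seed = 3))
  onc <- tab$data[c("oncus_height_min", "oncus_height_max",
                    "oncus_width_min", "oncus_width_max")]
  n_miss <- rowSums(is.na(onc))
  expect_true(all(n_miss %in% c(0L, 4L)))
  expect_gt(sum(n_miss == 4), 0)
})

test_that("same seed gives bit-identical tables", {
  cfg <- default_config(seed = 42)
  t1 <- generate_dataset(cfg)
  t2 <- generate_dataset(cfg)
  expect_identical(t1$data, t2$data)
  t3 <- generate_dataset(cfg, seed = 43)
  expect_false(identical(t1$data, t3$data))
})

test_that("narrative fractions are calibrated (Monte Carlo at n=1000)", {
  tab <- generate_dataset(default_config(n_per_taxon = 1000, seed = 7))
  d <- tab$data
  aln <- d[d$taxon == "Alnus", ]
  cor <- d[d$taxon == "Corylus", ]
  bet <- d[d$taxon == "Betula", ]
  # Alnus: over three visible pores in most grains (66/75 in the study)
  f_aln <- mean(aln$n_pores > 3)
  expect_gte(f_aln, 0.80)
  expect_lte(f_aln, 0.95)
  # Corylus: axes above 24.39 / 22.24 um (69/75 in the study)
  expect_gte(mean(cor$max_axis > 24.39), 0.82)
  expect_gte(mean(cor$min_axis > 22.24), 0.82)
  # Betula: small onci and small axes difference
  expect_gte(mean(bet$oncus_width_max <= 10.19 & bet$axes_diff < 2.92,
                  na.rm = TRUE), 0.77)
  # oncus unobservable for about 10% of grains
  expect_lt(abs(mean(is.na(d$oncus_width_max)) - 0.1), 0.03)
})

test_that("invalid profiles are rejected naming the offending field", {
  cfg <- default_config()
  bad <- cfg$profiles$Betula
  bad$pore_probs <- bad$pore_probs * 2
  expect_error(validate_taxon_profile(bad), "Betula.*pore_probs")
  bad <- cfg$profiles$Alnus
  bad$max_axis$sd <- -1
  expect_error(validate_taxon_profile(bad), "Alnus.*max_axis")
  bad <- cfg$profiles$Corylus
  bad$oncus_missing_prob <- 1.7
  expect_error(validate_taxon_profile(bad), "Corylus.*oncus_missing_prob")
  expect_error(synthetic_config(cfg$profiles[1]), "at least 2")
  expect_error(synthetic_config(cfg$profiles, n_per_taxon = 0), "n_per_taxon")
})

test_that("config round-trips through YAML", {
  cfg <- default_config(n_per_taxon = 10, seed = 5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$n_per_taxon, cfg$n_per_taxon)
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(names(cfg2$profiles), names(cfg$profiles))
  expect_identical(generate_dataset(cfg)$data, generate_dataset(cfg2)$data)
})
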