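#' Per-taxon generative profile for synthetic pollen morphometry
#'
#' A profile specifies the class-conditional distributions from which one
#' taxon's grain records are drawn: a categorical distribution over visible
#' pore configurations `(n_top, n_lateral, n_oblique)`, truncated-normal
#' distributions (um) for the maximum axis, the axes difference, wall
#' thickness and the oncus dimensions, a joint missingness probability for
#' the four oncus fields, and a categorical distribution over the five
#' slide positions. Derived attributes are computed, not drawn:
#' `min_axis = max_axis - axes_diff`, `n_pores = n_top + n_lateral +
#' n_oblique`, and each oncus minimum is the maximum minus a nonnegative
#' gap.
#'
#' @param taxon taxon label.
#' @param pore_tuples integer matrix with columns `top`, `lateral`,
#'   `oblique`, one row per configuration.
#' @param pore_probs probabilities for the rows of `pore_tuples` (sum 1).
#' @param max_axis,axes_diff,wall,oncus_width_max,oncus_width_gap,oncus_height_max,oncus_height_gap
#'   lists `list(mean=, sd=, lower=, upper=)`; bounds optional.
#' @param oncus_missing_prob probability in `[0, 1]` that all four oncus
#'   fields are jointly unobservable for a grain.
#' @param position_probs named probabilities over [position_levels()].
#' @return object of class `taxon_profile`.
#' @export
taxon_profile <- function(taxon, pore_tuples, pore_probs,
                          max_axis, axes_diff, wall,
                          oncus_width_max, oncus_width_gap,
                          oncus_height_max, oncus_height_gap,
                          oncus_missing_prob, position_probs) {
  prof <- structure(
    list(taxon = taxon,
         pore_tuples = pore_tuples, pore_probs = pore_probs,
         max_axis = max_axis, axes_diff = axes_diff, wall = wall,
         oncus_width_max = oncus_width_max,
         oncus_width_gap = oncus_width_gap,
         oncus_height_max = oncus_height_max,
         oncus_height_gap = oncus_height_gap,
         oncus_missing_prob = oncus_missing_prob,
         position_probs = position_probs),
    class = "taxon_profile"
  )
  validate_taxon_profile(prof)
  prof
}

# distribution spec helper
dspec <- function(mean, sd, lower = -Inf, upper = Inf) {
  list(mean = mean, sd = sd, lower = lower, upper = upper)
}

#' Validate a taxon profile
#'
#' Checks that all sds are positive, probability vectors sum to one within
#' 1e-9, pore tuples are nonnegative with at least two visible pores, and
#' the missingness probability lies in `[0, 1]`. Violations raise an error
#' naming the taxon and the offending field.
#'
#' @param prof a `taxon_profile`.
#' @return `prof`, invisibly.
#' @export
validate_taxon_profile <- function(prof) {
  stopifnot(inherits(prof, "taxon_profile"))
  fail <- function(field, why)
    stop("invalid profile for taxon '", prof$taxon, "', field '", field,
         "': ", why, call. = FALSE)
  tp <- prof$pore_tuples
  if (!is.matrix(tp) || ncol(tp) != 3) fail("pore_tuples", "need 3 columns")
  if (any(tp < 0) || any(tp != round(tp)))
    fail("pore_tuples", "entries must be nonnegative integers")
  if (any(rowSums(tp) < 2)) fail("pore_tuples", "each tuple must total >= 2")
  if (length(prof$pore_probs) != nrow(tp))
    fail("pore_probs", "length mismatch with pore_tuples")
  if (any(prof$pore_probs < 0) || abs(sum(prof$pore_probs) - 1) > 1e-9)
    fail("pore_probs", "must be nonnegative and sum to 1 (tol 1e-9)")
  for (field in c("max_axis", "axes_diff", "wall", "oncus_width_max",
                  "oncus_width_gap", "oncus_height_max", "oncus_height_gap")) {
    ds <- prof[[field]]
    if (!is.list(ds) || !all(c("mean", "sd") %in% names(ds)))
      fail(field, "needs mean and sd")
    if (!is.finite(ds$sd) || ds$sd <= 0) fail(field, "sd must be > 0")
    if ((ds$lower %||% -Inf) >= (ds$upper %||% Inf))
      fail(field, "lower bound must be below upper bound")
  }
  p <- prof$oncus_missing_prob
  if (!is.finite(p) || p < 0 || p > 1)
    fail("oncus_missing_prob", "must be in [0, 1]")
  pp <- prof$position_probs
  if (!setequal(names(pp), position_levels()))
    fail("position_probs", "must be named by the five position levels")
  if (any(pp < 0) || abs(sum(pp) - 1) > 1e-9)
    fail("position_probs", "must be nonnegative and sum to 1 (tol 1e-9)")
  invisible(prof)
}

#' Default synthetic-study configuration
#'
#' Three taxon profiles calibrated to the study's narrative structure,
#' 75 grains per taxon (225 records in total):
#' * *Alnus*: more than three visible pores for ~88% of grains, mostly
#'   lateral; intermediate grain size with the largest axes difference and
#'   the widest onci.
#' * *Corylus*: the largest grains — maximum axis above 24.39 um and
#'   minimum axis above 22.24 um for ~90% of grains; triangular polar view,
#'   so usually three lateral pores.
#' * *Betula*: the smallest grains — maximum oncus width at most 10.19 um
#'   and axes difference below 2.92 um for ~90% of grains; pores often seen
#'   from above or obliquely, so usually at most two lateral pores.
#'
#' Wall thickness, oncus heights, minimum oncus width and slide position
#' are identically distributed across the taxa and therefore carry no
#' discriminative signal. All four oncus fields are jointly missing with
#' probability 0.1 (grains whose onci could not be observed).
#'
#' @param n_per_taxon grains per taxon (default 75).
#' @param seed integer seed stored in the config (default 1).
#' @return object of class `synthetic_config` with elements `profiles`,
#'   `n_per_taxon`, `seed`.
#' @export
#' @examples
#' cfg <- default_config()
#' tab <- generate_dataset(cfg)
default_config <- function(n_per_taxon = 75, seed = 1) {
  pos <- c(P = 0.30, E = 0.30, nearly_polar = 0.15,
           nearly_equatorial = 0.15, intermediate = 0.10)
  # Pore configurations arise from a lateral-pore count (taxon-specific)
  # plus independent chances of one extra top (p = 0.10) and one extra
  # oblique (p = 0.08) pore being visible; grains of taxa with at most
  # three visible pores show no extras when all three laterals are seen.
  extras <- cbind(top = c(0, 1, 0, 1), oblique = c(0, 0, 1, 1))
  pore_mix <- function(lat, lat_probs, clip_at_3, p_top = 0.10,
                       p_obl = 0.08) {
    p_extras <- c((1 - p_top) * (1 - p_obl), p_top * (1 - p_obl),
                  (1 - p_top) * p_obl, p_top * p_obl)
    tuples <- NULL
    probs <- NULL
    for (i in seq_along(lat)) {
      if (clip_at_3 && lat[i] >= 3) {
        tuples <- rbind(tuples, c(0, lat[i], 0))
        probs <- c(probs, lat_probs[i])
      } else {
        tuples <- rbind(tuples, cbind(extras[, "top"], lat[i],
                                      extras[, "oblique"]))
        probs <- c(probs, lat_probs[i] * p_extras)
      }
    }
    colnames(tuples) <- c("top", "lateral", "oblique")
    list(tuples = tuples, probs = probs)
  }
  bet_p <- pore_mix(c(2, 3), c(0.88, 0.12), clip_at_3 = TRUE,
                    p_top = 0.05, p_obl = 0.04)
  cor_p <- pore_mix(c(2, 3), c(0.07, 0.93), clip_at_3 = TRUE,
                    p_top = 0.05, p_obl = 0.04)
  # alder often shows an extra top/oblique pore, so some grains with only
  # three lateral pores still total more than three visible pores
  aln_p <- pore_mix(c(2, 3, 4, 5, 6), c(0.05, 0.15, 0.52, 0.24, 0.04),
                    clip_at_3 = FALSE, p_top = 0.25, p_obl = 0.18)
  betula <- taxon_profile(
    "Betula",
    pore_tuples = bet_p$tuples,
    pore_probs  = bet_p$probs,
    max_axis  = dspec(22.3, 1.1, 19.0, 25.6),
    axes_diff = dspec(2.0, 0.6, 0.3, 5.0),
    wall      = dspec(1.25, 0.18, 0.6, 1.9),
    oncus_width_max  = dspec(8.4, 0.85, 5.85, 10.95),
    oncus_width_gap  = dspec(0.8, 0.9, 0.05, 3.8),
    oncus_height_max = dspec(9.5, 1.1, 6.2, 12.8),
    oncus_height_gap = dspec(2.2, 0.8, 0, 5.8),
    oncus_missing_prob = 0.1,
    position_probs = pos
  )
  corylus <- taxon_profile(
    "Corylus",
    pore_tuples = cor_p$tuples,
    pore_probs  = cor_p$probs,
    max_axis  = dspec(25.8, 1.25, 22.05, 29.55),
    axes_diff = dspec(1.8, 0.6, 0.15, 4.2),
    wall      = dspec(1.25, 0.18, 0.6, 1.9),
    oncus_width_max  = dspec(11.2, 0.9, 8.5, 13.9),
    oncus_width_gap  = dspec(3.6, 0.9, 0.6, 6.6),
    oncus_height_max = dspec(9.5, 1.1, 6.2, 12.8),
    oncus_height_gap = dspec(2.2, 0.8, 0, 5.8),
    oncus_missing_prob = 0.1,
    position_probs = pos
  )
  alnus <- taxon_profile(
    "Alnus",
    pore_tuples = aln_p$tuples,
    pore_probs  = aln_p$probs,
    max_axis  = dspec(24.0, 0.9, 21.3, 26.7),
    axes_diff = dspec(4.6, 1.3, 0.8, 8.0),
    wall      = dspec(1.25, 0.18, 0.6, 1.9),
    oncus_width_max  = dspec(12.6, 1.0, 9.6, 15.6),
    oncus_width_gap  = dspec(5.0, 0.9, 2.0, 8.0),
    oncus_height_max = dspec(9.5, 1.1, 6.2, 12.8),
    oncus_height_gap = dspec(2.2, 0.8, 0, 5.8),
    oncus_missing_prob = 0.1,
    position_probs = pos
  )
  synthetic_config(list(betula, corylus, alnus), n_per_taxon, seed)
}

#' Assemble and validate a synthetic-study configuration
#'
#' @param profiles list of [taxon_profile()] objects with distinct labels.
#' @param n_per_taxon grains per taxon, at least 1.
#' @param seed integer seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(profiles, n_per_taxon = 75, seed = 1) {
  if (length(profiles) < 2) stop("need at least 2 taxon profiles")
  lapply(profiles, validate_taxon_profile)
  labs <- vapply(profiles, `[[`, "", "taxon")
  if (anyDuplicated(labs)) stop("taxon labels must be distinct")
  if (!is.finite(n_per_taxon) || n_per_taxon < 1)
    stop("n_per_taxon must be >= 1")
  names(profiles) <- labs
  structure(list(profiles = profiles, n_per_taxon = as.integer(n_per_taxon),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic morphometry feature table
#'
#' Draws `n_per_taxon` grain records per profile. Per record: a pore
#' configuration is drawn and `n_pores` set to its total; the maximum axis
#' and the axes difference are drawn and `min_axis = max_axis - axes_diff`;
#' each oncus maximum and a nonnegative gap are drawn and the minimum set
#' to maximum minus gap; with probability `oncus_missing_prob` all four
#' oncus fields are set missing jointly. The same config (including its
#' seed) always yields a bit-identical table.
#'
#' @param config a `synthetic_config`; default [default_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return a [feature_table()] with records grouped by taxon, using the
#'   schema of the profiles' taxa in config order.
#' @export
generate_dataset <- function(config = default_config(), seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  lapply(config$profiles, validate_taxon_profile)
  seed <- seed %||% config$seed
  schema <- default_schema()
  schema$class_levels <- names(config$profiles)
  n <- config$n_per_taxon
  with_seed(seed, {
    parts <- lapply(config$profiles, function(pr) {
      draw <- function(ds) rtruncnorm(n, ds$mean, ds$sd,
                                      ds$lower %||% -Inf, ds$upper %||% Inf)
      ti <- sample.int(nrow(pr$pore_tuples), n, replace = TRUE,
                       prob = pr$pore_probs)
      tuples <- pr$pore_tuples[ti, , drop = FALSE]
      max_axis <- draw(pr$max_axis)
      axes_diff <- draw(pr$axes_diff)
      wmax <- draw(pr$oncus_width_max)
      wgap <- draw(pr$oncus_width_gap)
      hmax <- draw(pr$oncus_height_max)
      hgap <- draw(pr$oncus_height_gap)
      missing <- stats::runif(n) < pr$oncus_missing_prob
      pos <- sample(names(pr$position_probs), n, replace = TRUE,
                    prob = pr$position_probs)
      d <- data.frame(
        min_axis = max_axis - axes_diff,
        max_axis = max_axis,
        axes_diff = axes_diff,
        wall = draw(pr$wall),
        n_top_pores = tuples[, "top"],
        n_lateral_pores = tuples[, "lateral"],
        n_oblique_pores = tuples[, "oblique"],
        n_pores = rowSums(tuples),
        oncus_height_min = hmax - hgap,
        oncus_height_max = hmax,
        oncus_width_min = wmax - wgap,
        oncus_width_max = wmax,
        position = pos,
        taxon = pr$taxon
      )
      d[missing, c("oncus_height_min", "oncus_height_max",
                   "oncus_width_min", "oncus_width_max")] <- NA_real_
      d
    })
  })
  feature_table(do.call(rbind, parts), schema = schema)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("synthetic_config:", length(x$profiles), "taxa x", x$n_per_taxon,
      "grains, seed", x$seed, "\n")
  cat("  taxa:", paste(names(x$profiles), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a synthetic configuration as YAML
#'
#' @param config a `synthetic_config`.
#' @param path file path.
#' @return `read_config()` returns a `synthetic_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  ser <- list(
    n_per_taxon = config$n_per_taxon,
    seed = config$seed,
    profiles = lapply(config$profiles, function(pr) {
      list(taxon = pr$taxon,
           pore_tuples = apply(pr$pore_tuples, 1, as.list),
           pore_probs = pr$pore_probs,
           max_axis = pr$max_axis, axes_diff = pr$axes_diff, wall = pr$wall,
           oncus_width_max = pr$oncus_width_max,
           oncus_width_gap = pr$oncus_width_gap,
           oncus_height_max = pr$oncus_height_max,
           oncus_height_gap = pr$oncus_height_gap,
           oncus_missing_prob = pr$oncus_missing_prob,
           position_probs = as.list(pr$position_probs))
    })
  )
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  fixds <- function(ds) {
    ds$lower <- ds$lower %||% -Inf
    ds$upper <- ds$upper %||% Inf
    ds
  }
  profiles <- lapply(y$profiles, function(p) {
    tp <- do.call(rbind, lapply(p$pore_tuples, unlist))
    colnames(tp) <- c("top", "lateral", "oblique")
    taxon_profile(
      p$taxon, pore_tuples = tp, pore_probs = unlist(p$pore_probs),
      max_axis = fixds(p$max_axis), axes_diff = fixds(p$axes_diff),
      wall = fixds(p$wall),
      oncus_width_max = fixds(p$oncus_width_max),
      oncus_width_gap = fixds(p$oncus_width_gap),
      oncus_height_max = fixds(p$oncus_height_max),
      oncus_height_gap = fixds(p$oncus_height_gap),
      oncus_missing_prob = p$oncus_missing_prob,
      position_probs = unlist(p$position_probs)
    )
  })
  synthetic_config(profiles, y$n_per_taxon, y$seed)
}
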