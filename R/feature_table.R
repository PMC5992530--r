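#' Construct a feature table of pollen grain records
#'
#' A feature table couples a [default_schema()]-style schema with a
#' data frame of per-grain attribute values, a class label column, and a
#' vector of positive record weights (C4.5's fractional-instance weights;
#' all 1 for measured data). Missing values (`NA`) are allowed in any
#' non-derived attribute; the four oncus dimensions are typically missing
#' jointly when no oncus could be observed on the slide.
#'
#' @param data data frame with one column per schema attribute plus the
#'   class column (`taxon` by default).
#' @param schema a `pollen_schema`; defaults to [default_schema()].
#' @param weights positive record weights, recycled scalar allowed.
#' @param validate check values against the schema (default `TRUE`).
#' @return object of class `feature_table` with elements `schema`, `data`
#'   (attribute columns + class factor) and `weights`.
#' @export
feature_table <- function(data, schema = default_schema(), weights = 1,
                          validate = TRUE) {
  stopifnot(is.data.frame(data), inherits(schema, "pollen_schema"))
  an <- schema_attribute_names(schema)
  cn <- schema$class_name
  missing_cols <- setdiff(c(an, cn), names(data))
  if (length(missing_cols))
    stop("data lacks columns: ", paste(missing_cols, collapse = ", "))
  data <- data[c(an, cn)]
  rownames(data) <- NULL
  data[[cn]] <- factor(as.character(data[[cn]]), levels = schema$class_levels)
  for (a in schema$attributes) {
    col <- data[[a$name]]
    if (a$kind == "nominal") {
      data[[a$name]] <- factor(as.character(col), levels = a$categories)
    } else {
      data[[a$name]] <- as.numeric(col)
    }
  }
  weights <- rep_len(as.numeric(weights), nrow(data))
  tab <- structure(list(schema = schema, data = data, weights = weights),
                   class = "feature_table")
  if (validate) validate_feature_table(tab)
  tab
}

#' Validate a feature table against its schema
#'
#' Structural violations (unknown class label, non-positive weight,
#' negative measurement) are errors; derived-attribute inconsistencies
#' (axes difference vs. max - min beyond 0.01 um, pore sum mismatch,
#' max < min) are reported as warnings and the records kept, since
#' measured tables may carry rounding.
#'
#' @param tab a `feature_table`.
#' @return `tab`, invisibly.
#' @export
validate_feature_table <- function(tab) {
  stopifnot(inherits(tab, "feature_table"))
  d <- tab$data
  cn <- tab$schema$class_name
  if (anyNA(d[[cn]]))
    stop("unknown or missing class label in rows: ",
         paste(utils::head(which(is.na(d[[cn]])), 5), collapse = ", "))
  if (any(!is.finite(tab$weights)) || any(tab$weights <= 0))
    stop("record weights must be positive")
  for (a in tab$schema$attributes) {
    if (a$kind == "nominal") next
    v <- d[[a$name]]
    bad <- which(!is.na(v) & v < 0)
    if (length(bad))
      stop("negative value for '", a$name, "' in row ", bad[1])
  }
  warn_rows <- function(rows, what) {
    if (length(rows))
      warning(sprintf("%s in %d record(s), e.g. row %d", what,
                      length(rows), rows[1]), call. = FALSE)
  }
  has <- function(...) all(c(...) %in% names(d))
  ok <- function(...) Reduce(`&`, lapply(list(...), function(x) !is.na(x)))
  if (has("max_axis", "min_axis")) {
    i <- which(ok(d$max_axis, d$min_axis) & d$max_axis < d$min_axis)
    warn_rows(i, "max axis smaller than min axis")
  }
  if (has("max_axis", "min_axis", "axes_diff")) {
    i <- which(ok(d$max_axis, d$min_axis, d$axes_diff) &
                 abs(d$axes_diff - (d$max_axis - d$min_axis)) > 0.01)
    warn_rows(i, "axes difference inconsistent with axes (>0.01 um)")
  }
  if (has("n_top_pores", "n_lateral_pores", "n_oblique_pores", "n_pores")) {
    i <- which(ok(d$n_top_pores, d$n_lateral_pores, d$n_oblique_pores,
                  d$n_pores) &
                 d$n_pores != d$n_top_pores + d$n_lateral_pores +
                   d$n_oblique_pores)
    warn_rows(i, "number of pores not equal to sum of pore counts")
  }
  if (has("oncus_width_min", "oncus_width_max")) {
    i <- which(ok(d$oncus_width_min, d$oncus_width_max) &
                 d$oncus_width_min > d$oncus_width_max)
    warn_rows(i, "min oncus width exceeds max oncus width")
  }
  if (has("oncus_height_min", "oncus_height_max")) {
    i <- which(ok(d$oncus_height_min, d$oncus_height_max) &
                 d$oncus_height_min > d$oncus_height_max)
    warn_rows(i, "min oncus height exceeds max oncus height")
  }
  invisible(tab)
}

#' @export
print.feature_table <- function(x, ...) {
  cn <- x$schema$class_name
  cat("feature_table:", nrow(x$data), "records,",
      length(x$schema$attributes), "attributes, total weight",
      format(sum(x$weights)), "\n")
  print(table(x$data[[cn]]))
  invisible(x)
}

#' @export
as.data.frame.feature_table <- function(x, ...) x$data

#' Number of records in a feature table
#' @param tab a `feature_table`.
#' @return integer record count.
#' @export
n_records <- function(tab) nrow(tab$data)

#' Subset a feature table by records and/or attributes
#'
#' @param tab a `feature_table`.
#' @param rows record indices (default all).
#' @param attrs attribute-name subset (default all). The class column is
#'   always kept; attributes are reordered to schema order.
#' @return a `feature_table` whose schema retains only `attrs`.
#' @export
subset_table <- function(tab, rows = NULL, attrs = NULL) {
  stopifnot(inherits(tab, "feature_table"))
  sch <- tab$schema
  if (!is.null(attrs)) {
    unknown <- setdiff(attrs, schema_attribute_names(sch))
    if (length(unknown))
      stop("unknown attribute(s): ", paste(unknown, collapse = ", "))
    keep <- intersect(schema_attribute_names(sch), attrs)
    sch$attributes <- sch$attributes[keep]
  }
  rows <- rows %||% seq_len(nrow(tab$data))
  d <- tab$data[rows, c(names(sch$attributes), sch$class_name), drop = FALSE]
  rownames(d) <- NULL
  structure(list(schema = sch, data = d, weights = tab$weights[rows]),
            class = "feature_table")
}
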