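#' Read a feature table from CSV or ARFF
#'
#' CSV: header row, UTF-8, `.` decimal, missing values as `?` (empty cells
#' also accepted); an optional `weight` column carries record weights.
#' ARFF: WEKA's `@relation`/`@attribute`/`@data` format with nominal
#' category lists and `?` missing tokens (parsed via `foreign::read.arff`).
#' Values are validated against the schema: unknown columns, non-numeric
#' values in numeric columns and unknown nominal categories are errors
#' reporting the offending row; derived-attribute inconsistencies are
#' warnings and the records are kept.
#'
#' @param path input file.
#' @param format `"csv"` or `"arff"`; default guessed from the extension.
#' @param schema a `pollen_schema` (default [default_schema()]).
#' @return a [feature_table()].
#' @export
read_table <- function(path, format = c("auto", "csv", "arff"),
                       schema = default_schema()) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff"
              else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- if (format == "csv") {
    utils::read.csv(path, na.strings = c("?", ""), check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = NA)
  } else {
    foreign::read.arff(path)
  }
  an <- schema_attribute_names(schema)
  cn <- schema$class_name
  has_weight <- "weight" %in% names(raw)
  unknown <- setdiff(names(raw), c(an, cn, "weight"))
  if (length(unknown))
    stop("unknown attribute(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  missing_cols <- setdiff(c(an, cn), names(raw))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  for (a in schema$attributes) {
    col <- raw[[a$name]]
    if (a$kind == "nominal") {
      vals <- as.character(col)
      bad <- which(!is.na(vals) & !vals %in% a$categories)
      if (length(bad))
        stop("unknown category '", vals[bad[1]], "' for attribute '",
             a$name, "' at row ", bad[1])
    } else if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(as.character(col)))
      bad <- which(!is.na(as.character(col)) & is.na(num) &
                     as.character(col) != "?")
      if (length(bad))
        stop("non-numeric value '", as.character(col)[bad[1]],
             "' for attribute '", a$name, "' at row ", bad[1])
      raw[[a$name]] <- num
    }
  }
  labs <- as.character(raw[[cn]])
  bad <- which(!is.na(labs) & !labs %in% schema$class_levels)
  if (length(bad))
    stop("unknown class label '", labs[bad[1]], "' at row ", bad[1])
  w <- if (has_weight) as.numeric(raw[["weight"]]) else 1
  feature_table(raw[c(an, cn)], schema = schema, weights = w)
}

#' Write a feature table to CSV or ARFF
#'
#' Missing values are written as `?`. ARFF output declares numeric
#' attributes, nominal category lists, and the class attribute last;
#' non-unit record weights are only representable in CSV (as a `weight`
#' column) and raise an error for ARFF.
#'
#' @param tab a [feature_table()].
#' @param path output file.
#' @param format `"csv"` or `"arff"`; default guessed from the extension.
#' @param relation ARFF `@relation` name.
#' @return `path`, invisibly.
#' @export
write_table <- function(tab, path, format = c("auto", "csv", "arff"),
                        relation = "pollen_morphometry") {
  stopifnot(inherits(tab, "feature_table"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff"
              else "csv"
  d <- tab$data
  sch <- tab$schema
  fmt_col <- function(col) {
    out <- if (is.numeric(col)) {
      vapply(col, function(v) if (is.na(v)) "?" else
        format(v, digits = 15, scientific = FALSE), "")
    } else {
      ifelse(is.na(col), "?", as.character(col))
    }
    out
  }
  cols <- lapply(d, fmt_col)
  if (format == "csv") {
    if (any(tab$weights != 1)) cols$weight <- format(tab$weights, digits = 15)
    m <- do.call(cbind, cols)
    utils::write.table(m, path, sep = ",", quote = FALSE, row.names = FALSE,
                       col.names = names(cols), fileEncoding = "UTF-8")
  } else {
    if (any(tab$weights != 1))
      stop("ARFF output does not carry record weights; use CSV")
    decl <- vapply(sch$attributes, function(a) {
      if (a$kind == "nominal")
        paste0("@attribute ", a$name, " {",
               paste(a$categories, collapse = ","), "}")
      else paste0("@attribute ", a$name, " numeric")
    }, "")
    decl <- c(decl, paste0("@attribute ", sch$class_name, " {",
                           paste(sch$class_levels, collapse = ","), "}"))
    rows <- do.call(paste, c(unname(cols), sep = ","))
    writeLines(c(paste("@relation", relation), "", decl, "", "@data", rows),
               path)
  }
  invisible(path)
}
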