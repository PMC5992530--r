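#' Attribute schema for pollen grain morphometry
#'
#' The study design measures 13 morphological attributes per pollen grain:
#' the two grain axes and their difference, exine (wall) thickness, four
#' pore counts split by viewing position, four oncus dimensions, and the
#' nominal grain position on the slide. Two attributes are *derived*
#' (axes difference = maximum minus minimum axis; number of pores = sum of
#' top, lateral and oblique pore counts) and every attribute belongs to a
#' *measurement group*: features obtained from the same measurement act
#' (e.g. measuring all oncus widths yields both the maximum and the
#' minimum) share a group, which drives low-cost subset augmentation.
#'
#' @param name attribute identifier.
#' @param kind one of `"continuous"`, `"count"`, `"nominal"`.
#' @param unit measurement unit (`"um"` or `""`).
#' @param categories character vector of levels (nominal only).
#' @param derived_from character vector of constituent attribute names.
#' @param group measurement-group label.
#' @return `attribute_spec()` returns a list of class `attribute_spec`.
#' @export
attribute_spec <- function(name, kind, unit = "", categories = character(0),
                           derived_from = character(0), group = name) {
  kind <- match.arg(kind, c("continuous", "count", "nominal"))
  if (kind == "nominal" && length(categories) == 0)
    stop("nominal attribute '", name, "' needs categories")
  if (kind != "nominal" && length(categories) > 0)
    stop("non-nominal attribute '", name, "' must not have categories")
  structure(
    list(name = name, kind = kind, unit = unit, categories = categories,
         derived_from = derived_from, group = group),
    class = "attribute_spec"
  )
}

#' The five nominal grain positions
#'
#' Polar, equatorial, and three intermediate orientations of the grain on
#' the microscope slide.
#' @return character vector of the five position labels.
#' @export
position_levels <- function() {
  c("P", "E", "nearly_polar", "nearly_equatorial", "intermediate")
}

#' Taxon labels of the study design
#' @return character vector: Betula (birch), Corylus (hazel), Alnus (alder).
#' @export
taxon_levels <- function() c("Betula", "Corylus", "Alnus")

#' Default 13-attribute schema
#'
#' Returns the morphological attribute schema in measurement order:
#' minimum/maximum axis, axes difference, wall, the four pore counts,
#' the four oncus dimensions, and position, plus the taxon class
#' attribute.
#'
#' @return object of class `pollen_schema`: a list with `attributes`
#'   (named list of [attribute_spec()]), `class_name` and `class_levels`.
#' @export
#' @examples
#' sch <- default_schema()
#' length(sch$attributes)  # 13
default_schema <- function() {
  at <- list(
    attribute_spec("min_axis", "continuous", "um", group = "axes"),
    attribute_spec("max_axis", "continuous", "um", group = "axes"),
    attribute_spec("axes_diff", "continuous", "um",
                   derived_from = c("max_axis", "min_axis"), group = "axes"),
    attribute_spec("wall", "continuous", "um", group = "wall"),
    attribute_spec("n_top_pores", "count", group = "pores"),
    attribute_spec("n_lateral_pores", "count", group = "pores"),
    attribute_spec("n_oblique_pores", "count", group = "pores"),
    attribute_spec("n_pores", "count",
                   derived_from = c("n_top_pores", "n_lateral_pores",
                                    "n_oblique_pores"),
                   group = "pores"),
    attribute_spec("oncus_height_min", "continuous", "um",
                   group = "oncus_height"),
    attribute_spec("oncus_height_max", "continuous", "um",
                   group = "oncus_height"),
    attribute_spec("oncus_width_min", "continuous", "um",
                   group = "oncus_width"),
    attribute_spec("oncus_width_max", "continuous", "um",
                   group = "oncus_width"),
    attribute_spec("position", "nominal", categories = position_levels(),
                   group = "position")
  )
  names(at) <- vapply(at, `[[`, "", "name")
  bad <- unlist(lapply(at, function(a) setdiff(a$derived_from, names(at))))
  if (length(bad)) stop("derived_from references unknown attributes: ",
                        paste(bad, collapse = ", "))
  structure(
    list(attributes = at, class_name = "taxon", class_levels = taxon_levels()),
    class = "pollen_schema"
  )
}

#' @export
print.pollen_schema <- function(x, ...) {
  cat("pollen morphometry schema:", length(x$attributes), "attributes +",
      x$class_name, "class\n")
  for (a in x$attributes) {
    cat(sprintf("  %-18s %-10s %-4s group=%s%s\n", a$name, a$kind, a$unit,
                a$group,
                if (length(a$derived_from))
                  paste0(" <- ", paste(a$derived_from, collapse = "+"))
                else ""))
  }
  cat("  classes:", paste(x$class_levels, collapse = ", "), "\n")
  invisible(x)
}

#' Attribute names of a schema
#' @param schema a `pollen_schema`.
#' @return character vector of attribute names in schema order.
#' @export
schema_attribute_names <- function(schema) {
  stopifnot(inherits(schema, "pollen_schema"))
  names(schema$attributes)
}
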