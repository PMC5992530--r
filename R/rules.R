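#' Export a tree as indented rule text
#'
#' J4.8-style listing: one line per branch with the test (`attr <= t` /
#' `attr > t`, thresholds printed at 2 decimal places, or `attr = category`
#' for nominal tests), leaves annotated `: Class (total)` or
#' `: Class (total/misclassified)` with weights at 2 decimals.
#'
#' @param tree a `c45_tree`.
#' @return a single character string (lines separated by `\n`).
#' @export
#' @examples
#' tab <- generate_dataset(default_config(seed = 1))
#' cat(export_rules(build_tree(tab)))
export_rules <- function(tree) {
  stopifnot(inherits(tree, "c45_tree"))
  fmt_w <- function(x) formatC(round(x, 2), format = "f", digits = 2)
  leaf_txt <- function(node)
    paste0(": ", tree$classes[node$class], " (", fmt_w(node$weight),
           if (node$miscl > 0.005) paste0("/", fmt_w(node$miscl)) else "",
           ")")
  lines <- character(0)
  walk <- function(node, depth) {
    ind <- paste(rep("|  ", depth), collapse = "")
    if (node$leaf) {
      # root-level leaf: single line
      lines[[length(lines) + 1]] <<- paste0(ind, "class", leaf_txt(node))
      return(invisible())
    }
    labels <- if (node$kind == "numeric")
      paste(node$attr, c("<=", ">"), formatC(node$threshold, format = "f",
                                             digits = 2))
    else paste(node$attr, "=", node$cats)
    for (b in seq_along(node$children)) {
      child <- node$children[[b]]
      if (child$leaf) {
        lines[[length(lines) + 1]] <<- paste0(ind, labels[b], leaf_txt(child))
      } else {
        lines[[length(lines) + 1]] <<- paste0(ind, labels[b])
        walk(child, depth + 1)
      }
    }
  }
  walk(tree$root, 0)
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Parse rule text back into a tree shape
#'
#' Inverse of [export_rules()] up to the printing precision: rebuilds the
#' node structure (split attributes, rounded thresholds, nominal
#' categories, leaf classes and weights). Useful for structural
#' round-trip checks; the result is a bare shape, not a classifier.
#'
#' @param text rule text as produced by [export_rules()].
#' @return nested list mirroring the tree's node structure, with elements
#'   `leaf`, `attr`, `kind`, `threshold`, `cats`, `class`, `children`.
#' @export
parse_rules <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  depth <- nchar(sub("^((\\|  )*).*$", "\\1", lines)) / 3L
  body <- sub("^(\\|  )*", "", lines)
  leaf_re <- ": ([^ ]+) \\(([0-9.]+)(/([0-9.]+))?\\)$"
  parse_level <- function(rows, lvl) {
    stopifnot(length(rows) > 0)
    first <- body[rows[1]]
    if (grepl("^class: ", first)) {
      m <- regmatches(first, regexec(leaf_re, first))[[1]]
      return(list(leaf = TRUE, class = m[2], weight = as.numeric(m[3])))
    }
    heads <- rows[depth[rows] == lvl]
    children <- list()
    tests <- character(0)
    for (i in seq_along(heads)) {
      h <- heads[i]
      upper <- if (i < length(heads)) heads[i + 1] - 1 else rows[length(rows)]
      btxt <- body[h]
      if (grepl(leaf_re, btxt)) {
        m <- regmatches(btxt, regexec(leaf_re, btxt))[[1]]
        test <- sub(leaf_re, "", btxt)
        child <- list(leaf = TRUE, class = m[2], weight = as.numeric(m[3]))
      } else {
        test <- btxt
        child <- parse_level(setdiff(seq(h + 1, upper), h), lvl + 1)
      }
      tests <- c(tests, test)
      children[[length(children) + 1]] <- child
    }
    if (grepl(" <= ", tests[1])) {
      parts <- strsplit(tests[1], " <= ", fixed = TRUE)[[1]]
      list(leaf = FALSE, attr = parts[1], kind = "numeric",
           threshold = as.numeric(parts[2]), children = children)
    } else {
      parts <- strsplit(tests, " = ", fixed = TRUE)
      list(leaf = FALSE, attr = parts[[1]][1], kind = "nominal",
           cats = vapply(parts, `[`, "", 2), children = children)
    }
  }
  parse_level(seq_along(lines), 0)
}

#' Reduce a tree to its comparable shape
#'
#' Same representation as [parse_rules()] output (thresholds rounded to
#' 2 decimals), so `tree_shape(tree)` equals
#' `parse_rules(export_rules(tree))`.
#'
#' @param tree a `c45_tree`.
#' @return nested shape list.
#' @export
tree_shape <- function(tree) {
  shape <- function(node) {
    if (node$leaf)
      return(list(leaf = TRUE, class = tree$classes[node$class],
                  weight = round(node$weight, 2)))
    out <- list(leaf = FALSE, attr = node$attr, kind = node$kind,
                children = lapply(node$children, shape))
    if (node$kind == "numeric") out$threshold <- round(node$threshold, 2)
    else out$cats <- node$cats
    out[c("leaf", "attr", "kind",
          if (node$kind == "numeric") "threshold" else "cats", "children")]
  }
  shape(tree$root)
}
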