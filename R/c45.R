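#' Tree-induction parameters (J4.8-style defaults)
#'
#' @param min_leaf_weight minimum total instance weight required in at
#'   least two branches of any split (WEKA's `minNumObj`, default 2).
#' @param pruning apply pessimistic subtree-replacement pruning
#'   (default `TRUE`).
#' @param confidence confidence factor for the pessimistic error estimate,
#'   in (0, 0.5] (default 0.25).
#' @param avg_gain_heuristic restrict the gain-ratio maximization to
#'   attributes whose information gain is at least the average gain over
#'   admissible attributes (the C4.5/J4.8 selection rule; default `TRUE`;
#'   set `FALSE` for plain gain-ratio maximization).
#' @param threshold_by_gain choose each numeric attribute's threshold by
#'   maximum information gain, rating only the chosen threshold by gain
#'   ratio when comparing attributes, as C4.5/J4.8 do (default `TRUE`);
#'   `FALSE` maximizes gain ratio over thresholds as well.
#' @param mdl_correction penalize numeric threshold searches by
#'   `log2(number of candidate cuts) / node weight`, as C4.5 Release 8 and
#'   J4.8 do, so attributes offering many thresholds cannot win on chance
#'   alone (default `TRUE`).
#' @return list of class `induction_params`.
#' @export
induction_params <- function(min_leaf_weight = 2, pruning = TRUE,
                             confidence = 0.25, avg_gain_heuristic = TRUE,
                             mdl_correction = TRUE,
                             threshold_by_gain = TRUE) {
  stopifnot(min_leaf_weight >= 1, confidence > 0, confidence <= 0.5)
  structure(list(min_leaf_weight = min_leaf_weight, pruning = pruning,
                 confidence = confidence,
                 avg_gain_heuristic = isTRUE(avg_gain_heuristic),
                 mdl_correction = isTRUE(mdl_correction),
                 threshold_by_gain = isTRUE(threshold_by_gain)),
            class = "induction_params")
}

#' Class entropy in bits
#'
#' Shannon entropy of a weighted class distribution,
#' \eqn{-\sum_i p_i \log_2 p_i} with \eqn{0 \log 0 = 0}, where \eqn{p_i}
#' is the weight proportion of class \eqn{i}.
#'
#' @param counts nonnegative weighted class counts with positive total.
#' @return entropy in bits, in `[0, log2(k)]`.
#' @export
#' @examples
#' class_entropy(c(2, 2))  # 1 bit
class_entropy <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (sum(counts) <= 0) stop("total weight must be positive")
  entropy_bits(counts)
}

#' Describe a single split test
#'
#' A numeric-threshold test (`value <= t` / `value > t`) or a nominal
#' multiway test (one branch per category).
#'
#' @param attribute attribute name.
#' @param threshold numeric threshold for a numeric test; `NULL` for a
#'   nominal test.
#' @param categories category labels for a nominal test.
#' @return list of class `split_test`.
#' @export
split_test <- function(attribute, threshold = NULL, categories = NULL) {
  kind <- if (!is.null(threshold)) "numeric" else "nominal"
  if (kind == "nominal" && is.null(categories))
    stop("nominal test needs categories")
  structure(list(attribute = attribute, kind = kind, threshold = threshold,
                 categories = categories),
            class = "split_test")
}

# x * log2(x) with the 0 log 0 = 0 convention, elementwise on matrices.
xlog2x <- function(m) {
  r <- m * log2(m)
  r[m <= 0] <- 0
  r
}

# ---- internal prepared representation ------------------------------------

# Converts a feature_table (restricted to `attrs`) into matrices/vectors
# the recursive builder and router can index cheaply.
prep_c45 <- function(tab, attrs = NULL) {
  stopifnot(inherits(tab, "feature_table"))
  sch <- tab$schema
  attrs <- attrs %||% schema_attribute_names(sch)
  unknown <- setdiff(attrs, schema_attribute_names(sch))
  if (length(unknown))
    stop("unknown attribute(s): ", paste(unknown, collapse = ", "))
  attrs <- intersect(schema_attribute_names(sch), attrs)  # schema order
  vals <- lapply(attrs, function(a) {
    spec <- sch$attributes[[a]]
    col <- tab$data[[a]]
    if (spec$kind == "nominal")
      list(kind = "nominal", x = as.integer(col), cats = spec$categories)
    else
      list(kind = "numeric", x = as.numeric(col), cats = NULL)
  })
  names(vals) <- attrs
  y <- as.integer(tab$data[[sch$class_name]])
  list(vals = vals, y = y, w = tab$weights, attrs = attrs,
       classes = sch$class_levels, k = length(sch$class_levels),
       schema = sch)
}

weighted_class_counts <- function(y, w, k) {
  out <- numeric(k)
  if (length(y)) {
    t <- rowsum(w, y)
    out[as.integer(rownames(t))] <- t
  }
  out
}

# Best admissible split for one prepared attribute on records idx/w.
# Returns NULL or list(attr, kind, threshold/cats, gain, gain_ratio,
# split_info, known_fraction). `min_bw` is the minimum branch weight that
# at least two branches must reach.
best_split_one <- function(pv, attr, idx, w, y, k, min_bw,
                           mdl_correction = FALSE, dynamic_min = FALSE,
                           threshold_by_gain = FALSE) {
  x <- pv$x[idx]
  known <- !is.na(x)
  Wtot <- sum(w)
  wk <- w[known]
  Wk <- sum(wk)
  Wm <- Wtot - Wk
  if (Wk <= 0) return(NULL)
  F <- Wk / Wtot
  xs <- x[known]
  ys <- y[idx][known]
  si_missing_term <- if (Wm > 0) -(Wm / Wtot) * log2(Wm / Wtot) else 0

  if (dynamic_min) {
    # J4.8's per-node minimum branch weight for numeric tests:
    # 10% of the average class weight, floored at min_bw, capped at 25
    ms <- 0.1 * Wtot / k
    if (ms > min_bw) min_bw <- min(ms, 25)
  }
  if (pv$kind == "numeric") {
    o <- order(xs)
    xs <- xs[o]; yo <- ys[o]; wo <- wk[o]
    n <- length(xs)
    if (n < 2) return(NULL)
    cuts <- which(diff(xs) > 0)
    if (!length(cuts)) return(NULL)
    C <- matrix(0, n, k)
    C[cbind(seq_len(n), yo)] <- wo
    # duplicate x positions collapse later; cumulative weighted counts
    C <- apply(C, 2, cumsum)
    if (is.null(dim(C))) C <- matrix(C, nrow = 1)
    totk <- C[n, ]
    WL <- C[cuts, , drop = FALSE]
    wl <- rowSums(WL)
    wr <- Wk - wl
    ok <- wl >= min_bw & wr >= min_bw
    if (!any(ok)) return(NULL)
    WR <- rep(totk, each = length(cuts)) - WL
    hl <- log2(wl) - rowSums(xlog2x(WL)) / wl
    hr <- log2(wr) - rowSums(xlog2x(WR)) / wr
    hp <- entropy_bits(totk)
    gain_known <- hp - (wl * hl + wr * hr) / Wk
    gain <- F * gain_known
    if (mdl_correction && sum(ok) > 1)
      gain <- gain - log2(sum(ok)) / Wtot
    si <- -(xlog2x(wl / Wtot) + xlog2x(wr / Wtot)) + si_missing_term
    score <- if (threshold_by_gain) {
      ifelse(ok & gain > 1e-12 & si > 1e-12, gain, -Inf)
    } else {
      ifelse(ok & gain > 1e-12 & si > 1e-12, gain / si, -Inf)
    }
    score[is.na(score)] <- -Inf
    # ties within tolerance resolve to the lowest threshold
    b <- which(score >= max(score) - 1e-9)[1]
    if (length(b) == 0 || is.na(b) || !is.finite(score[b])) return(NULL)
    list(attr = attr, kind = "numeric", threshold = xs[cuts[b]],
         gain = gain[b], gain_ratio = gain[b] / si[b], split_info = si[b],
         known_fraction = F)
  } else {
    ncat <- length(pv$cats)
    B <- matrix(0, ncat, k)
    if (length(xs)) {
      lin <- (ys - 1L) * ncat + xs
      t <- rowsum(wk, lin)
      B[as.integer(rownames(t))] <- t
    }
    wb <- rowSums(B)
    if (sum(wb > 0) < 2 || sum(wb >= min_bw) < 2) return(NULL)
    hb <- numeric(ncat)
    pos <- wb > 0
    hb[pos] <- log2(wb[pos]) - rowSums(xlog2x(B[pos, , drop = FALSE])) / wb[pos]
    hp <- entropy_bits(colSums(B))
    gain_known <- hp - sum(wb * hb) / Wk
    gain <- F * gain_known
    si <- -sum(xlog2x(wb / Wtot)) + si_missing_term
    if (gain <= 1e-12 || si <= 1e-12) return(NULL)
    list(attr = attr, kind = "nominal", cats = pv$cats,
         gain = gain, gain_ratio = gain / si, split_info = si,
         known_fraction = F)
  }
}

# Argmax of gain ratio over attributes, ties broken by schema order
# (strictly-greater comparison while iterating in schema order).
find_best_split <- function(prep, idx, w, params) {
  cands <- vector("list", length(prep$attrs))
  for (j in seq_along(prep$attrs)) {
    cands[[j]] <- best_split_one(prep$vals[[j]], prep$attrs[j], idx, w,
                                 prep$y, prep$k, params$min_leaf_weight,
                                 params$mdl_correction %||% FALSE,
                                 dynamic_min = TRUE,
                                 params$threshold_by_gain %||% FALSE)
  }
  cands <- Filter(Negate(is.null), cands)
  if (!length(cands)) return(NULL)
  if (params$avg_gain_heuristic && length(cands) > 1) {
    gains <- vapply(cands, `[[`, 0, "gain")
    keep <- gains >= mean(gains) - 1e-9
    if (any(keep)) cands <- cands[keep]
  }
  best <- cands[[1]]
  for (cand in cands[-1])                    # ties keep schema order
    if (cand$gain_ratio > best$gain_ratio + 1e-9) best <- cand
  best
}

leaf_node <- function(dist, classes) {
  cls <- if (sum(dist) > 0) which.max(dist) else 1L
  list(leaf = TRUE, dist = dist, class = cls,
       weight = sum(dist), miscl = sum(dist) - max(dist))
}

grow_c45 <- function(prep, idx, w, params) {
  dist <- weighted_class_counts(prep$y[idx], w, prep$k)
  if (sum(dist > 0) <= 1 || sum(dist) < 2 * params$min_leaf_weight)
    return(leaf_node(dist, prep$classes))
  sp <- find_best_split(prep, idx, w, params)
  if (is.null(sp)) return(leaf_node(dist, prep$classes))
  x <- prep$vals[[sp$attr]]$x[idx]
  known <- !is.na(x)
  midx <- idx[!known]
  mw <- w[!known]
  Wk <- sum(w[known])
  if (sp$kind == "numeric") {
    left <- known & x <= sp$threshold
    right <- known & x > sp$threshold
    props <- c(sum(w[left]), sum(w[right])) / Wk
    groups <- list(list(i = idx[left], w = w[left]),
                   list(i = idx[right], w = w[right]))
  } else {
    props <- numeric(length(sp$cats))
    groups <- vector("list", length(sp$cats))
    for (ci in seq_along(sp$cats)) {
      sel <- known & x == ci
      props[ci] <- sum(w[sel]) / Wk
      groups[[ci]] <- list(i = idx[sel], w = w[sel])
    }
  }
  children <- vector("list", length(groups))
  for (b in seq_along(groups)) {
    gi <- groups[[b]]$i
    gw <- groups[[b]]$w
    if (length(midx)) {                       # fractional routing
      gi <- c(gi, midx)
      gw <- c(gw, mw * props[b])
    }
    children[[b]] <- if (sum(gw) <= 0)
      leaf_node(structure(numeric(prep$k), names = NULL), prep$classes)
    else grow_c45(prep, gi, gw, params)
    if (children[[b]]$leaf && children[[b]]$weight == 0)
      children[[b]]$class <- which.max(dist)  # empty branch: parent majority
  }
  list(leaf = FALSE, attr = sp$attr, kind = sp$kind,
       threshold = sp$threshold, cats = sp$cats,
       props = props, children = children, dist = dist,
       weight = sum(dist), miscl = sum(dist) - max(dist))
}

# ---- pessimistic pruning (subtree replacement) ---------------------------

# Upper confidence bound on the number of additional errors among N
# training instances with e observed errors (normal approximation to the
# binomial, as in C4.5/J4.8's pessimistic error estimate).
add_errs <- function(N, e, cf = 0.25) {
  if (N <= 0) return(0)
  if (e < 1) {
    base <- N * (1 - cf^(1 / N))
    if (e == 0) return(base)
    return(base + e * (add_errs(N, 1, cf) - base))
  }
  if (e + 0.5 >= N) return(max(N - e, 0))
  z <- stats::qnorm(1 - cf)
  f <- (e + 0.5) / N
  r <- (f + z^2 / (2 * N) +
          z * sqrt(f / N - f^2 / N + z^2 / (4 * N^2))) / (1 + z^2 / N)
  r * N - e
}

subtree_pessimistic_errors <- function(node, cf) {
  if (node$leaf) return(node$miscl + add_errs(node$weight, node$miscl, cf))
  sum(vapply(node$children, subtree_pessimistic_errors, 0, cf = cf))
}

prune_node <- function(node, cf) {
  if (node$leaf) return(node)
  node$children <- lapply(node$children, prune_node, cf = cf)
  e_tree <- subtree_pessimistic_errors(node, cf)
  e_leaf <- node$miscl + add_errs(node$weight, node$miscl, cf)
  if (e_leaf <= e_tree + 0.1)
    return(leaf_node(node$dist, NULL))
  node
}

# ---- public induction / prediction ---------------------------------------

#' Induce a gain-ratio decision tree
#'
#' Recursive partitioning in the C4.5/J4.8 style: at each node the split
#' (numeric threshold or nominal multiway) maximizing the gain ratio is
#' chosen among admissible candidates — those with positive
#' known-fraction-scaled information gain, positive split information, and
#' at least two branches carrying at least `min_leaf_weight` instance
#' weight. Records missing the split attribute descend every branch with
#' their weight multiplied by the branch's weight proportion among
#' known-valued records (fractional instance weighting). A node becomes a
#' leaf when pure, too light, or when no admissible split remains.
#' Pessimistic subtree-replacement pruning is applied afterwards when
#' enabled.
#'
#' @param tab a [feature_table()].
#' @param attrs attribute subset to split on (default: all 13).
#' @param params an [induction_params()].
#' @return object of class `c45_tree`.
#' @export
#' @examples
#' tab <- generate_dataset(default_config(seed = 1))
#' tree <- build_tree(tab)
#' split_attributes(tree)
build_tree <- function(tab, attrs = NULL, params = induction_params()) {
  if (n_records(tab) == 0) stop("cannot build a tree on an empty table")
  prep <- prep_c45(tab, attrs)
  if (!length(prep$attrs)) stop("attrs must contain at least one attribute")
  root <- grow_c45(prep, seq_len(n_records(tab)), tab$weights, params)
  if (params$pruning) root <- prune_node(root, params$confidence)
  structure(list(root = root, classes = prep$classes, attrs = prep$attrs,
                 params = params, schema = prep$schema),
            class = "c45_tree")
}

#' Evaluate a candidate split on a table
#'
#' Computes the full gain-ratio bookkeeping for one explicit [split_test()]:
#' class probabilities, per-branch weighted class counts, entropies, the
#' information gain on the known-valued subset scaled by the known
#' fraction F, and the split information (entropy of branch weight
#' proportions, with the missing-weight group as an extra term when
#' F < 1). An inadmissible split (single non-empty branch, or zero split
#' information) is signalled via `admissible = FALSE`, not an error.
#'
#' @param tab a [feature_table()].
#' @param test a [split_test()].
#' @param min_branch_weight admissibility floor for branch weights
#'   (default 0: branches need only be non-empty).
#' @return list of class `split_evaluation`.
#' @export
evaluate_split <- function(tab, test, min_branch_weight = 0) {
  stopifnot(inherits(tab, "feature_table"), inherits(test, "split_test"))
  sch <- tab$schema
  if (!test$attribute %in% schema_attribute_names(sch))
    stop("unknown attribute: ", test$attribute)
  y <- as.integer(tab$data[[sch$class_name]])
  k <- length(sch$class_levels)
  w <- tab$weights
  col <- tab$data[[test$attribute]]
  x <- if (is.factor(col)) as.integer(col) else as.numeric(col)
  known <- !is.na(x)
  Wtot <- sum(w); Wk <- sum(w[known]); Wm <- Wtot - Wk
  F <- Wk / Wtot
  parent_counts <- weighted_class_counts(y[known], w[known], k)
  if (test$kind == "numeric") {
    branch_of <- ifelse(x <= test$threshold, 1L, 2L)
    branch_labels <- c(paste0("<= ", test$threshold),
                       paste0("> ", test$threshold))
    nb <- 2L
  } else {
    branch_of <- x
    branch_labels <- test$categories
    nb <- length(test$categories)
  }
  counts <- matrix(0, nb, k,
                   dimnames = list(branch_labels, sch$class_levels))
  for (b in seq_len(nb)) {
    sel <- known & branch_of == b
    counts[b, ] <- weighted_class_counts(y[sel], w[sel], k)
  }
  wb <- rowSums(counts)
  branch_entropy <- apply(counts, 1, entropy_bits)
  e_parent <- entropy_bits(parent_counts)
  gain_known <- e_parent - sum(wb * branch_entropy) / Wk
  gain <- F * gain_known
  split_info <- -sum(xlog2x(wb / Wtot)) +
    (if (Wm > 0) -(Wm / Wtot) * log2(Wm / Wtot) else 0)
  admissible <- sum(wb > 0) >= 2 &&
    sum(wb >= max(min_branch_weight, .Machine$double.eps)) >= 2 &&
    split_info > 1e-12
  structure(list(
    attribute = test$attribute, test = test,
    known_fraction = F,
    class_probs = parent_counts / max(Wk, .Machine$double.eps),
    branch_counts = counts,
    entropy_parent = e_parent, branch_entropies = branch_entropy,
    gain_known = gain_known, gain = gain, split_info = split_info,
    gain_ratio = if (admissible && gain > 0) gain / split_info else NA_real_,
    admissible = admissible
  ), class = "split_evaluation")
}

#' Best admissible split for one attribute
#'
#' For a numeric attribute, candidate thresholds are the midpoints of
#' consecutive distinct sorted known values; the chosen threshold is
#' reported as the largest observed value not exceeding the best midpoint,
#' so printed thresholds are data values. For a nominal attribute the
#' single multiway split is evaluated.
#'
#' @param tab a [feature_table()].
#' @param attribute attribute name.
#' @param min_branch_weight admissibility floor for branch weights.
#' @return a `split_evaluation` (with the chosen test), or `NULL` when no
#'   admissible split with positive scaled gain exists.
#' @export
best_split_for_attribute <- function(tab, attribute, min_branch_weight = 0) {
  prep <- prep_c45(tab, attribute)
  sp <- best_split_one(prep$vals[[1]], attribute, seq_len(n_records(tab)),
                       tab$weights, prep$y, prep$k,
                       max(min_branch_weight, .Machine$double.eps))
  if (is.null(sp)) return(NULL)
  test <- if (sp$kind == "numeric") split_test(attribute, sp$threshold)
          else split_test(attribute, categories = sp$cats)
  evaluate_split(tab, test, min_branch_weight)
}

# Distribution matrix (records x classes) for records idx of prep.
tree_distributions <- function(tree, prep, idx, w) {
  env <- new.env()
  assign("acc", matrix(0, length(prep$y), length(tree$classes)),
         envir = env)
  route_env(tree$root, idx, w, prep, env, length(tree$classes))
  get("acc", envir = env)[idx, , drop = FALSE]
}

# router accumulating weight x leaf-distribution into env$acc
route_env <- function(node, idx, w, prep, env, k) {
  if (!length(idx)) return(invisible())
  if (node$leaf) {
    s <- sum(node$dist)
    pd <- if (s > 0) node$dist / s else replace(numeric(k), node$class, 1)
    acc <- get("acc", envir = env)
    acc[idx, ] <- acc[idx, , drop = FALSE] + outer(w, pd)
    assign("acc", acc, envir = env)
    return(invisible())
  }
  x <- prep$vals[[node$attr]]$x[idx]
  known <- !is.na(x)
  if (node$kind == "numeric")
    sel <- list(known & x <= node$threshold, known & x > node$threshold)
  else
    sel <- lapply(seq_along(node$cats), function(ci) known & x == ci)
  for (b in seq_along(node$children)) {
    route_env(node$children[[b]], idx[sel[[b]]], w[sel[[b]]], prep, env, k)
    if (any(!known))
      route_env(node$children[[b]], idx[!known], w[!known] * node$props[b],
                prep, env, k)
  }
  invisible()
}

#' Classify a single record
#'
#' Routes the record from the root to the leaves: a known test value
#' follows one branch; a missing test value descends all branches with
#' weight multiplied by the branch proportions, and the reached leaves'
#' class distributions are summed. Ties in the resulting distribution are
#' broken by class order.
#'
#' @param tree a `c45_tree`.
#' @param record one-row data frame (or list coercible to one) with the
#'   tree's attributes.
#' @return list with `distribution` (named, sums to 1) and `class`.
#' @export
classify <- function(tree, record) {
  stopifnot(inherits(tree, "c45_tree"))
  record <- as.data.frame(record)
  cn <- tree$schema$class_name
  if (!cn %in% names(record)) record[[cn]] <- tree$classes[1]
  tab <- feature_table(record, schema = tree$schema, validate = FALSE)
  D <- predict_distribution(tree, tab)
  dist <- D[1, ]
  list(distribution = dist / sum(dist),
       class = tree$classes[which.max(dist)])
}

#' Class-distribution matrix for all records of a table
#'
#' @param tree a `c45_tree`.
#' @param tab a `feature_table` with a compatible schema.
#' @return numeric matrix, one row per record, one column per class.
#' @export
predict_distribution <- function(tree, tab) {
  prep <- prep_c45(tab, tree$attrs)
  D <- tree_distributions(tree, prep, seq_len(n_records(tab)), tab$weights)
  colnames(D) <- tree$classes
  D
}

#' Evaluate a tree on a test table
#'
#' @param tree a `c45_tree`.
#' @param tab non-empty `feature_table`.
#' @return list with `percent_correct` (100 x weighted fraction of records
#'   whose predicted class equals the true class) and `confusion`
#'   (weighted true x predicted matrix).
#' @export
evaluate_tree <- function(tree, tab) {
  if (n_records(tab) == 0) stop("empty test table")
  D <- predict_distribution(tree, tab)
  pred <- factor(tree$classes[max.col(D, ties.method = "first")],
                 levels = tree$classes)
  truth <- factor(as.character(tab$data[[tab$schema$class_name]]),
                  levels = tree$classes)
  w <- tab$weights
  confusion <- matrix(0, length(tree$classes), length(tree$classes),
                      dimnames = list(true = tree$classes,
                                      predicted = tree$classes))
  agg <- rowsum(w, interaction(truth, pred, drop = FALSE))
  grid <- expand.grid(t = tree$classes, p = tree$classes)
  key <- paste(grid$t, grid$p, sep = ".")
  confusion[cbind(as.character(grid$t), as.character(grid$p))] <-
    agg[match(key, rownames(agg)), 1]
  confusion[is.na(confusion)] <- 0
  list(percent_correct = 100 * sum(w[as.character(pred) ==
                                       as.character(truth)]) / sum(w),
       confusion = confusion)
}

#' Attributes used in a tree's internal nodes
#'
#' @param tree a `c45_tree`.
#' @return character vector (schema order) of split attributes; empty for
#'   a single-leaf tree.
#' @export
split_attributes <- function(tree) {
  stopifnot(inherits(tree, "c45_tree"))
  collect <- function(node) {
    if (node$leaf) return(character(0))
    c(node$attr, unlist(lapply(node$children, collect)))
  }
  found <- unique(collect(tree$root))
  intersect(tree$attrs, found)
}

#' @export
print.c45_tree <- function(x, ...) {
  cat("c45_tree on", length(x$attrs), "attributes; split attributes:",
      paste(split_attributes(x), collapse = ", "), "\n")
  cat(export_rules(x))
  invisible(x)
}
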