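# Brute-force split-selection oracle, independent of the package's
# vectorized search. Replicates the induction semantics by direct, naive
# evaluation: for every attribute, every threshold between consecutive
# distinct sorted values is scored by information gain (with the
# log2(#cuts)/weight numeric-search penalty); each attribute's best-gain
# threshold is rated by gain ratio; attributes below the average gain are
# dropped; the surviving attribute with the strictly highest gain ratio
# (first in schema order on ties) wins. No missing values supported.
oracle_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  if (!length(p)) return(0)
  -sum(p * log2(p))
}

oracle_best_split <- function(tab, min_branch = 2) {
  d <- tab$data
  y <- d[[tab$schema$class_name]]
  n <- nrow(d)
  k <- nlevels(y)
  cands <- list()
  for (a in names(tab$schema$attributes)) {
    spec <- tab$schema$attributes[[a]]
    x <- d[[a]]
    if (spec$kind == "nominal") {
      counts <- table(x, y)
      wb <- rowSums(counts)
      if (sum(wb > 0) < 2 || sum(wb >= min_branch) < 2) next
      gain <- oracle_entropy(table(y)) -
        sum(vapply(seq_len(nrow(counts)), function(b)
          wb[b] * oracle_entropy(counts[b, ]), 0)) / n
      si <- oracle_entropy(wb)
      if (gain <= 1e-12 || si <= 1e-12) next
      cands[[length(cands) + 1]] <-
        list(attr = a, threshold = NA_real_, gain = gain, ratio = gain / si)
    } else {
      vals <- sort(unique(x))
      if (length(vals) < 2) next
      best <- NULL
      n_adm <- 0
      for (i in seq_len(length(vals) - 1)) {
        thr <- vals[i]
        left <- x <= thr
        if (sum(left) < min_branch || sum(!left) < min_branch) next
        n_adm <- n_adm + 1
        gain <- oracle_entropy(table(y)) -
          (sum(left) * oracle_entropy(table(y[left])) +
             sum(!left) * oracle_entropy(table(y[!left]))) / n
        si <- oracle_entropy(c(sum(left), sum(!left)))
        if (is.null(best) || gain > best$gain + 1e-9)
          best <- list(attr = a, threshold = thr, gain = gain, si = si)
      }
      if (is.null(best)) next
      if (n_adm > 1) best$gain <- best$gain - log2(n_adm) / n
      if (best$gain <= 1e-12 || best$si <= 1e-12) next
      best$ratio <- best$gain / best$si
      cands[[length(cands) + 1]] <- best
    }
  }
  if (!length(cands)) return(NULL)
  gains <- vapply(cands, `[[`, 0, "gain")
  cands <- cands[gains >= mean(gains) - 1e-9]
  best <- cands[[1]]
  for (cand in cands[-1]) if (cand$ratio > best$ratio + 1e-9) best <- cand
  best
}

# Random small table on a subset of the morphometry schema (numeric
# attributes, no missing values), for oracle-equivalence checks.
random_small_table <- function(n = 8, n_attr = 3, n_class = 2) {
  attrs <- c("min_axis", "wall", "oncus_height_min")[seq_len(n_attr)]
  sch <- default_schema()
  sch$attributes <- sch$attributes[attrs]
  sch$class_levels <- taxon_levels()[seq_len(n_class)]
  d <- as.data.frame(lapply(setNames(attrs, attrs), function(a)
    round(runif(n, 1, 10), 2)))
  d$taxon <- sample(sch$class_levels, n, replace = TRUE)
  feature_table(d, schema = sch)
}
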