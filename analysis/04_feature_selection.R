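#!/usr/bin/env Rscript
# The feature-selection analysis: rank attributes by the trees that split
# on them (full-data tree + fold trees), select the core subset by the
# union rule, augment it with co-measured low-cost features, and compare
# full / core / augmented / easiest-four subsets by paired repeated CV.

suppressPackageStartupMessages(library(pollentree))
dir.create("results", showWarnings = FALSE)
SEED <- 20180411 %% 1e6

tab <- generate_dataset(default_config(seed = SEED))
report <- run_full_procedure(tab, k = 5, R = 200, seed = SEED)
print(report)

comparison <- data.frame(
  subset = names(report$comparison$mean_accuracy),
  n_attributes = vapply(list(schema_attribute_names(tab$schema),
                             report$core, report$augmented,
                             report$easiest), length, 0L),
  cv_mean = round(unname(report$comparison$mean_accuracy), 2)
)
write.csv(comparison, "results/subset_comparison.csv", row.names = FALSE)
write.csv(data.frame(attribute = names(report$ranking),
                     trees = as.integer(report$ranking)),
          "results/split_attribute_ranking.csv", row.names = FALSE)
writeLines(export_rules(report$full_tree), "results/selection_full_tree.txt")

if (requireNamespace("jsonlite", quietly = TRUE)) {
  jsonlite::write_json(
    list(core = report$core, augmented = report$augmented,
         easiest = report$easiest,
         cv_mean = as.list(round(report$comparison$mean_accuracy, 4)),
         diff_pp = round(report$diff_pp, 4)),
    "results/selection_report.json", auto_unbox = TRUE, digits = NA)
}

d <- report$diff_pp
cat(sprintf("\ncore vs full:      %+.2f pp\n", d["core", "full"]))
cat(sprintf("easiest vs full:   %+.2f pp\n", d["easiest", "full"]))
cat(sprintf("easiest vs core:   %+.2f pp\n", d["easiest", "core"]))
cat("\nA small, cheaply measured subset retains almost all of the full",
    "set's discriminative power; the core subset typically matches or",
    "beats the full set because noisy attributes can only mislead the",
    "split search.\n")
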