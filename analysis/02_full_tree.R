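#!/usr/bin/env Rscript
# Build the gain-ratio tree on the full feature set and all 225 grains
# (training set = test set), export its rules, and report resubstitution
# accuracy — the optimistic benchmark the cross-validation in 03 corrects.

suppressPackageStartupMessages(library(pollentree))
dir.create("results", showWarnings = FALSE)
SEED <- 20180411 %% 1e6

tab <- generate_dataset(default_config(seed = SEED))
tree <- build_tree(tab)

rules <- export_rules(tree)
writeLines(rules, "results/full_tree_rules.txt")
cat(rules)

ev <- evaluate_tree(tree, tab)
cat(sprintf("\nresubstitution accuracy: %.2f%%\n", ev$percent_correct))
print(round(ev$confusion, 1))
cat("\nsplit attributes:", paste(split_attributes(tree), collapse = ", "),
    "\n")
cat(sprintf("The root tests '%s'; ", tree$root$attr),
    "the pore count isolates alder from the three-pored taxa, grain size",
    "separates hazel, and the axes difference, oncus width and lateral",
    "pore count resolve the remaining overlap.\n")
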