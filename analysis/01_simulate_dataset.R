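#!/usr/bin/env Rscript
# Generate the synthetic 225-grain morphometry dataset (75 grains each of
# Betula, Corylus, Alnus) and check its calibration against the narrative
# fractions that motivated the design. Writes the dataset in CSV and ARFF
# plus a calibration table under results/.

suppressPackageStartupMessages(library(pollentree))
dir.create("results", showWarnings = FALSE)
SEED <- 20180411 %% 1e6

cfg <- default_config(seed = SEED)
tab <- generate_dataset(cfg)
print(tab)

write_table(tab, "results/pollen_synthetic.csv")
write_table(tab, "results/pollen_synthetic.arff")
write_config(cfg, "results/synthetic_config.yaml")

d <- tab$data
frac <- function(x) round(100 * mean(x, na.rm = TRUE), 1)
calib <- data.frame(
  taxon = c("Alnus", "Corylus", "Corylus", "Betula", "Betula", "all"),
  property = c("number of pores > 3",
               "max axis > 24.39 um", "min axis > 22.24 um",
               "max oncus width <= 10.19 um", "axes difference < 2.92 um",
               "oncus fields missing"),
  percent = c(frac(d$n_pores[d$taxon == "Alnus"] > 3),
              frac(d$max_axis[d$taxon == "Corylus"] > 24.39),
              frac(d$min_axis[d$taxon == "Corylus"] > 22.24),
              frac(d$oncus_width_max[d$taxon == "Betula"] <= 10.19),
              frac(d$axes_diff[d$taxon == "Betula"] < 2.92),
              frac(is.na(d$oncus_width_max)))
)
write.csv(calib, "results/calibration_check.csv", row.names = FALSE)
print(calib)
cat("\nThe grain counts and fractions above emulate the study design:",
    "most alder grains show more than three pores, hazel grains are the",
    "largest, and birch grains combine small onci with small axes",
    "differences.\n")
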