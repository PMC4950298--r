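#!/usr/bin/env Rscript

# Transition-zone widths and dispersal lower bounds. The two survey
# periods give end-to-end latitudinal spans of transitional populations
# of 260 km (1999) and 170 km (2008); with invasion proceeding from both
# north and south, half of each span bounds the single-front zone width,
# and the travelling-wave relation sigma = delta_x * sqrt(l_CI) / 3
# converts the width bound into a dispersal bound.

suppressPackageStartupMessages(library(cytosweep))
dir.create("results", showWarnings = FALSE)

l_ci <- 0.98
report <- data.frame(
  period = c("1999", "2008"),
  span_km = c(260, 170),
  delta_x_km = c(260, 170) / 2,
  l_ci = l_ci
)
report$sigma_km <- sigma_lower_bound(report$delta_x_km, l_ci)
report$sigma_km_reported <- sigma_lower_bound(report$delta_x_km, l_ci,
                                              round_km = TRUE)
write.table(report, "results/wave_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

for (i in 1:2) cat(sprintf(
  "%s: end-to-end span %d km -> zone width > %d km -> dispersal sigma > %d km per generation\n",
  report$period[i], report$span_km[i], report$delta_x_km[i],
  report$sigma_km_reported[i]))
cat("\nBoth bounds dwarf the ~4 km mark-recapture flight range of the\n")
cat("host fly, pointing at long-distance or human-assisted dispersal.\n\n")

# Self-consistency: measure the width of a simulated sampled cline with
# known sigma and compare with the analytic relation.
set.seed(42)
pos <- seq(0, 300, by = 10)
sigma_true <- 25
p <- cline_frequency(pos, centre = 150, sigma = sigma_true, l_ci = l_ci)
obs <- rbinom(length(p), 200, p) / 200
w <- transition_zone_width(pos, obs)
cat(sprintf(
  "Simulated cline (sigma = %d km, 200 flies/site): measured width %.1f km vs analytic %.1f km\n",
  sigma_true, w, 3 * sigma_true / sqrt(l_ci)))

run_provenance(list(stage = "wave", l_ci = l_ci), seed = 42L,
               path = "results/wave_provenance.json")
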