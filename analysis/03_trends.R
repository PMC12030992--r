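#!/usr/bin/env Rscript
# Per-pixel trend analysis of the inverted FVC archive: Theil-Sen slope,
# Mann-Kendall significance at the 99% level, five-class trend grading,
# R/S Hurst persistence, and the combined future-trend classification.
# Compares the slope map against the planted truth.

suppressMessages(library(fvcdyn))

inp <- "results/sim_inputs"
out <- "results"
years <- 2000:2024

ndvi <- stack_grids(lapply(years, function(y)
  read_asc(file.path(inp, sprintf("ndvi_%d.asc", y)))), years)
fvc <- fvc_stack(ndvi, per_year = TRUE)

tr <- trend_stack(fvc)
hu <- hurst_stack(fvc)
fut <- classify_future(tr$trend_class, hu$h)

write_asc(tr$beta, file.path(out, "sen_slope.asc"))
write_asc(tr$z, file.path(out, "mk_z.asc"))
write_asc(hu$h, file.path(out, "hurst.asc"))

trend_shares <- area_fractions(tr$trend_class)
future_shares <- area_fractions(fut)
write.csv(trend_shares, file.path(out, "trend_class_shares.csv"),
          row.names = FALSE)
write.csv(future_shares, file.path(out, "future_class_shares.csv"),
          row.names = FALSE)

truth <- read.csv(file.path(inp, "truth_slopes.csv"))
slope_true <- matrix(truth$slope[order(truth$col, truth$row)], 60)
err <- grid_values(tr$beta) - slope_true

cat("trend class shares (%):\n")
print(cbind(trend_shares[1], round(100 * trend_shares$fraction, 1)))
cat("future class shares (%):\n")
print(cbind(future_shares[1], round(100 * future_shares$fraction, 1)))
cat(sprintf("slope recovery: MAE %.5f FVC/yr (planted slopes 0, -0.003, +0.004)\n",
            mean(abs(err))))
cat(sprintf("greening block detected as increase: %.0f%% of its pixels\n",
            100 * mean(grid_values(tr$trend_class)[11:30, 11:30] >= 4)))
cat(sprintf("mean Hurst exponent %.2f (noise planted at H = 0.5)\n",
            mean(grid_values(hu$h), na.rm = TRUE)))
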