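#!/usr/bin/env Rscript
# Build the synthetic study scene every later step consumes: a 25-year
# annual NDVI archive over a 60x60 km grid whose underlying cover field
# carries planted trends (a greening block, a degrading block, a stable
# background), plus co-varying climate stacks and a driving-factor table
# with known explanatory power. Ground truth is written alongside so each
# downstream analysis can be judged against what was planted.

suppressMessages(library(fvcdyn))

out <- "results/sim_inputs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
set.seed(20240101)

nr <- 60; nc <- 60
years <- 2000:2024

# planted trend field: FVC/yr
slopes <- matrix(0, nr, nc)
slopes[11:30, 11:30] <- 0.004    # restoration block: strong greening
slopes[41:55, 41:55] <- -0.003   # degradation block

# baseline cover: a smooth southwest-northeast moisture gradient squashed
# through a logistic so most of the scene is sparse (desert-like) while the
# wet corner approaches full cover - the scene spans the whole [0, 1] range
# so percentile endmembers are meaningful
g <- outer(seq_len(nr), seq_len(nc), function(i, j) (i + j - 2) / (nr + nc - 2))
baseline <- 0.03 + 0.94 * stats::plogis((g - 0.6) / 0.12)
baseline[11:30, 11:30] <- pmax(baseline[11:30, 11:30], 0.25)  # oasis blocks
baseline[41:55, 41:55] <- pmax(baseline[41:55, 41:55], 0.45)

sim <- gen_fvc_stack(shape = c(nr, nc), years = years, baseline = baseline,
                     slope_field = slopes, noise_sd = 0.015, h = 0.5,
                     seed = 11)

# translate true cover to NDVI scenes (soil/veg endmembers 0.05 / 0.85),
# then stack the NDVI years as the "archive" the pipeline starts from
soil <- 0.05; veg <- 0.85
ndvi_layers <- lapply(seq_along(years), function(i) {
  cover <- sim$stack$values[, , i]
  gen_ndvi_scene(cover, soil = soil, veg = veg, noise_sd = 0.01,
                 seed = 100 + i)$ndvi
})
ndvi <- stack_grids(ndvi_layers, years)
for (i in seq_along(years))
  write_asc(stack_layer(ndvi, years[i]),
            file.path(out, sprintf("ndvi_%d.asc", years[i])))

# ecological zones: left half (zone 1) vs right half (zone 2)
zones <- grid(matrix(rep(c(1, 2), each = nr * nc / 2), nr))
write_asc(zones, file.path(out, "zones.asc"))

# climate stacks with a planted FVC-temperature partial correlation of 0.5
cv3 <- diag(3); cv3[1, 2] <- cv3[2, 1] <- 0.5
clim <- gen_climate_stacks(shape = c(nr, nc), years = years, cov_mat = cv3,
                           seed = 21)
for (i in seq_along(years)) {
  write_asc(stack_layer(clim$fvc, years[i]),
            file.path(out, sprintf("climfvc_%d.asc", years[i])))
  write_asc(stack_layer(clim$temp, years[i]),
            file.path(out, sprintf("temp_%d.asc", years[i])))
  write_asc(stack_layer(clim$precip, years[i]),
            file.path(out, sprintf("precip_%d.asc", years[i])))
}

# driving-factor table: a dominant categorical driver, a weaker continuous
# one, a bystander; analytic q of the dominant driver ~ 0.6
spec <- data.frame(fraction = c(0.3, 0.4, 0.3), mean = c(0.1, 0.3, 0.6),
                   sd = 0.14)
ft <- gen_factor_table(2000, spec, seed = 31)
tab <- ft$table
tab$land_use <- factor(letters[tab$stratum])
tab$elevation <- tab$y * 0.3 + rnorm(2000, sd = 0.2)  # weak continuous driver
tab$night_light <- runif(2000)                        # no influence
tab$zone <- rep(1:2, each = 1000)
tab$stratum <- NULL
write.csv(tab, file.path(out, "factor_table.csv"), row.names = FALSE)

# ground truth sidecars
write.csv(data.frame(row = rep(1:nr, nc), col = rep(1:nc, each = nr),
                     slope = as.vector(slopes)),
          file.path(out, "truth_slopes.csv"), row.names = FALSE)
write.csv(data.frame(q_true_land_use = ft$q_true,
                     partial_fvc_temp = clim$truth$r_fvc_temp.precip,
                     soil = soil, veg = veg, noise_h = 0.5),
          file.path(out, "truth_params.csv"), row.names = FALSE)

cat(sprintf("scene: %dx%d pixels, %d years; planted q (land use) = %.3f; planted FVC~temp partial = %.2f\n",
            nr, nc, length(years), ft$q_true, clim$truth$r_fvc_temp.precip))
cat("inputs written under", out, "\n")
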