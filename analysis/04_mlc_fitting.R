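#!/usr/bin/env Rscript
# Static MLC leaf fitting: fit 0.5 cm leaves to a synthetic aperture with the
# edge-midpoint rule, quantify the scalloping (symmetric-difference) area
# error, compare the two leaf-stacking orientations, and show the error's
# convergence as the leaf width shrinks.

library(hypofrac)
dir.create("results", showWarnings = FALSE)
seed <- 20260926

poly <- synth_aperture(seed, mean_radius = 2.5, irregularity = 0.15)
write_polygon_csv(poly, "results/aperture_polygon.csv")
cat(sprintf("Synthetic aperture (seed %d): area %.2f cm^2\n",
            seed, polygon_area(poly)))

bank <- fit_leaf_positions(poly, leaf_width = 0.5)
write_leaf_bank_csv(bank, "results/leaf_bank.csv")
err <- aperture_area_error(poly, bank)
oracle <- rasterize_area_error(poly, bank, cell = 0.01)
cat(sprintf("0.5 cm leaves: %d open pairs, scalloping area error %.3f cm^2\n",
            sum(bank$open), err))
cat(sprintf("  (0.01 cm rasterization oracle: %.3f cm^2)\n", oracle))

both <- orientation_variants(poly, leaf_width = 0.5)
cat(sprintf("Leaf stacking along y: %.3f cm^2; along x: %.3f cm^2\n",
            both$y$area_error, both$x$area_error))

widths <- c(1, 0.5, 0.25, 0.125)
conv <- data.frame(
  leaf_width_cm = widths,
  area_error_cm2 = vapply(widths, function(w)
    aperture_area_error(poly, fit_leaf_positions(poly, w)), numeric(1))
)
write.csv(conv, "results/leaf_width_convergence.csv",
          row.names = FALSE, quote = FALSE)
cat("\nScalloping error vs leaf width (halving never increases it):\n")
print(conv, row.names = FALSE)
cat("\nWrote results/aperture_polygon.csv, results/leaf_bank.csv,\n")
cat("results/leaf_width_convergence.csv\n")
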