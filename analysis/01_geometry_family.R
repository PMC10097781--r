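#!/usr/bin/env Rscript
# Generate the idealized LV geometry family (five volume-matched fetal
# shapes, the asymmetric "regular" fetal LV, and the size-scaled adult LV),
# mesh each with quadratic tetrahedra at default resolution, and tabulate
# dimensions, element counts and measured cavity volumes.
#
# Finding: the volume-matched family agrees in cavity volume to well under
# the 2% matching requirement, because the free radii/lengths are solved in
# closed form and the curved quadratic surface mesh measures the analytic
# volume to < 0.1%.

suppressPackageStartupMessages(library(lvhelix))
dir.create("results", showWarnings = FALSE)

shapes <- c("symmetric", "hypertrophic", "long", "hemisphere", "wide",
            "regular", "adult_regular")
rows <- lapply(shapes, function(s) {
  spec <- lv_geometry_spec(s)
  mesh <- generate_idealized_lv(spec)
  data.frame(shape = s,
             cavity_length_mm = spec$cavity_length,
             basal_width_mm = spec$basal_cavity_width,
             wall_mm = spec$wall_thickness,
             lean_mm = spec$septal_lean_amplitude,
             elements = nrow(mesh$elems),
             nodes = nrow(mesh$nodes),
             cavity_volume_ml = compute_cavity_volume(mesh),
             analytic_volume_ml = analytic_cavity_volume(spec))
})
tab <- do.call(rbind, rows)
print(tab, digits = 5)

fam <- tab$cavity_volume_ml[tab$shape %in% shapes[1:5]]
cat(sprintf("\nvolume-matched family spread: %.4g%% (must be <= 2%%)\n",
            100 * (max(fam) - min(fam)) / min(fam)))

write.csv(tab, "results/geometry_family.csv", row.names = FALSE)
cat("wrote results/geometry_family.csv\n")
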