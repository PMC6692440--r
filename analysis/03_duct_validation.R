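#!/usr/bin/env Rscript
# Validation of the power-law duct solver.
#
# (a) Newtonian square duct vs the rectangular-duct series solution;
# (b) grid-convergence of the midline maximum (second-order scheme);
# (c) high-aspect duct vs the planar slit closed form;
# (d) a case-13-like shear-thinning solve with slip: field statistics.

suppressPackageStartupMessages(library(microvisc))

out_dir <- "results/03_duct"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
geom <- channel_geometry()  # 50 x 50 um, 15 mm

## (a) Newtonian oracle
G <- 1e6
ff <- solve_square_duct(power_law_fluid(n = 1, K = 1), geom,
                        duct_drive(pressure_gradient = G), ny = 65, nz = 65)
fs <- field_statistics(ff)
oracle <- newtonian_duct_series(fs$midline$y_m, geom$height / 2, geom, G = G)
err <- max(abs(fs$midline$u_mps - oracle)) / max(oracle)
cat(sprintf("Newtonian 65x65 vs series: max midline error %.3f%%\n",
            100 * err))
cat(sprintf("Section mean/max = %.4f (series value 0.4770)\n",
            fs$mean_over_max))

## (b) grid convergence, shear-thinning
umax <- vapply(c(17, 33, 65), function(nn) {
  solve_square_duct(power_law_fluid(n = 0.9), geom,
                    duct_drive(pressure_gradient = 3e7),
                    ny = nn, nz = nn)$u_max
}, numeric(1))
rich <- umax[3] + (umax[3] - umax[2]) / 3
cat(sprintf("Grid convergence (n=0.9): errors vs Richardson %g / %g / %g\n",
            abs(umax[1] - rich), abs(umax[2] - rich), abs(umax[3] - rich)))

## (c) slit limit
tall <- channel_geometry(width = 50e-6, height = 400e-6)
fl <- power_law_fluid(n = 0.883, K = 1.0)
mid <- field_statistics(solve_square_duct(
  fl, tall, duct_drive(pressure_gradient = 3e7), ny = 49, nz = 97))$midline
trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))
rd <- trapz(mid$y_m, mid$u_mps) / diff(range(mid$y_m)) / max(mid$u_mps)
sp <- slit_profile(fl, tall, duct_drive(pressure_gradient = 3e7))
rs <- trapz(sp$y, sp$v) / diff(range(sp$y)) / max(sp$v)
cat(sprintf("High-aspect (h/w=8) line mean/max: duct %.4f vs slit %.4f\n",
            rd, rs))

## (d) case-13-like solve
f13 <- solve_square_duct(power_law_fluid(n = 0.9389, K = 1.0), geom,
                         duct_drive(mean_velocity = 6.7e-3, u0 = 2.2e-3))
s13 <- field_statistics(f13)
cat(sprintf("Case-13-like duct solve: u_max = %.3e m/s, G = %.3e Pa/m\n",
            s13$u_max, f13$G))
cat(sprintf("  interior shear-rate range %.2f - %.1f 1/s, viscosity %.3f - %.3f Pa.s\n",
            s13$shear_range[1], s13$shear_range[2],
            s13$viscosity_range[1], s13$viscosity_range[2]))

utils::write.csv(data.frame(y_m = fs$midline$y_m,
                            u_numeric = fs$midline$u_mps,
                            u_series = oracle),
                 file.path(out_dir, "newtonian_midline.csv"),
                 row.names = FALSE)
utils::write.csv(s13$midline, file.path(out_dir, "case13_midline.csv"),
                 row.names = FALSE)
jsonlite::write_json(
  list(newtonian_midline_err = err, section_mean_over_max = fs$mean_over_max,
       grid_umax = umax, slit_ratio = rs, duct_ratio = rd,
       case13 = list(u_max = s13$u_max, G = f13$G,
                     shear_range = s13$shear_range,
                     viscosity_range = s13$viscosity_range)),
  file.path(out_dir, "validation.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("wrote", out_dir, "\n")
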