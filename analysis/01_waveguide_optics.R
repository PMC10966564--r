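#!/usr/bin/env Rscript
# Waveguide optics of the stimulation platform: guided modes of the 4.5 um x
# 340 nm OrmoClear rib in water, their evanescent penetration depths, the
# surface power density driving channelrhodopsin-2, the height at which the
# 5 mW/mm2 activation threshold is crossed, and the fiber edge-coupling
# budget. All quantities are computed from the package's mode solver; writes
# tables under results/waveguide_optics/.

suppressMessages(library(photonstim))
out <- "results/waveguide_optics"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ind <- material_indices() # OrmoClear / silica / water at 491 nm
cat(sprintf("Index contrast core/water: %.3f (OrmoClear), %.3f (OrmoComp)\n",
            index_contrast(1.566, 1.340), index_contrast(1.527, 1.340)))

geometry <- waveguide_geometry(indices = ind)
modes <- solve_modes(geometry, n_modes = 3)

mode_tbl <- do.call(rbind, lapply(modes, function(m) data.frame(
  mode = sprintf("TE%d0", m$mode_label$order),
  n_eff = m$n_eff,
  d_p_nm = m$d_p_nm,
  surface_density_mW_mm2_per_mW = m$surface_peak_density_per_mW)))
write.csv(mode_tbl, file.path(out, "modes.csv"), row.names = FALSE)
print(mode_tbl, row.names = FALSE)
cat(sprintf("Penetration depth spread across the first three modes: %.1f%%\n",
            100 * diff(range(mode_tbl$d_p_nm)) / min(mode_tbl$d_p_nm)))

te00 <- modes[[1]]
i_surf <- surface_intensity(te00, 1)
h_thr <- threshold_height(i_surf, 5, te00$d_p_nm)
cat(sprintf("TE00 surface density at 1 mW: %.3g mW/mm2\n", i_surf))
cat(sprintf("5 mW/mm2 threshold crossed at %.0f nm above the surface\n", h_thr))
cat(sprintf("Minimum input power for threshold at the surface: %.1f nW\n",
            min_input_power_mW(5, i_surf) * 1e6))

# objective-TIRF penetration depth versus incidence angle (silica / water)
th_c <- asin(ind$n_cladding / ind$n_substrate) * 180 / pi
angles <- seq(ceiling(th_c * 10) / 10 + 0.1, 90, by = 0.1)
tirf <- data.frame(
  angle_deg = angles,
  d_p_nm = vapply(angles, function(a) {
    tirf_penetration_depth(a, ind$n_substrate, ind$n_cladding, 488)$d_p_nm
  }, numeric(1)))
write.csv(tirf, file.path(out, "tirf_dp_vs_angle.csv"), row.names = FALSE)
cat(sprintf("Objective-TIRF range beyond the critical angle (%.1f deg): d_p %.0f nm (grazing) and upward\n",
            th_c, min(tirf$d_p_nm)))

# fiber edge coupling versus longitudinal gap, MFD matched to the rib width
gaps <- seq(0, 20, by = 1)
coupling <- data.frame(
  gap_um = gaps,
  efficiency_dB = vapply(gaps, function(z) {
    as.numeric(gaussian_overlap(te00, fiber_beam(4.5), z))
  }, numeric(1)))
write.csv(coupling, file.path(out, "edge_coupling_vs_gap.csv"), row.names = FALSE)
cat(sprintf("Edge coupling (MFD 4.5 um): %.2f dB in contact, %.2f dB at 10 um gap\n",
            coupling$efficiency_dB[1], coupling$efficiency_dB[11]))
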