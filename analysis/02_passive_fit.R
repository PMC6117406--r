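#!/usr/bin/env Rscript
# Stage 2: passive material calibration.
#
# Fits the eight passive constants so the model's end-diastolic
# pressure-volume curve follows the single-point Klotz EDPVR of the subject
# (coarse-mesh fit, then a common-stiffness polish on the production mesh so
# the model EDV lands on the measured 53 ml), and writes the fitted curve.

library(lvmech)
dir.create("results", showWarnings = FALSE)

meas <- paper_patient()
v0 <- klotz_unloaded_volume(meas$edv, meas$edp)
geom0 <- scale_to_unloaded(build_ed_surfaces(meas), v0)
curve <- klotz_curve(meas$edv, meas$edp, v0 = v0)

fit_mesh <- mesh_lv(geom0, 8, 6)
fit_model <- lv_model(fit_mesh, assign_fibers(fit_mesh))
fit <- fit_passive_params(fit_model, curve, meas$edp)
cat(sprintf("coarse-mesh fit: RMS %.2f ml (%.2f%% of EDV), %d evaluations\n",
            fit$rms_ml, 100 * fit$rms_frac_edv, fit$n_eval))

mesh <- mesh_lv(geom0, 16, 10)
model <- lv_model(mesh, assign_fibers(mesh), mp = fit$params)
pol <- rescale_stiffness_to_edv(model, meas$edp, meas$edv)
model <- set_material(model, pol$params)
cat(sprintf("production-mesh polish: scale %.3f, V(EDP) = %.2f ml\n",
            pol$scale, pol$edv))
print(unlist(pol$params[c("a", "b", "a_f", "b_f", "a_s", "b_s",
                          "a_fs", "b_fs")]))

pr <- meas$edp * (1:8) / 8
ed <- inflate_to_edp(model, meas$edp, pressures = pr)
out <- data.frame(pressure_mmHg = ed$pv$pressure_mmHg,
                  volume_model_ml = ed$pv$volume_ml,
                  volume_klotz_ml = c(v0, klotz_volume(curve, pr)))
write.csv(out, "results/ed_pv_fit.csv", row.names = FALSE)
cat(sprintf("production-mesh EDPVR RMS: %.2f ml\n",
            sqrt(mean((out$volume_model_ml[-1] - out$volume_klotz_ml[-1])^2))))
saveRDS(list(params = pol$params, fit = fit), "results/passive_fit.rds")
cat("wrote results/ed_pv_fit.csv, results/passive_fit.rds\n")
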