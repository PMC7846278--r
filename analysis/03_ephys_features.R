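#!/usr/bin/env Rscript
# Patch-clamp stage: generate synthetic PSC and AP recordings with known
# ground truth and extract the standard feature set (amplitudes, 20-80% rise
# kinetics, AP waveform features, ramp excitability, Rs quality control).
#
# Writes results/psc_features.csv, results/ap_features.json,
# results/ramp_fi.csv and a provenance record.

library(spontnet)

seed <- 1L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

message("PSC train: 2 Hz Poisson, 30 pA biexponential (0.5/5 ms), 180 s ...")
spec <- ephys_synth_spec(psc_rate_hz = 2, psc_amplitude_pa = 30,
                         noise_sd_pa = 1, sample_rate_hz = 20000, seed = seed)
g <- generate_psc_trace(spec, duration_s = 180)
ev <- detect_psc_events(g$trace, g$sample_rate_hz, min_amplitude_pa = 10)
write.csv(ev, file.path(out_dir, "psc_features.csv"), row.names = FALSE)
bf <- bin_frequency(ev$onset_s, 180, bin_s = 90)
message(sprintf("%d PSCs detected (%d injected); mean 90-s binned frequency %.2f Hz;",
                nrow(ev), nrow(g$ground_truth), mean(bf$frequency_hz)))
message(sprintf("median amplitude %.1f pA, median rise rate %.1f pA/ms (analytic rise %.3f ms).",
                median(ev$amplitude_pa), median(ev$rise_rate_pa_per_ms),
                psc_rise_time_2080(0.5, 5)))

message("Single AP elicited by a current pulse ...")
gap <- generate_ap_trace(ephys_synth_spec(ap_overshoot_mv = 15, seed = seed))
f <- ap_features(gap$trace, gap$sample_rate_hz, gap$ground_truth$pulse_onset_s)
message(sprintf("overshoot %.1f mV, amplitude %.1f mV, half-width %.3f ms, dTime %.2f ms, max dV/dt %.0f mV/ms",
                f$overshoot_mv, f$amplitude_mv, f$halfwidth_ms, f$dtime_ms,
                f$max_dvdt_mv_per_ms))
jsonlite::write_json(unclass(f), file.path(out_dir, "ap_features.json"),
                     auto_unbox = TRUE, digits = NA)

message("Ramp excitability of the model SST cell (-100 to 140 pA at 96 pA/s) ...")
cfg <- model_config(seed = seed)
sr <- simulate_ramp(cfg, "sst")
rr <- ramp_fi(sr$trace, sr$sample_rate_hz, ramp = sr$ramp)
write.csv(rr, file.path(out_dir, "ramp_fi.csv"), row.names = FALSE)
pop <- !is.na(rr$instantaneous_freq_hz)
message(sprintf("%d of %d full 175-ms bins populated; peak instantaneous rate %.1f Hz.",
                sum(pop & !rr$partial), attr(rr, "n_full_bins"),
                max(rr$instantaneous_freq_hz, na.rm = TRUE)))

qc <- qc_series_resistance(c(18, 19, 21))
message(sprintf("Rs QC example [18, 19, 21] MOhm: %s.",
                if (qc$pass) "pass" else "fail"))

write_provenance(provenance_record(list(stage = "ephys"), seed = seed),
                 file.path(out_dir, "ephys_provenance.json"), force = TRUE)
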