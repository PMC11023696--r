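#!/usr/bin/env Rscript
# Generate the synthetic session bundle every later step consumes:
# a vessel image stack, a spontaneous-event trace, an entrained photometry
# channel pair, and eye traces — each with its ground truth alongside.

suppressPackageStartupMessages(library(vasoentrain))

seed <- 1
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("Vessel stack (45.7 um vessel with spontaneous events, 120 s @ 5 Hz) ...")
vs <- gen_vessel_stack(duration = 120, noise_sd = 1, events = event_model(),
                       seed = seed)
write_stack(vs$stack, file.path(out, "vessel_stack.tif"))
write_ground_truth(vs$ground_truth, file.path(out, "vessel_stack_truth.json"))

message("Spontaneous-event trace (10 min @ 5 Hz, Fig-1G-style statistics) ...")
ev <- gen_event_trace(duration = 600, seed = seed)
write_trace(ev$trace, file.path(out, "event_trace.csv"))
write_ground_truth(ev$ground_truth, file.path(out, "event_trace_truth.json"))

message("Entrained photometry pair (15 min @ 5 Hz, dYFP-like mirror) ...")
pp <- gen_photometry_pair(stimulus_spec(duration = 900),
                          channel_lag = dyfp_model()$channel_lag,
                          seed = seed)
write_trace(pp$ch1, file.path(out, "texasred.csv"))
write_trace(pp$ch2, file.path(out, "dyfp.csv"))
write_ground_truth(pp$ground_truth, file.path(out, "photometry_truth.json"))

message("Eye trace (5 min @ 30 Hz, gain 0.5, lag 2.3 deg) ...")
ey <- gen_eye_trace(stimulus_spec(duration = 300), seed = seed)
write_trace(ey$trace, file.path(out, "eye.csv"))
write_ground_truth(ey$ground_truth, file.path(out, "eye_truth.json"))

message("Done; bundle written under ", out)
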