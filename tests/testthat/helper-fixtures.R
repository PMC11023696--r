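# Shared fixture builders. Everything is generated in code at test time.

withr_local_dir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

withr_local_file <- function(name, env = parent.frame()) {
  file.path(withr::local_tempdir(.local_envir = env), name)
}

# A small vessel stack plus the flank/vessel ROI geometry it needs.
make_vessel_fixture <- function(duration = 120, noise_sd = 1, seed = 1, ...) {
  vs <- gen_vessel_stack(duration = duration, noise_sd = noise_sd, seed = seed, ...)
  nx <- dim(vs$stack$data)[3]
  ny <- dim(vs$stack$data)[2]
  list(
    stack = vs$stack,
    truth = vs$ground_truth,
    left_roi = pixel_roi(1:ny, 1:8),
    right_roi = pixel_roi(1:ny, (nx - 7):nx),
    vessel_roi = pixel_roi(1:ny, (round(nx / 2) - 5):(round(nx / 2) + 5)),
    line_rows = 1:ny
  )
}

# Raw-fluorescence trace wrapping a percent modulation around a baseline.
make_raw_trace <- function(mod, rate = 5, baseline = 100) {
  trace_series(baseline * (1 + mod / 100), rate, channel = "TexasRed")
}
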