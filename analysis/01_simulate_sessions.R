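#!/usr/bin/env Rscript
# Simulate one control and one DISC1-overexpression-like session and store
# them as bundle directories under results/sessions/. All later drivers read
# these bundles, so the whole analysis is reproducible from this script.
#
# Sizes: 10-min familiar exploration, 5-min novel exploration, 5-min sleep
# epochs, 30 pyramidal cells -- large enough for stable population metrics,
# small enough to run in a couple of minutes.

suppressPackageStartupMessages(library(ripplemap))

dur <- c(rest_pre = 30, familiar_explore = 600, sleep_familiar = 300,
         novel_explore = 300, sleep_novel = 300)

dir.create("results/sessions", recursive = TRUE, showWarnings = FALSE)
for (lab in c("control", "tgDISC1like")) {
  message("simulating ", lab, " session ...")
  ses <- simulate_session(ripple_preset(lab), n_pyr = 30, n_int = 6,
                          epoch_durations_s = dur, seed = 20240901)
  write_session_bundle(ses, file.path("results/sessions", lab))
  message("  ", sum(lengths(ses$spike_times)), " spikes, ",
          length(ses$ground_truth$swr_times), " SWRs injected")
}
message("bundles written under results/sessions/")
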