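#!/usr/bin/env Rscript
# Peri-SWR population firing and exploration-to-sleep reactivation:
# 10-ms-binned firing around detected SWR centres per cell class, and the
# correlation between waking theta cofiring and sleep SWR cofiring.
# Writes results/peri_swr_*.csv and results/reactivation.csv.

suppressPackageStartupMessages(library(ripplemap))

re_rows <- list()
for (lab in c("control", "tgDISC1like")) {
  ses <- read_session_bundle(file.path("results/sessions", lab))
  sleep <- rbind(session_epoch(ses, "sleep_familiar"),
                 session_epoch(ses, "sleep_novel"))
  ev <- detect_swrs(ses$lfp, sleep)
  for (cls in c("pyr", "int")) {
    cells <- ses$spike_times[ses$units$cell_class == cls]
    peri <- peri_swr_rates(cells, ev)
    write.csv(peri, sprintf("results/peri_swr_%s_%s.csv", lab, cls),
              row.names = FALSE)
    message(sprintf("%s %s: peri-SWR peak %.2f Hz (baseline %.2f Hz)",
                    lab, cls, max(peri$rate_hz),
                    mean(peri$rate_hz[abs(peri$t_rel) > 0.2])))
  }
  fam <- session_epoch(ses, "familiar_explore")
  te <- detect_theta_epochs(ses$lfp, fam)
  pyr_cells <- ses$spike_times[ses$units$cell_class == "pyr"]
  wake_co <- cofiring(pyr_cells, iv_intersect(te, fam))
  ev_fam <- ev[iv_contains(session_epoch(ses, "sleep_familiar"), ev$t), ]
  swr_co <- cofiring(pyr_cells, ev_fam, center_events = TRUE)
  re <- reactivation_strength(wake_co, swr_co)
  re_rows[[lab]] <- data.frame(session = lab,
                               reactivation_r = re$reactivation_r,
                               n_pairs = re$n_pairs)
}
out <- do.call(rbind, re_rows)
write.csv(out, "results/reactivation.csv", row.names = FALSE)
print(out, row.names = FALSE)
z <- fisher_z_test(out$reactivation_r[1], out$n_pairs[1],
                   out$reactivation_r[2], out$n_pairs[2])
message(sprintf("\ngroup comparison (Fisher z): z = %.2f, p = %.3g", z$z,
                z$p_value))
message("Pyramidal firing rises several-fold at SWR centres (more in ",
        "control, whose preset plants the higher ripple gain) while ",
        "interneuron profiles are similar; waking cofiring patterns ",
        "reappear during sleep SWRs, giving positive reactivation in both ",
        "sessions.")
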