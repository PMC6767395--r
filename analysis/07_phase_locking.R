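#!/usr/bin/env Rscript
# Spike-phase circular statistics: per-unit theta mean vectors in familiar
# and novel exploration, population locking strength, preferred-phase
# concentration with chi-square intervals, the variance-ratio comparison
# between sessions, and the novelty phase-shift Watson-Williams test.
# Writes results/mean_vectors.csv and results/phase_population.csv.

suppressPackageStartupMessages(library(ripplemap))

mv_all <- list(); pop <- list(); conc_store <- list()
for (lab in c("control", "tgDISC1like")) {
  ses <- read_session_bundle(file.path("results/sessions", lab))
  pyr <- which(ses$units$cell_class == "pyr")
  ph <- theta_phase(ses$lfp)
  mvs <- list()
  for (ep in c("familiar_explore", "novel_explore")) {
    iv <- session_epoch(ses, ep)
    te <- detect_theta_epochs(ses$lfp, iv)
    mv <- spike_phase_mean_vector(ses$spike_times[pyr], ph,
                                  epochs = iv_intersect(te, iv))
    mv_all[[paste(lab, ep)]] <- cbind(session = lab, epoch = ep, mv)
    conc <- preferred_phase_concentration(mv)
    conc_store[[paste(lab, ep)]] <- conc
    pop[[paste(lab, ep)]] <- data.frame(
      session = lab, epoch = ep,
      mean_locking = population_locking_strength(mv),
      r = conc$r, S2 = conc$S2,
      S2_ci_lower = conc$ci_lower, S2_ci_upper = conc$ci_upper,
      n_significant = conc$n)
    mvs[[ep]] <- mv
  }
  sh <- novelty_phase_shift(mvs$familiar_explore, mvs$novel_explore)
  message(sprintf(
    "%s: novelty shift %.1f deg, Watson-Williams p = %.3g", lab,
    sh$shift_deg, sh$test$p_value))
}
write.csv(do.call(rbind, mv_all), "results/mean_vectors.csv",
          row.names = FALSE)
p <- do.call(rbind, pop)
write.csv(p, "results/phase_population.csv", row.names = FALSE)
print(p, row.names = FALSE)

for (ep in c("familiar_explore", "novel_explore")) {
  a <- conc_store[[paste("control", ep)]]
  b <- conc_store[[paste("tgDISC1like", ep)]]
  vr <- variance_ratio_test(a$S2, a$n, b$S2, b$n)
  message(sprintf("angular variance %s: F = %.2f, p = %.3g", ep, vr$F,
                  vr$p_value))
}
message("\nThe DISC1-like population locks more strongly during novelty ",
        "but its preferred phases scatter more (larger angular variance), ",
        "and only the control population shifts its preferred phase ",
        "between environments -- the three signatures the presets plant.")
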