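#!/usr/bin/env Rscript
# Direction-only genotype contrast suite: 20 paired simulations (identical
# trajectories per pair), seven population metrics each, sign-consistency
# table. Writes results/preset_contrasts.csv.

suppressPackageStartupMessages(library(ripplemap))

dur <- c(rest_pre = 10, familiar_explore = 300, sleep_familiar = 110,
         novel_explore = 200, sleep_novel = 110)
rows <- list()
for (i in 1:20) {
  p <- preset_contrast_pair(1000 + i, n_pyr = 18, n_int = 3,
                            epoch_durations_s = dur)
  rows[[i]] <- cbind(pair = i, p)
  message("pair ", i, " done")
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/preset_contrasts.csv", row.names = FALSE)

d <- tab[tab$preset == "tgDISC1like", ]
c_ <- tab[tab$preset == "control", ]
cons <- c(
  smaller_field_size = mean(d$field_size_fraction < c_$field_size_fraction),
  higher_spatial_info = mean(d$spatial_info_bits > c_$spatial_info_bits),
  smaller_decode_error = mean(d$decoding_error_cm < c_$decoding_error_cm),
  weaker_speed_modulation = mean(d$speed_rate_r < c_$speed_rate_r),
  stronger_novel_locking = mean(d$theta_locking_novel > c_$theta_locking_novel),
  larger_angular_variance = mean(d$phase_angular_variance >
                                   c_$phase_angular_variance),
  lower_peri_swr_rate = mean(d$peri_swr_peak_hz < c_$peri_swr_peak_hz))
print(round(cons, 2))
message("\nEach row is the fraction of the 20 pairs in which the ",
        "DISC1-like session differs from its matched control in the ",
        "planted direction; all seven contrasts are expected at >= 0.9.")
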