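#' Variance-ratio test for angular variances
#'
#' Compares the angular variances `S2 = 1 - r` of preferred-phase
#' distributions from two groups of units with an F test on their ratio
#' (larger variance in the numerator, two-sided p).
#'
#' The angular variance of a von Mises sample is not chi-square distributed
#' with `n - 1` degrees of freedom except at high concentration, so naive
#' `(n-1, n-1)` degrees of freedom make the test badly calibrated at the
#' concentrations typical of preferred-phase data. The degrees of freedom are
#' therefore moment-matched: with `kappa` estimated from `r = 1 - S2`, the
#' delta-method variance of the mean resultant length is
#' `sigma_r^2 = (1 - A(kappa)^2 - A(kappa)/kappa) / n`, and a chi-square
#' variable matching the first two moments of `S2` has
#' `df = 2 S2^2 / Var(S2)`. At high concentration this recovers the classic
#' `~n` degrees of freedom; at low concentration it is appropriately larger.
#'
#' @param S2_a,S2_b angular variances of the two groups (> 0)
#' @param n_a,n_b numbers of units behind each variance
#' @return list: `F` (larger/smaller ratio), `df`, `p_value`, `flag`
#'   (`"degenerate"` when a variance is 0, p reported at machine floor)
#' @export
variance_ratio_test <- function(S2_a, n_a, S2_b, n_b) {
  if (S2_a <= 0 || S2_b <= 0) {
    return(list(F = Inf, df = c(NA, NA), p_value = .Machine$double.xmin,
                flag = "degenerate"))
  }
  df_eff <- function(S2, n) {
    r <- min(1 - S2, 1 - 1e-9)
    if (r <= 0) return(n - 1)           # uniform-side fallback
    kappa <- vm_A_inv(r)
    A <- vm_A(kappa)
    s2r <- if (kappa < 1e-8) 0.5 else 1 - A^2 - A / kappa
    v <- s2r / n
    max(1, 2 * S2^2 / v)
  }
  if (S2_a >= S2_b) {
    f <- S2_a / S2_b; d1 <- df_eff(S2_a, n_a); d2 <- df_eff(S2_b, n_b)
  } else {
    f <- S2_b / S2_a; d1 <- df_eff(S2_b, n_b); d2 <- df_eff(S2_a, n_a)
  }
  p <- 2 * stats::pf(f, d1, d2, lower.tail = FALSE)
  list(F = f, df = c(d1, d2), p_value = min(1, p), flag = NA_character_)
}

#' Watson-Williams test for equality of circular means
#'
#' Classic one-way circular analysis of variance for two groups, with the
#' standard concentration-based correction factor `1 + 3/(8 kappa)`. Valid
#' when the groups are reasonably concentrated; a warning flag is set when
#' the pooled mean resultant length is below 0.45.
#'
#' @param angles_a_deg,angles_b_deg angle samples (degrees)
#' @return list: `F`, `df`, `p_value`, `mean_a_deg`, `mean_b_deg`,
#'   `shift_deg` (signed difference b - a wrapped to (-180, 180]),
#'   `low_concentration` validity flag
#' @export
watson_williams_test <- function(angles_a_deg, angles_b_deg) {
  na <- length(angles_a_deg); nb <- length(angles_b_deg)
  if (na < 10 || nb < 10) stop("each group needs at least 10 angles")
  mva <- circ_mean_vector(angles_a_deg)
  mvb <- circ_mean_vector(angles_b_deg)
  Ra <- na * mva$length; Rb <- nb * mvb$length
  N <- na + nb
  mv_all <- circ_mean_vector(c(angles_a_deg, angles_b_deg))
  R <- N * mv_all$length
  rbar <- (Ra + Rb) / N
  kappa <- vm_A_inv(min(rbar, 1 - 1e-9))
  g <- 1 + 3 / (8 * kappa)
  Fstat <- g * (N - 2) * (Ra + Rb - R) / (N - (Ra + Rb))
  Fstat <- max(Fstat, 0)
  p <- stats::pf(Fstat, 1, N - 2, lower.tail = FALSE)
  shift <- ((mvb$angle_deg - mva$angle_deg + 180) %% 360) - 180
  list(F = Fstat, df = c(1, N - 2), p_value = p,
       mean_a_deg = mva$angle_deg, mean_b_deg = mvb$angle_deg,
       shift_deg = shift, low_concentration = rbar < 0.45)
}

#' Novelty-induced preferred-phase shift
#'
#' Compares the population of preferred phases between a familiar and a novel
#' exploration epoch: circular mean per epoch, the signed shift, and a
#' Watson-Williams test for a common mean direction. Units need not be
#' matched across epochs (population-level comparison, as used for group
#' phase-shift figures).
#'
#' @param mean_vectors_familiar,mean_vectors_novel data frames from
#'   [spike_phase_mean_vector], computed with the same phase convention
#' @param significant_only restrict to Rayleigh-significant units (default
#'   TRUE, matching the concentration analyses)
#' @return list: `mean_familiar_deg`, `mean_novel_deg`, `shift_deg`, `test`
#'   (Watson-Williams result)
#' @export
novelty_phase_shift <- function(mean_vectors_familiar, mean_vectors_novel,
                                significant_only = TRUE) {
  fam <- mean_vectors_familiar; nov <- mean_vectors_novel
  if (significant_only) {
    fam <- fam[fam$significant, , drop = FALSE]
    nov <- nov[nov$significant, , drop = FALSE]
  }
  ww <- watson_williams_test(fam$angle_deg, nov$angle_deg)
  list(mean_familiar_deg = ww$mean_a_deg, mean_novel_deg = ww$mean_b_deg,
       shift_deg = ww$shift_deg, test = ww)
}

#' Z-test on two Fisher-transformed correlation coefficients
#'
#' @param r1,r2 Pearson correlations
#' @param n1,n2 sample sizes behind them
#' @return list: `z`, `p_value` (two-sided)
#' @export
fisher_z_test <- function(r1, n1, r2, n2) {
  stopifnot(n1 > 3, n2 > 3)
  z1 <- atanh(r1); z2 <- atanh(r2)
  z <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}
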