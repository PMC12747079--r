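# Deterministic SYNTHETIC stand-ins for the study's supplementary tables,
# which are not redistributable here. Each construction is built to possess
# the study's printed marginal statistics exactly, so the checks verify that
# the package's summarisers recover those statistics from data that carry
# them (see the methods vignette for what this does and does not show).

# Synthetic survey stand-in: 263 lineage percentages with mean 16.47,
# median 12.08, SD 15.95, range [0, 96.5], 154 values > 10 and 39 < 1.
# Fixed low/mid blocks plus a high block whose interior is affinely scaled
# to meet the total sum and sum of squares exactly.
synthetic_survey_pcts <- function() {
  n <- 263
  target_mean <- 16.47; target_sd <- 15.95
  low <- c(0, seq(0.1, 0.9, length.out = 38))        # 39 values < 1
  mid <- seq(1.5, 9.5, length.out = 70)              # 70 values in [1, 10]
  h_low <- seq(10.2, 12.0, length.out = 22)          # below the median
  fixed_high <- c(12.08, 96.5)                       # median order stat, max
  total_sum <- n * target_mean
  total_ss <- (n - 1) * target_sd^2 + n * target_mean^2
  rem_n <- 154 - length(h_low) - length(fixed_high)  # 130 free high values
  rem_sum <- total_sum - sum(low, mid, h_low, fixed_high)
  rem_ss <- total_ss - sum(low^2, mid^2, h_low^2, fixed_high^2)
  z <- (seq_len(rem_n) / rem_n)^3                    # right-skewed pattern
  z <- (z - mean(z)) / sqrt(sum((z - mean(z))^2))    # zero-sum, unit sumsq
  m <- rem_sum / rem_n
  s <- sqrt(rem_ss - rem_n * m^2)
  v <- m + s * z
  stopifnot(min(v) > 12.08, max(v) < 96.5)           # category constraints hold
  pct <- c(low, mid, h_low, fixed_high, v)
  stopifnot(length(pct) == n)
  pct
}

synthetic_survey_table <- function() {
  pct <- synthetic_survey_pcts()
  hnf <- rep(1e4, length(pct))  # large denominator keeps pct exact
  tibble::tibble(sample_id = sprintf("S%03d", seq_along(pct)),
                 hnf_count = hnf,
                 cry1a_count = hnf * pct / 100,
                 cry1a_pct = pct)
}

# Synthetic element-catalogue stand-in: 13 elements, 11 TIR-flanked and 2
# TDR-flanked, with lower-median length 20.29 kb, TIR median 488 bp and TDR
# (lower-)median 266 bp.
synthetic_plv_catalogue <- function() {
  lengths <- c(14000, 15000, 16200, 17500, 18400, 19800, 20290,
               22000, 24500, 27000, 30000, 34000, 39500)
  tir_len <- c(150, 220, 300, 380, 450, 488, 520, 600, 700, 800, 900)
  tdr_len <- c(266, 312)
  tibble::tibble(
    contig_id = sprintf("chr%02d", seq_along(lengths)),
    start = 1e5, end = 1e5 + lengths - 1,
    length = lengths,
    gc = 0.35,
    repeat_kind = c(rep("TIR", 11), rep("TDR", 2)),
    repeat_len = c(tir_len, tdr_len))
}

# Synthetic growth-table stand-in: three replicates generated at the
# study's observed kinetics (29 h doubling, ~1 week lag, collapse in one
# replicate).
synthetic_growth_table <- function() {
  reps <- lapply(1:3, function(i) {
    gen_growth(inoculum = 200, lag = 168, mu = log(2) / 29,
               t_collapse = if (i == 3) 456 else Inf,
               collapse_frac = if (i == 3) 0.8 else 0,
               cv = 0.1, timepoints = seq(0, 552, by = 24),
               replicate_id = sprintf("rep%d", i), seed = 400 + i)
  })
  dplyr::bind_rows(reps)
}
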