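# Independent oracles and fixture generators for the test suite.
# These re-derive the model quantities from the written formulas directly,
# bypassing the package's own code paths.

# fitness gap computed straight from the share/Monod formulas
oracle_gap <- function(alpha, r, fmax, Km, C, x) {
  R_co <- alpha * r + (1 - alpha) * r * x
  R_ch <- (1 - alpha) * r * x
  fmax * R_co / (Km + R_co) - C - fmax * R_ch / (Km + R_ch)
}

# brute-force root of the gap on [0, 1]: sign change on a fine grid,
# midpoint of the bracketing pair; same clamping convention at the ends
oracle_grid_root <- function(p, step = 1e-6) {
  x <- seq(0, 1, by = step)
  gx <- oracle_gap(p$alpha, p$r, p$fmax, p$Km, p$C, x)
  if (gx[1L] <= 0) return(0)
  if (gx[length(gx)] >= 0) return(1)
  i <- which(diff(sign(gx)) < 0)[1L]
  (x[i] + x[i + 1L]) / 2
}

# random parameter sets with privatization strictly inside (0, 1)
random_params <- function(n, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      coop_params(
        alpha = runif(1, 0.02, 0.95),
        r = runif(1, 0.2, 5),
        C = runif(1, 0, 0.3),
        fmax = runif(1, 0.5, 2),
        Km = runif(1, 0.2, 2)
      )
    })
  })
}

# reference interior parameter set used across the suite
ref_params <- function() coop_params(alpha = 0.2, r = 1, C = 0.1,
                                     fmax = 1, Km = 1)

logit <- function(p) log(p / (1 - p))
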