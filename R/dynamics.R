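#' Generations elapsed per serial transfer
#'
#' In a batch regrowth cycle, a 1:`d` dilution is restored by `log2(d)`
#' doublings, so a daily 1:100 transfer corresponds to about 6.6--6.7
#' generations per day.
#'
#' @param dilution_factor Fold-dilution per transfer (> 1), e.g. 100.
#' @return `log2(dilution_factor)`, the doublings per transfer.
#' @examples
#' generations_per_transfer(100)
#' @export
generations_per_transfer <- function(dilution_factor) {
  if (!is.numeric(dilution_factor) || length(dilution_factor) != 1L ||
      !is.finite(dilution_factor) || dilution_factor <= 1) {
    abort("`dilution_factor` must be a single number > 1.",
          class = "privcoop_domain_error")
  }
  log2(dilution_factor)
}

#' Serial-transfer experimental regime
#'
#' Describes the batch-dilution design of the coevolution experiment: a
#' daily 1:100 dilution into fresh medium (about 6.6 generations per
#' transfer), 30 transfers for roughly 200 generations, with frequency
#' assays every 50 generations.
#'
#' @param dilution_factor Fold-dilution per transfer (> 1). Default 100.
#' @param n_transfers Number of transfers. Default 30 (about 199
#'   generations at 1:100).
#' @param assay_interval Spacing of frequency assays, in generations.
#'   Default 50. Assays fall on the transfers nearest to multiples of this
#'   interval (generation 0 included).
#'
#' @return An object of class `transfer_regime`: a list with elements
#'   `dilution_factor`, `generations_per_transfer`, `n_transfers`,
#'   `assay_interval_generations`, `total_generations`.
#' @examples
#' transfer_regime()
#' @export
transfer_regime <- function(dilution_factor = 100, n_transfers = 30,
                            assay_interval = 50) {
  gpt <- generations_per_transfer(dilution_factor)
  if (!is.numeric(n_transfers) || length(n_transfers) != 1L ||
      n_transfers < 1 || n_transfers != round(n_transfers)) {
    abort("`n_transfers` must be a positive whole number.",
          class = "privcoop_domain_error")
  }
  if (!is.numeric(assay_interval) || length(assay_interval) != 1L ||
      !is.finite(assay_interval) || assay_interval <= 0) {
    abort("`assay_interval` must be a single positive number.",
          class = "privcoop_domain_error")
  }
  structure(
    list(
      dilution_factor = as.numeric(dilution_factor),
      generations_per_transfer = gpt,
      n_transfers = as.integer(n_transfers),
      assay_interval_generations = as.numeric(assay_interval),
      total_generations = as.integer(n_transfers) * gpt
    ),
    class = "transfer_regime"
  )
}

as_transfer_regime <- function(regime) {
  if (inherits(regime, "transfer_regime")) return(regime)
  abort("`regime` must be a `transfer_regime` object (see `transfer_regime()`).",
        class = "privcoop_domain_error")
}

#' @export
print.transfer_regime <- function(x, ...) {
  cat("<transfer_regime>\n")
  cat(sprintf("  1:%g dilution, %.3f generations/transfer\n",
              x$dilution_factor, x$generations_per_transfer))
  cat(sprintf("  %d transfers = %.1f generations, assays every %g generations\n",
              x$n_transfers, x$total_generations,
              x$assay_interval_generations))
  invisible(x)
}

#' Transfers at which frequency assays fall
#'
#' Maps the assay schedule (generation 0 and every
#' `assay_interval_generations` thereafter) onto the transfer grid, picking
#' for each scheduled time the transfer whose cumulative generation count is
#' nearest.
#'
#' @param regime A [transfer_regime()] object.
#' @return A tibble with columns `assay` (0-based index), `transfer` and
#'   `generation` (cumulative generations at that transfer).
#' @examples
#' assay_generations(transfer_regime())
#' @export
assay_generations <- function(regime) {
  regime <- as_transfer_regime(regime)
  gpt <- regime$generations_per_transfer
  # schedule to the nearest multiple of the interval, so a 30-transfer,
  # 1:100 regime (199.3 generations) still gets its ~generation-200 assay
  n_assays <- round(regime$total_generations /
                      regime$assay_interval_generations)
  targets <- regime$assay_interval_generations * (0:n_assays)
  transfer <- unique(pmin(round(targets / gpt), regime$n_transfers))
  tibble::tibble(
    assay = seq_along(transfer) - 1L,
    transfer = as.integer(transfer),
    generation = transfer * gpt
  )
}

#' One serial-transfer update of the cooperator frequency
#'
#' Advances the cooperator frequency through one batch of `dt_generations`
#' generations using Wrightian exponential weights evaluated at the
#' start-of-batch frequency: with `w_co = exp(f_co * dt)` and
#' `w_ch = exp(f_ch * dt)`,
#' \deqn{x' = \frac{x\,w_{co}}{x\,w_{co} + (1-x)\,w_{ch}}.}
#' Equivalently the log-odds of cooperators change by exactly
#' `(f_co - f_ch) * dt` per batch. The boundaries `x = 0` and `x = 1` are
#' absorbing.
#'
#' @param params A [coop_params()] object.
#' @param x Cooperator frequency (vectorised), each in \[0, 1\].
#' @param dt_generations Batch duration in generations (> 0).
#' @return Updated frequencies, same length as `x`.
#' @examples
#' p <- coop_params(alpha = 0.2, r = 1, C = 0.1)
#' step_frequency(p, 0.5, generations_per_transfer(100))
#' @export
step_frequency <- function(params, x, dt_generations) {
  params <- as_coop_params(params)
  validate_fraction(x, "x")
  if (!is.numeric(dt_generations) || length(dt_generations) != 1L ||
      !is.finite(dt_generations) || dt_generations <= 0) {
    abort("`dt_generations` must be a single positive number.",
          class = "privcoop_domain_error")
  }
  step_raw(params, x, dt_generations)
}

# hot-path update without tibble construction; inputs assumed valid
step_raw <- function(params, x, dt) {
  R_co <- params$alpha * params$r + (1 - params$alpha) * params$r * x
  R_ch <- (1 - params$alpha) * params$r * x
  f_co <- params$fmax * R_co / (params$Km + R_co) - params$C
  f_ch <- params$fmax * R_ch / (params$Km + R_ch)
  w_co <- exp(f_co * dt)
  w_ch <- exp(f_ch * dt)
  xp <- x * w_co / (x * w_co + (1 - x) * w_ch)
  # x = 0 and x = 1 are absorbing regardless of the weights
  xp[x == 0] <- 0
  xp[x == 1] <- 1
  xp
}

#' Deterministic serial-transfer trajectory of the cooperator frequency
#'
#' Iterates [step_frequency()] once per transfer, each batch lasting
#' `generations_per_transfer` generations, and records the frequency at
#' generation 0 and after every transfer. The deterministic map carries no
#' demographic drift (transfer bottlenecks of 10^5--10^7 cells make drift
#' negligible); an optional finite-population binomial bottleneck can be
#' switched on for sensitivity analyses.
#'
#' @param params A [coop_params()] object.
#' @param regime A [transfer_regime()] object.
#' @param x0 Initial cooperator frequency in \[0, 1\]. Default 0.5 (the
#'   1:1 starting mix of the experiment).
#' @param bottleneck_n Optional number of cells surviving each transfer; if
#'   supplied, the post-transfer frequency is resampled as
#'   `Binomial(bottleneck_n, x) / bottleneck_n`. Default `NULL` (off).
#' @param seed Seed for the bottleneck resampling (required when
#'   `bottleneck_n` is set); the global RNG state is left untouched.
#'
#' @return A tibble of class `coop_trajectory` with columns `transfer`,
#'   `generation`, `x`, one row per transfer plus the starting state.
#'
#' @examples
#' p <- coop_params(alpha = 0.2, r = 1, C = 0.1)
#' simulate_serial_transfers(p, transfer_regime(), x0 = 0.5)
#' @export
simulate_serial_transfers <- function(params, regime, x0 = 0.5,
                                      bottleneck_n = NULL, seed = NULL) {
  params <- as_coop_params(params)
  regime <- as_transfer_regime(regime)
  validate_fraction(x0, "x0")
  if (length(x0) != 1L) {
    abort("`x0` must be a single frequency.", class = "privcoop_domain_error")
  }
  gpt <- regime$generations_per_transfer
  n <- regime$n_transfers
  x <- numeric(n + 1L)
  x[1L] <- x0
  if (is.null(bottleneck_n)) {
    for (i in seq_len(n)) {
      x[i + 1L] <- step_raw(params, x[i], gpt)
    }
  } else {
    if (!is.numeric(bottleneck_n) || bottleneck_n < 1) {
      abort("`bottleneck_n` must be a positive count.",
            class = "privcoop_domain_error")
    }
    if (is.null(seed)) {
      abort("supply `seed` when `bottleneck_n` is used.",
            class = "privcoop_domain_error")
    }
    withr::with_seed(seed, {
      for (i in seq_len(n)) {
        xd <- step_raw(params, x[i], gpt)
        x[i + 1L] <- rbinom(1L, size = as.integer(bottleneck_n), prob = xd) /
          as.integer(bottleneck_n)
      }
    })
  }
  out <- tibble::tibble(
    transfer = 0:n,
    generation = (0:n) * gpt,
    x = x
  )
  class(out) <- c("coop_trajectory", class(out))
  attr(out, "params") <- params
  attr(out, "regime") <- regime
  out
}
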