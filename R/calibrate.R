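#' Calibrate privatization and cost from an observed frequency trajectory
#'
#' Fits the privatized fraction `alpha` and cooperation cost `C` by least
#' squares against an observed cooperator-frequency trajectory, holding
#' `fmax`, `Km` and `r` fixed. The model is over-parameterized for
#' frequency-only data, so only the two biologically interpreted constants
#' are fitted. A coarse grid over the (`alpha`, `C`) box seeds a bounded
#' quasi-Newton refinement (`L-BFGS-B`).
#'
#' Predicted frequencies come from [simulate_serial_transfers()]; each
#' observation is matched to the transfer whose cumulative generation count
#' is nearest to its `generation`.
#'
#' A trajectory that never moves (all observed frequencies identical to
#' within `1e-10`) carries no information about (`alpha`, `C`) — any
#' neutral pair fits — and is flagged non-identifiable with `convergence
#' = FALSE`.
#'
#' @param observed A data frame with columns `generation` and `p`
#'   (observed cooperator frequency), at least two rows.
#' @param regime A [transfer_regime()] object describing the transfers the
#'   trajectory was observed under.
#' @param fmax,Km,r Fixed model constants (see [coop_params()]).
#' @param x0 Initial cooperator frequency for the simulated trajectories.
#'   Default `NULL`: the observed frequency at the earliest generation.
#' @param C_max Upper bound of the cost search box. Default `fmax` (a cost
#'   above maximal fitness makes cooperator fitness negative everywhere).
#' @param grid_n Grid points per parameter for the coarse search stage.
#'
#' @return An object of class `coop_fit`: a list with elements `alpha`,
#'   `C`, `objective` (residual sum of squares), `convergence` (logical),
#'   `identifiable` (logical), `fixed` (named list `fmax`, `Km`, `r`),
#'   `x0`, `regime`, `observed`, and `fitted` (tibble of `generation`,
#'   `p`, `p_fit`). Use [tidy()] / [glance()] for tabular summaries.
#'
#' @examples
#' p <- coop_params(alpha = 0.3, C = 0.08)
#' reg <- transfer_regime()
#' traj <- simulate_serial_transfers(p, reg, x0 = 0.5)
#' obs <- data.frame(generation = traj$generation, p = traj$x)
#' fit <- calibrate_trajectory(obs, reg)
#' tidy(fit)
#' @export
calibrate_trajectory <- function(observed, regime, fmax = 1, Km = 1, r = 1,
                                 x0 = NULL, C_max = fmax, grid_n = 21) {
  regime <- as_transfer_regime(regime)
  if (!is.data.frame(observed) ||
      !all(c("generation", "p") %in% names(observed))) {
    abort("`observed` must be a data frame with columns `generation` and `p`.",
          class = "privcoop_domain_error")
  }
  observed <- dplyr::arrange(tibble::as_tibble(observed[c("generation", "p")]),
                             .data$generation)
  if (nrow(observed) < 2L) {
    abort("`observed` needs at least two time points.",
          class = "privcoop_domain_error")
  }
  validate_fraction(observed$p, "observed$p")
  coop_params(alpha = 0, r = r, C = 0, fmax = fmax, Km = Km)  # validate fixed
  if (is.null(x0)) x0 <- observed$p[1L]
  validate_fraction(x0, "x0")

  gpt <- regime$generations_per_transfer
  idx <- pmin(pmax(round(observed$generation / gpt), 0), regime$n_transfers) + 1L

  fixed <- list(fmax = fmax, Km = Km, r = r)

  if (diff(range(observed$p)) < 1e-10) {
    return(new_coop_fit(alpha = NA_real_, C = NA_real_, objective = 0,
                        convergence = FALSE, identifiable = FALSE,
                        fixed = fixed, x0 = x0, regime = regime,
                        observed = observed,
                        fitted = rep(observed$p[1L], nrow(observed))))
  }

  predict_p <- function(alpha, C) {
    p <- list(alpha = alpha, r = r, C = C, fmax = fmax, Km = Km)
    x <- numeric(regime$n_transfers + 1L)
    x[1L] <- x0
    for (i in seq_len(regime$n_transfers)) {
      x[i + 1L] <- step_raw(p, x[i], gpt)
    }
    x[idx]
  }
  objective <- function(theta) {
    sum((predict_p(theta[1L], theta[2L]) - observed$p)^2)
  }

  grid <- tidyr::expand_grid(
    alpha = seq(0, 1, length.out = grid_n),
    C = seq(0, C_max, length.out = grid_n)
  )
  grid_obj <- purrr::pmap_dbl(grid, function(alpha, C) objective(c(alpha, C)))
  starts <- grid[order(grid_obj)[seq_len(min(5L, nrow(grid)))], ]
  fits <- purrr::pmap(starts, function(alpha, C) {
    optim(c(alpha, C), objective, method = "L-BFGS-B",
          lower = c(0, 0), upper = c(1, C_max),
          control = list(factr = 10, maxit = 1000,
                         ndeps = c(1e-7, 1e-7)))
  })
  opt <- fits[[which.min(purrr::map_dbl(fits, "value"))]]

  new_coop_fit(
    alpha = opt$par[1L], C = opt$par[2L], objective = opt$value,
    convergence = opt$convergence == 0L, identifiable = TRUE,
    fixed = fixed, x0 = x0, regime = regime, observed = observed,
    fitted = predict_p(opt$par[1L], opt$par[2L])
  )
}

new_coop_fit <- function(alpha, C, objective, convergence, identifiable,
                         fixed, x0, regime, observed, fitted) {
  structure(
    list(
      alpha = alpha, C = C, objective = objective,
      convergence = convergence, identifiable = identifiable,
      fixed = fixed, x0 = x0, regime = regime, observed = observed,
      fitted = tibble::tibble(generation = observed$generation,
                              p = observed$p, p_fit = fitted)
    ),
    class = "coop_fit"
  )
}

#' @export
print.coop_fit <- function(x, ...) {
  cat("<coop_fit>\n")
  if (!x$identifiable) {
    cat("  non-identifiable: trajectory carries no selection signal\n")
  } else {
    cat(sprintf("  alpha = %.6g, C = %.6g\n", x$alpha, x$C))
    cat(sprintf("  RSS = %.3g over %d time points (converged: %s)\n",
                x$objective, nrow(x$observed), x$convergence))
  }
  invisible(x)
}

#' @rdname calibrate_trajectory
#' @param x A `coop_fit` object.
#' @param ... Unused.
#' @export
tidy.coop_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "C"),
    estimate = c(x$alpha, x$C),
    fixed = FALSE
  ) |>
    dplyr::bind_rows(tibble::tibble(
      term = names(x$fixed),
      estimate = unlist(x$fixed, use.names = FALSE),
      fixed = TRUE
    ))
}

#' @rdname calibrate_trajectory
#' @export
glance.coop_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective,
    convergence = x$convergence,
    identifiable = x$identifiable,
    nobs = nrow(x$observed)
  )
}
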