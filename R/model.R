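#' Per-capita resource shares of cooperators and cheaters
#'
#' At cooperator frequency `x`, each cooperator privatizes `alpha * r` of
#' what it releases, and the non-privatized output of all cooperators,
#' `(1 - alpha) * r * x` per capita, is equally accessible to every cell:
#'
#' \deqn{R_{co} = \alpha r + (1-\alpha) r x, \qquad R_{ch} = (1-\alpha) r x.}
#'
#' The cooperator advantage is exactly the privatized amount:
#' `R_co - R_ch = alpha * r` at every frequency.
#'
#' @param params A [coop_params()] object.
#' @param x Cooperator frequency (vectorised), each value in \[0, 1\].
#'
#' @return A tibble with one row per `x` and columns `x`, `R_co`, `R_ch`.
#'
#' @examples
#' p <- coop_params(alpha = 0.2, r = 1, C = 0.1)
#' resource_shares(p, x = c(0, 0.5, 1))
#' @export
resource_shares <- function(params, x) {
  params <- as_coop_params(params)
  validate_fraction(x, "x")
  tibble::tibble(
    x = as.numeric(x),
    R_co = params$alpha * params$r + (1 - params$alpha) * params$r * x,
    R_ch = (1 - params$alpha) * params$r * x
  )
}

#' Monod fitness of cooperators and cheaters given resource shares
#'
#' Applies saturating (Monod / Michaelis--Menten) growth to each share and
#' subtracts the cost of cooperation from the cooperator only:
#'
#' \deqn{f_{co} = f_{max} \frac{R_{co}}{K_m + R_{co}} - C, \qquad
#'       f_{ch} = f_{max} \frac{R_{ch}}{K_m + R_{ch}}.}
#'
#' @param shares A data frame with columns `R_co` and `R_ch` (e.g. from
#'   [resource_shares()]); shares must be non-negative.
#' @param params A [coop_params()] object.
#'
#' @return `shares` with columns `f_co` and `f_ch` appended.
#'
#' @examples
#' p <- coop_params(alpha = 0.2, r = 1, C = 0.1)
#' resource_shares(p, x = 0.5) |> fitness(p)
#' @export
fitness <- function(shares, params) {
  params <- as_coop_params(params)
  if (!is.data.frame(shares) || !all(c("R_co", "R_ch") %in% names(shares))) {
    abort("`shares` must be a data frame with columns `R_co` and `R_ch`.",
          class = "privcoop_domain_error")
  }
  if (any(!is.finite(shares$R_co)) || any(!is.finite(shares$R_ch)) ||
      any(shares$R_co < 0) || any(shares$R_ch < 0)) {
    abort("resource shares must be finite and non-negative.",
          class = "privcoop_domain_error")
  }
  dplyr::mutate(
    shares,
    f_co = params$fmax * .data$R_co / (params$Km + .data$R_co) - params$C,
    f_ch = params$fmax * .data$R_ch / (params$Km + .data$R_ch)
  )
}

#' Fitness gap between cooperators and cheaters
#'
#' The signed difference `g(x) = f_co(x) - f_ch(x)` whose root (if any) is
#' the coexistence frequency. Because the Monod map is concave and the
#' cooperator share exceeds the cheater share by the constant `alpha * r`,
#' `g` is strictly decreasing in `x` whenever `alpha` is in (0, 1) and
#' `r > 0`: the cooperator advantage is worth most when the common pool is
#' poor (low `x`) and least when it is rich.
#'
#' @inheritParams resource_shares
#' @return Numeric vector `g(x)`, same length as `x` (fitness units).
#' @examples
#' p <- coop_params(alpha = 0.2, r = 1, C = 0.1)
#' fitness_gap(p, c(0, 0.5, 1))
#' @export
fitness_gap <- function(params, x) {
  params <- as_coop_params(params)
  validate_fraction(x, "x")
  gap_raw(params, x)
}

# hot-path evaluation of g(x) without tibble construction; params assumed
# valid and x assumed in [0, 1]
gap_raw <- function(params, x) {
  R_co <- params$alpha * params$r + (1 - params$alpha) * params$r * x
  R_ch <- (1 - params$alpha) * params$r * x
  params$fmax * R_co / (params$Km + R_co) - params$C -
    params$fmax * R_ch / (params$Km + R_ch)
}

#' Solve for the cooperator--cheater coexistence frequency
#'
#' Finds the cooperator frequency `x*` at which cooperators and cheaters
#' are equally fit. Because the fitness gap `g` is monotone decreasing, the
#' interior root (when `g` changes sign on \[0, 1\]) is unique and is found
#' by bracketing bisection. Boundary cases encode competitive exclusion:
#' if `g(0) <= 0` cheaters exclude cooperators (`x* = 0`, `clamped_low`);
#' if `g(1) >= 0` cooperators fix (`x* = 1`, `clamped_high`).
#'
#' @param params A [coop_params()] object.
#' @param tol Bisection tolerance on `x` (width of the final bracket);
#'   default `1e-10`.
#'
#' @return An object of class `coop_coexistence`: a list with elements
#'   `x_star`, `status` (one of `"interior"`, `"clamped_low"`,
#'   `"clamped_high"`), `residual` (`|g(x*)|` when interior, `NA`
#'   otherwise), `tol` and `params`. Use [tidy()] for a one-row tibble.
#'
#' @examples
#' solve_coexistence(coop_params(alpha = 0.2, r = 1, C = 0.1))
#' @export
solve_coexistence <- function(params, tol = 1e-10) {
  params <- as_coop_params(params)
  if (!is.numeric(tol) || length(tol) != 1L || !is.finite(tol) || tol <= 0) {
    abort("`tol` must be a single positive number.",
          class = "privcoop_domain_error")
  }
  g <- function(x) gap_raw(params, x)
  g0 <- g(0)
  g1 <- g(1)
  if (g0 <= 0) {
    res <- list(x_star = 0, status = "clamped_low", residual = NA_real_)
  } else if (g1 >= 0) {
    res <- list(x_star = 1, status = "clamped_high", residual = NA_real_)
  } else {
    lo <- 0
    hi <- 1
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) lo <- mid else hi <- mid
    }
    xs <- (lo + hi) / 2
    res <- list(x_star = xs, status = "interior", residual = abs(g(xs)))
  }
  structure(c(res, list(tol = tol, params = params)),
            class = "coop_coexistence")
}

#' @export
print.coop_coexistence <- function(x, ...) {
  cat("<coop_coexistence>\n")
  cat(sprintf("  x* = %.10g (%s)\n", x$x_star, x$status))
  if (x$status == "interior") {
    cat(sprintf("  |f_co - f_ch| at x* = %.3g\n", x$residual))
  }
  invisible(x)
}

#' @rdname solve_coexistence
#' @param x A `coop_coexistence` object.
#' @param ... Unused.
#' @export
tidy.coop_coexistence <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    alpha = p$alpha, r = p$r, C = p$C, fmax = p$fmax, Km = p$Km,
    x_star = x$x_star, status = x$status, residual = x$residual
  )
}

#' Sweep the coexistence frequency over privatization and release rates
#'
#' Solves the equal-fitness coexistence frequency on the full grid of
#' `alphas` (privatized fraction) by `rs` (resource released per cell),
#' holding `fmax`, `Km` and `C` at their values in `base`. At fixed `r`,
#' `x*` is non-decreasing in `alpha` (more privatization supports more
#' cooperators), while `r` typically moves `x*` much less.
#'
#' @param base A [coop_params()] object supplying `fmax`, `Km`, `C`.
#' @param alphas Numeric vector of privatized fractions, each in \[0, 1\].
#' @param rs Numeric vector of release amounts, each `>= 0`.
#' @param tol Bisection tolerance passed to [solve_coexistence()].
#'
#' @return A tibble of class `coop_sweep` with columns `alpha`, `r`,
#'   `x_star`, `status` and one row per grid cell (alpha-major order).
#'
#' @examples
#' base <- coop_params(C = 0.1)
#' sweep_alpha_r(base, alphas = c(0.1, 0.2, 0.4), rs = c(0.5, 1))
#' @export
sweep_alpha_r <- function(base, alphas, rs, tol = 1e-10) {
  base <- as_coop_params(base)
  if (length(alphas) == 0L || length(rs) == 0L) {
    abort("`alphas` and `rs` must be non-empty.",
          class = "privcoop_domain_error")
  }
  validate_fraction(alphas, "alphas")
  if (any(!is.finite(rs)) || any(rs < 0)) {
    abort("`rs` must be finite and >= 0.", class = "privcoop_domain_error")
  }
  grid <- tidyr::expand_grid(alpha = as.numeric(alphas), r = as.numeric(rs))
  sol <- purrr::pmap(grid, function(alpha, r) {
    s <- solve_coexistence(
      coop_params(alpha = alpha, r = r, C = base$C,
                  fmax = base$fmax, Km = base$Km),
      tol = tol
    )
    tibble::tibble(x_star = s$x_star, status = s$status)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(sol))
  class(out) <- c("coop_sweep", class(out))
  attr(out, "base") <- base
  out
}
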