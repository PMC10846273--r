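#' Parameters of the privatization public-goods model
#'
#' Bundles the five constants of the resource-sharing fitness model for a
#' cooperator--cheater pair in a batch public-goods environment (the sucrose
#' system of budding yeast is the motivating case). Cooperators secrete an
#' enzyme that hydrolyses the environmental carbon source; a fraction
#' `alpha` of the released monosaccharides is retained (privatized) by the
#' producing cell and the rest enters a common pool shared by everyone.
#'
#' @param alpha Fraction of released resource retained by the producing cell,
#'   in \[0, 1\]. The ancestral strain retains about 1% of what it secretes,
#'   hence the default 0.01; evolved genotypes (e.g. with duplicated hexose
#'   transporters) are modelled by larger values.
#' @param r Amount of resource released per cooperating cell (resource
#'   units, same units as `Km`). Must be non-negative.
#' @param C Cost of cooperation (fitness units) paid by cooperators for
#'   producing the enzyme. Must be non-negative.
#' @param fmax Maximal fitness at saturating resource (fitness units).
#'   Must be positive. The model is reported in units where `fmax = 1`.
#' @param Km Resource amount at which fitness is half of `fmax` (resource
#'   units). Must be positive.
#'
#' @return An object of class `coop_params`: a validated named list with
#'   elements `alpha`, `r`, `C`, `fmax`, `Km`.
#'
#' @examples
#' coop_params(alpha = 0.2, r = 1, C = 0.1)
#'
#' @seealso [resource_shares()], [fitness()], [solve_coexistence()]
#' @export
coop_params <- function(alpha = 0.01, r = 1, C = 0.1, fmax = 1, Km = 1) {
  p <- list(alpha = as.numeric(alpha), r = as.numeric(r), C = as.numeric(C),
            fmax = as.numeric(fmax), Km = as.numeric(Km))
  validate_params(p)
  structure(p, class = "coop_params")
}

validate_params <- function(p) {
  for (nm in c("alpha", "r", "C", "fmax", "Km")) {
    v <- p[[nm]]
    if (length(v) != 1L || !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite number.", nm),
            class = "privcoop_domain_error")
    }
  }
  if (p$alpha < 0 || p$alpha > 1) {
    abort("`alpha` must lie in [0, 1].", class = "privcoop_domain_error")
  }
  if (p$r < 0) abort("`r` must be >= 0.", class = "privcoop_domain_error")
  if (p$C < 0) abort("`C` must be >= 0.", class = "privcoop_domain_error")
  if (p$fmax <= 0) abort("`fmax` must be > 0.", class = "privcoop_domain_error")
  if (p$Km <= 0) abort("`Km` must be > 0.", class = "privcoop_domain_error")
  invisible(p)
}

as_coop_params <- function(p) {
  if (inherits(p, "coop_params")) return(p)
  if (is.list(p) && all(c("alpha", "r", "C", "fmax", "Km") %in% names(p))) {
    return(coop_params(p$alpha, p$r, p$C, p$fmax, p$Km))
  }
  abort("`params` must be a `coop_params` object (see `coop_params()`).",
        class = "privcoop_domain_error")
}

validate_fraction <- function(x, what = "x") {
  if (length(x) == 0L || !is.numeric(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite numeric.", what),
          class = "privcoop_domain_error")
  }
  if (any(x < 0 | x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", what),
          class = "privcoop_domain_error")
  }
  invisible(x)
}

#' @export
print.coop_params <- function(x, ...) {
  cat("<coop_params>\n")
  cat(sprintf("  alpha (retained fraction): %g\n", x$alpha))
  cat(sprintf("  r     (release per cell) : %g\n", x$r))
  cat(sprintf("  C     (cooperation cost) : %g\n", x$C))
  cat(sprintf("  fmax  (max fitness)      : %g\n", x$fmax))
  cat(sprintf("  Km    (half-saturation)  : %g\n", x$Km))
  invisible(x)
}
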