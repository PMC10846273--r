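#' Simulate one colony-plating frequency assay
#'
#' Emulates the selective-plating readout of the experiment: a culture at
#' latent cooperator frequency `x_true` is plated to about `n_colonies`
#' colonies, which are replica-plated onto hygromycin; only cheater
#' colonies (resistance cassette in place of the invertase gene) grow, so
#' the resistant count is a `Binomial(n_colonies, 1 - x_true)` draw.
#'
#' The draw is deterministic given (`x_true`, `n_colonies`, `seed`); the
#' global RNG state is left untouched.
#'
#' @param x_true Latent cooperator frequency (vectorised), each in \[0, 1\].
#' @param n_colonies Colonies scored per assay (scalar or one per
#'   `x_true`), each `>= 1`. Default 200.
#' @param seed Integer seed for the draw.
#'
#' @return A tibble with columns `x_true`, `n_colonies`, `n_resistant`,
#'   `seed`.
#'
#' @examples
#' sample_assay(0.3, n_colonies = 200, seed = 42)
#' @export
sample_assay <- function(x_true, n_colonies = 200, seed) {
  validate_fraction(x_true, "x_true")
  if (any(!is.finite(n_colonies)) || any(n_colonies < 1)) {
    abort("`n_colonies` must be >= 1.", class = "privcoop_domain_error")
  }
  if (missing(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single integer.", class = "privcoop_domain_error")
  }
  n <- as.integer(rep_len(n_colonies, length(x_true)))
  k <- withr::with_seed(as.integer(seed),
                        rbinom(length(x_true), size = n, prob = 1 - x_true))
  tibble::tibble(
    x_true = as.numeric(x_true),
    n_colonies = n,
    n_resistant = as.integer(k),
    seed = as.integer(seed)
  )
}

#' Design of a synthetic coevolution experiment
#'
#' Describes a replicated serial-transfer coevolution experiment observed
#' through colony plating: `n_lines` replicate lines started at cooperator
#' frequency `x0`, propagated under `regime`, with the latent dynamics set
#' by `truth` and each assay scoring about `n_colonies` colonies. The
#' sucrose experiment uses six lines; the non-public-good sugar controls
#' (glucose, fructose, and their mixture, where neither strain pays a cost
#' or privatizes a public good) use three lines each with a neutral truth
#' (`alpha = 0`, `C = 0`).
#'
#' @param n_lines Number of replicate lines (>= 1).
#' @param regime A [transfer_regime()] object.
#' @param truth A [coop_params()] object driving the latent dynamics; use
#'   `coop_params(alpha = 0, C = 0)` for the neutral controls.
#' @param x0 Initial cooperator frequency. Default 0.5 (1:1 mix).
#' @param n_colonies Nominal colonies scored per assay. Default 200.
#' @param colony_model `"fixed"` (exactly `n_colonies` per assay, default)
#'   or `"poisson"` (Poisson-distributed about `n_colonies`, mimicking
#'   "~200 colonies" plating).
#' @param master_seed Integer master seed; per-line, per-assay child seeds
#'   are derived from it (see Details).
#'
#' @details Child seeds are derived as
#' `(master_seed * 10007 + line * 1009 + assay) mod 2147483647`, so any
#' single record can be regenerated in isolation with [sample_assay()].
#'
#' @return An object of class `coevolution_design` (a validated list).
#' @examples
#' coevolution_design(truth = coop_params(alpha = 0.2, C = 0.1),
#'                    master_seed = 1)
#' @export
coevolution_design <- function(n_lines = 6, regime = transfer_regime(),
                               truth = coop_params(), x0 = 0.5,
                               n_colonies = 200,
                               colony_model = c("fixed", "poisson"),
                               master_seed = 1L) {
  regime <- as_transfer_regime(regime)
  truth <- as_coop_params(truth)
  colony_model <- match.arg(colony_model)
  if (!is.numeric(n_lines) || length(n_lines) != 1L || n_lines < 1 ||
      n_lines != round(n_lines)) {
    abort("`n_lines` must be a positive whole number.",
          class = "privcoop_domain_error")
  }
  validate_fraction(x0, "x0")
  if (!is.numeric(n_colonies) || length(n_colonies) != 1L || n_colonies < 1) {
    abort("`n_colonies` must be >= 1.", class = "privcoop_domain_error")
  }
  if (length(master_seed) != 1L || !is.finite(master_seed)) {
    abort("`master_seed` must be a single integer.",
          class = "privcoop_domain_error")
  }
  structure(
    list(
      n_lines = as.integer(n_lines), regime = regime, truth = truth,
      x0 = as.numeric(x0), n_colonies = as.integer(n_colonies),
      colony_model = colony_model, master_seed = as.integer(master_seed)
    ),
    class = "coevolution_design"
  )
}

#' @export
print.coevolution_design <- function(x, ...) {
  cat("<coevolution_design>\n")
  cat(sprintf("  %d lines, x0 = %g, %s n = %d colonies/assay, master seed %d\n",
              x$n_lines, x$x0, x$colony_model, x$n_colonies, x$master_seed))
  print(x$regime)
  print(x$truth)
  invisible(x)
}

# child-seed splitting scheme: documented, collision-safe for the design
# sizes used here, and regenerable per (line, assay) in isolation
child_seed <- function(master_seed, line, assay) {
  as.integer((as.double(master_seed) * 10007 + line * 1009 + assay) %%
               2147483647)
}

#' Generate a synthetic coevolution dataset
#'
#' Runs the deterministic latent dynamics once under the design's `truth`
#' (all lines share it, so latent trajectories are identical across lines
#' and independent of every seed), then observes each line at generation 0
#' and every assay interval through seeded colony-plating draws
#' ([sample_assay()]). Stochasticity enters only through the observation
#' layer.
#'
#' @param design A [coevolution_design()] object.
#' @return A tibble of class `coop_dataset` in long format with columns
#'   `line_id`, `generation`, `x_true`, `n_colonies`, `n_resistant`,
#'   `seed`; `n_lines * n_assays` rows.
#'
#' @examples
#' d <- coevolution_design(truth = coop_params(alpha = 0.2, C = 0.1),
#'                         master_seed = 7)
#' generate_coevolution_dataset(d)
#' @export
generate_coevolution_dataset <- function(design) {
  if (!inherits(design, "coevolution_design")) {
    abort("`design` must be a `coevolution_design` object.",
          class = "privcoop_domain_error")
  }
  traj <- simulate_serial_transfers(design$truth, design$regime,
                                    x0 = design$x0)
  assays <- assay_generations(design$regime)
  latent <- traj$x[assays$transfer + 1L]

  out <- tidyr::expand_grid(line = seq_len(design$n_lines),
                            assay = assays$assay)
  out <- dplyr::mutate(
    out,
    generation = assays$generation[.data$assay + 1L],
    x_true = latent[.data$assay + 1L],
    seed = child_seed(design$master_seed, .data$line, .data$assay)
  )
  drawn <- purrr::pmap(
    out[c("x_true", "seed")],
    function(x_true, seed) {
      withr::with_seed(seed, {
        n <- if (design$colony_model == "poisson") {
          max(1L, rpois(1L, design$n_colonies))
        } else {
          design$n_colonies
        }
        k <- rbinom(1L, size = n, prob = 1 - x_true)
        c(n = n, k = k)
      })
    }
  )
  drawn <- do.call(rbind, drawn)
  out <- tibble::tibble(
    line_id = sprintf("line_%d", out$line),
    generation = out$generation,
    x_true = out$x_true,
    n_colonies = as.integer(drawn[, "n"]),
    n_resistant = as.integer(drawn[, "k"]),
    seed = out$seed
  )
  class(out) <- c("coop_dataset", class(out))
  attr(out, "design") <- design
  out
}

#' Simulate a single competition assay
#'
#' Emulates a one-batch head-to-head competition: two genotypes mixed at
#' cooperator frequency `x0` grow together for one batch (24 h, i.e. one
#' transfer's worth of generations), and the outcome is read by plating.
#' With a neutral parameter set (no privatization advantage, no cost) the
#' latent frequency is unchanged, the structure of the control
#' competitions in non-public-good sugars.
#'
#' @param params A [coop_params()] object for the competing pair.
#' @param x0 Starting cooperator frequency. Default 0.5.
#' @param duration_generations Batch length in generations; default
#'   `generations_per_transfer(100)` (a 24-h, 1:100-regime batch).
#' @param n_colonies Colonies scored. Default 200.
#' @param seed Integer seed for the plating draw.
#'
#' @return A one-row tibble with columns `x0`, `generation`, `x_true`,
#'   `n_colonies`, `n_resistant`, `seed`.
#' @examples
#' generate_competition_assay(coop_params(alpha = 0, C = 0), seed = 1)
#' @export
generate_competition_assay <- function(params, x0 = 0.5,
                                       duration_generations =
                                         generations_per_transfer(100),
                                       n_colonies = 200, seed) {
  params <- as_coop_params(params)
  validate_fraction(x0, "x0")
  x1 <- step_frequency(params, x0, duration_generations)
  obs <- sample_assay(x1, n_colonies = n_colonies, seed = seed)
  tibble::tibble(
    x0 = as.numeric(x0),
    generation = as.numeric(duration_generations),
    x_true = obs$x_true,
    n_colonies = obs$n_colonies,
    n_resistant = obs$n_resistant,
    seed = obs$seed
  )
}
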