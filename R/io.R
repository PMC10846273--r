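# all numeric TSV output goes through one formatter: 17 significant digits
# so a write/read round trip is bit-stable
fmt17 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

write_tsv_formatted <- function(df, path, numeric_cols) {
  out <- df
  for (nm in numeric_cols) out[[nm]] <- fmt17(df[[nm]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write / read a coexistence sweep as TSV
#'
#' One row per grid cell with columns `alpha`, `r`, `x_star`, `status`;
#' floats carry 17 significant digits so the round trip is bit-stable.
#'
#' @param sweep A sweep tibble from [sweep_alpha_r()].
#' @param path Output file path.
#' @return `path` (write) or the sweep tibble (read), invisibly for write.
#' @examples
#' sw <- sweep_alpha_r(coop_params(C = 0.1), c(0.1, 0.3), 1)
#' f <- tempfile(fileext = ".tsv")
#' write_sweep_tsv(sw, f)
#' read_sweep_tsv(f)
#' @export
write_sweep_tsv <- function(sweep, path) {
  stopifnot(all(c("alpha", "r", "x_star", "status") %in% names(sweep)))
  write_tsv_formatted(sweep[c("alpha", "r", "x_star", "status")], path,
                      c("alpha", "r", "x_star"))
}

#' @rdname write_sweep_tsv
#' @export
read_sweep_tsv <- function(path) {
  # base R parsing round-trips the 17-digit representation exactly
  tibble::as_tibble(utils::read.delim(path, colClasses = c(
    alpha = "numeric", r = "numeric", x_star = "numeric",
    status = "character"
  )))
}

#' Write / read a frequency trajectory as TSV
#'
#' Columns `transfer`, `generation`, `x`.
#'
#' @param trajectory A tibble from [simulate_serial_transfers()].
#' @param path Output file path.
#' @export
write_trajectory_tsv <- function(trajectory, path) {
  stopifnot(all(c("transfer", "generation", "x") %in% names(trajectory)))
  write_tsv_formatted(trajectory[c("transfer", "generation", "x")], path,
                      c("generation", "x"))
}

#' @rdname write_trajectory_tsv
#' @export
read_trajectory_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, colClasses = c(
    transfer = "integer", generation = "numeric", x = "numeric"
  )))
}

#' Write / read a synthetic assay dataset as TSV
#'
#' Long format with columns `line_id`, `generation`, `x_true`,
#' `n_colonies`, `n_resistant`, `seed`.
#'
#' @param records A tibble from [generate_coevolution_dataset()].
#' @param path Output file path.
#' @export
write_dataset_tsv <- function(records, path) {
  cols <- c("line_id", "generation", "x_true", "n_colonies", "n_resistant",
            "seed")
  stopifnot(all(cols %in% names(records)))
  write_tsv_formatted(records[cols], path, c("generation", "x_true"))
}

#' @rdname write_dataset_tsv
#' @export
read_dataset_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, colClasses = c(
    line_id = "character", generation = "numeric", x_true = "numeric",
    n_colonies = "integer", n_resistant = "integer", seed = "integer"
  )))
}

#' Serialize an experiment design to a flat key=value config file
#'
#' Flat `key=value` lines (one per scalar field) for diff-able provenance;
#' [read_design_config()] reconstructs the [coevolution_design()].
#'
#' @param design A [coevolution_design()] object.
#' @param path Output file path.
#' @examples
#' d <- coevolution_design(master_seed = 3)
#' f <- tempfile(fileext = ".cfg")
#' write_design_config(d, f)
#' read_design_config(f)
#' @export
write_design_config <- function(design, path) {
  stopifnot(inherits(design, "coevolution_design"))
  kv <- c(
    n_lines = design$n_lines,
    dilution_factor = fmt17(design$regime$dilution_factor),
    n_transfers = design$regime$n_transfers,
    assay_interval = fmt17(design$regime$assay_interval_generations),
    alpha = fmt17(design$truth$alpha),
    r = fmt17(design$truth$r),
    C = fmt17(design$truth$C),
    fmax = fmt17(design$truth$fmax),
    Km = fmt17(design$truth$Km),
    x0 = fmt17(design$x0),
    n_colonies = design$n_colonies,
    colony_model = design$colony_model,
    master_seed = design$master_seed
  )
  writeLines(paste0(names(kv), "=", kv), path)
  invisible(path)
}

#' @rdname write_design_config
#' @export
read_design_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- setNames(vapply(kv, function(p) paste(p[-1], collapse = "="),
                          character(1)),
                   vapply(kv, `[[`, character(1), 1L))
  num <- function(k) as.numeric(vals[[k]])
  coevolution_design(
    n_lines = num("n_lines"),
    regime = transfer_regime(num("dilution_factor"), num("n_transfers"),
                             num("assay_interval")),
    truth = coop_params(num("alpha"), num("r"), num("C"), num("fmax"),
                        num("Km")),
    x0 = num("x0"),
    n_colonies = num("n_colonies"),
    colony_model = vals[["colony_model"]],
    master_seed = num("master_seed")
  )
}
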