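#' Specify a synthetic initial-velocity dataset
#'
#' Velocities follow the Michaelis-Menten curve with multiplicative Gaussian
#' noise, `v = Vmax [S] / (Km + [S]) * (1 + eps)`, `eps ~ N(0, noise_cv)` —
#' the constant-CV error model typical of enzyme assays quantified by HPLC.
#'
#' @param Km_true Michaelis constant, mM.
#' @param Vmax_true maximal velocity, umol min^-1 mg^-1.
#' @param substrate_concs substrate concentrations, mM (all > 0).
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (>= 0; 0 gives data exactly on the curve).
#' @param replicates independent replicates per concentration.
#' @param seed integer seed.
#' @return a `kinetic_sim_spec` object.
#' @export
kinetic_sim_spec <- function(Km_true, Vmax_true, substrate_concs,
                             noise_cv = 0, replicates = 1L, seed = 1L) {
  check_number(Km_true, "Km_true", positive = TRUE)
  check_number(Vmax_true, "Vmax_true", positive = TRUE)
  if (!is.numeric(substrate_concs) || length(substrate_concs) == 0L)
    stop_invalid("substrate_concs", "must be a non-empty numeric vector")
  if (anyNA(substrate_concs) || any(substrate_concs <= 0))
    stop_invalid("substrate_concs", "all concentrations must be > 0")
  check_number(noise_cv, "noise_cv", nonneg = TRUE)
  check_number(replicates, "replicates", positive = TRUE, integerish = TRUE)
  check_number(seed, "seed", integerish = TRUE)
  structure(
    list(Km_true = Km_true, Vmax_true = Vmax_true,
         substrate_concs = as.numeric(substrate_concs),
         noise_cv = noise_cv, replicates = as.integer(replicates),
         seed = as.integer(seed)),
    class = "kinetic_sim_spec"
  )
}

#' Generate synthetic Michaelis-Menten initial-velocity data
#'
#' @param spec a [kinetic_sim_spec()].
#' @return a tibble with columns `substrate_mM`, `velocity_umol_min_mg` and
#'   `replicate`; the spec is attached as attribute `spec`.
#' @examples
#' d <- generate_kinetic_data(
#'   kinetic_sim_spec(36.174, 0.090, c(0.4, 2, 10, 50, 200)))
#' fit_lineweaver_burk(d)
#' @export
generate_kinetic_data <- function(spec) {
  if (!inherits(spec, "kinetic_sim_spec"))
    stop_invalid("spec", "must be a kinetic_sim_spec")
  withr::with_seed(spec$seed, {
    s <- rep(spec$substrate_concs, times = spec$replicates)
    rep_id <- rep(seq_len(spec$replicates),
                  each = length(spec$substrate_concs))
    v0 <- spec$Vmax_true * s / (spec$Km_true + s)
    eps <- if (spec$noise_cv > 0) rnorm(length(s), 0, spec$noise_cv) else 0
    out <- tibble(substrate_mM = s,
                  velocity_umol_min_mg = v0 * (1 + eps),
                  replicate = rep_id)
    attr(out, "spec") <- spec
    out
  })
}

#' Read / write initial-velocity CSV files
#'
#' The on-disk format is a plain CSV with header
#' `substrate_mM,velocity_umol_min_mg,replicate`.
#' @param data tibble as returned by [generate_kinetic_data()].
#' @param path file path.
#' @return `read_kinetic_csv()` returns the tibble; `write_kinetic_csv()`
#'   returns `path` invisibly.
#' @export
write_kinetic_csv <- function(data, path) {
  stopifnot(all(c("substrate_mM", "velocity_umol_min_mg", "replicate")
                %in% names(data)))
  utils::write.csv(
    data[, c("substrate_mM", "velocity_umol_min_mg", "replicate")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kinetic_csv
#' @export
read_kinetic_csv <- function(path) {
  if (!file.exists(path)) stop_parse(paste0("file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("substrate_mM", "velocity_umol_min_mg", "replicate")
  if (!all(need %in% names(df)))
    stop_parse(paste0("kinetics CSV must have columns ",
                      paste(need, collapse = ", ")))
  as_tibble(df)
}
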