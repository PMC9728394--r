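new_kinetic_fit <- function(regime, Km = NA_real_, Km_se = NA_real_,
                            Vmax = NA_real_, Vmax_se = NA_real_,
                            slope = NA_real_, slope_se = NA_real_,
                            kcat = NA_real_, kcat_over_Km = NA_real_,
                            MW = NA_real_, r_squared = NA_real_,
                            model = NULL, data = NULL, notes = character()) {
  structure(
    list(regime = regime, Km = Km, Km_se = Km_se, Vmax = Vmax,
         Vmax_se = Vmax_se, slope = slope, slope_se = slope_se,
         kcat = kcat, kcat_over_Km = kcat_over_Km, MW = MW,
         r_squared = r_squared, model = model, data = data, notes = notes),
    class = "kinetic_fit"
  )
}

check_kinetic_data <- function(data, min_conc = 3L, positive_v = TRUE) {
  need <- c("substrate_mM", "velocity_umol_min_mg")
  if (!all(need %in% names(data)))
    stop_invalid("data", paste0("needs columns ",
                                paste(need, collapse = ", ")))
  if (anyNA(data$substrate_mM) || any(data$substrate_mM <= 0))
    stop_invalid("substrate_mM", "all concentrations must be > 0")
  if (length(unique(data$substrate_mM)) < min_conc)
    stop_invalid("substrate_mM",
                 paste0("need >= ", min_conc, " distinct concentrations"))
  if (positive_v && (anyNA(data$velocity_umol_min_mg) ||
                     any(data$velocity_umol_min_mg <= 0)))
    stop_invalid("velocity_umol_min_mg", "all velocities must be > 0")
  invisible(data)
}

#' Lineweaver-Burk (double-reciprocal) Michaelis-Menten fit
#'
#' Ordinary least squares of `1/v` on `1/[S]` over the pooled data points.
#' `Vmax = 1/intercept`, `Km = slope/intercept`; standard errors follow by
#' the first-order delta method from the OLS coefficient covariance. A
#' nonpositive intercept means the data show no approach to saturation and
#' is a fit error.
#'
#' @param data tibble with `substrate_mM` (mM) and `velocity_umol_min_mg`
#'   (umol min^-1 mg^-1); >= 3 distinct concentrations, all velocities > 0.
#' @return a `kinetic_fit` with `regime = "saturation"`. See [derive_kcat()]
#'   to add `kcat` and `kcat/Km`.
#' @examples
#' d <- generate_kinetic_data(
#'   kinetic_sim_spec(36.174, 0.090, c(0.4, 2, 10, 50, 200)))
#' fit_lineweaver_burk(d)
#' @export
fit_lineweaver_burk <- function(data) {
  check_kinetic_data(data)
  inv_s <- 1 / data$substrate_mM
  inv_v <- 1 / data$velocity_umol_min_mg
  m <- lm(inv_v ~ inv_s)
  b0 <- unname(coef(m)[1])
  b1 <- unname(coef(m)[2])
  if (b0 <= 0)
    stop_fit("no saturation detectable (nonpositive double-reciprocal intercept)")
  vc <- suppressWarnings(vcov(m))   # zero-residual (noiseless) data are legal
  Vmax <- 1 / b0
  Km <- b1 / b0
  # delta method: grad(Vmax) = (-1/b0^2, 0); grad(Km) = (-b1/b0^2, 1/b0)
  gV <- c(-1 / b0^2, 0)
  gK <- c(-b1 / b0^2, 1 / b0)
  new_kinetic_fit(
    regime = "saturation",
    Km = Km, Km_se = sqrt(drop(t(gK) %*% vc %*% gK)),
    Vmax = Vmax, Vmax_se = sqrt(drop(t(gV) %*% vc %*% gV)),
    r_squared = suppressWarnings(summary(m)$r.squared),
    model = m, data = data,
    notes = "Lineweaver-Burk OLS of 1/v on 1/[S]; delta-method SEs"
  )
}

#' Nonlinear least-squares Michaelis-Menten fit
#'
#' Levenberg-Marquardt fit of `v = Vmax [S] / (Km + [S])`, initialised from
#' the Lineweaver-Burk estimates (falling back to `Vmax = max(v)`,
#' `Km = median([S])` when the double-reciprocal fit fails). The direct fit
#' avoids the reciprocal transform's noise amplification at low `[S]`.
#'
#' @inheritParams fit_lineweaver_burk
#' @return a `kinetic_fit` with `regime = "saturation"`.
#' @export
fit_mm_nonlinear <- function(data) {
  check_kinetic_data(data)
  fallback <- list(Vmax = max(data$velocity_umol_min_mg),
                   Km = median(data$substrate_mM))
  start <- tryCatch({
    lb <- fit_lineweaver_burk(data)
    list(Vmax = lb$Vmax, Km = lb$Km)
  }, error = function(e) fallback)
  # a noisy double-reciprocal fit can start outside the feasible region
  if (!all(is.finite(unlist(start))) || start$Vmax <= 0 || start$Km <= 0)
    start <- fallback
  do_fit <- function(st) minpack.lm::nlsLM(
    velocity_umol_min_mg ~ Vmax * substrate_mM / (Km + substrate_mM),
    data = data, start = st,
    lower = c(Vmax = 1e-12, Km = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  m <- tryCatch(do_fit(start), error = function(e) {
    # an extreme double-reciprocal start can sit in a flat/singular region
    tryCatch(do_fit(fallback),
             error = function(e2) stop_fit(paste0("nonlinear fit failed: ",
                                                  conditionMessage(e2))))
  })
  cf <- coef(m)
  se <- tryCatch(suppressWarnings(summary(m))$coefficients[, "Std. Error"],
                 error = function(e) c(Vmax = NA_real_, Km = NA_real_))
  v <- data$velocity_umol_min_mg
  r2 <- 1 - sum(residuals(m)^2) / sum((v - mean(v))^2)
  new_kinetic_fit(
    regime = "saturation",
    Km = unname(cf["Km"]), Km_se = unname(se["Km"]),
    Vmax = unname(cf["Vmax"]), Vmax_se = unname(se["Vmax"]),
    r_squared = r2, model = m, data = data,
    notes = "direct Michaelis-Menten fit (Levenberg-Marquardt)"
  )
}

#' Linear-regime catalytic-efficiency fit
#'
#' For substrates far below their Km the Michaelis-Menten curve is linear,
#' `v = (Vmax/Km) [S]`, and only the catalytic efficiency is identifiable.
#' Fits OLS of `v` on `[S]` through the origin (`v = 0` at `[S] = 0` is
#' mechanistically forced; set `intercept = TRUE` for a free-intercept
#' diagnostic variant). With replicated concentrations a pure-error
#' lack-of-fit test is run and a warning is raised when curvature is
#' detected (p < 0.05), signalling that the linear regime is not valid.
#'
#' @inheritParams fit_lineweaver_burk
#' @param MW optional enzyme molar mass (g/mol); converts the slope
#'   (umol min^-1 mg^-1 mM^-1) into `kcat/Km` (mM^-1 min^-1).
#' @param intercept fit a free intercept instead of through-origin.
#' @return a `kinetic_fit` with `regime = "linear"`; `Km` and `Vmax` are
#'   absent (NA), `slope` and (given `MW`) `kcat_over_Km` are set.
#' @export
fit_linear_regime <- function(data, MW = NULL, intercept = FALSE) {
  check_kinetic_data(data, min_conc = 2L, positive_v = FALSE)
  s <- data$substrate_mM
  v <- data$velocity_umol_min_mg
  m <- if (intercept) lm(v ~ s) else lm(v ~ 0 + s)
  cf <- suppressWarnings(summary(m))$coefficients
  slope <- cf["s", "Estimate"]
  slope_se <- cf["s", "Std. Error"]
  notes <- "through-origin OLS of v on [S]"
  if (length(unique(s)) < length(s)) {
    pure <- lm(v ~ 0 + factor(s))
    lof <- anova(m, pure)
    p_lof <- lof$`Pr(>F)`[2]
    if (!is.na(p_lof) && p_lof < 0.05) {
      warn(sprintf(
        "lack-of-fit test detects curvature (p = %.3g): data may not be in the linear regime",
        p_lof))
      notes <- c(notes, sprintf("lack-of-fit p = %.3g", p_lof))
    }
  }
  kok <- if (!is.null(MW)) slope * MW * 1e-3 else NA_real_
  new_kinetic_fit(
    regime = "linear", slope = slope, slope_se = slope_se,
    kcat_over_Km = kok, MW = MW %||% NA_real_,
    r_squared = suppressWarnings(summary(m)$r.squared), model = m, data = data,
    notes = notes
  )
}

#' Derive kcat and catalytic efficiency from a saturation fit
#'
#' `kcat = Vmax * MW * 1e-3` converts a specific maximal activity in
#' umol min^-1 mg^-1 into a turnover number in min^-1 (umol/mg x g/mol =
#' 1e-3 min^-1), and `kcat/Km` follows in mM^-1 min^-1. The enzyme molar
#' mass must be supplied by the caller.
#'
#' @param fit a saturation-regime `kinetic_fit` (with `Vmax` and `Km`).
#' @param MW enzyme molar mass, g/mol (> 0).
#' @return the fit, with `kcat`, `kcat_over_Km` and `MW` filled in.
#' @examples
#' kcat_over_km(6.574, 36.174)  # catalytic efficiency from printed pairs
#' @export
derive_kcat <- function(fit, MW) {
  stopifnot(inherits(fit, "kinetic_fit"))
  if (is.na(fit$Vmax))
    stop_fit("fit has no Vmax; use fit_linear_regime() for linear-regime data")
  if (missing(MW) || is.null(MW))
    stop_fit("supply the enzyme molar mass `MW` (g/mol) to derive kcat")
  check_number(MW, "MW", positive = TRUE)
  fit$MW <- MW
  fit$kcat <- fit$Vmax * MW * 1e-3
  fit$kcat_over_Km <- fit$kcat / fit$Km
  fit
}

#' Catalytic efficiency from a (kcat, Km) pair
#'
#' Plain ratio `kcat/Km` in mM^-1 min^-1, as tabulated in kinetics tables.
#' @param kcat turnover number, min^-1.
#' @param Km Michaelis constant, mM.
#' @export
kcat_over_km <- function(kcat, Km) {
  check_number(kcat, "kcat", positive = TRUE)
  check_number(Km, "Km", positive = TRUE)
  kcat / Km
}

#' Fold change of product yields with first-order error propagation
#'
#' Ratio of two product concentrations `a/b` with standard deviation
#' propagated to first order:
#' `sd = |a/b| * sqrt((sd_a/a)^2 + (sd_b/b)^2)`. The ratio is also reported
#' at 1-decimal rounding, the conventional precision for fold changes.
#'
#' @param a,b mean product yields (e.g. g/l); `b > 0`.
#' @param a_sd,b_sd standard deviations (default 0).
#' @return one-row tibble: `ratio`, `ratio_sd`, `ratio_1dp`.
#' @examples
#' fold_change(6.80, 4.76, 0.26, 0.02)
#' @export
fold_change <- function(a, b, a_sd = 0, b_sd = 0) {
  check_number(a, "a")
  check_number(b, "b")
  check_number(a_sd, "a_sd", nonneg = TRUE)
  check_number(b_sd, "b_sd", nonneg = TRUE)
  if (b == 0) stop_fit("denominator yield is zero")
  ratio <- a / b
  rsd <- abs(ratio) * sqrt((if (a != 0) (a_sd / a)^2 else 0) + (b_sd / b)^2)
  tibble(ratio = ratio, ratio_sd = rsd, ratio_1dp = round(ratio, 1))
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic_fit> regime:", x$regime, "\n")
  if (x$regime == "saturation") {
    cat(sprintf("  Km   = %.4g +/- %.3g mM\n", x$Km, x$Km_se))
    cat(sprintf("  Vmax = %.4g +/- %.3g umol/min/mg\n", x$Vmax, x$Vmax_se))
    if (!is.na(x$kcat))
      cat(sprintf("  kcat = %.4g min^-1, kcat/Km = %.4g mM^-1 min^-1\n",
                  x$kcat, x$kcat_over_Km))
  } else {
    cat(sprintf("  slope = %.4g +/- %.3g umol/min/mg/mM\n",
                x$slope, x$slope_se))
    if (!is.na(x$kcat_over_Km))
      cat(sprintf("  kcat/Km = %.4g mM^-1 min^-1\n", x$kcat_over_Km))
  }
  cat(sprintf("  R^2 = %.4f (n = %d)\n", x$r_squared, nrow(x$data)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.kinetic_fit <- function(x, ...) {
  if (x$regime == "saturation") {
    tibble(term = c("Km", "Vmax"),
           estimate = c(x$Km, x$Vmax),
           std.error = c(x$Km_se, x$Vmax_se),
           unit = c("mM", "umol/min/mg"))
  } else {
    tibble(term = "slope", estimate = x$slope, std.error = x$slope_se,
           unit = "umol/min/mg/mM")
  }
}

#' @exportS3Method generics::glance
glance.kinetic_fit <- function(x, ...) {
  tibble(regime = x$regime, Km = x$Km, Vmax = x$Vmax, kcat = x$kcat,
         kcat_over_Km = x$kcat_over_Km, r.squared = x$r_squared,
         nobs = nrow(x$data))
}
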