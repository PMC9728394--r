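# ggplot2 displays for the three result types. Smoothing here is a display
# device only; all statistics elsewhere use raw counts.

# separable Gaussian blur of a matrix (sd in bins), reflected edges
gaussian_smooth_matrix <- function(m, sd_bins = 1) {
  if (sd_bins <= 0) return(m)
  half <- max(1L, ceiling(3 * sd_bins))
  k <- stats::dnorm(seq(-half, half), sd = sd_bins)
  k <- k / sum(k)
  blur1 <- function(v) {
    n <- length(v)
    idx <- c(rev(seq_len(half)), seq_len(n), n + 1 - rev(seq_len(half)))
    padded <- v[pmax(1L, pmin(n, idx))]
    as.vector(stats::filter(padded, k, sides = 2))[half + seq_len(n)]
  }
  m2 <- apply(m, 2, blur1)
  t(apply(m2, 1, blur1))
}

#' Plot a conformation-difference map
#'
#' Tile map of the mutant-minus-wild-type density difference in the
#' (`d1`, `a1`) plane, with the reactive region outlined and the enrichment
#' count annotated above it. Optional Gaussian smoothing (in bin units)
#' affects the display only.
#'
#' @param object a `conformation_map`.
#' @param smooth_sd display smoothing sd in bins (0 = raw; default 1).
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.conformation_map <- function(object, smooth_sd = 1, ...) {
  td <- tidy(object)
  if (smooth_sd > 0) {
    nb_d <- length(object$d1_edges) - 1L
    nb_a <- length(object$a1_edges) - 1L
    sm <- gaussian_smooth_matrix(
      matrix(td$density_diff, nb_d, nb_a), smooth_sd)
    td$density_diff <- as.vector(sm)
  }
  cr <- object$criteria
  lim <- max(abs(td$density_diff))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$d1_mid, y = .data$a1_mid,
                                   fill = .data$density_diff)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", limits = c(-lim, lim)) +
    ggplot2::annotate("rect", xmin = 0, xmax = cr$d1_max,
                      ymin = cr$a1_min, ymax = cr$a1_max,
                      fill = NA, colour = "grey30", linewidth = 0.6) +
    ggplot2::annotate("text", x = cr$d1_max / 2, y = cr$a1_max + 6,
                      label = sprintf("%+d", object$enrichment_count),
                      size = 4) +
    ggplot2::labs(x = "d1 (Å)", y = "a1 (°)",
                  fill = "Δ density",
                  title = "Mutant - WT conformational density") +
    ggplot2::theme_minimal()
}

#' Plot a replica-averaged RMSF profile
#'
#' Mean per-residue RMSF with the t confidence band as a shaded ribbon; pass
#' a second profile via `compare` to overlay two variants.
#'
#' @param object an `rmsf_profile`.
#' @param compare optional second `rmsf_profile` to overlay.
#' @param labels length-2 labels used when `compare` is given.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.rmsf_profile <- function(object, compare = NULL,
                                  labels = c("WT", "mutant"), ...) {
  d <- tidy(object)
  d$variant <- labels[1]
  if (!is.null(compare)) {
    d2 <- tidy(compare)
    d2$variant <- labels[2]
    d <- bind_rows(d, d2)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$residue, y = .data$mean_rmsf,
                                  colour = .data$variant,
                                  fill = .data$variant)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_rmsf - .data$ci_halfwidth,
      ymax = .data$mean_rmsf + .data$ci_halfwidth),
      alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "RMSF (Å)",
                  colour = NULL, fill = NULL,
                  title = sprintf("Replica-mean RMSF with %d%% CI band",
                                  round(object$conf_level * 100))) +
    ggplot2::theme_minimal()
}

#' Plot a kinetic fit
#'
#' Saturation fits are drawn as the Michaelis-Menten curve over the data (or
#' as the double-reciprocal plot with `type = "lineweaver_burk"`); linear
#' fits as the through-origin line.
#'
#' @param object a `kinetic_fit`.
#' @param type `"mm"` (velocity vs substrate) or `"lineweaver_burk"`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.kinetic_fit <- function(object, type = c("mm", "lineweaver_burk"),
                                 ...) {
  type <- match.arg(type)
  d <- object$data
  if (type == "lineweaver_burk" && object$regime == "saturation") {
    d$inv_s <- 1 / d$substrate_mM
    d$inv_v <- 1 / d$velocity_umol_min_mg
    return(
      ggplot2::ggplot(d, ggplot2::aes(x = .data$inv_s, y = .data$inv_v)) +
        ggplot2::geom_point() +
        ggplot2::geom_abline(intercept = 1 / object$Vmax,
                             slope = object$Km / object$Vmax,
                             colour = "steelblue") +
        ggplot2::labs(x = "1/[S] (mM⁻¹)",
                      y = "1/v (mg·min·µmol⁻¹)",
                      title = "Lineweaver-Burk plot") +
        ggplot2::theme_minimal())
  }
  grid <- tibble(substrate_mM = seq(0, max(d$substrate_mM), length.out = 200))
  grid$velocity_umol_min_mg <- if (object$regime == "saturation") {
    object$Vmax * grid$substrate_mM / (object$Km + grid$substrate_mM)
  } else {
    object$slope * grid$substrate_mM
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$substrate_mM,
                                  y = .data$velocity_umol_min_mg)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "[S] (mM)", y = "v (µmol·min⁻¹·mg⁻¹)",
                  title = sprintf("Michaelis-Menten fit (%s regime)",
                                  object$regime)) +
    ggplot2::theme_minimal()
}
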