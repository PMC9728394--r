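#' Ensemble-construction bookkeeping
#'
#' Describes how a docking ensemble is assembled from replica MD
#' trajectories: frames are taken every `stride_ps` over `sim_length_ps`,
#' optionally including the t = 0 frame, for each replica.
#'
#' @param n_replicas number of independent replicas (>= 1).
#' @param sim_length_ps simulated length per replica, ps.
#' @param stride_ps sampling interval, ps; must divide `sim_length_ps`.
#' @param include_t0 include the frame at t = 0 (default TRUE).
#' @return an `ensemble_definition`.
#' @examples
#' # 5 replicas x 5 ns at 50 ps, with t = 0: the 505-member ensemble
#' ensemble_size(ensemble_definition(5, 5000, 50))
#' @export
ensemble_definition <- function(n_replicas, sim_length_ps, stride_ps,
                                include_t0 = TRUE) {
  check_number(n_replicas, "n_replicas", positive = TRUE, integerish = TRUE)
  check_number(sim_length_ps, "sim_length_ps", positive = TRUE)
  check_number(stride_ps, "stride_ps", positive = TRUE)
  ratio <- sim_length_ps / stride_ps
  if (abs(ratio - round(ratio)) > 1e-9)
    stop_invalid("stride_ps", "must divide sim_length_ps")
  if (!is.logical(include_t0) || length(include_t0) != 1L ||
      is.na(include_t0))
    stop_invalid("include_t0", "must be TRUE or FALSE")
  structure(list(n_replicas = as.integer(n_replicas),
                 sim_length_ps = sim_length_ps, stride_ps = stride_ps,
                 include_t0 = include_t0),
            class = "ensemble_definition")
}

#' @rdname ensemble_definition
#' @param defn an `ensemble_definition`.
#' @return `ensemble_size()` returns the integer number of conformations,
#'   `n_replicas * (sim_length_ps / stride_ps + include_t0)`.
#' @export
ensemble_size <- function(defn) {
  if (!inherits(defn, "ensemble_definition"))
    stop_invalid("defn", "must be an ensemble_definition")
  as.integer(defn$n_replicas *
               (round(defn$sim_length_ps / defn$stride_ps) +
                  as.integer(defn$include_t0)))
}

# half-open [lo, hi) bins, last bin closed; edges are extended in whole bins
# when data exceed the nominal range so binning stays exhaustive
bin_edges <- function(values, lo, hi, width) {
  top <- hi
  mx <- suppressWarnings(max(values, na.rm = TRUE))
  if (is.finite(mx) && mx >= top) top <- lo + width * ceiling((mx - lo) / width + 1e-12)
  mn <- suppressWarnings(min(values, na.rm = TRUE))
  bot <- lo
  if (is.finite(mn) && mn < bot) bot <- lo - width * ceiling((bot - mn) / width)
  seq(bot, top, by = width)
}

bin_index <- function(values, edges) {
  idx <- findInterval(values, edges, rightmost.closed = TRUE,
                      left.open = FALSE)
  if (any(idx < 1L | idx >= length(edges)))
    stop_analysis("binning not exhaustive: value outside edge range")
  idx
}

#' Build a 2D (d1, a1) conformation-difference map
#'
#' Bins the per-pose geometries of two variants in the
#' (distance `d1`, angle `a1`) plane after the `d2 < d2_max` prefilter, and
#' forms the difference of the two unit-mass densities (mutant minus
#' wild type). The enrichment count is the raw difference in the number of
#' reactive poses (all three criteria) between mutant and wild type.
#'
#' @param geometries_wt,geometries_mut per-pose geometry tibbles from
#'   [classify_poses()] (need columns `d1`, `d2`, `a1`, `reactive`).
#' @param criteria a [reactive_criteria()]; defines both the `d2` prefilter
#'   and the reactive region drawn on the map.
#' @param d1_bin,a1_bin bin widths (angstrom / degrees). Defaults 0.25 A and
#'   5 degrees resolve the 4-angstrom / 80-140 degree reactive box exactly on
#'   bin edges.
#' @param d1_range,a1_range nominal axis ranges; extended in whole bins when
#'   data fall outside.
#' @return a `conformation_map`: list with `d1_edges`, `a1_edges`,
#'   `counts_wt`, `counts_mut` (integer matrices, d1 x a1),
#'   `density_diff` (mutant - WT, each normalised to unit mass),
#'   `enrichment_count`, `n_wt`, `n_mut` (post-filter sizes) and `criteria`.
#' @export
build_conformation_map <- function(geometries_wt, geometries_mut,
                                   criteria = reactive_criteria(),
                                   d1_bin = 0.25, a1_bin = 5,
                                   d1_range = c(0, 15),
                                   a1_range = c(0, 180)) {
  pref <- function(g, label) {
    keep <- if (criteria$strict) g$d2 < criteria$d2_max
            else g$d2 <= criteria$d2_max
    keep[is.na(keep)] <- FALSE
    out <- g[keep, , drop = FALSE]
    if (nrow(out) == 0L)
      stop_analysis(paste0("no ", label, " poses left after d2 < ",
                           criteria$d2_max, " A prefilter"))
    out
  }
  wt <- pref(geometries_wt, "wild-type")
  mut <- pref(geometries_mut, "mutant")

  d1_edges <- bin_edges(c(wt$d1, mut$d1), d1_range[1], d1_range[2], d1_bin)
  a1_edges <- bin_edges(c(wt$a1, mut$a1), a1_range[1], a1_range[2], a1_bin)
  nb_d <- length(d1_edges) - 1L
  nb_a <- length(a1_edges) - 1L
  bin2d <- function(g) {
    i <- bin_index(g$d1, d1_edges)
    j <- bin_index(g$a1, a1_edges)
    m <- matrix(0L, nb_d, nb_a)
    tab <- table(factor(i, levels = seq_len(nb_d)),
                 factor(j, levels = seq_len(nb_a)))
    m + as.integer(tab)
  }
  counts_wt <- matrix(bin2d(wt), nb_d, nb_a)
  counts_mut <- matrix(bin2d(mut), nb_d, nb_a)
  density_diff <- counts_mut / sum(counts_mut) - counts_wt / sum(counts_wt)
  enrichment <- sum(mut$reactive) - sum(wt$reactive)
  structure(
    list(d1_edges = d1_edges, a1_edges = a1_edges,
         counts_wt = counts_wt, counts_mut = counts_mut,
         density_diff = density_diff,
         enrichment_count = as.integer(enrichment),
         n_wt = nrow(wt), n_mut = nrow(mut), criteria = criteria),
    class = "conformation_map"
  )
}

#' @export
print.conformation_map <- function(x, ...) {
  cat("<conformation_map> ", x$n_wt, " WT / ", x$n_mut,
      " mutant poses after d2 prefilter; enrichment (mut - WT reactive): ",
      x$enrichment_count, "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.conformation_map <- function(x, ...) {
  nb_d <- length(x$d1_edges) - 1L
  nb_a <- length(x$a1_edges) - 1L
  tibble(
    d1_mid = rep((x$d1_edges[-1] + x$d1_edges[-(nb_d + 1L)]) / 2, nb_a),
    a1_mid = rep((x$a1_edges[-1] + x$a1_edges[-(nb_a + 1L)]) / 2,
                 each = nb_d),
    count_wt = as.vector(x$counts_wt),
    count_mut = as.vector(x$counts_mut),
    density_diff = as.vector(x$density_diff)
  )
}

#' Per-ligand reactive-population summary across variants
#'
#' For each acceptor ligand, counts reactive poses per variant, reports the
#' reactive fractions and their mutant-minus-wild-type difference, and runs a
#' two-proportion test (an inferential layer added on top of the raw counts,
#' not part of the original screening). A `consistent_direction` attribute
#' flags whether the difference has the same sign for every ligand.
#'
#' @param geometries tibble of per-pose geometries with columns `ligand`,
#'   `variant` (values `"wt"` and `"mut"`) and `reactive`, e.g. row-bound
#'   [classify_poses()] outputs.
#' @param conf_level confidence level for the two-proportion test.
#' @return tibble with one row per ligand: counts, fractions, difference,
#'   p-value and direction; attribute `consistent_direction` is TRUE when all
#'   per-ligand differences share a sign.
#' @export
reactive_population_summary <- function(geometries, conf_level = 0.95) {
  if (nrow(geometries) == 0L) {
    out <- tibble(ligand = character(), n_wt = integer(), n_mut = integer(),
                  reactive_wt = integer(), reactive_mut = integer(),
                  fraction_wt = double(), fraction_mut = double(),
                  difference = double(), p_value = double(),
                  direction = character())
    attr(out, "consistent_direction") <- NA
    return(out)
  }
  need <- c("ligand", "variant", "reactive")
  if (!all(need %in% names(geometries)))
    stop_invalid("geometries", paste0("needs columns ",
                                      paste(need, collapse = ", ")))
  smry <- geometries |>
    group_by(.data$ligand, .data$variant) |>
    summarise(n = n(), reactive = sum(.data$reactive), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "variant",
                       values_from = c("n", "reactive"))
  out <- smry |>
    mutate(fraction_wt = .data$reactive_wt / .data$n_wt,
           fraction_mut = .data$reactive_mut / .data$n_mut,
           difference = .data$fraction_mut - .data$fraction_wt)
  out$p_value <- vapply(seq_len(nrow(out)), function(i) {
    x <- c(out$reactive_mut[i], out$reactive_wt[i])
    n <- c(out$n_mut[i], out$n_wt[i])
    if (out$fraction_mut[i] == out$fraction_wt[i]) return(1.0)
    suppressWarnings(
      prop.test(x, n, correct = FALSE, conf.level = conf_level)$p.value)
  }, numeric(1))
  out$direction <- ifelse(out$difference > 0, "mut>wt",
                          ifelse(out$difference < 0, "mut<wt", "equal"))
  attr(out, "consistent_direction") <-
    length(unique(sign(out$difference))) == 1L
  out
}
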