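#' Atom selectors and the catalytic-site map
#'
#' An atom selector identifies exactly one atom in a structure by residue
#' number and atom name (optionally chain). The catalytic-site map names the
#' four receptor atoms that define the glucosyl-transfer geometry: the
#' anomeric carbon of the covalent glucosyl-aspartate intermediate (the
#' electrophile), the aspartate ester oxygen (the leaving group), and the two
#' carboxylate oxygens of the catalytic-base glutamate.
#'
#' @param residue_number integer residue number.
#' @param atom_name atom name string (e.g. `"OE1"`).
#' @param chain optional chain identifier; `NULL` matches any chain.
#' @return `atom_selector()` returns an `atom_selector`;
#'   `catalytic_site_map()` a `catalytic_site_map`.
#' @export
atom_selector <- function(residue_number, atom_name, chain = NULL) {
  check_number(residue_number, "residue_number", integerish = TRUE)
  if (!is.character(atom_name) || length(atom_name) != 1L)
    stop_invalid("atom_name", "must be a single string")
  structure(list(residue_number = as.integer(residue_number),
                 atom_name = atom_name, chain = chain),
            class = "atom_selector")
}

#' @rdname atom_selector
#' @param anomeric_carbon,leaving_oxygen [atom_selector()]s for the glucosyl
#'   anomeric carbon and the aspartate ester (leaving) oxygen.
#' @param carboxylate_oxygens list of exactly two [atom_selector()]s for the
#'   catalytic-base carboxylate oxygens.
#' @export
catalytic_site_map <- function(anomeric_carbon, leaving_oxygen,
                               carboxylate_oxygens) {
  for (s in c(list(anomeric_carbon, leaving_oxygen), carboxylate_oxygens))
    if (!inherits(s, "atom_selector"))
      stop_invalid("site", "all site entries must be atom_selector objects")
  if (length(carboxylate_oxygens) != 2L)
    stop_invalid("carboxylate_oxygens", "exactly two selectors required")
  structure(list(anomeric_carbon = anomeric_carbon,
                 leaving_oxygen = leaving_oxygen,
                 carboxylate_oxygens = carboxylate_oxygens),
            class = "catalytic_site_map")
}

#' Reactive-conformation criteria
#'
#' A docked acceptor pose is a reactive (near-attack) conformation when its
#' attacking hydroxyl satisfies `d1 < 4` angstrom (hydroxyl O to anomeric C),
#' `d2 < 4` angstrom (hydroxyl O to nearest catalytic-base carboxylate O) and
#' `80 < a1 < 140` degrees (attack angle at the anomeric carbon). These
#' thresholds are the screening defaults; inequalities are strict unless
#' `strict = FALSE`.
#'
#' @param d1_max,d2_max distance thresholds, angstrom (> 0).
#' @param a1_min,a1_max angle window, degrees (`0 <= a1_min < a1_max <= 180`).
#' @param strict use strict inequalities (default) or non-strict.
#' @return a `reactive_criteria` object.
#' @export
reactive_criteria <- function(d1_max = 4, d2_max = 4, a1_min = 80,
                              a1_max = 140, strict = TRUE) {
  check_number(d1_max, "d1_max", positive = TRUE)
  check_number(d2_max, "d2_max", positive = TRUE)
  check_number(a1_min, "a1_min", nonneg = TRUE)
  check_number(a1_max, "a1_max", positive = TRUE)
  if (!(a1_min < a1_max) || a1_max > 180)
    stop_invalid("a1_min/a1_max", "need 0 <= a1_min < a1_max <= 180")
  if (!is.logical(strict) || length(strict) != 1L || is.na(strict))
    stop_invalid("strict", "must be TRUE or FALSE")
  structure(list(d1_max = d1_max, d2_max = d2_max, a1_min = a1_min,
                 a1_max = a1_max, strict = strict),
            class = "reactive_criteria")
}

# resolve one selector in (possibly multi-model) receptor atoms; returns a
# tibble with one row per model and columns model, x, y, z
resolve_selector <- function(atoms, sel, what = "selector") {
  hit <- atoms[atoms$residue_number == sel$residue_number &
                 atoms$name == sel$atom_name, , drop = FALSE]
  if (!is.null(sel$chain)) hit <- hit[hit$chain == sel$chain, , drop = FALSE]
  if (!"model" %in% names(hit)) hit$model <- 1L
  per <- table(hit$model)
  if (nrow(hit) == 0L)
    stop_analysis(paste0("site map: ", what, " (residue ",
                         sel$residue_number, ", atom ", sel$atom_name,
                         ") matches no atom"))
  if (any(per != 1L))
    stop_analysis(paste0("site map: ", what, " (residue ",
                         sel$residue_number, ", atom ", sel$atom_name,
                         ") is ambiguous (", max(per), " matches in a model)"))
  hit[, c("model", "x", "y", "z")]
}

# O-H covalent cutoff for hydroxyl detection; O-C covalent cutoff for the
# hydrogen-free heavy-neighbor rule
OH_CUTOFF <- 1.2
HEAVY_CUTOFF <- 1.8

#' Find hydroxyl oxygens in ligand poses
#'
#' Oxygens are classified as hydroxyl either by a bonded hydrogen (O-H
#' distance < 1.2 angstrom) when the pose carries hydrogens, or — for
#' hydrogen-free poses — by having exactly one heavy covalent neighbour,
#' a carbon within 1.8 angstrom (an ether or carboxylate oxygen has two
#' neighbours or a non-carbon partner).
#'
#' @param atoms ligand atom tibble; a `model` column groups poses (absent:
#'   one pose).
#' @return tibble with one row per hydroxyl oxygen: `model`, `serial`,
#'   `name`, `x`, `y`, `z`. Empty (with a warning) when the ligand has no
#'   oxygen.
#' @export
find_hydroxyl_oxygens <- function(atoms) {
  if (!"model" %in% names(atoms)) atoms$model <- 1L
  ox <- atoms[toupper(atoms$element) == "O", , drop = FALSE]
  if (nrow(ox) == 0L) {
    warn("ligand contains no oxygen atoms")
    return(tibble(model = integer(), serial = integer(), name = character(),
                  x = double(), y = double(), z = double()))
  }
  hy <- atoms[toupper(atoms$element) == "H", , drop = FALSE]
  sel_cols <- c("model", "serial", "name", "x", "y", "z")

  has_h <- unique(hy$model)
  out <- list()

  ox_h <- ox[ox$model %in% has_h, , drop = FALSE]
  if (nrow(ox_h) > 0L) {
    pairs <- inner_join(
      ox_h[, sel_cols],
      hy[, c("model", "x", "y", "z")] |>
        rename(hx = "x", hy = "y", hz = "z"),
      by = "model", relationship = "many-to-many")
    pairs$d <- sqrt((pairs$x - pairs$hx)^2 + (pairs$y - pairs$hy)^2 +
                      (pairs$z - pairs$hz)^2)
    keep <- pairs |>
      group_by(.data$model, .data$serial) |>
      summarise(bonded = any(.data$d < OH_CUTOFF), .groups = "drop") |>
      filter(.data$bonded)
    out$withH <- inner_join(ox_h[, sel_cols], keep[, c("model", "serial")],
                            by = c("model", "serial"))
  }

  ox_noh <- ox[!(ox$model %in% has_h), , drop = FALSE]
  if (nrow(ox_noh) > 0L) {
    heavy <- atoms[!(toupper(atoms$element) %in% "H") &
                     !(atoms$model %in% has_h), , drop = FALSE]
    pairs <- inner_join(
      ox_noh[, sel_cols],
      heavy[, c("model", "serial", "element", "x", "y", "z")] |>
        rename(nserial = "serial", nelement = "element",
               nx = "x", ny = "y", nz = "z"),
      by = "model", relationship = "many-to-many") |>
      filter(.data$serial != .data$nserial)
    pairs$d <- sqrt((pairs$x - pairs$nx)^2 + (pairs$y - pairs$ny)^2 +
                      (pairs$z - pairs$nz)^2)
    keep <- pairs |>
      filter(.data$d < HEAVY_CUTOFF) |>
      group_by(.data$model, .data$serial) |>
      summarise(n_nb = n(),
                all_c = all(toupper(.data$nelement) == "C"),
                .groups = "drop") |>
      filter(.data$n_nb == 1L, .data$all_c)
    out$noH <- inner_join(ox_noh[, sel_cols], keep[, c("model", "serial")],
                          by = c("model", "serial"))
  }

  res <- bind_rows(out)
  arrange(res, .data$model, .data$serial)
}

# site coordinates per pose model: receptor may be single-model (used for all
# poses) or multi-model (matched to pose model index, the ensemble-docking
# case where each pose was docked into its own receptor frame)
site_coords <- function(receptor, site, models) {
  anch <- list(
    c1 = resolve_selector(receptor, site$anomeric_carbon, "anomeric carbon"),
    lo = resolve_selector(receptor, site$leaving_oxygen, "leaving oxygen"),
    e1 = resolve_selector(receptor, site$carboxylate_oxygens[[1]],
                          "carboxylate oxygen 1"),
    e2 = resolve_selector(receptor, site$carboxylate_oxygens[[2]],
                          "carboxylate oxygen 2"))
  anch <- lapply(anch, function(t) arrange(t, .data$model))
  multi <- nrow(anch$c1) > 1L
  tab <- tibble(model = anch$c1$model,
                c1x = anch$c1$x, c1y = anch$c1$y, c1z = anch$c1$z,
                lox = anch$lo$x, loy = anch$lo$y, loz = anch$lo$z,
                e1x = anch$e1$x, e1y = anch$e1$y, e1z = anch$e1$z,
                e2x = anch$e2$x, e2y = anch$e2$y, e2z = anch$e2$z)
  if (!multi) {
    tab <- tab[rep(1L, length(models)), ]
    tab$model <- models
  } else if (!all(models %in% tab$model)) {
    stop_analysis("multi-model receptor does not cover all pose models")
  }
  tab
}

geometry_features <- function(hydroxyls, sites) {
  g <- inner_join(hydroxyls, sites, by = "model")
  o <- cbind(g$x, g$y, g$z)
  c1 <- cbind(g$c1x, g$c1y, g$c1z)
  lo <- cbind(g$lox, g$loy, g$loz)
  e1 <- cbind(g$e1x, g$e1y, g$e1z)
  e2 <- cbind(g$e2x, g$e2y, g$e2z)
  g$d1 <- unname(row_norm(o - c1))
  g$d2 <- unname(pmin(row_norm(o - e1), row_norm(o - e2)))
  g$a1 <- unname(angle_deg(o, c1, lo))
  g[, c("model", "serial", "name", "d1", "d2", "a1")]
}

#' Compute the reaction-geometry features for one hydroxyl in one pose
#'
#' `d1` is the distance from the hydroxyl oxygen to the anomeric carbon;
#' `d2` the minimum distance from the hydroxyl oxygen to either catalytic
#' carboxylate oxygen; `a1` the angle at the anomeric carbon subtended by the
#' hydroxyl oxygen and the leaving-group oxygen (an in-line-attack proxy).
#'
#' @param pose ligand atom tibble for one pose (single model).
#' @param receptor receptor atom tibble (see [read_pdb()]).
#' @param site a [catalytic_site_map()].
#' @param hydroxyl an [atom_selector()] (residue/atom name) or an atom serial
#'   number identifying the hydroxyl oxygen within the pose.
#' @param criteria a [reactive_criteria()].
#' @return one-row tibble: `pose_id`, `hydroxyl_serial`, `hydroxyl_name`,
#'   `d1`, `d2`, `a1` (angstrom / degrees), `reactive`.
#' @export
compute_geometry <- function(pose, receptor, site, hydroxyl,
                             criteria = reactive_criteria()) {
  if (!"model" %in% names(pose)) pose$model <- 1L
  if (length(unique(pose$model)) != 1L)
    stop_invalid("pose", "must contain a single model")
  if (inherits(hydroxyl, "atom_selector")) {
    hit <- pose[pose$residue_number == hydroxyl$residue_number &
                  pose$name == hydroxyl$atom_name, , drop = FALSE]
  } else {
    hit <- pose[pose$serial == hydroxyl, , drop = FALSE]
  }
  if (nrow(hit) != 1L)
    stop_analysis(paste0("hydroxyl selector matches ", nrow(hit),
                         " atoms (need exactly 1)"))
  hx <- hit[, c("model", "serial", "name", "x", "y", "z")]
  sites <- site_coords(receptor, site, unique(pose$model))
  feat <- geometry_features(hx, sites)
  feat$reactive <- triple_reactive(feat$d1, feat$d2, feat$a1, criteria)
  tibble(pose_id = feat$model, hydroxyl_serial = feat$serial,
         hydroxyl_name = feat$name, d1 = feat$d1, d2 = feat$d2,
         a1 = feat$a1, reactive = feat$reactive)
}

#' Classify poses as reactive conformations
#'
#' Evaluates the `(d1, d2, a1)` features for every hydroxyl oxygen of every
#' pose and calls a pose reactive if ANY hydroxyl satisfies all criteria
#' (any transfer-competent hydroxyl enables glucosylation). The reported
#' features are those of the representative hydroxyl: the criteria-satisfying
#' one with smallest `d1` when the pose is reactive, otherwise the smallest
#' `d1` overall; ties break on smaller `d2`, then atom serial. Poses with no
#' hydroxyl get `reactive = FALSE` and `NA` features.
#'
#' @param poses ligand atom tibble across poses (`model` column = pose index),
#'   e.g. from [read_pdbqt_poses()] or a [generate_pose_ensemble()]'s
#'   `$atoms`.
#' @param receptor receptor atom tibble; either a single structure or a
#'   multi-model ensemble matched to pose models.
#' @param site a [catalytic_site_map()]; default matches the synthetic
#'   receptor.
#' @param criteria a [reactive_criteria()].
#' @return tibble with one row per pose: `pose_id`, `hydroxyl_serial`,
#'   `hydroxyl_name`, `d1`, `d2`, `a1`, `reactive`, `n_hydroxyls`.
#' @examples
#' ens <- generate_pose_ensemble(pose_ensemble_spec(25, seed = 7))
#' classify_poses(ens$atoms, ens$receptor, ens$site)
#' @export
classify_poses <- function(poses, receptor, site = default_site_map(),
                           criteria = reactive_criteria()) {
  if (!"model" %in% names(poses)) poses$model <- 1L
  models <- sort(unique(poses$model))
  hydroxyls <- suppressWarnings(find_hydroxyl_oxygens(poses))
  base <- tibble(pose_id = models)
  if (nrow(hydroxyls) == 0L) {
    warn("no hydroxyl oxygens found in any pose")
    return(mutate(base, hydroxyl_serial = NA_integer_,
                  hydroxyl_name = NA_character_, d1 = NA_real_,
                  d2 = NA_real_, a1 = NA_real_, reactive = FALSE,
                  n_hydroxyls = 0L))
  }
  sites <- site_coords(receptor, site, models)
  feat <- geometry_features(hydroxyls, sites)
  feat$reactive <- triple_reactive(feat$d1, feat$d2, feat$a1, criteria)
  nhy <- feat |> count(.data$model, name = "n_hydroxyls")
  rep_row <- feat |>
    arrange(.data$model, !.data$reactive, .data$d1, .data$d2, .data$serial) |>
    distinct(.data$model, .keep_all = TRUE)
  res <- base |>
    left_join(rep_row, by = c(pose_id = "model")) |>
    left_join(nhy, by = c(pose_id = "model")) |>
    mutate(reactive = !is.na(.data$reactive) & .data$reactive,
           n_hydroxyls = ifelse(is.na(.data$n_hydroxyls), 0L,
                                .data$n_hydroxyls)) |>
    rename(hydroxyl_serial = "serial", hydroxyl_name = "name")
  res
}

#' @rdname classify_poses
#' @param pose single-pose atom tibble.
#' @export
classify_pose <- function(pose, receptor, site = default_site_map(),
                          criteria = reactive_criteria()) {
  if (!"model" %in% names(pose)) pose$model <- 1L
  if (length(unique(pose$model)) != 1L)
    stop_invalid("pose", "must contain a single model")
  classify_poses(pose, receptor, site, criteria)
}
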