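#' Specify a synthetic docking pose ensemble
#'
#' Describes an ensemble of docked acceptor poses around a glucosyl-enzyme
#' intermediate, with the three reaction-geometry features drawn from
#' configurable normal distributions: `d1` (hydroxyl O to anomeric C distance,
#' in angstrom), `d2` (hydroxyl O to nearest catalytic-base carboxylate O,
#' angstrom) and `a1` (attack angle at the anomeric carbon between the
#' incoming hydroxyl O and the leaving-group O, degrees). The realized triple
#' is recorded per pose as exact ground truth, which is what makes the
#' generator usable as an oracle for the screening code.
#'
#' @param n_conformations number of poses to generate.
#' @param ligand_name short identifier for the acceptor ligand.
#' @param n_hydroxyls number of hydroxyl groups on the ligand. The first is
#'   the "designated" hydroxyl placed at the sampled geometry; any extras sit
#'   far (>= 25 angstrom) from the catalytic site so they never out-compete it.
#' @param d1_dist,d2_dist length-2 numeric `(mean, sd)` in angstrom; sd may be
#'   0 for degenerate cases. Nonpositive draws are resampled.
#' @param a1_dist length-2 numeric `(mean, sd)` in degrees; draws outside
#'   `[0, 180]` are resampled (not clamped) to preserve distribution shape.
#' @param fraction_reactive_target optional proportion in `[0, 1]`. When set,
#'   each pose is first assigned a reactive/non-reactive label with this
#'   probability and its geometry is rejection-sampled from the spec
#'   distributions conditional on the label (under the default
#'   [reactive_criteria()]).
#' @param seed integer seed; identical specs give bit-identical ensembles.
#' @return a `pose_ensemble_spec` object.
#' @seealso [generate_pose_ensemble()]
#' @export
pose_ensemble_spec <- function(n_conformations,
                               ligand_name = "LIG",
                               n_hydroxyls = 1,
                               d1_dist = c(4.0, 1.0),
                               d2_dist = c(3.5, 1.0),
                               a1_dist = c(110, 25),
                               fraction_reactive_target = NULL,
                               seed = 1L) {
  check_number(n_conformations, "n_conformations", positive = TRUE,
               integerish = TRUE)
  if (!is.character(ligand_name) || length(ligand_name) != 1L ||
      !nzchar(ligand_name))
    stop_invalid("ligand_name", "must be a non-empty string")
  check_number(n_hydroxyls, "n_hydroxyls", positive = TRUE, integerish = TRUE)
  for (nm in c("d1_dist", "d2_dist", "a1_dist")) {
    v <- get(nm)
    check_number(v, nm, len = 2L)
    if (v[2] < 0) stop_invalid(nm, "sd must be >= 0")
  }
  if (!is.null(fraction_reactive_target)) {
    check_number(fraction_reactive_target, "fraction_reactive_target")
    if (fraction_reactive_target < 0 || fraction_reactive_target > 1)
      stop_invalid("fraction_reactive_target", "must be in [0, 1]")
  }
  check_number(seed, "seed", integerish = TRUE)
  structure(
    list(n_conformations = as.integer(n_conformations),
         ligand_name = ligand_name,
         n_hydroxyls = as.integer(n_hydroxyls),
         d1_dist = as.numeric(d1_dist),
         d2_dist = as.numeric(d2_dist),
         a1_dist = as.numeric(a1_dist),
         fraction_reactive_target = fraction_reactive_target,
         seed = as.integer(seed)),
    class = "pose_ensemble_spec"
  )
}

# sample n values from N(mean, sd) with a per-value acceptance predicate;
# rejected values are redrawn (never clamped)
sample_trunc <- function(n, dist, ok, max_rounds = 10000L, field = "dist") {
  out <- rnorm(n, dist[1], dist[2])
  bad <- which(!ok(out))
  rounds <- 0L
  while (length(bad) > 0L) {
    rounds <- rounds + 1L
    if (rounds > max_rounds)
      stop_invalid(field, "distribution cannot satisfy its support constraint")
    out[bad] <- rnorm(length(bad), dist[1], dist[2])
    bad <- bad[!ok(out[bad])]
  }
  out
}

triple_reactive <- function(d1, d2, a1, criteria) {
  if (criteria$strict) {
    d1 < criteria$d1_max & d2 < criteria$d2_max &
      a1 > criteria$a1_min & a1 < criteria$a1_max
  } else {
    d1 <= criteria$d1_max & d2 <= criteria$d2_max &
      a1 >= criteria$a1_min & a1 <= criteria$a1_max
  }
}

# draw n (d1, d2, a1) triples from the spec distributions, optionally
# conditioned on a target reactive/non-reactive label per pose
sample_geometry_triples <- function(spec, criteria) {
  n <- spec$n_conformations
  draw <- function(k) {
    list(
      d1 = sample_trunc(k, spec$d1_dist, function(x) x > 0, field = "d1_dist"),
      d2 = sample_trunc(k, spec$d2_dist, function(x) x > 0, field = "d2_dist"),
      a1 = sample_trunc(k, spec$a1_dist, function(x) x >= 0 & x <= 180,
                        field = "a1_dist")
    )
  }
  g <- draw(n)
  if (is.null(spec$fraction_reactive_target)) return(g)

  target <- runif(n) < spec$fraction_reactive_target
  pending <- which(triple_reactive(g$d1, g$d2, g$a1, criteria) != target)
  rounds <- 0L
  while (length(pending) > 0L) {
    rounds <- rounds + 1L
    if (rounds > 10000L)
      stop_invalid("fraction_reactive_target",
                   paste("geometry distributions cannot realize the requested",
                         "reactive fraction"))
    fresh <- draw(length(pending))
    hit <- triple_reactive(fresh$d1, fresh$d2, fresh$a1, criteria) ==
      target[pending]
    idx <- pending[hit]
    g$d1[idx] <- fresh$d1[hit]
    g$d2[idx] <- fresh$d2[hit]
    g$a1[idx] <- fresh$a1[hit]
    pending <- pending[!hit]
  }
  g
}

#' Generate a synthetic pose ensemble with exact geometric ground truth
#'
#' Builds, for each pose, a catalytic-site frame and a small acceptor ligand
#' whose designated hydroxyl oxygen realizes the sampled `(d1, d2, a1)`
#' exactly: the anomeric carbon sits at the origin, the aspartate leaving
#' oxygen on the +y axis at bond distance, the hydroxyl oxygen at distance
#' `d1` and angle `a1` (random azimuth), and the catalytic-base carboxylate
#' oxygens along the outward ray at distance `d2` (nearest) from the hydroxyl
#' oxygen. Because each docking pose comes from its own receptor conformation,
#' the site atoms are emitted as a multi-model receptor, one model per pose.
#'
#' @param spec a [pose_ensemble_spec()].
#' @return a `pose_ensemble`: list with elements `atoms` (ligand atom tibble
#'   across models), `receptor` (multi-model site-atom tibble), `site` (the
#'   matching [catalytic_site_map()]), `truth` (per-pose tibble of realized
#'   `d1`, `d2`, `a1` and the reactive verdict under default criteria) and
#'   `spec`.
#' @examples
#' ens <- generate_pose_ensemble(pose_ensemble_spec(10, seed = 42))
#' ens$truth
#' @export
generate_pose_ensemble <- function(spec) {
  if (!inherits(spec, "pose_ensemble_spec"))
    stop_invalid("spec", "must be a pose_ensemble_spec")
  criteria <- reactive_criteria()
  withr::with_seed(spec$seed, {
    n <- spec$n_conformations
    g <- sample_geometry_triples(spec, criteria)
    phi <- runif(n, 0, 2 * pi)
    score <- round(-runif(n, 4, 9), 1)

    arad <- g$a1 * pi / 180
    # hydroxyl O: distance d1 from origin, angle a1 to the +y (leaving-O) axis
    o1 <- cbind(g$d1 * sin(arad) * cos(phi),
                g$d1 * cos(arad),
                g$d1 * sin(arad) * sin(phi))
    u <- unit_rows(o1)                      # outward ray from anomeric C
    # tangent t perpendicular to u (for placing H and the ipso carbon)
    ey <- matrix(rep(c(0, 1, 0), each = n), ncol = 3)
    tv <- cbind(u[, 2] * ey[, 3] - u[, 3] * ey[, 2],
                u[, 3] * ey[, 1] - u[, 1] * ey[, 3],
                u[, 1] * ey[, 2] - u[, 2] * ey[, 1])
    degen <- row_norm(tv) < 1e-8            # u parallel to y: use x instead
    if (any(degen)) tv[degen, ] <- matrix(c(1, 0, 0), sum(degen), 3,
                                          byrow = TRUE)
    tv <- unit_rows(tv)

    oe1 <- o1 + g$d2 * u
    oe2 <- oe1 + 2.2 * u                    # strictly farther: min dist = d2
    c2 <- o1 + 1.36 * unit_rows(0.5 * u + 0.866 * tv)
    h1 <- o1 + 0.97 * tv

    resn <- toupper(substr(spec$ligand_name, 1, 3))
    # per-pose atom template: designated hydroxyl triplet, then a far-away
    # O-H-C triplet per extra hydroxyl (fixed coordinates, shared by poses)
    nh_extra <- spec$n_hydroxyls - 1L
    tmpl_serial <- c(1:3, if (nh_extra > 0L) 3L + seq_len(3L * nh_extra))
    tmpl_name <- c("O1", "H1", "C2",
                   if (nh_extra > 0L) as.vector(vapply(seq_len(nh_extra),
                     function(j) paste0(c("O", "H", "C"),
                                        c(j + 1L, j + 1L, j + 2L)),
                     character(3))))
    tmpl_elem <- c("O", "H", "C", rep(c("O", "H", "C"), nh_extra))
    extra_xyz <- NULL
    if (nh_extra > 0L) {
      extra_xyz <- do.call(rbind, lapply(seq_len(nh_extra), function(j) {
        th <- 2 * pi * j / 8
        dir <- c(cos(th), 0.2, sin(th))
        dir <- dir / sqrt(sum(dir^2))
        perp <- c(-sin(th), 0, cos(th))
        ox <- (25 + 1.5 * j) * dir
        rbind(ox, ox + 0.97 * perp, ox + 1.36 * dir)
      }))
    }
    na_pose <- length(tmpl_serial)
    # interleave per-pose coordinates: rows ordered model-major
    per_pose <- function(m) rbind(o1[m, ], h1[m, ], c2[m, ], extra_xyz)
    xyz_all <- do.call(rbind, lapply(seq_len(n), per_pose))
    atoms <- tibble(
      model = rep(seq_len(n), each = na_pose),
      serial = rep(tmpl_serial, n),
      name = rep(tmpl_name, n),
      element = rep(tmpl_elem, n),
      residue_name = resn, residue_number = 1L, insert = "", chain = "L",
      x = xyz_all[, 1], y = xyz_all[, 2], z = xyz_all[, 3],
      occupancy = 1.0, bfactor = 0.0,
      score = rep(score, each = na_pose)
    )

    rec_xyz <- do.call(rbind, lapply(seq_len(n), function(m)
      rbind(c(0, 0, 0), c(0, 1.43, 0), c(0, 2.76, 0), oe1[m, ], oe2[m, ])))
    receptor <- tibble(
      model = rep(seq_len(n), each = 5L),
      serial = rep(1:5, n),
      name = rep(c("C1", "OD1", "CG", "OE1", "OE2"), n),
      element = rep(c("C", "O", "C", "O", "O"), n),
      residue_name = rep(c("GLC", "ASP", "ASP", "GLU", "GLU"), n),
      residue_number = rep(c(501L, 284L, 284L, 326L, 326L), n),
      insert = "", chain = "A",
      x = rec_xyz[, 1], y = rec_xyz[, 2], z = rec_xyz[, 3],
      occupancy = 1.0, bfactor = 0.0
    )

    truth <- tibble(
      model = seq_len(n),
      hydroxyl_serial = 1L,
      hydroxyl_name = "O1",
      d1 = g$d1, d2 = g$d2, a1 = g$a1,
      reactive = triple_reactive(g$d1, g$d2, g$a1, criteria),
      score = score
    )

    structure(
      list(atoms = atoms, receptor = receptor,
           site = default_site_map(), truth = truth, spec = spec),
      class = "pose_ensemble"
    )
  })
}

#' Default catalytic-site map matching the synthetic receptor
#'
#' Selectors follow the amylosucrase numbering: the glucosyl anomeric carbon
#' of the covalent glucosyl-Asp284 intermediate, the Asp284 ester (leaving)
#' oxygen, and the two carboxylate oxygens of the catalytic base Glu326.
#' @return a [catalytic_site_map()].
#' @export
default_site_map <- function() {
  catalytic_site_map(
    anomeric_carbon = atom_selector(501, "C1"),
    leaving_oxygen = atom_selector(284, "OD1"),
    carboxylate_oxygens = list(atom_selector(326, "OE1"),
                               atom_selector(326, "OE2"))
  )
}

#' @export
print.pose_ensemble <- function(x, ...) {
  cat("<pose_ensemble> ", x$spec$ligand_name, ": ",
      x$spec$n_conformations, " poses, ",
      x$spec$n_hydroxyls, " hydroxyl(s), ",
      sum(x$truth$reactive), " reactive (ground truth)\n", sep = "")
  invisible(x)
}
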