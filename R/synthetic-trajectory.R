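#' Specify synthetic replica trajectories
#'
#' Each replica is a set of frames in which residue coordinates fluctuate
#' independently about a fixed reference (an extended C-alpha trace at 3.8
#' angstrom spacing) with per-residue Gaussian displacements. This emulates
#' the stationary fluctuation regime of an equilibrated MD run — the part
#' RMSF analysis assumes — without any actual dynamics.
#'
#' @param n_residues number of residues (one C-alpha-like atom each).
#' @param n_frames frames per replica (>= 1).
#' @param per_residue_sigma per-axis fluctuation scale in angstrom: a scalar,
#'   a length-`n_residues` vector (isotropic per residue), or an
#'   `n_residues x 3` matrix for anisotropic fluctuation.
#' @param n_replicas number of independent replicas.
#' @param stride_ps time between saved frames, picoseconds.
#' @param seed integer seed; identical specs give bit-identical trajectories.
#' @return a `trajectory_spec` object.
#' @export
trajectory_spec <- function(n_residues, n_frames, per_residue_sigma = 0.5,
                            n_replicas = 1L, stride_ps = 50, seed = 1L) {
  check_number(n_residues, "n_residues", positive = TRUE, integerish = TRUE)
  check_number(n_frames, "n_frames", positive = TRUE, integerish = TRUE)
  check_number(n_replicas, "n_replicas", positive = TRUE, integerish = TRUE)
  check_number(stride_ps, "stride_ps", positive = TRUE)
  check_number(seed, "seed", integerish = TRUE)
  sig <- per_residue_sigma
  if (is.matrix(sig)) {
    if (nrow(sig) != n_residues || ncol(sig) != 3L)
      stop_invalid("per_residue_sigma", "matrix must be n_residues x 3")
  } else {
    if (!is.numeric(sig) || !(length(sig) %in% c(1L, n_residues)))
      stop_invalid("per_residue_sigma",
                   "must be length 1 or n_residues (or an n x 3 matrix)")
    sig <- matrix(rep(sig, length.out = n_residues), n_residues, 3)
  }
  if (anyNA(sig) || any(sig < 0))
    stop_invalid("per_residue_sigma", "must be >= 0 elementwise")
  structure(
    list(n_residues = as.integer(n_residues),
         n_frames = as.integer(n_frames),
         sigma = sig,
         n_replicas = as.integer(n_replicas),
         stride_ps = as.numeric(stride_ps),
         seed = as.integer(seed)),
    class = "trajectory_spec"
  )
}

new_trajectory <- function(replica_id, atoms, times, coords) {
  structure(
    list(replica_id = replica_id, atoms = atoms, times = times,
         coords = coords),
    class = "trajectory"
  )
}

#' Generate synthetic replica trajectories
#'
#' @param spec a [trajectory_spec()].
#' @return a list of `trajectory` objects (length `n_replicas`), each holding
#'   an atom roster tibble, strictly increasing frame times (ps) and an
#'   `n_atoms x 3 x n_frames` coordinate array. The reference structure and
#'   sigma matrix are attached as attributes `reference` and `sigma` (ground
#'   truth).
#' @examples
#' trajs <- generate_trajectory(trajectory_spec(5, 100, 0.5, n_replicas = 2))
#' compute_rmsf(trajs[[1]])
#' @export
generate_trajectory <- function(spec) {
  if (!inherits(spec, "trajectory_spec"))
    stop_invalid("spec", "must be a trajectory_spec")
  nr <- spec$n_residues
  nf <- spec$n_frames
  reference <- cbind((seq_len(nr) - 1) * 3.8, 0, 0)
  atoms <- tibble(residue = seq_len(nr), atom = "CA", element = "C")
  times <- (seq_len(nf) - 1) * spec$stride_ps
  withr::with_seed(spec$seed, {
    lapply(seq_len(spec$n_replicas), function(r) {
      disp <- array(rnorm(nr * 3 * nf), dim = c(nr, 3, nf)) *
        array(spec$sigma, dim = c(nr, 3, nf))
      coords <- array(rep(reference, nf), dim = c(nr, 3, nf)) + disp
      tr <- new_trajectory(paste0("rep", r), atoms, times, coords)
      attr(tr, "reference") <- reference
      attr(tr, "sigma") <- spec$sigma
      tr
    })
  })
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", x$replica_id, ": ", dim(x$coords)[3], " frames, ",
      nrow(x$atoms), " atoms, t = ", x$times[1], "..",
      x$times[length(x$times)], " ps\n", sep = "")
  invisible(x)
}

#' Coerce a trajectory to a long tibble
#'
#' One row per atom per frame, with columns `replica`, `frame`, `time_ps`,
#' `residue`, `atom`, `x`, `y`, `z`.
#' @param x a `trajectory`.
#' @param ... unused.
#' @exportS3Method tibble::as_tibble
as_tibble.trajectory <- function(x, ...) {
  nf <- dim(x$coords)[3]
  na <- nrow(x$atoms)
  tibble(
    replica = x$replica_id,
    frame = rep(seq_len(nf), each = na),
    time_ps = rep(x$times, each = na),
    residue = rep(x$atoms$residue, nf),
    atom = rep(x$atoms$atom, nf),
    x = as.vector(x$coords[, 1, ]),
    y = as.vector(x$coords[, 2, ]),
    z = as.vector(x$coords[, 3, ])
  )
}
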