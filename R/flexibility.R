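# Least-squares (Kabsch) superposition: rotation + translation of `mobile`
# minimizing RMSD to `fixed` (both n x 3). Returns the transformed mobile.
kabsch_superpose <- function(mobile, fixed) {
  cm <- colMeans(mobile)
  cf <- colMeans(fixed)
  p <- sweep(mobile, 2, cm)
  q <- sweep(fixed, 2, cf)
  s <- svd(crossprod(p, q))            # t(P) %*% Q = U D V'
  d <- sign(det(s$u) * det(s$v))
  r <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sweep(p %*% r, 2, cf, "+")
}

select_atom_idx <- function(traj, selection) {
  idx <- if (is.null(selection)) seq_len(nrow(traj$atoms))
         else which(traj$atoms$atom %in% selection)
  if (length(idx) == 0L) stop_analysis("atom selection matches no atoms")
  idx
}

#' Per-residue RMSF of one replica trajectory
#'
#' Each frame is least-squares superposed onto the reference over the
#' selected atoms (removing rigid-body motion), then
#' `RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2)` about the post-superposition
#' mean position. With `superpose = FALSE` frames are used as stored, which
#' is appropriate when the input has no net rigid motion (e.g. the synthetic
#' generator, whose fluctuations are about a fixed reference).
#'
#' @param traj a `trajectory` (from [generate_trajectory()] or
#'   [read_trajectory()]).
#' @param selection atom names to analyse (`NULL` = all atoms; the
#'   conventional per-residue choice is one C-alpha-like atom per residue,
#'   which is all the synthetic roster contains).
#' @param reference `"first"` (default), `"mean"`, or an `n_sel x 3` matrix.
#' @param superpose remove rigid-body motion frame by frame (default TRUE).
#' @return tibble with one row per selected atom: `residue`, `atom`, `rmsf`
#'   (angstrom), plus a `replica` column.
#' @export
compute_rmsf <- function(traj, selection = NULL, reference = "first",
                         superpose = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- dim(traj$coords)[3]
  if (nf < 2L) stop_analysis("RMSF needs at least 2 frames")
  idx <- select_atom_idx(traj, selection)
  xyz <- traj$coords[idx, , , drop = FALSE]
  if (superpose) {
    ref <- reference_coords(xyz, reference)
    for (k in seq_len(nf)) xyz[, , k] <- kabsch_superpose(xyz[, , k], ref)
  }
  mean_pos <- apply(xyz, c(1, 2), mean)
  dev2 <- (xyz - array(mean_pos, dim = dim(xyz)))^2
  rmsf <- sqrt(rowMeans(dev2[, 1, , drop = FALSE] +
                          dev2[, 2, , drop = FALSE] +
                          dev2[, 3, , drop = FALSE], dims = 1))
  tibble(replica = traj$replica_id,
         residue = traj$atoms$residue[idx],
         atom = traj$atoms$atom[idx],
         rmsf = as.vector(rmsf))
}

reference_coords <- function(xyz, reference) {
  if (is.matrix(reference)) {
    if (!all(dim(reference) == dim(xyz)[1:2]))
      stop_invalid("reference", "matrix must be n_selected x 3")
    return(reference)
  }
  if (identical(reference, "first")) return(xyz[, , 1])
  if (identical(reference, "mean")) return(apply(xyz, c(1, 2), mean))
  stop_invalid("reference", "must be \"first\", \"mean\" or a matrix")
}

#' Replica-averaged RMSF profile with 95% t confidence band
#'
#' Averages per-residue RMSF over independent replicas and attaches the
#' two-sided t confidence half-width at `df = n_replicas - 1`, the shaded
#' band conventionally drawn around replica-mean RMSF curves.
#'
#' @param profiles per-replica RMSF values: a long tibble with columns
#'   `replica`, `residue`, `rmsf` (e.g. row-bound [compute_rmsf()] outputs)
#'   or a list of such tibbles.
#' @param conf_level confidence level (default 0.95).
#' @return an `rmsf_profile`: list with `residue_ids`, `per_replica`
#'   (replica x residue matrix), `mean_rmsf`, `ci_halfwidth`, `n_replicas`,
#'   `conf_level`. Use [tidy()] for a per-residue tibble.
#' @export
aggregate_replicas <- function(profiles, conf_level = 0.95) {
  if (is.list(profiles) && !is.data.frame(profiles))
    profiles <- bind_rows(profiles)
  need <- c("replica", "residue", "rmsf")
  if (!all(need %in% names(profiles)))
    stop_invalid("profiles", paste0("needs columns ",
                                    paste(need, collapse = ", ")))
  wide <- tidyr::pivot_wider(profiles[, need], names_from = "residue",
                             values_from = "rmsf")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  if (anyNA(mat))
    stop_analysis("replicas do not share a common residue roster")
  n <- nrow(mat)
  if (n < 2L) stop_analysis("need at least 2 replicas to form an interval")
  m <- colMeans(mat)
  s <- apply(mat, 2, sd)
  hw <- qt(1 - (1 - conf_level) / 2, df = n - 1) * s / sqrt(n)
  structure(
    list(residue_ids = as.integer(colnames(wide)[-1]),
         per_replica = mat, mean_rmsf = unname(m),
         ci_halfwidth = unname(hw), n_replicas = n,
         conf_level = conf_level),
    class = "rmsf_profile"
  )
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat("<rmsf_profile> ", length(x$residue_ids), " residues, ",
      x$n_replicas, " replicas; mean RMSF ",
      sprintf("%.3f", mean(x$mean_rmsf)), " A\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rmsf_profile <- function(x, ...) {
  tibble(residue = x$residue_ids, mean_rmsf = x$mean_rmsf,
         ci_halfwidth = x$ci_halfwidth)
}

#' Per-residue flexibility comparison between variants
#'
#' Welch two-sample t-test on the per-replica RMSF values of each residue
#' (the variants need not have equal replica counts). No multiple-testing
#' correction is applied by default — per-residue significance is reported as
#' is — but any [stats::p.adjust()] method can be requested.
#'
#' @param wt,mut `rmsf_profile` objects over the same residue roster.
#' @param alpha significance level for the mask (default 0.05).
#' @param p_adjust p-adjustment method (default `"none"`; e.g. `"BH"`).
#' @return tibble with one row per residue: `residue`, `mean_wt`, `mean_mut`,
#'   `difference` (mut - WT, angstrom), `p_value`, `significant`.
#' @export
compare_flexibility <- function(wt, mut, alpha = 0.05, p_adjust = "none") {
  stopifnot(inherits(wt, "rmsf_profile"), inherits(mut, "rmsf_profile"))
  if (!identical(wt$residue_ids, mut$residue_ids))
    stop_analysis("variants do not share a residue roster")
  check_number(alpha, "alpha", nonneg = TRUE)
  p <- vapply(seq_along(wt$residue_ids), function(i) {
    a <- wt$per_replica[, i]
    b <- mut$per_replica[, i]
    if (sd(a) == 0 && sd(b) == 0)
      return(if (mean(a) == mean(b)) 1.0 else 0.0)
    t.test(b, a, var.equal = FALSE)$p.value
  }, numeric(1))
  p <- stats::p.adjust(p, method = p_adjust)
  tibble(residue = wt$residue_ids,
         mean_wt = wt$mean_rmsf, mean_mut = mut$mean_rmsf,
         difference = mut$mean_rmsf - wt$mean_rmsf,
         p_value = p,
         significant = p < alpha)
}

#' Per-frame RMSD trace against a reference structure
#'
#' @param traj a `trajectory`.
#' @param reference `"first"` (default) or an `n_sel x 3` matrix.
#' @param selection atom names (`NULL` = all).
#' @param superpose least-squares superpose each frame before measuring
#'   (default TRUE).
#' @return tibble: `frame`, `time_ps`, `rmsd` (angstrom).
#' @export
compute_rmsd_trace <- function(traj, reference = "first", selection = NULL,
                               superpose = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  idx <- select_atom_idx(traj, selection)
  xyz <- traj$coords[idx, , , drop = FALSE]
  nf <- dim(xyz)[3]
  ref <- if (is.matrix(reference)) reference_coords(xyz, reference)
         else xyz[, , 1]
  rmsd <- vapply(seq_len(nf), function(k) {
    fr <- xyz[, , k]
    if (superpose) fr <- kabsch_superpose(fr, ref)
    sqrt(mean(rowSums((fr - ref)^2)))
  }, numeric(1))
  tibble(frame = seq_len(nf), time_ps = traj$times, rmsd = rmsd)
}
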