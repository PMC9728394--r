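# Multi-frame XYZ: repeating blocks of
#   <n_atoms>
#   <comment>            (the writer stores "frame <i> t= <ps> ps")
#   <label> <x> <y> <z>  (n_atoms lines)
# The atom roster must be identical in every frame.

#' Read a multi-frame trajectory file
#'
#' @param path path to a multi-frame XYZ file or a multi-model PDB.
#' @param format `"xyz"` or `"pdb"`; guessed from the extension by default.
#' @param stride_ps frame spacing in picoseconds, used when the file carries
#'   no time metadata (XYZ comment `t= <ps>`); default 50 ps.
#' @param replica_id identifier attached to the returned trajectory.
#' @return a `trajectory` object (atom roster tibble, frame times in ps, and
#'   an `n_atoms x 3 x n_frames` coordinate array).
#' @export
read_trajectory <- function(path, format = c("auto", "xyz", "pdb"),
                            stride_ps = 50, replica_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("pdb", "ent")) "pdb" else "xyz"
  }
  replica_id <- replica_id %||% tools::file_path_sans_ext(basename(path))
  if (format == "xyz") read_xyz_trajectory(path, stride_ps, replica_id)
  else pdb_to_trajectory(read_pdb(path), stride_ps, replica_id)
}

read_xyz_trajectory <- function(path, stride_ps = 50, replica_id = "traj") {
  if (!file.exists(path)) stop_parse(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  frames <- list()
  labels0 <- NULL
  times <- numeric(0)
  fidx <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    fidx <- fidx + 1L
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(na) || na <= 0L)
      stop_parse(paste0("bad atom count in frame ", fidx), line = i)
    if (i + 1L + na > length(lines))
      stop_parse(paste0("frame ", fidx, " truncated"), line = i)
    comment <- lines[i + 1L]
    tm <- regmatches(comment, regexec("t=\\s*([0-9.eE+-]+)", comment))[[1]]
    times[fidx] <- if (length(tm) == 2L) as.numeric(tm[2])
                   else (fidx - 1L) * stride_ps
    block <- lines[(i + 2L):(i + 1L + na)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(parts, length, 1L) < 4L)
    if (length(bad) > 0L)
      stop_parse(paste0("malformed coordinate line in frame ", fidx),
                 line = i + 1L + bad[1])
    labels <- vapply(parts, `[[`, "", 1L)
    xyz <- t(vapply(parts, function(p) {
      v <- suppressWarnings(as.numeric(p[2:4]))
      if (anyNA(v)) stop_parse(paste0("malformed coordinate in frame ", fidx))
      v
    }, numeric(3)))
    if (is.null(labels0)) {
      labels0 <- labels
    } else if (length(labels) != length(labels0) ||
               !all(labels == labels0)) {
      stop_parse(paste0("atom roster mismatch at frame ", fidx))
    }
    frames[[fidx]] <- xyz
    i <- i + 2L + na
  }
  if (fidx == 0L) stop_parse(paste0("no frames in ", path))
  coords <- array(unlist(frames), dim = c(length(labels0), 3, fidx))
  atoms <- tibble(residue = seq_along(labels0), atom = labels0,
                  element = labels0)
  new_trajectory(replica_id, atoms, times, coords)
}

pdb_to_trajectory <- function(atoms, stride_ps = 50, replica_id = "traj") {
  models <- sort(unique(atoms$model))
  counts <- vapply(models, function(m) sum(atoms$model == m), 1L)
  if (length(unique(counts)) != 1L)
    stop_parse(paste0("atom roster mismatch at frame ",
                      which(counts != counts[1])[1]))
  first <- atoms[atoms$model == models[1], ]
  coords <- array(NA_real_, dim = c(counts[1], 3, length(models)))
  for (k in seq_along(models)) {
    sub <- atoms[atoms$model == models[k], ]
    coords[, , k] <- cbind(sub$x, sub$y, sub$z)
  }
  roster <- tibble(residue = first$residue_number, atom = first$name,
                   element = first$element)
  new_trajectory(replica_id, roster, (seq_along(models) - 1) * stride_ps,
                 coords)
}

#' Write a trajectory as a multi-frame XYZ file
#'
#' @param traj a `trajectory`.
#' @param path output path.
#' @param digits coordinate precision (decimal places).
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path, digits = 6) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- dim(traj$coords)[3]
  na <- nrow(traj$atoms)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("%-4s %", digits + 8, ".", digits, "f %",
                digits + 8, ".", digits, "f %", digits + 8, ".", digits, "f")
  for (k in seq_len(nf)) {
    writeLines(as.character(na), con)
    writeLines(sprintf("frame %d t= %.3f ps", k, traj$times[k]), con)
    writeLines(sprintf(fmt, traj$atoms$element,
                       traj$coords[, 1, k], traj$coords[, 2, k],
                       traj$coords[, 3, k]), con)
  }
  invisible(path)
}
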