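# Independent brute-force oracles, deliberately written with plain loops and
# no shared code with the package internals.

dist3 <- function(p, q) sqrt(sum((p - q)^2))

angle3 <- function(a, b, c) {
  u <- a - b
  v <- c - b
  acos(max(-1, min(1, sum(u * v) / (dist3(a, b) * dist3(c, b))))) * 180 / pi
}

# exhaustive re-check of one pose: loop over every oxygen, decide hydroxyl
# status, compute features against the given receptor model, and apply the
# criteria; returns list(reactive, d1, d2, a1, serial) for the representative
brute_force_pose <- function(pose_df, rec_df, d1_max = 4, d2_max = 4,
                             a1_min = 80, a1_max = 140) {
  get_xyz <- function(df, i) c(df$x[i], df$y[i], df$z[i])
  rec_at <- function(resno, nm) {
    i <- which(rec_df$residue_number == resno & rec_df$name == nm)
    stopifnot(length(i) == 1)
    get_xyz(rec_df, i)
  }
  c1 <- rec_at(501, "C1")
  lo <- rec_at(284, "OD1")
  e1 <- rec_at(326, "OE1")
  e2 <- rec_at(326, "OE2")

  has_h <- any(toupper(pose_df$element) == "H")
  rows <- list()
  for (i in seq_len(nrow(pose_df))) {
    if (toupper(pose_df$element[i]) != "O") next
    o <- get_xyz(pose_df, i)
    is_oh <- FALSE
    if (has_h) {
      for (j in seq_len(nrow(pose_df))) {
        if (toupper(pose_df$element[j]) == "H" &&
            dist3(o, get_xyz(pose_df, j)) < 1.2) is_oh <- TRUE
      }
    } else {
      nb <- 0; all_c <- TRUE
      for (j in seq_len(nrow(pose_df))) {
        if (j == i || toupper(pose_df$element[j]) == "H") next
        if (dist3(o, get_xyz(pose_df, j)) < 1.8) {
          nb <- nb + 1
          if (toupper(pose_df$element[j]) != "C") all_c <- FALSE
        }
      }
      is_oh <- nb == 1 && all_c
    }
    if (!is_oh) next
    d1 <- dist3(o, c1)
    d2 <- min(dist3(o, e1), dist3(o, e2))
    a1 <- angle3(o, c1, lo)
    rows[[length(rows) + 1]] <- list(
      serial = pose_df$serial[i], d1 = d1, d2 = d2, a1 = a1,
      reactive = d1 < d1_max && d2 < d2_max && a1 > a1_min && a1 < a1_max)
  }
  if (length(rows) == 0)
    return(list(reactive = FALSE, d1 = NA, d2 = NA, a1 = NA, serial = NA))
  ok <- Filter(function(r) r$reactive, rows)
  pool <- if (length(ok) > 0) ok else rows
  best <- pool[[1]]
  for (r in pool[-1]) {
    if (r$d1 < best$d1 ||
        (r$d1 == best$d1 && r$d2 < best$d2) ||
        (r$d1 == best$d1 && r$d2 == best$d2 && r$serial < best$serial))
      best <- r
  }
  best$reactive <- length(ok) > 0
  best
}

# random proper rotation matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(df, rot, shift) {
  xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(rot)
  df$x <- xyz[, 1] + shift[1]
  df$y <- xyz[, 2] + shift[2]
  df$z <- xyz[, 3] + shift[3]
  df
}

# hand-built single pose: hydroxyl O (+H +C) at given position, for
# constructed-geometry cases
manual_pose <- function(o_xyz, with_h = TRUE, model = 1L, serial0 = 0L) {
  rows <- data.frame(
    model = model,
    serial = serial0 + if (with_h) 1:3 else 1:2,
    name = if (with_h) c("O1", "H1", "C2") else c("O1", "C2"),
    element = if (with_h) c("O", "H", "C") else c("O", "C"),
    residue_name = "LIG", residue_number = 1L, insert = "", chain = "L",
    stringsAsFactors = FALSE)
  shift <- rbind(c(0, 0, 0), if (with_h) c(0.95, 0, 0), c(0, 1.36, 0.2))
  rows$x <- o_xyz[1] + shift[, 1]
  rows$y <- o_xyz[2] + shift[, 2]
  rows$z <- o_xyz[3] + shift[, 3]
  rows$occupancy <- 1
  rows$bfactor <- 0
  tibble::as_tibble(rows)
}

# the fixed-anchor synthetic receptor (single model) used by manual poses
manual_receptor <- function(e_xyz = c(3, 3, 0), e2_xyz = c(6, 6, 0)) {
  tibble::tibble(
    model = 1L, serial = 1:4,
    name = c("C1", "OD1", "OE1", "OE2"),
    element = c("C", "O", "O", "O"),
    residue_name = c("GLC", "ASP", "GLU", "GLU"),
    residue_number = c(501L, 284L, 326L, 326L),
    insert = "", chain = "A",
    x = c(0, 0, e_xyz[1], e2_xyz[1]),
    y = c(0, 2, e_xyz[2], e2_xyz[2]),
    z = c(0, 0, e_xyz[3], e2_xyz[3]),
    occupancy = 1, bfactor = 0)
}
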