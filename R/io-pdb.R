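# Fixed-column PDB v3.3 reading/writing. Only ATOM/HETATM (plus MODEL/ENDMDL)
# records carry information the pipeline uses; everything else is skipped and
# counted. Columns (1-based): record 1-6, serial 7-11, name 13-16, altLoc 17,
# resName 18-20, chain 22, resSeq 23-26, iCode 27, x/y/z 31-54, occ 55-60,
# B 61-66, element 77-78.

parse_atom_line <- function(line, lineno, model) {
  num <- function(s, what) {
    s <- trimws(s)
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) stop_parse(paste0("malformed ", what, " field '", s, "'"),
                             line = lineno)
    v
  }
  nc <- nchar(line)
  if (nc < 54) stop_parse("ATOM/HETATM record too short", line = lineno)
  pad <- function(from, to) substr(sprintf("%-80s", line), from, to)
  occ <- trimws(pad(55, 60))
  bf <- trimws(pad(61, 66))
  el <- trimws(pad(77, 78))
  name <- trimws(pad(13, 16))
  if (el == "") {
    # fall back to the first letter of the atom name (common for minimal files)
    el <- sub("^[0-9]*", "", name)
    el <- toupper(substr(el, 1, 1))
  }
  tibble(
    record = trimws(pad(1, 6)),
    model = model,
    serial = as.integer(num(pad(7, 11), "serial")),
    name = name,
    altloc = trimws(pad(17, 17)),
    residue_name = trimws(pad(18, 20)),
    chain = trimws(pad(22, 22)),
    residue_number = as.integer(num(pad(23, 26), "residue number")),
    insert = trimws(pad(27, 27)),
    x = num(pad(31, 38), "x coordinate"),
    y = num(pad(39, 46), "y coordinate"),
    z = num(pad(47, 54), "z coordinate"),
    occupancy = if (occ == "") 1.0 else num(occ, "occupancy"),
    bfactor = if (bf == "") 0.0 else num(bf, "B-factor"),
    element = el
  )
}

# altloc rule: within each (model, chain, residue, insert, atom name) keep the
# highest-occupancy record; ties keep the first encountered
resolve_altlocs <- function(atoms) {
  if (all(atoms$altloc == "")) return(list(atoms = atoms, dropped = 0L))
  atoms$.ord <- seq_len(nrow(atoms))
  kept <- atoms |>
    arrange(dplyr::desc(.data$occupancy), .data$.ord) |>
    distinct(.data$model, .data$chain, .data$residue_number, .data$insert,
             .data$name, .keep_all = TRUE) |>
    arrange(.data$.ord)
  dropped <- nrow(atoms) - nrow(kept)
  kept$.ord <- NULL
  list(atoms = kept, dropped = dropped)
}

#' Read a PDB file into an atom tibble
#'
#' Parses ATOM/HETATM records by fixed columns. Multi-model files get a
#' `model` column (1-based, taken from the MODEL record when numbered).
#' Alternate locations are resolved to the highest-occupancy copy (ties:
#' first encountered) with a warning stating how many records were dropped.
#' No ATOM/HETATM record is silently lost: records in equals records
#' returned plus warned drops.
#'
#' @param path path to a PDB (or PDB-like) file.
#' @return a tibble with one row per atom: `record`, `model`, `serial`,
#'   `name`, `altloc`, `residue_name`, `chain`, `residue_number`, `insert`,
#'   `x`, `y`, `z`, `occupancy`, `bfactor`, `element` (coordinates in
#'   angstrom).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop_parse(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  model <- 1L
  seen_model <- FALSE
  rows <- list()
  for (i in seq_along(lines)) {
    rec <- substr(lines[i], 1, 6)
    if (startsWith(rec, "MODEL")) {
      m <- suppressWarnings(as.integer(trimws(substr(lines[i], 7, 80))))
      model <- if (is.na(m)) model + seen_model else m
      seen_model <- TRUE
    } else if (startsWith(rec, "ATOM") || startsWith(rec, "HETATM")) {
      rows[[length(rows) + 1L]] <- parse_atom_line(lines[i], i, model)
    }
  }
  if (length(rows) == 0L) {
    warn(paste0("no ATOM/HETATM records in ", path))
    return(empty_atoms())
  }
  atoms <- bind_rows(rows)
  res <- resolve_altlocs(atoms)
  if (res$dropped > 0L)
    warn(paste0("dropped ", res$dropped,
                " alternate-location record(s) (kept highest occupancy)"))
  res$atoms
}

empty_atoms <- function() {
  tibble(record = character(), model = integer(), serial = integer(),
         name = character(), altloc = character(),
         residue_name = character(), chain = character(),
         residue_number = integer(), insert = character(),
         x = double(), y = double(), z = double(),
         occupancy = double(), bfactor = double(), element = character())
}

format_atom_line <- function(a, record = "ATOM") {
  name <- a$name
  # short names start in column 14 by convention
  name_fmt <- if (nchar(name) < 4L) sprintf(" %-3s", name)
              else sprintf("%-4s", name)
  sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, a$serial %% 100000L, name_fmt,
          a$altloc %||% "", a$residue_name, a$chain,
          a$residue_number %% 10000L, a$insert %||% "",
          a$x, a$y, a$z, a$occupancy %||% 1.0, a$bfactor %||% 0.0,
          toupper(a$element))
}

atoms_to_lines <- function(atoms, record = "ATOM") {
  if (!"altloc" %in% names(atoms)) atoms$altloc <- ""
  if (!"insert" %in% names(atoms)) atoms$insert <- ""
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1.0
  if (!"bfactor" %in% names(atoms)) atoms$bfactor <- 0.0
  vapply(seq_len(nrow(atoms)),
         function(i) format_atom_line(as.list(atoms[i, ]), record),
         character(1))
}

#' Write an atom tibble as a PDB file
#'
#' If `atoms` has a `model` column with more than one distinct value the file
#' is written with MODEL/ENDMDL blocks, one per model, in ascending order.
#'
#' @param atoms atom tibble (as returned by [read_pdb()] or built by the
#'   generators); requires at least `serial`, `name`, `residue_name`,
#'   `chain`, `residue_number`, `x`, `y`, `z`, `element`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(atoms, path) {
  need <- c("serial", "name", "residue_name", "chain", "residue_number",
            "x", "y", "z", "element")
  if (!all(need %in% names(atoms)))
    stop_invalid("atoms", paste0("missing column(s): ",
                                 paste(setdiff(need, names(atoms)),
                                       collapse = ", ")))
  models <- if ("model" %in% names(atoms)) sort(unique(atoms$model)) else 1L
  out <- character(0)
  multi <- length(models) > 1L
  for (m in models) {
    sub <- if ("model" %in% names(atoms)) atoms[atoms$model == m, ] else atoms
    if (multi) out <- c(out, sprintf("MODEL     %4d", m))
    out <- c(out, atoms_to_lines(sub))
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}
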