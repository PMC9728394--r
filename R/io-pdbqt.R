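# PDBQT (AutoDock dialect): PDB atom columns 1-66, then partial charge and
# AutoDock atom type as the two trailing whitespace-separated fields. Docked
# results are MODEL/ENDMDL-delimited, one pose per MODEL, each optionally
# preceded by a "REMARK VINA RESULT: <affinity> <rmsd_lb> <rmsd_ub>" line.

parse_pdbqt_atom <- function(line, lineno, model) {
  base <- parse_atom_line(substr(line, 1, 66), lineno, model)
  trailer <- strsplit(trimws(substr(sprintf("%-80s", line), 67, 80)),
                      "\\s+")[[1]]
  trailer <- trailer[nzchar(trailer)]
  nt <- length(trailer)
  base$atom_type <- if (nt >= 1L) trailer[nt] else ""
  base$charge <- if (nt >= 2L) {
    v <- suppressWarnings(as.numeric(trailer[nt - 1L]))
    if (is.na(v)) 0.0 else v
  } else 0.0
  # PDBQT element from the AutoDock type when the element columns were reused
  if (base$element == "" && base$atom_type != "")
    base$element <- toupper(substr(base$atom_type, 1, 1))
  base
}

#' Read docked poses from a multi-model PDBQT file
#'
#' One pose per MODEL/ENDMDL block; the Vina affinity is taken from the
#' "REMARK VINA RESULT" line when present (`NA` otherwise). A file with
#' ATOM/HETATM records but no MODEL records is read as a single pose. An
#' empty file yields an empty tibble with a warning; a MODEL block not closed
#' by ENDMDL is a parse error.
#'
#' @param path path to a PDBQT file.
#' @return a tibble of atoms with the [read_pdb()] columns plus `charge`,
#'   `atom_type` and a per-model `score` (kcal/mol, engine units); `model` is
#'   the pose index.
#' @export
read_pdbqt_poses <- function(path) {
  if (!file.exists(path)) stop_parse(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  scores <- numeric(0)
  model <- 0L
  in_model <- FALSE
  cur_score <- NA_real_
  for (i in seq_along(lines)) {
    ln <- lines[i]
    rec <- substr(ln, 1, 6)
    if (startsWith(rec, "MODEL")) {
      if (in_model) stop_parse("MODEL block not terminated by ENDMDL",
                               line = i)
      in_model <- TRUE
      m <- suppressWarnings(as.integer(trimws(substr(ln, 7, 80))))
      model <- if (is.na(m)) model + 1L else m
      cur_score <- NA_real_
    } else if (startsWith(rec, "ENDMDL")) {
      if (!in_model) stop_parse("ENDMDL without matching MODEL", line = i)
      in_model <- FALSE
      scores[as.character(model)] <- cur_score
    } else if (grepl("^REMARK VINA RESULT:", ln)) {
      fields <- strsplit(trimws(sub("^REMARK VINA RESULT:", "", ln)),
                         "\\s+")[[1]]
      cur_score <- suppressWarnings(as.numeric(fields[1]))
    } else if (startsWith(rec, "ATOM") || startsWith(rec, "HETATM")) {
      if (!in_model && model == 0L) {
        model <- 1L  # tolerated: un-delimited single pose
        scores["1"] <- NA_real_
      }
      rows[[length(rows) + 1L]] <- parse_pdbqt_atom(ln, i, model)
    }
  }
  if (in_model) stop_parse("file ends inside an unterminated MODEL block")
  if (length(rows) == 0L) {
    warn(paste0("no poses found in ", path))
    out <- empty_atoms()
    out$charge <- double()
    out$atom_type <- character()
    out$score <- double()
    return(out)
  }
  atoms <- bind_rows(rows)
  sc <- tibble(model = as.integer(names(scores)),
               score = unname(scores))
  left_join(atoms, sc, by = "model")
}

#' Write a pose ensemble as a multi-model PDBQT file
#'
#' Each model is wrapped in MODEL/ENDMDL records with a
#' "REMARK VINA RESULT" line carrying its docking score.
#'
#' @param atoms atom tibble with a `model` column (and optionally `score`,
#'   `charge`, `atom_type` columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdbqt_poses <- function(atoms, path) {
  if (!"model" %in% names(atoms))
    stop_invalid("atoms", "needs a `model` column")
  if (!"charge" %in% names(atoms)) atoms$charge <- 0.0
  if (!"atom_type" %in% names(atoms))
    atoms$atom_type <- toupper(atoms$element)
  out <- character(0)
  for (m in sort(unique(atoms$model))) {
    sub <- atoms[atoms$model == m, ]
    score <- if ("score" %in% names(sub)) sub$score[1] else NA_real_
    out <- c(out, sprintf("MODEL %d", m))
    if (!is.na(score))
      out <- c(out, sprintf("REMARK VINA RESULT: %8.1f %10.3f %10.3f",
                            score, 0, 0))
    # PDBQT: PDB columns 1-66, then partial charge and AutoDock type
    body <- substr(atoms_to_lines(sub), 1, 66)
    out <- c(out, paste0(body, sprintf("    %6.3f %-2s",
                                       sub$charge, sub$atom_type)),
             "ENDMDL")
  }
  writeLines(out, path)
  invisible(path)
}
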