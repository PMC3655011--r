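# Structural and tabular I/O: multi-model PDB trajectories, PDBQT pose files
# with per-model energy remarks, and tab-separated contact reports.

#' Construct an atom table
#'
#' Builds the atom annotation table shared by trajectory frames and docking
#' poses. One row per atom; coordinates are stored separately so that the
#' same table can describe every frame of a trajectory.
#'
#' @param serial positive integer atom serial numbers.
#' @param name short atom labels (e.g. `"CA"`, `"N"`).
#' @param element element symbols (e.g. `"C"`, `"N"`, `"H"`).
#' @param resname three-letter residue codes (e.g. `"GLU"`).
#' @param resno 1-based residue numbers (the crystallographic numbering is
#'   kept as-is; `Ser623` stays residue 623).
#' @param chain single-character chain identifiers; must be non-blank.
#' @return A `data.frame` with columns `serial`, `name`, `element`,
#'   `resname`, `resno`, `chain`.
#' @export
atom_table <- function(serial, name, element, resname, resno, chain) {
  at <- data.frame(
    serial = as.integer(serial), name = as.character(name),
    element = as.character(element), resname = as.character(resname),
    resno = as.integer(resno), chain = as.character(chain),
    stringsAsFactors = FALSE
  )
  validate_atom_table(at)
  at
}

validate_atom_table <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  need <- c("serial", "name", "element", "resname", "resno", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table missing column(s): ", paste(miss, collapse = ", "))
  if (any(is.na(atoms$chain) | atoms$chain == "" | atoms$chain == " "))
    stop("atoms without a chain identifier are not accepted")
  if (any(atoms$resno < 1L))
    stop("residue numbers must be >= 1")
  invisible(atoms)
}

#' Construct a single structure frame
#'
#' @param atoms atom table as from [atom_table()].
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param index frame ordinal (1-based).
#' @param time_ps optional simulation time in picoseconds.
#' @return An object of class `gtusc_frame`.
#' @export
make_frame <- function(atoms, xyz, index = 1L, time_ps = NULL) {
  validate_atom_table(atoms)
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(atoms) || ncol(xyz) != 3L)
    stop("xyz must be an n_atoms x 3 matrix")
  if (!all(is.finite(xyz)))
    stop("non-finite coordinates in frame ", index)
  structure(list(atoms = atoms, xyz = unname(xyz), index = as.integer(index),
                 time_ps = time_ps),
            class = "gtusc_frame")
}

#' Construct a trajectory
#'
#' All frames must share atom identity (serial, name, residue, chain) and
#' atom count; coordinates are stacked into a `n_frames x n_atoms x 3` array.
#'
#' @param frames list of [make_frame()] objects.
#' @return An object of class `gtusc_traj` with elements `atoms`, `coords`
#'   (array), `time_ps` and `chain_ids`.
#' @export
make_trajectory <- function(frames) {
  if (!length(frames)) stop("empty input: a trajectory needs at least one frame")
  ref <- frames[[1L]]$atoms
  ident <- function(a) paste(a$serial, a$name, a$resname, a$resno, a$chain)
  for (k in seq_along(frames)) {
    a <- frames[[k]]$atoms
    if (nrow(a) != nrow(ref))
      stop("structural inconsistency: frame ", k, " has ", nrow(a),
           " atoms, expected ", nrow(ref))
    if (!identical(ident(a), ident(ref)))
      stop("structural inconsistency: atom identity differs in frame ", k)
  }
  coords <- array(NA_real_, dim = c(length(frames), nrow(ref), 3L))
  for (k in seq_along(frames)) coords[k, , ] <- frames[[k]]$xyz
  tp <- vapply(frames, function(f) {
    if (is.null(f$time_ps)) NA_real_ else as.numeric(f$time_ps)
  }, numeric(1))
  structure(list(atoms = ref, coords = coords,
                 time_ps = if (all(is.na(tp))) NULL else tp,
                 chain_ids = sort(unique(ref$chain))),
            class = "gtusc_traj")
}

#' Number of frames in a trajectory
#' @param traj a `gtusc_traj`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1L]

#' Extract one frame from a trajectory
#' @param traj a `gtusc_traj`.
#' @param i frame index (1-based).
#' @return A `gtusc_frame`.
#' @export
get_frame <- function(traj, i) {
  nf <- n_frames(traj)
  if (i < 1L || i > nf) stop("frame index ", i, " out of range 1..", nf)
  make_frame(traj$atoms, traj$coords[i, , , drop = TRUE], index = i,
             time_ps = if (is.null(traj$time_ps)) NULL else traj$time_ps[i])
}

#' @export
print.gtusc_traj <- function(x, ...) {
  cat("gtusc trajectory:", n_frames(x), "frames,", nrow(x$atoms),
      "atoms, chains", paste(x$chain_ids, collapse = ","), "\n")
  invisible(x)
}

# ---- PDB (multi-model) ------------------------------------------------------

parse_pdb_atom_line <- function(line) {
  # PDB v3 fixed columns
  list(serial = as.integer(substr(line, 7, 11)),
       name = trimws(substr(line, 13, 16)),
       resname = trimws(substr(line, 18, 20)),
       chain = substr(line, 22, 22),
       resno = as.integer(substr(line, 23, 26)),
       x = as.numeric(substr(line, 31, 38)),
       y = as.numeric(substr(line, 39, 46)),
       z = as.numeric(substr(line, 47, 54)),
       element = trimws(substr(line, 77, 78)))
}

parse_atom_block <- function(lines, frame_id) {
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  if (!length(lines)) stop("empty input: no ATOM records in frame ", frame_id)
  n <- length(lines)
  serial <- as.integer(substr(lines, 7, 11))
  name <- trimws(substr(lines, 13, 16))
  resname <- trimws(substr(lines, 18, 20))
  chain <- substr(lines, 22, 22)
  resno <- as.integer(substr(lines, 23, 26))
  x <- as.numeric(substr(lines, 31, 38))
  y <- as.numeric(substr(lines, 39, 46))
  z <- as.numeric(substr(lines, 47, 54))
  element <- trimws(substr(lines, 77, 78))
  # fall back on the first character of the atom name when the element
  # column is blank (common in minimised files)
  blank <- element == ""
  element[blank] <- substr(gsub("[^A-Za-z].*", "", name[blank]), 1, 1)
  atoms <- atom_table(serial, name, element, resname, resno, chain)
  make_frame(atoms, cbind(x, y, z), index = frame_id)
}

read_pdb_multimodel <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(trimws(lines)) || !any(nzchar(trimws(lines))))
    stop("empty input: ", path)
  model_at <- grep("^MODEL", lines)
  frames <- list()
  if (!length(model_at)) {
    frames[[1L]] <- parse_atom_block(lines, 1L)
  } else {
    end_at <- grep("^ENDMDL", lines)
    if (length(end_at) != length(model_at))
      stop("unbalanced MODEL/ENDMDL records in ", path)
    for (k in seq_along(model_at)) {
      block <- lines[(model_at[k] + 1L):(end_at[k] - 1L)]
      frames[[k]] <- parse_atom_block(block, k)
    }
  }
  make_trajectory(frames)
}

format_pdb_atom_line <- function(atoms, xyz) {
  nm <- atoms$name
  # names shorter than 4 characters start in column 14
  nm <- ifelse(nchar(nm) < 4L, paste0(" ", nm), nm)
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$serial, nm, atoms$resname, atoms$chain, atoms$resno,
          xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, atoms$element)
}

# ---- XYZ-per-frame dialect --------------------------------------------------
# Extended XYZ: per frame a count line, a comment line, then per atom
# "element x y z chain resno resname name". Chain fields are mandatory:
# files without chain identity are rejected rather than guessed.

read_xyz_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty input: ", path)
  frames <- list()
  pos <- 1L
  k <- 0L
  while (pos <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 1L) stop("malformed XYZ count line at line ", pos)
    k <- k + 1L
    block <- lines[(pos + 2L):(pos + 1L + n)]
    tok <- strsplit(trimws(block), "[[:space:]]+")
    nf <- lengths(tok)
    if (any(nf < 8L))
      stop("XYZ frame ", k, ": atom lines must carry ",
           "'element x y z chain resno resname name' (chain required)")
    m <- do.call(rbind, tok)
    atoms <- atom_table(seq_len(n), m[, 8], m[, 1], m[, 7],
                        as.integer(m[, 6]), m[, 5])
    xyz <- cbind(as.numeric(m[, 2]), as.numeric(m[, 3]), as.numeric(m[, 4]))
    frames[[k]] <- make_frame(atoms, xyz, index = k)
    pos <- pos + 2L + n
  }
  make_trajectory(frames)
}

write_xyz_frames <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  a <- traj$atoms
  for (i in seq_len(n_frames(traj))) {
    xyz <- traj$coords[i, , , drop = TRUE]
    writeLines(c(as.character(nrow(a)), paste("frame", i)), con)
    writeLines(sprintf("%s %.6f %.6f %.6f %s %d %s %s", a$element,
                       xyz[, 1], xyz[, 2], xyz[, 3], a$chain, a$resno,
                       a$resname, a$name), con)
  }
  invisible(path)
}

#' Read a trajectory file
#'
#' Reads either a multi-model PDB file (one `MODEL`/`ENDMDL` block per frame,
#' or a single block for a one-frame file) or an extended XYZ-per-frame file
#' carrying chain/residue identity. Atom identity (serial, name, residue,
#' chain) is validated to be constant across frames; a mismatch raises a
#' structural-inconsistency error naming the offending frame.
#'
#' @param path file path.
#' @param format `"pdb_multimodel"` or `"xyz_frames"`.
#' @return A `gtusc_traj`.
#' @export
read_trajectory <- function(path, format = c("pdb_multimodel", "xyz_frames")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format,
         pdb_multimodel = read_pdb_multimodel(path),
         xyz_frames = read_xyz_frames(path))
}

#' Write a trajectory file
#'
#' Inverse of [read_trajectory()]. PDB coordinates are written with three
#' decimals, so a write/read round trip preserves coordinates to 1e-3 A.
#'
#' @inheritParams read_trajectory
#' @param traj a `gtusc_traj`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path,
                             format = c("pdb_multimodel", "xyz_frames")) {
  format <- match.arg(format)
  if (format == "xyz_frames") return(write_xyz_frames(traj, path))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(format_pdb_atom_line(traj$atoms,
                                    traj$coords[i, , , drop = TRUE]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- PDBQT poses ------------------------------------------------------------

#' Read a multi-model PDBQT docking pose file
#'
#' One pose per `MODEL`; the docking score is parsed from the per-model
#' `REMARK VINA RESULT:` line (first numeric field, kcal/mol). The compound
#' identifier is taken from a `REMARK  Name = <id>` line when present, else
#' from the file name.
#'
#' @param path file path.
#' @return A list of `gtusc_pose` objects in file order, each with
#'   `compound_id`, `model_index`, `energy`, `atoms` and `xyz`.
#' @export
read_pose_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  model_at <- grep("^MODEL", lines)
  if (!length(model_at))
    stop("empty input: no MODEL records in ", path)
  end_at <- grep("^ENDMDL", lines)
  if (length(end_at) != length(model_at))
    stop("unbalanced MODEL/ENDMDL records in ", path)
  name_ln <- grep("^REMARK[[:space:]]+Name[[:space:]]*=", lines, value = TRUE)
  cid <- if (length(name_ln)) {
    trimws(sub(".*=", "", name_ln[1L]))
  } else sub("\\.[^.]*$", "", basename(path))
  poses <- vector("list", length(model_at))
  for (k in seq_along(model_at)) {
    block <- lines[(model_at[k] + 1L):(end_at[k] - 1L)]
    en_ln <- grep("VINA RESULT", block, value = TRUE)
    if (!length(en_ln))
      stop("model ", k, " in ", basename(path),
           " has no VINA RESULT energy remark")
    en <- suppressWarnings(as.numeric(
      strsplit(trimws(sub(".*VINA RESULT:", "", en_ln[1L])),
               "[[:space:]]+")[[1L]][1L]))
    if (!is.finite(en))
      stop("model ", k, " in ", basename(path), ": unparseable energy remark")
    fr <- parse_atom_block(block, k)
    poses[[k]] <- structure(list(compound_id = cid, model_index = k,
                                 energy = en, atoms = fr$atoms, xyz = fr$xyz),
                            class = "gtusc_pose")
  }
  poses
}

#' Write a multi-model PDBQT pose file
#'
#' @param poses list of `gtusc_pose` objects (one compound).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pose_file <- function(poses, path) {
  if (!length(poses)) stop("empty input: no poses to write")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("REMARK  Name = ", poses[[1L]]$compound_id), con)
  for (k in seq_along(poses)) {
    p <- poses[[k]]
    writeLines(sprintf("MODEL %d", k), con)
    writeLines(sprintf("REMARK VINA RESULT:  %8.1f      0.000      0.000",
                       p$energy), con)
    writeLines(format_pdb_atom_line(p$atoms, p$xyz), con)
    writeLines("ENDMDL", con)
  }
  invisible(path)
}

# ---- contact reports --------------------------------------------------------

contact_report_cols <- c("chain_i", "resno_i", "resname_i", "name_i",
                         "chain_j", "resno_j", "resname_j", "name_j",
                         "n_frames_present", "n_frames_total",
                         "persistence_fraction")

#' Write a persistent-contact report
#'
#' Tab-separated, one row per persistent atom-pair contact, deterministically
#' ordered by (chain, residue number, atom name) of both partners regardless
#' of input order.
#'
#' @param contacts data.frame as returned by [persistent_contacts()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contact_report <- function(contacts, path) {
  if (is.null(contacts) || !nrow(contacts)) {
    contacts <- as.data.frame(
      setNames(rep(list(character(0)), length(contact_report_cols)),
               contact_report_cols))
  } else {
    miss <- setdiff(contact_report_cols, names(contacts))
    if (length(miss)) stop("contact table missing: ", paste(miss, collapse = ", "))
    contacts <- contacts[order(contacts$chain_i, contacts$resno_i,
                               contacts$name_i, contacts$chain_j,
                               contacts$resno_j, contacts$name_j),
                         contact_report_cols]
  }
  utils::write.table(contacts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a persistent-contact report
#' @param path report path written by [write_contact_report()].
#' @return data.frame with the report columns.
#' @export
read_contact_report <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "integer", "character",
                                   "character", "character", "integer",
                                   "character", "character", "integer",
                                   "integer", "numeric"))
}

#' Validate a structure file
#'
#' Light-weight check used by the command-line wrapper: parses the file and
#' reports frame/atom counts, or the first structural error encountered.
#'
#' @param path file path.
#' @param format as in [read_trajectory()], or `"pdbqt"` for pose files.
#' @return A list with `ok`, `message`, and on success `n_frames`/`n_atoms`.
#' @export
validate_structure_file <- function(path,
                                    format = c("pdb_multimodel", "xyz_frames",
                                               "pdbqt")) {
  format <- match.arg(format)
  res <- tryCatch({
    if (format == "pdbqt") {
      p <- read_pose_file(path)
      list(ok = TRUE, message = "ok", n_frames = length(p),
           n_atoms = nrow(p[[1L]]$atoms))
    } else {
      tr <- read_trajectory(path, format)
      list(ok = TRUE, message = "ok", n_frames = n_frames(tr),
           n_atoms = nrow(tr$atoms))
    }
  }, error = function(e) list(ok = FALSE, message = conditionMessage(e)))
  res
}
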