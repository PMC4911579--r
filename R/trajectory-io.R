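#' Read a trajectory from disk
#'
#' Core formats are plain-text: multi-model PDB (`MODEL`/`ENDMDL` blocks)
#' and XYZ frame series. Binary dialects (DCD/XTC, ...) are supported via
#' the `reader` plugin seam: pass any function `file -> trajectory` without
#' making the dialect a package dependency.
#'
#' @param file Path.
#' @param format `"auto"` (by extension), `"pdb"` or `"xyz"`.
#' @param topology Optional [charged_structure()] supplying
#'   masses/charges/labels for XYZ input (XYZ carries only elements and
#'   positions).
#' @param reader Optional plugin function taking `file` and returning a
#'   [trajectory()]; overrides `format`.
#' @param ... Passed to the underlying reader.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(file, format = c("auto", "pdb", "xyz"),
                            topology = NULL, reader = NULL, ...) {
  if (!is.null(reader)) return(reader(file, ...))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(file))
    format <- if (ext %in% c("pdb", "ent")) "pdb"
              else if (ext == "xyz") "xyz"
              else stop("cannot infer trajectory format from '", file,
                        "'; pass `format` or a `reader`", call. = FALSE)
  }
  switch(format,
         pdb = read_trajectory_pdb(file, ...),
         xyz = read_trajectory_xyz(file, topology = topology, ...))
}

#' @rdname read_trajectory
#' @param frame_spacing_ps Frame spacing in picoseconds (default 10).
#' @export
read_trajectory_pdb <- function(file, frame_spacing_ps = 10, ...) {
  pdb <- bio3d::read.pdb(file, multi = TRUE)
  a <- pdb$atom
  elem <- infer_elements(a)
  mono <- ifelse(nzchar(a$chain) & !is.na(a$chain), a$chain, "A")
  topo <- charged_structure(data.frame(
    serial = a$eleno, elety = a$elety, resid = a$resid, resno = a$resno,
    monomer = mono, x = a$x, y = a$y, z = a$z,
    mass = element_mass(elem), charge = 0, element = elem,
    stringsAsFactors = FALSE))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nfr <- nrow(xyz); nat <- ncol(xyz) / 3
  arr <- array(NA_real_, c(nat, 3, nfr))
  for (f in seq_len(nfr))
    arr[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  trajectory(topo, arr, frame_spacing_ps = frame_spacing_ps)
}

#' @rdname read_trajectory
#' @export
read_trajectory_xyz <- function(file, topology = NULL,
                                frame_spacing_ps = 10, ...) {
  lines <- readLines(file)
  frames <- list(); elements <- NULL; i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- as.integer(trimws(lines[i]))
    if (is.na(nat)) stop("malformed XYZ: expected atom count at line ", i,
                         call. = FALSE)
    block <- lines[(i + 2L):(i + 1L + nat)]
    fields <- strsplit(trimws(block), "\\s+")
    xyz <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
    if (is.null(elements)) elements <- vapply(fields, `[`, "", 1)
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + nat
  }
  if (!length(frames)) stop("no frames in '", file, "'", call. = FALSE)
  nat <- nrow(frames[[1]])
  if (is.null(topology)) {
    topology <- charged_structure(data.frame(
      serial = seq_len(nat), elety = "CA", resid = "BEA",
      resno = seq_len(nat), monomer = "A",
      x = frames[[1]][, 1], y = frames[[1]][, 2], z = frames[[1]][, 3],
      mass = 1, charge = 0, element = elements, stringsAsFactors = FALSE))
  } else if (nrow(topology$atoms) != nat) {
    stop("topology atom count does not match XYZ frames", call. = FALSE)
  }
  trajectory(topology, frames, frame_spacing_ps = frame_spacing_ps)
}

#' Write a trajectory (or structure) to plain-text formats
#'
#' `write_trajectory_xyz()` emits the standard XYZ frame series;
#' `write_trajectory_pdb()` emits a multi-model PDB (`MODEL`/`ENDMDL`)
#' readable by any trajectory viewer. `write_structure_pdb()` writes a
#' single-model PDB from a [charged_structure()].
#'
#' @param traj A [trajectory()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, file) {
  stopifnot(inherits(traj, "trajectory"))
  elem <- traj$topology$atoms$element
  con <- file(file, "w"); on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, f)
    writeLines(c(as.character(length(elem)), sprintf("frame %d", f)), con)
    writeLines(sprintf("%-2s %12.5f %12.5f %12.5f",
                       elem, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(file)
}

pdb_atom_lines <- function(atoms, xyz) {
  # fixed columns: name 13-16, altloc 17 (blank), resname 18-20, chain 22
  nm <- ifelse(nchar(atoms$elety) < 4, paste0(" ", atoms$elety), atoms$elety)
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$serial %% 100000, nm, atoms$resid,
          substr(as.character(atoms$monomer), 1, 1), atoms$resno %% 10000,
          xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, atoms$element)
}

#' @rdname write_trajectory_xyz
#' @export
write_trajectory_pdb <- function(traj, file) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(file, "w"); on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(pdb_atom_lines(traj$topology$atoms, frame_coords(traj, f)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' @rdname write_trajectory_xyz
#' @param x A [charged_structure()].
#' @export
write_structure_pdb <- function(x, file) {
  stopifnot(inherits(x, "charged_structure"))
  writeLines(c(pdb_atom_lines(x$atoms, coords(x)), "END"), file)
  invisible(file)
}

#' Export a dipole or RMSF table as delimited text
#'
#' @param x A [rmsf()] profile or the result of
#'   [trajectory_dipole_stats()].
#' @param file Output path (tab-separated, header row).
#' @return `file`, invisibly.
#' @export
write_profile <- function(x, file) {
  tab <- if (inherits(x, "rmsf_profile")) {
    x$per_residue
  } else if (is.list(x) && !is.null(x$series)) {
    data.frame(frame = rep(seq_len(nrow(x$series)), ncol(x$series)),
               monomer = rep(colnames(x$series), each = nrow(x$series)),
               dipole_D = as.vector(x$series))
  } else stop("unsupported profile object", call. = FALSE)
  utils::write.table(tab, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
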