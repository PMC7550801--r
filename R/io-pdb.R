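# PDB fixed-column reader/writer (single and multi-model).
#
# Column layout per the wwPDB format v3.3 ATOM/HETATM records. Alternate
# locations are resolved to the highest-occupancy conformer; insertion codes
# are rejected (none occur in the kinase intervals this package targets).

.parse_pdb_atoms <- function(lines, path = "<pdb>") {
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  idx <- which(is_atom)
  if (length(idx) == 0L) stop("empty-input error: no ATOM/HETATM records in ", path)
  ln <- lines[idx]
  f <- function(a, b) substr(ln, a, b)
  x <- suppressWarnings(as.numeric(f(31, 38)))
  y <- suppressWarnings(as.numeric(f(39, 46)))
  z <- suppressWarnings(as.numeric(f(47, 54)))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad) > 0L)
    stop("format error: unparsable coordinates at line ", idx[bad[1]],
         " of ", path)
  resid <- suppressWarnings(as.integer(f(23, 26)))
  if (anyNA(resid))
    stop("format error: unparsable residue number at line ",
         idx[which(is.na(resid))[1]], " of ", path)
  icode <- trimws(f(27, 27))
  if (any(icode != ""))
    stop("format error: insertion codes are not supported (line ",
         idx[which(icode != "")[1]], " of ", path, ")")
  occ <- suppressWarnings(as.numeric(f(55, 60)))
  occ[!is.finite(occ)] <- 1
  list(serial = suppressWarnings(as.integer(f(7, 11))),
       name = trimws(f(13, 16)),
       altloc = trimws(f(17, 17)),
       resname = trimws(f(18, 20)),
       chain = trimws(f(22, 22)),
       resid = resid,
       xyz = cbind(x, y, z),
       occ = occ,
       element = trimws(f(77, 78)))
}

# Keep, per (chain, resid, name), the highest-occupancy alternate location.
.resolve_altloc <- function(p) {
  has_alt <- p$altloc != ""
  if (!any(has_alt)) return(seq_along(p$name))
  key <- paste(p$chain, p$resid, p$name, sep = "|")
  ord <- order(-p$occ)            # highest occupancy first, stable
  keep_first <- ord[!duplicated(key[ord])]
  sort(keep_first)
}

#' Read a structure file
#'
#' Reads a single-model PDB into a one-frame [new_trajectory()]. HETATM
#' waters are flagged, chains are preserved, alternate locations are resolved
#' to the highest-occupancy conformer, and author residue numbering is kept
#' verbatim.
#'
#' @param path file path.
#' @param format only `"pdb"` is supported for structures.
#' @param system_label,replica_index metadata stored on the result.
#' @return a `Trajectory` with one frame at `time_ns = 0`.
#' @export
read_structure <- function(path, format = "pdb",
                           system_label = basename(path), replica_index = 1L) {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # Only the first model of a multi-model file.
  endm <- which(startsWith(lines, "ENDMDL"))
  if (length(endm) > 0L) lines <- lines[seq_len(endm[1] - 1L)]
  p <- .parse_pdb_atoms(lines, path)
  keep <- .resolve_altloc(p)
  top <- atom_table(p$serial[keep], p$name[keep], p$resname[keep],
                    p$resid[keep], p$chain[keep], p$element[keep])
  new_trajectory(top, p$xyz[keep, , drop = FALSE], time_ns = 0,
                 system_label = system_label, replica_index = replica_index)
}

#' Read a trajectory file
#'
#' Multi-model PDB files are self-contained; DCD files need `topology_path`
#' (a PDB with matching atom count). The frame-to-ns mapping is mandatory
#' user metadata: pass either a scalar ns-per-frame stride or an explicit
#' vector of frame times.
#'
#' @param topology_path PDB path providing the topology (required for DCD).
#' @param traj_path trajectory file path.
#' @param format `"pdb"` (multi-model), `"dcd"`, or `"xtc"` (unsupported,
#'   raises an informative error).
#' @param frame_time_map scalar ns/frame (times `0, dt, 2dt, ...`) or numeric
#'   vector of per-frame times in ns.
#' @param system_label,replica_index metadata stored on the result.
#' @return a `Trajectory`.
#' @export
read_trajectory <- function(topology_path = NULL, traj_path,
                            format = c("pdb", "dcd", "xtc"),
                            frame_time_map = NULL,
                            system_label = basename(traj_path),
                            replica_index = 1L) {
  format <- match.arg(format)
  if (is.null(frame_time_map))
    stop("configuration error: frame_time_map (ns per frame, or explicit ",
         "frame times) is required")
  if (format == "xtc")
    stop("unsupported format: xtc decoding is not implemented; convert to ",
         "dcd or multi-model pdb")
  if (format == "pdb") {
    frames <- .read_multimodel_pdb(traj_path)
    top <- frames$topology
    coords <- frames$coords
  } else {
    if (is.null(topology_path))
      stop("configuration error: dcd trajectories need topology_path")
    top <- read_structure(topology_path)$topology
    coords <- .read_dcd_coords(traj_path)
    if (dim(coords)[1] != nrow(top))
      stop("topology error: trajectory has ", dim(coords)[1],
           " atoms but topology has ", nrow(top))
  }
  nf <- dim(coords)[3]
  time_ns <- if (length(frame_time_map) == 1L)
    (seq_len(nf) - 1) * frame_time_map else as.numeric(frame_time_map)
  if (length(time_ns) != nf)
    stop("configuration error: frame_time_map length (", length(time_ns),
         ") != number of frames (", nf, ")")
  if (!is.null(topology_path) && format == "pdb") {
    ref <- read_structure(topology_path)
    if (nrow(ref$topology) != nrow(top))
      stop("topology error: topology_path atom count (", nrow(ref$topology),
           ") != trajectory atom count (", nrow(top), ")")
  }
  new_trajectory(top, coords, time_ns, system_label = system_label,
                 replica_index = replica_index)
}

.read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) == 0L) {          # plain single-model file
    p <- .parse_pdb_atoms(lines, path)
    keep <- .resolve_altloc(p)
    top <- atom_table(p$serial[keep], p$name[keep], p$resname[keep],
                      p$resid[keep], p$chain[keep], p$element[keep])
    return(list(topology = top,
                coords = array(p$xyz[keep, , drop = FALSE],
                               dim = c(length(keep), 3L, 1L))))
  }
  model_ends <- which(startsWith(lines, "ENDMDL"))
  if (length(model_ends) != length(model_starts))
    stop("format error: MODEL/ENDMDL mismatch in ", path)
  parsed <- mapply(function(a, b) .parse_pdb_atoms(lines[a:b], path),
                   model_starts, model_ends, SIMPLIFY = FALSE)
  n0 <- length(parsed[[1]]$name)
  for (k in seq_along(parsed))
    if (length(parsed[[k]]$name) != n0)
      stop("topology error: model ", k, " has ", length(parsed[[k]]$name),
           " atoms, expected ", n0)
  p1 <- parsed[[1]]
  top <- atom_table(p1$serial, p1$name, p1$resname, p1$resid, p1$chain,
                    p1$element)
  coords <- array(NA_real_, dim = c(n0, 3L, length(parsed)))
  for (k in seq_along(parsed)) coords[, , k] <- parsed[[k]]$xyz
  list(topology = top, coords = coords)
}

#' Write a trajectory as (multi-model) PDB
#'
#' @param traj a `Trajectory`.
#' @param path output path.
#' @export
write_pdb <- function(traj, path) {
  top <- traj$topology
  nf <- n_frames(traj)
  record <- ifelse(top$is_water, "HETATM", "ATOM  ")
  # pad atom name per PDB convention: 1-char elements start in column 14
  aname <- ifelse(nchar(top$name) >= 4L, substr(top$name, 1, 4),
                  sprintf(" %-3s", top$name))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nf)) {
    if (nf > 1L) writeLines(sprintf("MODEL     %4d", k), con)
    xyz <- traj$coords[, , k]
    writeLines(sprintf(
      "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      record, top$serial %% 100000L, aname, top$resname, top$chain,
      top$resid, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, top$element), con)
    if (nf > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
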