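# Minimal DCD (CHARMM/X-PLOR binary trajectory) reader and writer.
#
# DCD is a sequence of Fortran unformatted records (4-byte length markers
# around each payload). The writer emits X-PLOR style single-precision
# coordinates without unit-cell blocks; the reader additionally skips
# CHARMM unit-cell records when the header flags them.

.read_record <- function(con) {
  len <- readBin(con, "integer", 1L, size = 4L)
  if (length(len) == 0L) return(NULL)
  payload <- readBin(con, "raw", len)
  tail <- readBin(con, "integer", 1L, size = 4L)
  if (length(tail) == 0L || tail != len)
    stop("format error: corrupt Fortran record in DCD")
  payload
}

.read_dcd_coords <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- .read_record(con)
  if (is.null(hdr) || length(hdr) != 84L ||
      rawToChar(hdr[1:4]) != "CORD")
    stop("format error: not a DCD file (missing CORD magic): ", path)
  icntrl <- readBin(hdr[5:84], "integer", 20L, size = 4L)
  nset <- icntrl[1]
  charmm <- icntrl[20] != 0L
  has_cell <- charmm && icntrl[11] != 0L
  .read_record(con)                      # title block (ignored)
  natom_rec <- .read_record(con)
  natoms <- readBin(natom_rec, "integer", 1L, size = 4L)
  frames <- list()
  repeat {
    if (has_cell) {
      cell <- .read_record(con)
      if (is.null(cell)) break
    }
    xr <- .read_record(con)
    if (is.null(xr)) break
    yr <- .read_record(con)
    zr <- .read_record(con)
    if (is.null(yr) || is.null(zr))
      stop("format error: truncated DCD frame in ", path)
    x <- readBin(xr, "numeric", natoms, size = 4L)
    y <- readBin(yr, "numeric", natoms, size = 4L)
    z <- readBin(zr, "numeric", natoms, size = 4L)
    frames[[length(frames) + 1L]] <- cbind(x, y, z)
  }
  if (length(frames) == 0L) stop("empty-input error: DCD has no frames")
  if (nset > 0L && length(frames) != nset)
    warning("DCD header declares ", nset, " frames but file holds ",
            length(frames))
  coords <- array(NA_real_, dim = c(natoms, 3L, length(frames)))
  for (k in seq_along(frames)) coords[, , k] <- frames[[k]]
  coords
}

.write_record <- function(con, payload) {
  writeBin(length(payload), con, size = 4L)
  writeBin(payload, con)
  writeBin(length(payload), con, size = 4L)
}

#' Write a trajectory as DCD
#'
#' Coordinates are stored as single-precision floats (X-PLOR layout), so a
#' round trip preserves positions to roughly 1e-5 Angstrom relative
#' precision. Frame times are not representable in DCD; keep the
#' frame-to-ns mapping alongside (it is required again at read time).
#'
#' @param traj a `Trajectory`.
#' @param path output path.
#' @export
write_dcd <- function(traj, path) {
  nf <- n_frames(traj)
  con <- file(path, "wb")
  on.exit(close(con))
  icntrl <- integer(20)
  icntrl[1] <- nf
  icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  hdr <- c(charToRaw("CORD"), writeBin(icntrl, raw(), size = 4L))
  .write_record(con, hdr)
  title <- sprintf("%-80s", "kinasedyn synthetic trajectory")
  .write_record(con, c(writeBin(1L, raw(), size = 4L), charToRaw(title)))
  .write_record(con, writeBin(as.integer(nrow(traj$topology)), raw(), size = 4L))
  for (k in seq_len(nf)) {
    xyz <- traj$coords[, , k]
    for (d in 1:3)
      .write_record(con, writeBin(as.numeric(xyz[, d]), raw(), size = 4L))
  }
  invisible(path)
}
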