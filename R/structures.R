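# Residue names recognised as water in topologies from common MD stacks.
.WATER_RESNAMES <- c("HOH", "WAT", "TIP3", "TIP3P", "SOL", "SPC", "T3P")

# Backbone heavy-atom names (protein).
.BACKBONE_NAMES <- c("N", "CA", "C", "O")

# Hydrogens attached to the backbone (amide H, alpha H, terminal variants).
.BACKBONE_H_NAMES <- c("H", "H1", "H2", "H3", "HN", "HA", "HA1", "HA2", "HA3",
                       "HXT")

#' Build an atom table (topology)
#'
#' The topology is an ordinary `data.frame`, one row per atom in file order,
#' with classification flags derived once at construction. Residue numbers
#' follow the source file's author numbering; no re-indexing is ever applied.
#'
#' @param serial integer atom serial numbers.
#' @param name atom names (PDB convention, e.g. `"CA"`, `"NZ"`, `"O1P"`).
#' @param resname 3-letter residue codes (phospho codes `SEP`/`TPO` included).
#' @param resid author-assigned residue numbers.
#' @param chain single-character chain identifiers.
#' @param element element symbols; inferred from the atom name when `NA`.
#' @return `data.frame` with columns `serial`, `name`, `element`, `resname`,
#'   `resid`, `chain`, `is_backbone`, `is_sidechain`, `is_hydrogen`,
#'   `is_water`.
#' @export
atom_table <- function(serial, name, resname, resid, chain, element = NA) {
  n <- length(name)
  stopifnot(length(resname) == n, length(resid) == n, length(chain) == n)
  if (length(serial) != n) serial <- seq_len(n)
  name <- toupper(trimws(name))
  resname <- toupper(trimws(resname))
  chain <- as.character(chain)
  element <- rep_len(toupper(trimws(as.character(element))), n)
  infer <- is.na(element) | element == ""
  if (any(infer)) element[infer] <- .infer_element(name[infer])
  is_hydrogen <- element == "H"
  is_water <- resname %in% .WATER_RESNAMES
  is_backbone <- !is_hydrogen & !is_water & name %in% .BACKBONE_NAMES
  is_sidechain <- !is_hydrogen & !is_water & !is_backbone
  data.frame(serial = as.integer(serial), name = name, element = element,
             resname = resname, resid = as.integer(resid), chain = chain,
             is_backbone = is_backbone, is_sidechain = is_sidechain,
             is_hydrogen = is_hydrogen, is_water = is_water,
             stringsAsFactors = FALSE)
}

.infer_element <- function(name) {
  # PDB names lead with the element; digits may prefix hydrogens (e.g. 1HB).
  stripped <- sub("^[0-9']+", "", name)
  ifelse(grepl("^H", stripped), "H", substr(stripped, 1L, 1L))
}

#' Construct a trajectory
#'
#' A trajectory couples one topology with a time-ordered stack of coordinate
#' frames (in Angstrom) and carries the system label and replica index used
#' by every replica-aggregating statistic downstream.
#'
#' @param topology atom table from [atom_table()] or a reader.
#' @param coords numeric array `n_atoms x 3 x n_frames` (Angstrom), or an
#'   `n_atoms x 3` matrix for a single frame.
#' @param time_ns numeric vector of frame times (ns), strictly increasing.
#'   Mandatory: trajectory formats do not carry a trustworthy clock, so the
#'   frame-to-ns mapping is user metadata.
#' @param system_label free-form system name (e.g. `"Up"`, `"pS257+pT261"`).
#' @param replica_index replica number (1-based).
#' @return object of class `Trajectory`.
#' @export
new_trajectory <- function(topology, coords, time_ns,
                           system_label = "system", replica_index = 1L) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (dim(coords)[1] != nrow(topology))
    stop("topology error: coordinate rows (", dim(coords)[1],
         ") != topology atoms (", nrow(topology), ")")
  if (length(time_ns) != dim(coords)[3])
    stop("configuration error: time_ns length (", length(time_ns),
         ") != number of frames (", dim(coords)[3], ")")
  if (any(!is.finite(coords))) stop("non-finite coordinates in trajectory")
  if (length(time_ns) > 1L && any(diff(time_ns) <= 0))
    stop("time_ns must be strictly increasing")
  structure(list(topology = topology, coords = coords,
                 time_ns = as.numeric(time_ns),
                 system_label = system_label,
                 replica_index = as.integer(replica_index)),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("<Trajectory> %s replica %d: %d atoms, %d frames, %.1f-%.1f ns\n",
              x$system_label, x$replica_index, nrow(x$topology),
              n_frames(x), x$time_ns[1], x$time_ns[n_frames(x)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `Trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame
#'
#' @param traj a `Trajectory`.
#' @param i frame index (1-based).
#' @return object of class `Frame`: topology plus an `n_atoms x 3` coordinate
#'   matrix and the frame's time in ns.
#' @export
get_frame <- function(traj, i) {
  i <- as.integer(i)
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range: ", i)
  new_frame(traj$topology, traj$coords[, , i, drop = TRUE],
            time_ns = traj$time_ns[i], frame_index = i)
}

#' Construct a single frame
#' @param topology atom table.
#' @param coords `n_atoms x 3` matrix (Angstrom).
#' @param time_ns frame time (ns).
#' @param frame_index integer index within its parent trajectory.
#' @export
new_frame <- function(topology, coords, time_ns = 0, frame_index = 1L) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L)
  if (nrow(coords) != nrow(topology))
    stop("topology error: coordinate rows != topology atoms")
  if (any(!is.finite(coords))) stop("non-finite coordinates in frame")
  structure(list(topology = topology, coords = coords,
                 time_ns = time_ns, frame_index = as.integer(frame_index)),
            class = "Frame")
}

#' @export
print.Frame <- function(x, ...) {
  cat(sprintf("<Frame %d> %d atoms at %.2f ns\n", x$frame_index,
              nrow(x$topology), x$time_ns))
  invisible(x)
}

.topology <- function(x) {
  if (inherits(x, "Trajectory") || inherits(x, "Frame")) return(x$topology)
  if (is.data.frame(x)) return(x)
  stop("expected a Trajectory, Frame or topology data.frame")
}

#' Define a residue-interval selection
#'
#' Selections are the package's unit of geometry: a chain, an inclusive
#' author-numbered residue interval, and an atom-subset rule. All of the
#' canonical kinase intervals (activation segment helix, alphaC-helix, hinge
#' region, N-lobe section, alphaF-helix) are expressed this way; see
#' [default_selections()].
#'
#' @param chain_id single chain character.
#' @param start_residue,end_residue inclusive author residue numbers.
#' @param atom_subset one of `"all"`, `"backbone"` (N, CA, C, O), `"ca"`,
#'   `"sidechain"` (heavy side-chain atoms), `"heavy"` (all non-hydrogens).
#' @return object of class `SegmentSelection`.
#' @export
segment_selection <- function(chain_id, start_residue, end_residue,
                              atom_subset = c("all", "backbone", "ca",
                                              "sidechain", "heavy")) {
  atom_subset <- match.arg(atom_subset)
  start_residue <- as.integer(start_residue)
  end_residue <- as.integer(end_residue)
  if (start_residue > end_residue)
    stop("invalid selection: start_residue (", start_residue,
         ") > end_residue (", end_residue, ")")
  structure(list(chain_id = as.character(chain_id),
                 start_residue = start_residue, end_residue = end_residue,
                 atom_subset = atom_subset),
            class = "SegmentSelection")
}

#' @export
format.SegmentSelection <- function(x, ...) {
  sprintf("%s:%d-%d[%s]", x$chain_id, x$start_residue, x$end_residue,
          x$atom_subset)
}

#' @export
print.SegmentSelection <- function(x, ...) {
  cat("<SegmentSelection>", format(x), "\n"); invisible(x)
}

#' Parse a selection string like "A:250-264" or "A:250-264:ca"
#' @param text selection string `chain:start-end[:subset]`.
#' @export
parse_selection <- function(text) {
  parts <- strsplit(text, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2L) stop("cannot parse selection: ", text)
  rng <- strsplit(parts[2], "-", fixed = TRUE)[[1]]
  if (length(rng) != 2L) stop("cannot parse residue range: ", parts[2])
  subset <- if (length(parts) >= 3L) parts[3] else "all"
  segment_selection(parts[1], as.integer(rng[1]), as.integer(rng[2]), subset)
}

#' Resolve a selection to atom indices
#'
#' @param x a `Trajectory`, `Frame` or topology data.frame.
#' @param sel a `SegmentSelection`.
#' @return integer vector of atom indices in topology order.
#' @export
resolve_selection <- function(x, sel) {
  top <- .topology(x)
  stopifnot(inherits(sel, "SegmentSelection"))
  in_range <- top$chain == sel$chain_id &
    top$resid >= sel$start_residue & top$resid <= sel$end_residue &
    !top$is_water
  keep <- switch(sel$atom_subset,
    all = in_range,
    backbone = in_range & top$is_backbone,
    ca = in_range & top$name == "CA" & !top$is_hydrogen,
    sidechain = in_range & top$is_sidechain,
    heavy = in_range & !top$is_hydrogen)
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("empty selection: ", format(sel), " resolves to no atoms")
  idx
}

#' Named default selections for the kinase intervals
#'
#' The intervals the analysis scheme is built around: activation segment
#' helix (ASH) ILE250-ALA264, alphaC-helix GLU139-ARG154, hinge region (HR)
#' GLU179-SER182, N-lobe section LEU102-GLN126, alphaF-helix VAL286-THR302,
#' and the four N-lobe sub-intervals used for interface distances.
#'
#' @param chain chain identifier the selections refer to.
#' @param atom_subset atom subset applied to each selection.
#' @return named list of `SegmentSelection` objects.
#' @export
default_selections <- function(chain = "A", atom_subset = "all") {
  mk <- function(a, b) segment_selection(chain, a, b, atom_subset)
  list(ash = mk(250L, 264L),
       alpha_c = mk(139L, 154L),
       hinge = mk(179L, 182L),
       n_lobe = mk(102L, 126L),
       alpha_f = mk(286L, 302L),
       nlobe_116_120 = mk(116L, 120L),
       nlobe_120_127 = mk(120L, 127L),
       nlobe_164_168 = mk(164L, 168L),
       nlobe_111_114 = mk(111L, 114L))
}

# Coordinate matrix of frame k restricted to atom indices, never dropped.
.frame_mat <- function(coords, idx, k) {
  matrix(coords[idx, , k], ncol = 3L)
}

# Atom indices of one residue (chain-qualified); errors when absent.
.residue_atoms <- function(top, chain, resid) {
  idx <- which(top$chain == chain & top$resid == resid)
  if (length(idx) == 0L)
    stop("residue ", chain, ":", resid, " not found in topology")
  idx
}

# Side-chain atom indices of one residue, optionally with its hydrogens.
.sidechain_atoms <- function(top, chain, resid, include_h = TRUE) {
  idx <- .residue_atoms(top, chain, resid)
  sub <- top[idx, ]
  keep <- sub$is_sidechain
  if (include_h) keep <- keep | (sub$is_hydrogen & !(sub$name %in% .BACKBONE_H_NAMES))
  idx[keep]
}
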