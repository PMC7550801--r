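# Distance-based contact detectors and replica-aggregated frequencies.
#
# All criteria are purely geometric, mirroring the defaults of the common
# trajectory-analysis stacks: salt bridges at a 4.0 A nitrogen-oxygen
# cutoff, hydrophobic side-chain contacts below 2.5 A (hydrogens included),
# hydrogen bonds at 3.5 A donor-acceptor distance with a 110 degree
# donor-H-acceptor angle, water bridges as a single water hydrogen-bonded to
# both partners, and pi-pi stacking by ring-centroid distance and plane
# angle.

# Charged side-chain atom sets. Phospho-residue oxygens accept both the
# O1P/O2P/O3P and OP1/OP2/OP3 naming variants.
.BASIC_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                     HIS = c("ND1", "NE2"),
                     HIP = c("ND1", "NE2"), HSP = c("ND1", "NE2"))
.ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                      SEP = c("O1P", "O2P", "O3P", "OP1", "OP2", "OP3", "OG"),
                      TPO = c("O1P", "O2P", "O3P", "OP1", "OP2", "OP3", "OG1"),
                      PTR = c("O1P", "O2P", "O3P", "OP1", "OP2", "OP3", "OH"))

.RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

#' Reference a residue by chain and number
#' @param chain chain identifier.
#' @param resid author residue number.
#' @export
residue_ref <- function(chain, resid) {
  structure(list(chain = as.character(chain), resid = as.integer(resid)),
            class = "ResidueRef")
}

#' @export
format.ResidueRef <- function(x, ...) paste0(x$chain, ":", x$resid)

.res_info <- function(top, ref) {
  idx <- .residue_atoms(top, ref$chain, ref$resid)
  list(idx = idx, resname = top$resname[idx[1]])
}

.min_pair_dist <- function(coords, idx_a, idx_b) {
  a <- coords[idx_a, , drop = FALSE]
  b <- coords[idx_b, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

#' Salt-bridge detector
#'
#' TRUE when the minimum distance between any basic side-chain nitrogen
#' (Lys NZ; Arg NE/NH1/NH2; His ND1/NE2) and any acidic or phospho
#' side-chain oxygen (Asp OD1/OD2; Glu OE1/OE2; pSer/pThr phosphate oxygens
#' and the bridging OG/OG1) is at or below the cutoff.
#'
#' @param frame a `Frame`.
#' @param res_basic,res_acidic `residue_ref()`s; chain-qualified, so the
#'   same residue number on two subunits is two distinct residues.
#' @param cutoff distance cutoff in Angstrom (default 4.0).
#' @return logical.
#' @export
detect_salt_bridge <- function(frame, res_basic, res_acidic, cutoff = 4.0) {
  stopifnot(cutoff > 0)
  top <- frame$topology
  a <- .res_info(top, res_basic)
  b <- .res_info(top, res_acidic)
  an <- .BASIC_ATOMS[[a$resname]]
  bn <- .ACIDIC_ATOMS[[b$resname]]
  if (is.null(an))
    stop("atom-set error: ", format(res_basic), " (", a$resname,
         ") is not a basic residue")
  if (is.null(bn))
    stop("atom-set error: ", format(res_acidic), " (", b$resname,
         ") is not an acidic/phospho residue")
  ia <- a$idx[top$name[a$idx] %in% an]
  ib <- b$idx[top$name[b$idx] %in% bn]
  if (length(ia) == 0L)
    stop("atom-set error: ", format(res_basic), " lacks atoms ",
         paste(an, collapse = "/"))
  if (length(ib) == 0L)
    stop("atom-set error: ", format(res_acidic), " lacks atoms ",
         paste(bn, collapse = "/"))
  .min_pair_dist(frame$coords, ia, ib) <= cutoff
}

#' Hydrophobic contact detector
#'
#' TRUE when the minimum distance between side-chain atoms of the two
#' residues is strictly below the cutoff. Hydrogens participate by default
#' (at 2.5 A a heavy-atom-only contact would be a near-clash); set
#' `include_hydrogens = FALSE` to restrict to heavy atoms.
#'
#' @param frame a `Frame`.
#' @param res_a,res_b `residue_ref()`s.
#' @param cutoff distance cutoff in Angstrom (default 2.5, strict `<`).
#' @param include_hydrogens include side-chain hydrogens?
#' @return logical.
#' @export
detect_hydrophobic <- function(frame, res_a, res_b, cutoff = 2.5,
                               include_hydrogens = TRUE) {
  stopifnot(cutoff > 0)
  top <- frame$topology
  ia <- .sidechain_atoms(top, res_a$chain, res_a$resid, include_hydrogens)
  ib <- .sidechain_atoms(top, res_b$chain, res_b$resid, include_hydrogens)
  if (length(ia) == 0L)
    stop("atom-set error: ", format(res_a), " has no side chain")
  if (length(ib) == 0L)
    stop("atom-set error: ", format(res_b), " has no side chain")
  .min_pair_dist(frame$coords, ia, ib) < cutoff
}

# Polar heavy atoms of a residue (N/O, including phosphate oxygens).
.polar_atoms <- function(top, idx) {
  idx[top$element[idx] %in% c("N", "O") & !top$is_hydrogen[idx]]
}

# Hydrogens covalently attached to heavy atom i (same residue, < 1.25 A).
.attached_h <- function(top, coords, i) {
  same_res <- which(top$chain == top$chain[i] & top$resid == top$resid[i] &
                    top$is_hydrogen)
  if (length(same_res) == 0L) return(integer(0))
  d <- sqrt(rowSums(sweep(coords[same_res, , drop = FALSE], 2,
                          coords[i, ])^2))
  same_res[d < 1.25]
}

# Hydrogen bond between heavy polar atoms i (on one partner) and j, using
# the donor-H-acceptor angle when an attached hydrogen exists on either
# side; with no hydrogens available the distance criterion alone decides.
.hbonded_pair <- function(top, coords, i, j, dist_cutoff, angle_min) {
  d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
  if (d > dist_cutoff) return(FALSE)
  if (is.null(angle_min)) return(TRUE)
  hi <- .attached_h(top, coords, i)
  hj <- .attached_h(top, coords, j)
  if (length(hi) + length(hj) == 0L) return(TRUE)
  ang <- function(donor, h, acceptor) {
    v1 <- coords[donor, ] - coords[h, ]
    v2 <- coords[acceptor, ] - coords[h, ]
    acos(min(1, max(-1, sum(v1 * v2) /
                      sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
  }
  any(vapply(hi, function(h) ang(i, h, j) >= angle_min, TRUE)) ||
    any(vapply(hj, function(h) ang(j, h, i) >= angle_min, TRUE))
}

# Is this water hydrogen-bonded to any polar atom of the residue?
.water_hbonded <- function(top, coords, water_idx, polar_idx,
                           dist_cutoff, angle_min) {
  wo <- water_idx[!top$is_hydrogen[water_idx]]
  for (i in wo) for (j in polar_idx)
    if (.hbonded_pair(top, coords, i, j, dist_cutoff, angle_min))
      return(TRUE)
  FALSE
}

#' Water-bridge detector
#'
#' TRUE when some single water molecule is simultaneously hydrogen-bonded
#' to polar atoms of both residues. The hydrogen-bond criterion is a
#' donor-acceptor heavy-atom distance of at most `dist_cutoff` and, when
#' hydrogens are present, a donor-H-acceptor angle of at least `angle_min`
#' degrees (`angle_min = NULL` disables the angular term).
#'
#' @param frame a `Frame` whose topology contains water molecules.
#' @param res_a,res_b `residue_ref()`s.
#' @param dist_cutoff heavy-atom distance cutoff in Angstrom.
#' @param angle_min minimum donor-H-acceptor angle (degrees) or `NULL`.
#' @return logical.
#' @export
detect_water_bridge <- function(frame, res_a, res_b, dist_cutoff = 3.5,
                                angle_min = 110) {
  top <- frame$topology
  waters <- which(top$is_water)
  if (length(waters) == 0L)
    stop("configuration error: topology contains no water molecules")
  pa <- .polar_atoms(top, .residue_atoms(top, res_a$chain, res_a$resid))
  pb <- .polar_atoms(top, .residue_atoms(top, res_b$chain, res_b$resid))
  if (length(pa) == 0L || length(pb) == 0L) return(FALSE)
  wkey <- paste(top$chain[waters], top$resid[waters])
  for (w in split(waters, wkey)) {
    if (.water_hbonded(top, frame$coords, w, pa, dist_cutoff, angle_min) &&
        .water_hbonded(top, frame$coords, w, pb, dist_cutoff, angle_min))
      return(TRUE)
  }
  FALSE
}

#' Direct hydrogen-bond detector
#'
#' TRUE when any polar-atom pair of the two residues satisfies the
#' hydrogen-bond criterion of [detect_water_bridge()].
#'
#' @inheritParams detect_water_bridge
#' @export
detect_hbond <- function(frame, res_a, res_b, dist_cutoff = 3.5,
                         angle_min = 110) {
  top <- frame$topology
  pa <- .polar_atoms(top, .residue_atoms(top, res_a$chain, res_a$resid))
  pb <- .polar_atoms(top, .residue_atoms(top, res_b$chain, res_b$resid))
  for (i in pa) for (j in pb)
    if (.hbonded_pair(top, frame$coords, i, j, dist_cutoff, angle_min))
      return(TRUE)
  FALSE
}

#' Pi-pi stacking detector
#'
#' TRUE when the aromatic ring centroids are within `centroid_cutoff` and
#' the ring planes are either near-parallel (angle at most
#' `parallel_max`) or T-shaped (angle within `t_shape_range`).
#'
#' @param frame a `Frame`.
#' @param res_a,res_b `residue_ref()`s to aromatic residues.
#' @param centroid_cutoff ring-centroid distance cutoff (Angstrom).
#' @param parallel_max maximum inter-plane angle for parallel stacking.
#' @param t_shape_range two-element range for T-shaped stacking (degrees).
#' @return logical.
#' @export
detect_pi_pi <- function(frame, res_a, res_b, centroid_cutoff = 5.5,
                         parallel_max = 30, t_shape_range = c(60, 90)) {
  top <- frame$topology
  ring <- function(ref) {
    info <- .res_info(top, ref)
    names_needed <- .RING_ATOMS[[info$resname]]
    if (is.null(names_needed))
      stop("atom-set error: ", format(ref), " (", info$resname,
           ") is not aromatic")
    idx <- info$idx[top$name[info$idx] %in% names_needed]
    if (length(idx) < 3L)
      stop("atom-set error: ", format(ref), " lacks ring atoms")
    xyz <- frame$coords[idx, , drop = FALSE]
    ctr <- colMeans(xyz)
    normal <- svd(sweep(xyz, 2, ctr))$v[, 3]
    list(centre = ctr, normal = normal)
  }
  ra <- ring(res_a); rb <- ring(res_b)
  if (sqrt(sum((ra$centre - rb$centre)^2)) > centroid_cutoff) return(FALSE)
  cosang <- abs(sum(ra$normal * rb$normal))
  ang <- acos(min(1, cosang)) * 180 / pi
  ang <= parallel_max || (ang >= t_shape_range[1] && ang <= t_shape_range[2])
}

#' Specify a contact to monitor
#'
#' @param res_a,res_b `residue_ref()`s (distinct).
#' @param kind one of `"salt_bridge"`, `"hydrophobic"`, `"hbond"`,
#'   `"pi_pi"`, `"water_bridge"`.
#' @param cutoff detector cutoff in Angstrom (`NULL` = the kind's default).
#' @param label optional display label.
#' @export
contact_spec <- function(res_a, res_b,
                         kind = c("salt_bridge", "hydrophobic", "hbond",
                                  "pi_pi", "water_bridge"),
                         cutoff = NULL, label = NULL) {
  kind <- match.arg(kind)
  if (res_a$chain == res_b$chain && res_a$resid == res_b$resid)
    stop("contact spec requires two distinct residues")
  if (is.null(cutoff))
    cutoff <- switch(kind, salt_bridge = 4.0, hydrophobic = 2.5,
                     hbond = 3.5, water_bridge = 3.5, pi_pi = 5.5)
  stopifnot(cutoff > 0)
  if (is.null(label))
    label <- paste0(format(res_a), "-", format(res_b), ":", kind)
  structure(list(res_a = res_a, res_b = res_b, kind = kind, cutoff = cutoff,
                 label = label), class = "ContactSpec")
}

.detect_contact <- function(frame, spec) {
  switch(spec$kind,
    salt_bridge = detect_salt_bridge(frame, spec$res_a, spec$res_b,
                                     spec$cutoff),
    hydrophobic = detect_hydrophobic(frame, spec$res_a, spec$res_b,
                                     spec$cutoff),
    hbond = detect_hbond(frame, spec$res_a, spec$res_b, spec$cutoff),
    water_bridge = detect_water_bridge(frame, spec$res_a, spec$res_b,
                                       spec$cutoff),
    pi_pi = detect_pi_pi(frame, spec$res_a, spec$res_b, spec$cutoff))
}

#' Contact occupancy and frequency over a trajectory
#'
#' Runs the spec's detector on every retained frame and reports the
#' percentage of frames with the contact present.
#'
#' @param traj a `Trajectory`.
#' @param spec a [contact_spec()].
#' @param exclude_ns equilibration cutoff in ns (default 250); `NULL`
#'   keeps all frames.
#' @return object of class `ContactSeries` with per-frame `occupancy`,
#'   `frequency_percent`, and provenance labels.
#' @export
contact_frequency <- function(traj, spec, exclude_ns = 250) {
  if (!is.null(exclude_ns) && exclude_ns > 0)
    traj <- exclude_equilibration(traj, exclude_ns)
  nf <- n_frames(traj)
  occ <- vapply(seq_len(nf), function(k) .detect_contact(get_frame(traj, k),
                                                         spec), TRUE)
  structure(list(spec = spec, occupancy = occ,
                 frequency_percent = 100 * mean(occ),
                 n_frames = nf, time_ns = traj$time_ns,
                 system_label = traj$system_label,
                 replica_index = traj$replica_index),
            class = "ContactSeries")
}

#' @export
print.ContactSeries <- function(x, ...) {
  cat(sprintf("<ContactSeries> %s %s replica %d: %.1f%% of %d frames\n",
              x$spec$label, x$system_label, x$replica_index,
              x$frequency_percent, x$n_frames))
  invisible(x)
}

#' Count replicas where a contact is persistent
#'
#' @param series_list list of `ContactSeries`, one per replica, all for the
#'   same contact spec.
#' @param threshold_percent persistence threshold; a replica counts when its
#'   frequency is strictly above it (default 30).
#' @return integer count in `0..length(series_list)`.
#' @export
replica_heatmap <- function(series_list, threshold_percent = 30) {
  stopifnot(length(series_list) >= 1L)
  labels <- vapply(series_list, function(s) s$spec$label, "")
  if (length(unique(labels)) != 1L)
    stop("aggregation error: series are for different contact specs")
  sum(vapply(series_list, function(s) s$frequency_percent, 0) >
        threshold_percent)
}

#' Cross-system contact-frequency table
#'
#' Computes each spec's pooled frequency per system (replica occupancies
#' concatenated) and optionally keeps only the specs whose frequency range
#' across systems exceeds `min_reporting_delta` percentage points, the
#' convention for reporting only system-discriminating interactions.
#'
#' @param trajs_by_system named list: system label -> `Trajectory` or list
#'   of replica `Trajectory`s.
#' @param specs list of [contact_spec()]s.
#' @param min_reporting_delta minimum max-min spread (points) for a spec to
#'   be retained; `0` reports all.
#' @param exclude_ns equilibration cutoff in ns.
#' @return data.frame with `contact`, `kind`, one column per system, and
#'   `delta`.
#' @export
interaction_table <- function(trajs_by_system, specs,
                              min_reporting_delta = 20, exclude_ns = 250) {
  stopifnot(length(names(trajs_by_system)) == length(trajs_by_system))
  if (inherits(specs, "ContactSpec")) specs <- list(specs)
  rows <- lapply(specs, function(sp) {
    freqs <- vapply(trajs_by_system, function(trs) {
      if (inherits(trs, "Trajectory")) trs <- list(trs)
      occ <- unlist(lapply(trs, function(tr)
        contact_frequency(tr, sp, exclude_ns)$occupancy))
      100 * mean(occ)
    }, 0)
    c(freqs, delta = max(freqs) - min(freqs))
  })
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- cbind(data.frame(contact = vapply(specs, function(s) s$label, ""),
                          kind = vapply(specs, function(s) s$kind, ""),
                          stringsAsFactors = FALSE), tab)
  if (min_reporting_delta <= 0) tab       # filter disabled
  else tab[tab$delta > min_reporting_delta, , drop = FALSE]
}
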