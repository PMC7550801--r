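# Seeded synthetic-trajectory generators with analytic ground truth.
#
# These stand in for (undeposited) production MD data: a hinged
# pseudo-kinase whose apex angle follows a mean-reverting process, a
# two-subunit dimer with scripted twist/translation schedules and bridging
# pseudo-waters, a Bernoulli contact pair, and isotropic jitter replicas.
# Every generator is a pure function of (parameters, seed), and ground
# truth is returned alongside the trajectory, never embedded in it.

# --- internal peptide builder (NeRF chain extension) -----------------------

# Place atom d at distance/angle/dihedral from reference atoms a-b-c.
.place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an idealised peptide backbone
#'
#' Constructs an all-alanine backbone (N, CA, C, O) from per-residue
#' phi/psi dihedrals using ideal bond lengths and angles, the standard
#' internal-coordinate chain extension. An ideal alpha-helix corresponds to
#' `phi = -57`, `psi = -47`; a fully extended chain to `phi = psi = 180`.
#'
#' @param n_residues number of residues.
#' @param phi,psi backbone dihedrals in degrees (recycled to length
#'   `n_residues`).
#' @param chain chain identifier.
#' @param start_resid first author residue number.
#' @param resname residue code used for every residue.
#' @return a one-frame `Trajectory`.
#' @export
build_peptide <- function(n_residues, phi = -57, psi = -47, chain = "A",
                          start_resid = 1L, resname = "ALA") {
  stopifnot(n_residues >= 2L)
  phi <- rep_len(phi, n_residues)
  psi <- rep_len(psi, n_residues)
  b_NCA <- 1.458; b_CAC <- 1.525; b_CN <- 1.329; b_CO <- 1.231
  a_NCAC <- 111.2; a_CACN <- 116.2; a_CNCA <- 121.7; a_CACO <- 120.8
  omega <- 180
  coords <- matrix(NA_real_, nrow = n_residues * 4L, ncol = 3L)
  # seed atoms of residue 1
  coords[1, ] <- c(0, 0, 0)                               # N
  coords[2, ] <- c(b_NCA, 0, 0)                           # CA
  ang <- a_NCAC * pi / 180
  coords[3, ] <- coords[2, ] + b_CAC * c(-cos(ang), sin(ang), 0)  # C
  row <- function(i, what) (i - 1L) * 4L +
    match(what, c("N", "CA", "C", "O"))
  for (i in seq_len(n_residues)) {
    if (i > 1L) {
      coords[row(i, "N"), ] <- .place_atom(
        coords[row(i - 1L, "N"), ], coords[row(i - 1L, "CA"), ],
        coords[row(i - 1L, "C"), ], b_CN, a_CACN, psi[i - 1L])
      coords[row(i, "CA"), ] <- .place_atom(
        coords[row(i - 1L, "CA"), ], coords[row(i - 1L, "C"), ],
        coords[row(i, "N"), ], b_NCA, a_CNCA, omega)
      coords[row(i, "C"), ] <- .place_atom(
        coords[row(i - 1L, "C"), ], coords[row(i, "N"), ],
        coords[row(i, "CA"), ], b_CAC, a_NCAC, phi[i])
    }
    # carbonyl O: in the peptide plane, anti to the next amide nitrogen
    ref_dih <- if (i < n_residues) psi[i] + 180 else psi[i] + 180
    coords[row(i, "O"), ] <- .place_atom(
      coords[row(i, "N"), ], coords[row(i, "CA"), ], coords[row(i, "C"), ],
      b_CO, a_CACO, ref_dih)
  }
  top <- atom_table(seq_len(n_residues * 4L),
                    rep(c("N", "CA", "C", "O"), n_residues),
                    rep(resname, n_residues * 4L),
                    rep(seq(start_resid, length.out = n_residues), each = 4L),
                    rep(chain, n_residues * 4L))
  new_trajectory(top, coords, time_ns = 0)
}

# Rigid helix segment re-centred at a target cog.
.segment_at <- function(n_res, start_resid, chain, at, axis = c(0, 0, 1)) {
  seg <- build_peptide(n_res, chain = chain, start_resid = start_resid)
  xyz <- seg$coords[, , 1]
  xyz <- sweep(xyz, 2, colMeans(xyz))
  # orient the helix axis (first principal direction) along `axis`
  v1 <- svd(xyz)$v[, 1]
  axis <- axis / sqrt(sum(axis^2))
  rot <- .rotation_between(v1, axis)
  xyz <- xyz %*% t(rot)
  list(topology = seg$topology, coords = sweep(xyz, 2, at, "+"))
}

# Rotation matrix sending unit vector a to unit vector b.
.rotation_between <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (abs(cth + 1) < 1e-12) return(diag(c(-1, -1, 1)))   # antiparallel
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

.rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

.rot_x <- function(deg) {
  th <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
}

# Ornstein-Uhlenbeck (AR(1)) sample path around theta0.
.ou_path <- function(n, theta0, reversion, noise, dt) {
  th <- numeric(n)
  th[1] <- theta0
  if (n > 1L) for (k in 2:n)
    th[k] <- th[k - 1L] + reversion * (theta0 - th[k - 1L]) * dt +
      noise * sqrt(dt) * stats::rnorm(1)
  th
}

#' Hinged pseudo-kinase trajectory with known apex angle
#'
#' Builds a three-segment pseudo-protein on chain A using the canonical
#' kinase residue numbering (activation segment helix 250-264, alphaC-helix
#' 139-154, hinge 179-182, plus a static scaffold) and rotates the ASH
#' segment rigidly about an axis through the hinge cog so that the
#' apex angle measured by [segment_angle()] with the default
#' [angle_definition()] equals, frame by frame, a mean-reverting
#' (Ornstein-Uhlenbeck) sample path around `theta0`.
#'
#' Defaults emulate the observed phenomenology of activation-segment
#' bending: sustained fluctuation around a shifted mean far from the
#' crystal reference, on a 1 ns frame grid.
#'
#' @param theta0 stationary mean angle (degrees).
#' @param reversion mean-reversion rate (1/ns).
#' @param noise noise amplitude (degrees / sqrt(ns)); `0` gives a
#'   noiseless constant-angle trajectory.
#' @param n_frames number of frames.
#' @param frame_dt_ns frame spacing (ns).
#' @param seed RNG seed (mandatory: generators are seeded by contract).
#' @param system_label,replica_index trajectory metadata.
#' @return list with `trajectory`, `angles` (ground-truth degrees per
#'   frame), and `definition` (the matching [angle_definition()]).
#' @export
make_hinged_trajectory <- function(theta0 = 40, reversion = 0.5, noise = 2,
                                   n_frames = 1500, frame_dt_ns = 1,
                                   seed, system_label = "hinged",
                                   replica_index = 1L) {
  if (n_frames <= 0L) stop("n_frames must be positive")
  set.seed(seed)
  d <- 20
  hinge <- .segment_at(4L, 179L, "A", at = c(0, 0, 0))
  alpha_c <- .segment_at(16L, 139L, "A", at = c(d, 0, 0))
  ash0 <- .segment_at(15L, 250L, "A", at = c(d, 0, 0))
  scaffold <- .segment_at(10L, 300L, "A", at = c(0, -30, 0))
  top <- rbind(hinge$topology, alpha_c$topology, ash0$topology,
               scaffold$topology)
  top$serial <- seq_len(nrow(top))
  angles <- .ou_path(n_frames, theta0, reversion, noise, frame_dt_ns)
  angles <- pmin(179, pmax(1, angles))
  static <- rbind(hinge$coords, alpha_c$coords)
  coords <- array(NA_real_, dim = c(nrow(top), 3L, n_frames))
  for (k in seq_len(n_frames)) {
    ash_k <- ash0$coords %*% t(.rot_z(angles[k]))
    coords[, , k] <- rbind(static, ash_k, scaffold$coords)
  }
  traj <- new_trajectory(top, coords,
                         time_ns = (seq_len(n_frames) - 1) * frame_dt_ns,
                         system_label = system_label,
                         replica_index = replica_index)
  list(trajectory = traj, angles = angles,
       definition = angle_definition(chain = "A"))
}

# one toy kinase subunit: named rigid segments at fixed body positions
.toy_subunit <- function(chain) {
  segs <- list(
    n_lobe   = .segment_at(29L, 102L, chain, at = c(10, 0, 0)),
    seg_164  = .segment_at(5L, 164L, chain, at = c(12, 6, 4)),
    alpha_c  = .segment_at(16L, 139L, chain, at = c(14, -10, 0)),
    hinge    = .segment_at(4L, 179L, chain, at = c(2, -6, 0)),
    ash      = .segment_at(15L, 250L, chain, at = c(25, -8, 0),
                           axis = c(0, 1, 0)),
    alpha_f  = .segment_at(17L, 286L, chain, at = c(5, -20, 0)))
  top <- do.call(rbind, lapply(segs, `[[`, "topology"))
  rownames(top) <- NULL
  list(topology = top, coords = do.call(rbind, lapply(segs, `[[`, "coords")))
}

#' Two-subunit dimer trajectory with scripted twist and translation
#'
#' Subunit A is a toy kinase (segments at the canonical residue numbers);
#' subunit B is its copy rotated 180 degrees about the z-axis through the
#' interface centre `(25, 0, 0)`, so at zero schedules the dimer is exactly
#' symmetric and static. Per frame, subunit B is rotated by
#' `twist_schedule` degrees about the interface normal (the x-axis, which
#' passes through both N-lobe cogs) and translated by
#' `translation_schedule` nm along it; both schedules are returned as
#' ground truth. The N-lobe cogs sit on the twist/translation axis and the
#' ASH cogs sit at equal x on opposite sides of it, so translation moves
#' the N-lobe distance one-for-one while touching the ASH distance only at
#' second order, and twist leaves the N-lobe distance unchanged.
#' Optional bridging pseudo-waters are placed midway between the ASH cogs.
#'
#' @param twist_schedule degrees per frame (scalar or vector).
#' @param translation_schedule nm per frame (scalar or vector).
#' @param n_frames number of frames (default: schedule length).
#' @param frame_dt_ns frame spacing (ns).
#' @param n_waters bridging waters to add at the interface.
#' @param system_label trajectory metadata.
#' @return list with `trajectory`, `twist` (degrees), `translation` (nm),
#'   and `geometry` (named cog positions of subunit A/B segments at
#'   frame 1).
#' @export
make_dimer_trajectory <- function(twist_schedule = 0,
                                  translation_schedule = 0,
                                  n_frames = NULL, frame_dt_ns = 1,
                                  n_waters = 0L, system_label = "dimer") {
  if (is.null(n_frames))
    n_frames <- max(length(twist_schedule), length(translation_schedule))
  twist <- rep_len(twist_schedule, n_frames)
  transl <- rep_len(translation_schedule, n_frames)
  sa <- .toy_subunit("A")
  sb <- .toy_subunit("B")
  if (any(sa$topology$chain == sb$topology$chain[1]))
    stop("overlapping chain identifiers between subunits")
  centre <- c(25, 0, 0)
  # rigid 180-degree rotation about z through the interface centre
  flip <- function(x) sweep(sweep(x, 2, centre) %*% t(.rot_z(180)), 2,
                            centre, "+")
  sb$coords <- flip(sb$coords)
  tops <- rbind(sa$topology, sb$topology)
  if (n_waters > 0L) {
    wy <- seq(-2, 2, length.out = n_waters)
    wat_xyz <- do.call(rbind, lapply(seq_len(n_waters), function(i) {
      o <- c(25, wy[i], 3)
      rbind(o, o + c(0.76, 0.59, 0), o + c(-0.76, 0.59, 0))
    }))
    wat_top <- atom_table(seq_len(3L * n_waters),
                          rep(c("O", "H1", "H2"), n_waters),
                          rep("HOH", 3L * n_waters),
                          rep(seq_len(n_waters) + 900L, each = 3L),
                          rep("W", 3L * n_waters))
    tops <- rbind(tops, wat_top)
  } else wat_xyz <- NULL
  tops$serial <- seq_len(nrow(tops))
  coords <- array(NA_real_, dim = c(nrow(tops), 3L, n_frames))
  for (k in seq_len(n_frames)) {
    bk <- sweep(sweep(sb$coords, 2, centre) %*% t(.rot_x(twist[k])), 2,
                centre, "+")
    bk <- sweep(bk, 2, c(10 * transl[k], 0, 0), "+")
    coords[, , k] <- rbind(sa$coords, bk, wat_xyz)
  }
  traj <- new_trajectory(tops, coords,
                         time_ns = (seq_len(n_frames) - 1) * frame_dt_ns,
                         system_label = system_label)
  geometry <- list(
    n_lobe_A = c(10, 0, 0), n_lobe_B = c(40, 0, 0),
    ash_A = c(25, -8, 0), ash_B = c(25, 8, 0),
    alpha_f_A = c(5, -20, 0), alpha_f_B = c(45, 20, 0),
    centre = centre)
  list(trajectory = traj, twist = twist, translation = transl,
       geometry = geometry)
}

#' Bernoulli contact-pair trajectory
#'
#' A lysine/glutamate pseudo-pair whose charged atoms sit at
#' `bonded_distance` (default 3.0 A, inside the salt-bridge cutoff) on
#' frames drawn TRUE and `unbonded_distance` (6.0 A) otherwise, by seeded
#' Bernoulli draws with occupancy `p`. The realised draw vector is the
#' ground truth; a distance detector must reproduce it exactly.
#'
#' @param p contact probability per frame, in `[0, 1]`.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param frame_dt_ns frame spacing (ns).
#' @param bonded_distance,unbonded_distance NZ-OE1 distances (Angstrom).
#' @param system_label,replica_index trajectory metadata.
#' @return list with `trajectory`, `occupancy` (logical ground truth), and
#'   `spec` (the matching salt-bridge [contact_spec()]).
#' @export
make_contact_trajectory <- function(p, n_frames = 1500, seed,
                                    frame_dt_ns = 1,
                                    bonded_distance = 3.0,
                                    unbonded_distance = 6.0,
                                    system_label = "contact",
                                    replica_index = 1L) {
  stopifnot(p >= 0, p <= 1)
  set.seed(seed)
  occ <- stats::runif(n_frames) < p
  # LYS 260 side chain (NZ) vs GLU 144 side chain (OE1/OE2); backbone-complete
  lys_names <- c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ")
  glu_names <- c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2")
  top <- atom_table(seq_len(18L), c(lys_names, glu_names),
                    rep(c("LYS", "GLU"), each = 9L),
                    rep(c(260L, 144L), each = 9L), rep("A", 18L))
  base <- rbind(
    # LYS: extended side chain along +x, NZ at origin end
    cbind(seq(-8, 0, length.out = 9), 0, 0),
    # GLU: mirrored on the other side; OE1 at x = d, OE2 slightly beyond
    cbind(c(seq(14, 8, length.out = 7), 6, 7), c(rep(0, 7), 0, 1.2), 0))
  coords <- array(NA_real_, dim = c(18L, 3L, n_frames))
  for (k in seq_len(n_frames)) {
    d <- if (occ[k]) bonded_distance else unbonded_distance
    xyz <- base
    xyz[10:18, 1] <- base[10:18, 1] + (d - 6)   # shift GLU so NZ-OE1 = d
    coords[, , k] <- xyz
  }
  traj <- new_trajectory(top, coords,
                         time_ns = (seq_len(n_frames) - 1) * frame_dt_ns,
                         system_label = system_label,
                         replica_index = replica_index)
  list(trajectory = traj, occupancy = occ,
       spec = contact_spec(residue_ref("A", 260), residue_ref("A", 144),
                           "salt_bridge"))
}

#' Isotropic jitter replicas of a rigid body
#'
#' Adds independent Gaussian displacement (`sigma` per coordinate) to every
#' atom of `base` in every frame, independently per replica. For a large
#' rigid body the per-atom fluctuation converges to the closed form
#' `sigma * sqrt(3)` (0.0866 nm at sigma = 0.5 A), which pins the RMSF
#' implementation.
#'
#' @param base a `Frame` or one-frame `Trajectory` giving the rigid body.
#' @param sigma Gaussian displacement per coordinate (Angstrom).
#' @param n_replicas number of replicas.
#' @param n_frames frames per replica.
#' @param seed base RNG seed; replica r uses `seed + r - 1`.
#' @param frame_dt_ns frame spacing (ns).
#' @param system_label trajectory metadata.
#' @return list of `Trajectory`s (replica indices 1..n_replicas).
#' @export
make_jitter_replicas <- function(base, sigma = 0.5, n_replicas = 5L,
                                 n_frames = 2000L, seed, frame_dt_ns = 1,
                                 system_label = "jitter") {
  stopifnot(sigma >= 0)
  if (inherits(base, "Trajectory")) base <- get_frame(base, 1L)
  na <- nrow(base$topology)
  lapply(seq_len(n_replicas), function(r) {
    set.seed(seed + r - 1L)
    noise <- array(stats::rnorm(na * 3L * n_frames, sd = sigma),
                   dim = c(na, 3L, n_frames))
    coords <- array(base$coords, dim = c(na, 3L, n_frames)) + noise
    new_trajectory(base$topology, coords,
                   time_ns = (seq_len(n_frames) - 1) * frame_dt_ns,
                   system_label = system_label, replica_index = r)
  })
}
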