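# Core geometric statistics: centre of geometry, apex angles, cog-cog
# distances, rigid-body superposition (Kabsch), RMSD/RMSF and their replica
# aggregation, equilibration exclusion, and 1.5*IQR boxplot summaries.
#
# Internal unit is Angstrom (native to PDB); distances, RMSD and RMSF are
# *reported* in nm, angles in degrees.

#' Centre of geometry
#'
#' Unweighted arithmetic mean of a point set (no mass weighting).
#'
#' @param points numeric `n x 3` matrix.
#' @return numeric length-3 position.
#' @export
centre_of_geometry <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("empty selection: no points for cog")
  if (any(!is.finite(points))) stop("non-finite coordinates in cog input")
  colMeans(points)
}

.cog_of_selection <- function(frame, sel) {
  centre_of_geometry(frame$coords[resolve_selection(frame, sel), , drop = FALSE])
}

#' Define a cog apex angle
#'
#' The angle is measured at the vertex segment's centre of geometry, between
#' rays pointing to the cogs of `ray_a` and `ray_b`. Defaults are the
#' activation-segment-helix / hinge / alphaC-helix triple on chain A, the
#' metric used to track activation-segment bending relative to the stable
#' kinase core.
#'
#' @param ray_a,vertex,ray_b `SegmentSelection`s; pairwise distinct.
#' @param chain convenience: chain used for the default selections.
#' @return object of class `AngleDefinition`.
#' @export
angle_definition <- function(ray_a = NULL, vertex = NULL, ray_b = NULL,
                             chain = "A") {
  defs <- default_selections(chain)
  if (is.null(ray_a)) ray_a <- defs$ash
  if (is.null(vertex)) vertex <- defs$hinge
  if (is.null(ray_b)) ray_b <- defs$alpha_c
  key <- vapply(list(ray_a, vertex, ray_b), format, "")
  if (anyDuplicated(key))
    stop("angle definition requires three pairwise distinct selections")
  structure(list(ray_a = ray_a, vertex = vertex, ray_b = ray_b),
            class = "AngleDefinition")
}

#' Apex angle of one frame
#'
#' @param frame a `Frame`.
#' @param defn an [angle_definition()].
#' @return angle in degrees, in `[0, 180]`.
#' @export
segment_angle <- function(frame, defn) {
  stopifnot(inherits(defn, "AngleDefinition"))
  a <- .cog_of_selection(frame, defn$ray_a)
  v <- .cog_of_selection(frame, defn$vertex)
  b <- .cog_of_selection(frame, defn$ray_b)
  u1 <- a - v; u2 <- b - v
  n1 <- sqrt(sum(u1^2)); n2 <- sqrt(sum(u2^2))
  if (n1 < 1e-9 || n2 < 1e-9)
    stop("degenerate geometry: coincident centres of geometry")
  cosang <- sum(u1 * u2) / (n1 * n2)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Per-frame metric series
#'
#' Container for a per-frame scalar (angle or distance) with system/replica
#' labels, supporting equilibration exclusion and replica pooling.
#'
#' @param values numeric per-frame values.
#' @param time_ns frame times (ns).
#' @param unit `"degrees"` or `"nm"`.
#' @param system_label,replica_index provenance labels.
#' @param equilibration_excluded whether the initial segment was dropped.
#' @export
metric_series <- function(values, time_ns, unit = c("degrees", "nm", "percent"),
                          system_label = "system", replica_index = 1L,
                          equilibration_excluded = FALSE) {
  unit <- match.arg(unit)
  stopifnot(length(values) == length(time_ns))
  if (unit == "degrees" && length(values) &&
      (min(values) < -1e-9 || max(values) > 180 + 1e-9))
    stop("degree values must lie in [0, 180]")
  structure(list(values = as.numeric(values), time_ns = as.numeric(time_ns),
                 unit = unit, system_label = system_label,
                 replica_index = as.integer(replica_index),
                 equilibration_excluded = isTRUE(equilibration_excluded)),
            class = "MetricSeries")
}

#' @export
print.MetricSeries <- function(x, ...) {
  cat(sprintf("<MetricSeries> %s replica %d: %d frames [%s]%s\n",
              x$system_label, x$replica_index, length(x$values), x$unit,
              if (x$equilibration_excluded) " (equilibration excluded)" else ""))
  invisible(x)
}

#' @export
as.data.frame.MetricSeries <- function(x, ...) {
  data.frame(system = x$system_label, replica = x$replica_index,
             frame = seq_along(x$values), time_ns = x$time_ns,
             value = x$values, stringsAsFactors = FALSE)
}

#' Apex-angle series over a trajectory
#'
#' @param traj a `Trajectory`.
#' @param defn an [angle_definition()].
#' @param exclude_ns drop frames before this time (ns); `NULL` keeps all.
#' @return a `MetricSeries` in degrees.
#' @export
angle_series <- function(traj, defn, exclude_ns = NULL) {
  if (!is.null(exclude_ns)) traj <- exclude_equilibration(traj, exclude_ns)
  ia <- resolve_selection(traj, defn$ray_a)
  iv <- resolve_selection(traj, defn$vertex)
  ib <- resolve_selection(traj, defn$ray_b)
  nf <- n_frames(traj)
  vals <- vapply(seq_len(nf), function(k) {
    xyz <- traj$coords[, , k]
    a <- colMeans(xyz[ia, , drop = FALSE])
    v <- colMeans(xyz[iv, , drop = FALSE])
    b <- colMeans(xyz[ib, , drop = FALSE])
    u1 <- a - v; u2 <- b - v
    cosang <- sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))
    acos(min(1, max(-1, cosang))) * 180 / pi
  }, 0)
  metric_series(vals, traj$time_ns, "degrees", traj$system_label,
                traj$replica_index, !is.null(exclude_ns))
}

#' Interval-shift validation of the apex angle
#'
#' Recomputes the angle with the `ray_a` residue interval slid within
#' itself and returns `angle(shifted) - angle(reference)` per frame. A
#' negative `shift` truncates the C-terminal end (window slides toward the
#' N-terminus, e.g. 250-264 -> 250-259 at `shift = -5`); a positive `shift`
#' truncates the N-terminal end (250-264 -> 255-264 at `shift = +5`).
#'
#' @param x a `Trajectory` or `Frame`.
#' @param defn an [angle_definition()].
#' @param shift signed residue count.
#' @return numeric deviation per frame (degrees); scalar for a `Frame`.
#' @export
interval_shift_validation <- function(x, defn, shift) {
  shift <- as.integer(shift)
  sel <- defn$ray_a
  new_sel <- if (shift >= 0L)
    segment_selection(sel$chain_id, sel$start_residue + shift,
                      sel$end_residue, sel$atom_subset)
  else
    segment_selection(sel$chain_id, sel$start_residue,
                      sel$end_residue + shift, sel$atom_subset)
  defn2 <- angle_definition(new_sel, defn$vertex, defn$ray_b)
  if (inherits(x, "Frame"))
    return(segment_angle(x, defn2) - segment_angle(x, defn))
  angle_series(x, defn2)$values - angle_series(x, defn)$values
}

#' Distance between two selection cogs
#'
#' @param frame a `Frame`.
#' @param sel_a,sel_b `SegmentSelection`s.
#' @return distance in nm.
#' @export
cog_distance <- function(frame, sel_a, sel_b) {
  a <- .cog_of_selection(frame, sel_a)
  b <- .cog_of_selection(frame, sel_b)
  sqrt(sum((a - b)^2)) / 10
}

#' Cog-cog distance series over a trajectory
#'
#' @inheritParams cog_distance
#' @param traj a `Trajectory`.
#' @param exclude_ns drop frames before this time (ns); `NULL` keeps all.
#' @return a `MetricSeries` in nm.
#' @export
distance_series <- function(traj, sel_a, sel_b, exclude_ns = NULL) {
  if (!is.null(exclude_ns)) traj <- exclude_equilibration(traj, exclude_ns)
  ia <- resolve_selection(traj, sel_a)
  ib <- resolve_selection(traj, sel_b)
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    xyz <- traj$coords[, , k]
    d <- colMeans(xyz[ia, , drop = FALSE]) - colMeans(xyz[ib, , drop = FALSE])
    sqrt(sum(d^2)) / 10
  }, 0)
  metric_series(vals, traj$time_ns, "nm", traj$system_label,
                traj$replica_index, !is.null(exclude_ns))
}

# Optimal rotation (Kabsch, via SVD) mapping centred mob onto centred ref.
.kabsch_rotation <- function(mob, ref) {
  h <- crossprod(mob, ref)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Rigid-body superposition
#'
#' Least-squares fit of `mobile` onto `reference` over `fit_selection`
#' (Kabsch algorithm); the transform is applied to all atoms of `mobile`.
#'
#' @param mobile,reference `Frame`s sharing the fit selection's atom layout.
#' @param fit_selection a `SegmentSelection`, a list of them, or `NULL`
#'   (all atoms).
#' @return list with `frame` (fitted `Frame`), `rotation` (3x3), and
#'   `translation` (length 3), such that
#'   `fitted = (x - centroid_mob) %*% rotation + centroid_ref`.
#' @export
superpose <- function(mobile, reference, fit_selection = NULL) {
  idx_m <- .selection_indices(mobile, fit_selection)
  idx_r <- .selection_indices(reference, fit_selection)
  if (length(idx_m) != length(idx_r))
    stop("fit selection resolves to different atom counts")
  m <- mobile$coords[idx_m, , drop = FALSE]
  r <- reference$coords[idx_r, , drop = FALSE]
  if (nrow(m) < 3L) stop("underdetermined fit: fewer than 3 fit atoms")
  cm <- colMeans(m); cr <- colMeans(r)
  mc <- sweep(m, 2, cm); rc <- sweep(r, 2, cr)
  if (sum(svd(mc)$d > 1e-8) < 2L)
    stop("underdetermined fit: fit atoms are collinear")
  rot <- .kabsch_rotation(mc, rc)
  fitted <- sweep(sweep(mobile$coords, 2, cm) %*% rot, 2, cr, "+")
  list(frame = new_frame(mobile$topology, fitted, mobile$time_ns,
                         mobile$frame_index),
       rotation = rot, translation = cr - cm %*% rot)
}

.selection_indices <- function(x, selection) {
  top <- .topology(x)
  if (is.null(selection)) return(seq_len(nrow(top)))
  if (inherits(selection, "SegmentSelection")) selection <- list(selection)
  sort(unique(unlist(lapply(selection, resolve_selection, x = x))))
}

# RMSD between two coordinate blocks, in Angstrom.
.rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame RMSD series
#'
#' RMSD of the selected atoms from a reference frame, optionally after
#' rigid-body superposition on the same selection. Reported in nm;
#' defaults to Calpha atoms.
#'
#' @param traj a `Trajectory`.
#' @param reference a `Frame` (defaults to the first frame of `traj`).
#' @param selection `SegmentSelection`(s) or `NULL` = all Calpha atoms.
#' @param fit superpose each frame on the reference first?
#' @param exclude_ns drop frames before this time (ns); `NULL` keeps all.
#' @return a `MetricSeries` in nm.
#' @export
rmsd_series <- function(traj, reference = NULL, selection = NULL, fit = TRUE,
                        exclude_ns = NULL) {
  if (!is.null(exclude_ns)) traj <- exclude_equilibration(traj, exclude_ns)
  if (is.null(reference)) reference <- get_frame(traj, 1L)
  idx <- if (is.null(selection))
    which(traj$topology$name == "CA" & !traj$topology$is_hydrogen)
  else .selection_indices(traj, selection)
  if (length(idx) == 0L) stop("empty selection for RMSD")
  ridx <- if (is.null(selection))
    which(reference$topology$name == "CA" & !reference$topology$is_hydrogen)
  else .selection_indices(reference, selection)
  ref <- reference$coords[ridx, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    m <- .frame_mat(traj$coords, idx, k)
    if (fit) {
      cm <- colMeans(m); cr <- colMeans(ref)
      mc <- sweep(m, 2, cm)
      rot <- .kabsch_rotation(mc, sweep(ref, 2, cr))
      m <- sweep(mc %*% rot, 2, cr, "+")
    }
    .rmsd(m, ref) / 10
  }, 0)
  metric_series(vals, traj$time_ns, "nm", traj$system_label,
                traj$replica_index, !is.null(exclude_ns))
}

#' Per-residue RMSF with replica aggregation
#'
#' For each replica, every frame is superposed on the replica's mean
#' structure (computed by one re-fit iteration: fit to the first frame,
#' average, re-fit the original frames to that mean), atomic RMSF is the
#' root-mean-square displacement about the mean position, and a residue's
#' value is the mean over its selected atoms. Across replicas the
#' arithmetic mean and standard deviation are reported, the convention used
#' for multi-replica fluctuation profiles.
#'
#' @param replicas a `Trajectory` or list of `Trajectory`s sharing one
#'   topology.
#' @param selection atoms to report on: `SegmentSelection`(s) or `NULL` =
#'   all backbone atoms.
#' @param fit_selection atoms used for superposition (default: `selection`).
#' @param exclude_ns drop frames before this time (ns); `NULL` keeps all.
#' @return list with `residues` (data.frame chain/resid/resname),
#'   `per_replica` (residues x replicas matrix, nm), `mean` and `sd`
#'   (numeric vectors, nm).
#' @export
rmsf_per_residue <- function(replicas, selection = NULL,
                             fit_selection = NULL, exclude_ns = NULL) {
  if (inherits(replicas, "Trajectory")) replicas <- list(replicas)
  stopifnot(length(replicas) >= 1L)
  top0 <- replicas[[1]]$topology
  for (r in replicas)
    if (!identical(dim(r$topology), dim(top0)) ||
        !identical(r$topology$name, top0$name))
      stop("topology error: replicas do not share a topology")
  idx <- if (is.null(selection)) which(top0$is_backbone)
  else .selection_indices(top0, selection)
  if (length(idx) == 0L) stop("empty selection for RMSF")
  fidx <- if (is.null(fit_selection)) idx
  else .selection_indices(top0, fit_selection)
  res_key <- paste(top0$chain[idx], top0$resid[idx], sep = ":")
  res_levels <- unique(res_key)
  per_rep <- matrix(NA_real_, nrow = length(res_levels),
                    ncol = length(replicas))
  for (r in seq_along(replicas)) {
    traj <- replicas[[r]]
    if (!is.null(exclude_ns)) traj <- exclude_equilibration(traj, exclude_ns)
    fitted <- .fit_to_mean(traj$coords, fidx)
    sel_coords <- fitted[idx, , , drop = FALSE]
    mean_pos <- apply(sel_coords, c(1, 2), mean)
    disp2 <- sweep(sel_coords, c(1, 2), mean_pos)^2
    atom_rmsf <- sqrt(apply(disp2, 1, mean) * 3)  # mean over dims*frames * 3
    per_rep[, r] <- tapply(atom_rmsf, factor(res_key, levels = res_levels),
                           mean) / 10
  }
  first <- match(res_levels, res_key)
  residues <- data.frame(chain = top0$chain[idx][first],
                         resid = top0$resid[idx][first],
                         resname = top0$resname[idx][first],
                         stringsAsFactors = FALSE)
  list(residues = residues, per_replica = per_rep,
       mean = rowMeans(per_rep),
       sd = apply(per_rep, 1, stats::sd))
}

# Superpose all frames on the ensemble mean (one re-fit iteration).
.fit_to_mean <- function(coords, fit_idx) {
  nf <- dim(coords)[3]
  fit_once <- function(stack, ref) {
    rc <- sweep(ref, 2, colMeans(ref))
    out <- stack
    for (k in seq_len(nf)) {
      m <- stack[, , k]
      cm <- colMeans(m[fit_idx, , drop = FALSE])
      mc <- sweep(m, 2, cm)
      rot <- .kabsch_rotation(mc[fit_idx, , drop = FALSE], rc)
      out[, , k] <- sweep(mc %*% rot, 2, colMeans(ref), "+")
    }
    out
  }
  pass1 <- fit_once(coords, coords[fit_idx, , 1, drop = TRUE])
  mean1 <- apply(pass1[fit_idx, , , drop = FALSE], c(1, 2), mean)
  fit_once(coords, mean1)
}

#' Drop the equilibration segment
#'
#' Retains frames with `time_ns >= cutoff_ns` (the frame exactly at the
#' cutoff is kept). 250 ns is the conventional stabilisation window for
#' microsecond kinase runs and is the package-wide default.
#'
#' @param x a `Trajectory` or `MetricSeries`.
#' @param cutoff_ns cutoff time in ns.
#' @export
exclude_equilibration <- function(x, cutoff_ns = 250) {
  UseMethod("exclude_equilibration")
}

#' @export
exclude_equilibration.Trajectory <- function(x, cutoff_ns = 250) {
  keep <- x$time_ns >= cutoff_ns
  if (!any(keep)) stop("empty-series error: all frames before ", cutoff_ns,
                       " ns")
  new_trajectory(x$topology, x$coords[, , keep, drop = FALSE],
                 x$time_ns[keep], x$system_label, x$replica_index)
}

#' @export
exclude_equilibration.MetricSeries <- function(x, cutoff_ns = 250) {
  keep <- x$time_ns >= cutoff_ns
  if (!any(keep)) stop("empty-series error: all frames before ", cutoff_ns,
                       " ns")
  metric_series(x$values[keep], x$time_ns[keep], x$unit, x$system_label,
                x$replica_index, equilibration_excluded = TRUE)
}

#' Boxplot summary with 1.5*IQR whiskers
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7, the convention of the common plotting
#' stacks); whiskers reach the most extreme data point within
#' `1.5 * IQR` of the quartiles and outliers fall strictly beyond the
#' whiskers. Mean and standard deviation are reported alongside.
#'
#' @param x numeric vector, `MetricSeries`, or list of `MetricSeries`
#'   (pooled by concatenation, the all-replica pooling convention).
#' @return object of class `BoxplotSummary`.
#' @export
boxplot_summary <- function(x) {
  if (inherits(x, "MetricSeries")) x <- x$values
  if (is.list(x))
    x <- unlist(lapply(x, function(s)
      if (inherits(s, "MetricSeries")) s$values else s))
  x <- as.numeric(x)
  if (length(x) == 0L) stop("empty-series error: no values to summarise")
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- qs[3] - qs[1]
  lo_fence <- qs[1] - 1.5 * iqr
  hi_fence <- qs[3] + 1.5 * iqr
  inside <- x >= lo_fence & x <= hi_fence
  structure(list(median = qs[2], q1 = qs[1], q3 = qs[3], iqr = iqr,
                 whisker_low = min(x[inside]), whisker_high = max(x[inside]),
                 outliers = sort(x[!inside]),
                 mean = mean(x), sd = stats::sd(x), n = length(x)),
            class = "BoxplotSummary")
}

#' @export
print.BoxplotSummary <- function(x, ...) {
  cat(sprintf(
    "<BoxplotSummary> n=%d median=%.3f [q1=%.3f q3=%.3f] whiskers=[%.3f, %.3f] mean=%.3f sd=%.3f outliers=%d\n",
    x$n, x$median, x$q1, x$q3, x$whisker_low, x$whisker_high, x$mean, x$sd,
    length(x$outliers)))
  invisible(x)
}
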