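# Cross-ensemble principal component analysis on a shared atom selection.
#
# One PCA is fitted over the pooled frames of all systems so that score
# plots are directly comparable between systems; atoms that differ between
# systems (e.g. phosphorylated residues) must be excluded from the shared
# selection by the caller. Covariance is unweighted and uses the 1/N
# (population) normalisation, so the score variance of the fitting ensemble
# along PC k equals eigenvalue k exactly.

#' Fit a shared PCA across systems
#'
#' All frames of all trajectories are superposed on the pooled mean
#' structure (one re-fit iteration: fit to the first frame, average, re-fit
#' to the mean), the pooled covariance of the fitted selection coordinates
#' is eigen-decomposed, and per-PC variance fractions are recorded.
#'
#' @param trajs a `Trajectory` or list of `Trajectory`s (one or more per
#'   system).
#' @param selection `SegmentSelection`(s) defining the analysed atoms, or
#'   `NULL` for all backbone atoms. Must resolve to the same atom count in
#'   every trajectory.
#' @param fit_selection atoms used for superposition (default: `selection`).
#' @return object of class `PCAModel`: `mean_coordinates` (M x 3, Angstrom),
#'   `eigenvectors` (3M x k), `eigenvalues` (Angstrom^2, non-increasing),
#'   `variance_fractions`, plus bookkeeping needed by [project_scores()].
#' @export
fit_pca <- function(trajs, selection = NULL, fit_selection = NULL) {
  if (inherits(trajs, "Trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1L)
  sel_idx <- lapply(trajs, function(tr)
    if (is.null(selection)) which(tr$topology$is_backbone)
    else .selection_indices(tr, selection))
  m0 <- length(sel_idx[[1]])
  if (any(vapply(sel_idx, length, 0L) != m0))
    stop("incompatible ensembles: selection resolves to different atom ",
         "counts across systems")
  fit_idx <- lapply(seq_along(trajs), function(i)
    if (is.null(fit_selection)) sel_idx[[i]]
    else .selection_indices(trajs[[i]], fit_selection))
  # pooled stack of selection coordinates, fitted on fit_selection
  blocks <- lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    list(sel = tr$coords[sel_idx[[i]], , , drop = FALSE],
         fit = tr$coords[fit_idx[[i]], , , drop = FALSE])
  })
  nfr <- vapply(blocks, function(b) dim(b$sel)[3], 0L)
  ntot <- sum(nfr)
  fit_frames <- function(ref_fit) {
    out <- array(NA_real_, dim = c(m0, 3L, ntot))
    meanfit <- array(0, dim = dim(blocks[[1]]$fit)[1:2])
    pos <- 0L
    cr <- colMeans(ref_fit)
    rc <- sweep(ref_fit, 2, cr)
    for (b in blocks) {
      for (k in seq_len(dim(b$sel)[3])) {
        fm <- matrix(b$fit[, , k], ncol = 3L)
        cm <- colMeans(fm)
        rot <- .kabsch_rotation(sweep(fm, 2, cm), rc)
        pos <- pos + 1L
        out[, , pos] <- sweep(sweep(matrix(b$sel[, , k], ncol = 3L), 2,
                                    cm) %*% rot, 2, cr, "+")
        meanfit <- meanfit + sweep(sweep(fm, 2, cm) %*% rot, 2, cr, "+")
      }
    }
    list(sel = out, meanfit = meanfit / ntot)
  }
  pass1 <- fit_frames(blocks[[1]]$fit[, , 1])
  pass2 <- fit_frames(pass1$meanfit)
  x <- t(matrix(pass2$sel, nrow = m0 * 3L, ncol = ntot))  # frames x 3M
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc)
  eig <- sv$d^2 / ntot
  keep <- seq_len(min(ntot, m0 * 3L))
  eig <- eig[keep]
  structure(list(
    selection = selection, fit_selection = fit_selection,
    mean_coordinates = matrix(mu, ncol = 3L),
    mean_fit_coordinates = pass1$meanfit,
    eigenvectors = sv$v[, keep, drop = FALSE],
    eigenvalues = eig,
    variance_fractions = eig / sum(eig),
    n_frames = ntot, n_atoms = m0), class = "PCAModel")
}

#' @export
print.PCAModel <- function(x, ...) {
  cat(sprintf("<PCAModel> %d atoms, %d pooled frames; top fractions: %s\n",
              x$n_atoms, x$n_frames,
              paste(sprintf("%.1f%%", 100 * utils::head(x$variance_fractions, 4)),
                    collapse = " ")))
  invisible(x)
}

#' Project a trajectory onto a fitted PCA
#'
#' Frames are superposed on the model's mean structure over the fit
#' selection, mean-centred with the model mean, and dotted with the
#' eigenvectors.
#'
#' @param model a `PCAModel`.
#' @param traj a `Trajectory` compatible with the model's selection.
#' @return matrix `n_frames x n_PCs` of scores (Angstrom), with the
#'   trajectory's system label as attribute `system`.
#' @export
project_scores <- function(model, traj) {
  sel_idx <- if (is.null(model$selection)) which(traj$topology$is_backbone)
  else .selection_indices(traj, model$selection)
  fit_idx <- if (is.null(model$fit_selection)) sel_idx
  else .selection_indices(traj, model$fit_selection)
  if (length(sel_idx) != model$n_atoms)
    stop("incompatible selection: trajectory resolves ", length(sel_idx),
         " atoms, model has ", model$n_atoms)
  ref <- model$mean_fit_coordinates
  cr <- colMeans(ref)
  rc <- sweep(ref, 2, cr)
  mu <- as.numeric(model$mean_coordinates)
  nf <- n_frames(traj)
  scores <- matrix(NA_real_, nf, ncol(model$eigenvectors))
  for (k in seq_len(nf)) {
    fm <- .frame_mat(traj$coords, fit_idx, k)
    cm <- colMeans(fm)
    rot <- .kabsch_rotation(sweep(fm, 2, cm), rc)
    fitted <- sweep(sweep(.frame_mat(traj$coords, sel_idx, k), 2, cm) %*% rot,
                    2, cr, "+")
    scores[k, ] <- (as.numeric(fitted) - mu) %*% model$eigenvectors
  }
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  attr(scores, "system") <- traj$system_label
  scores
}

#' Retain principal components by variance fraction
#'
#' Components whose individual variance contribution exceeds the threshold
#' (strictly) are retained; the conventional cut is >9%.
#'
#' @param model a `PCAModel`, or a numeric vector of variance fractions.
#' @param threshold_fraction retention threshold (default 0.09).
#' @return integer vector of retained PC indices (possibly empty).
#' @export
retain_pcs <- function(model, threshold_fraction = 0.09) {
  fr <- if (inherits(model, "PCAModel")) model$variance_fractions
  else as.numeric(model)
  which(fr > threshold_fraction)
}

#' Coordinates of a PC's extreme motion
#'
#' Interpolates the mean structure along one eigenvector, the standard way
#' of visualising an essential-dynamics mode; rendering is left to external
#' viewers.
#'
#' @param model a `PCAModel`.
#' @param pc component index.
#' @param amplitudes numeric multipliers in units of the mode's standard
#'   deviation (`sqrt(eigenvalue)`).
#' @return list of M x 3 coordinate matrices, one per amplitude.
#' @export
pca_mode_coordinates <- function(model, pc = 1L,
                                 amplitudes = c(-3, 0, 3)) {
  stopifnot(pc >= 1L, pc <= ncol(model$eigenvectors))
  sdk <- sqrt(model$eigenvalues[pc])
  v <- model$eigenvectors[, pc]
  lapply(amplitudes, function(a)
    model$mean_coordinates + matrix(a * sdk * v, ncol = 3L))
}
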