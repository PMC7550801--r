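# DSSP-style secondary-structure assignment and %SSE occupancy.
#
# The backbone hydrogen-bond energy follows the classic electrostatic
# model, E = 0.084 * (1/rON + 1/rCH - 1/rOH - 1/rCN) * 332 kcal/mol, with a
# bond called below -0.5 kcal/mol. Amide hydrogens are reconstructed at
# 1.01 A along the bisector of C(i-1)-N-CA when absent. Helix pools the
# alpha (i->i+4) and 3-10 (i->i+3) patterns; strand uses the parallel and
# antiparallel bridge patterns; everything else is "other".

.HB_Q <- 0.084 * 332      # kcal/mol * Angstrom
.HB_ENERGY_CUTOFF <- -0.5

# Per-chain residue backbone bookkeeping for one frame.
.backbone_frames <- function(top) {
  prot <- !top$is_water
  key <- paste(top$chain, top$resid, sep = ":")
  res_keys <- unique(key[prot])
  out <- lapply(res_keys, function(k) {
    idx <- which(key == k & prot)
    pick <- function(nm) {
      i <- idx[top$name[idx] == nm & !top$is_hydrogen[idx]]
      if (length(i)) i[1] else NA_integer_
    }
    list(key = k, chain = top$chain[idx[1]], resid = top$resid[idx[1]],
         resname = top$resname[idx[1]],
         N = pick("N"), CA = pick("CA"), C = pick("C"), O = pick("O"),
         H = { i <- idx[top$name[idx] %in% c("H", "HN")]
               if (length(i)) i[1] else NA_integer_ })
  })
  out
}

#' Assign secondary structure to one frame
#'
#' @param frame a `Frame` with backbone N, CA, C, O atoms.
#' @return named character vector (`"chain:resid"` -> label in
#'   `c("helix", "strand", "other")`). Residues with incomplete backbones
#'   are labelled `"other"` with a warning.
#' @export
assign_ss <- function(frame) {
  top <- frame$topology
  xyz <- frame$coords
  res <- .backbone_frames(top)
  n <- length(res)
  labels <- rep("other", n)
  names(labels) <- vapply(res, function(r) r$key, "")
  complete <- vapply(res, function(r)
    !anyNA(c(r$N, r$CA, r$C, r$O)), TRUE)
  if (any(!complete))
    warning("residues with incomplete backbone labelled 'other': ",
            paste(names(labels)[!complete], collapse = ", "))
  if (n < 5L) return(labels)
  chain_of <- vapply(res, function(r) r$chain, "")
  resid_of <- vapply(res, function(r) r$resid, 0L)
  # consecutive-in-chain flags (peptide bond assumed at sequential numbering)
  follows <- c(FALSE, chain_of[-1] == chain_of[-n] &
                 resid_of[-1] == resid_of[-n] + 1L)
  # donor geometry: N, H (reconstructed when missing and not proline/start)
  hpos <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    r <- res[[i]]
    if (!complete[i] || r$resname == "PRO") next
    if (!is.na(r$H)) { hpos[i, ] <- xyz[r$H, ]; next }
    if (!follows[i]) next                    # chain start: no amide H
    prevC <- res[[i - 1L]]$C
    if (is.na(prevC)) next
    nn <- xyz[r$N, ]
    d1 <- nn - xyz[prevC, ]; d1 <- d1 / sqrt(sum(d1^2))
    d2 <- nn - xyz[r$CA, ]; d2 <- d2 / sqrt(sum(d2^2))
    bis <- d1 + d2
    nb <- sqrt(sum(bis^2))
    if (nb < 1e-6) next
    hpos[i, ] <- nn + 1.01 * bis / nb
  }
  # H-bond matrix: hb[d, a] = TRUE when NH of residue d donates to CO of a
  hb <- matrix(FALSE, n, n)
  dOK <- complete & !is.na(hpos[, 1])
  for (d in which(dOK)) {
    nd <- xyz[res[[d]]$N, ]; hd <- hpos[d, ]
    for (a in seq_len(n)) {
      # no bond to self or to the preceding residue's carbonyl (covalent)
      if (!complete[a] || a == d ||
          (a == d - 1L && chain_of[a] == chain_of[d]))
        next
      ca <- xyz[res[[a]]$C, ]; oa <- xyz[res[[a]]$O, ]
      rON <- sqrt(sum((oa - nd)^2))
      if (rON > 5.2) next                    # distance prefilter
      rCH <- sqrt(sum((ca - hd)^2))
      rOH <- sqrt(sum((oa - hd)^2))
      rCN <- sqrt(sum((ca - nd)^2))
      e <- .HB_Q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      if (e < .HB_ENERGY_CUTOFF) hb[d, a] <- TRUE
    }
  }
  seq_ok <- function(i, j) {
    # residues i..j consecutive within one chain
    all(follows[(i + 1L):j])
  }
  turn4 <- rep(FALSE, n); turn3 <- rep(FALSE, n)
  for (i in seq_len(n - 4L))
    if (chain_of[i] == chain_of[i + 4L] && seq_ok(i, i + 4L) &&
        hb[i + 4L, i]) turn4[i] <- TRUE
  for (i in seq_len(n - 3L))
    if (chain_of[i] == chain_of[i + 3L] && seq_ok(i, i + 3L) &&
        hb[i + 3L, i]) turn3[i] <- TRUE
  helix <- rep(FALSE, n)
  if (n >= 6L) for (i in 2:(n - 4L))
    if (turn4[i - 1L] && turn4[i]) helix[i:(i + 3L)] <- TRUE
  if (n >= 5L) for (i in 2:(n - 3L))
    if (turn3[i - 1L] && turn3[i]) helix[i:(i + 2L)] <- TRUE
  # bridges (parallel / antiparallel), DSSP patterns
  strand <- rep(FALSE, n)
  for (i in 2:(n - 1L)) {
    for (j in 2:(n - 1L)) {
      if (abs(i - j) < 3L) next
      par <- (hb[j, i - 1L] && hb[i + 1L, j]) ||
             (hb[i, j - 1L] && hb[j + 1L, i])
      anti <- (hb[j, i] && hb[i, j]) ||
              (hb[j + 1L, i - 1L] && hb[i + 1L, j - 1L])
      if (par || anti) { strand[i] <- TRUE; strand[j] <- TRUE }
    }
  }
  labels[helix] <- "helix"
  labels[strand & !helix] <- "strand"
  labels[!complete] <- "other"
  labels
}

#' Percentage of an interval in a secondary-structure state
#'
#' Per frame, the share of the interval's residues carrying `label`;
#' the scalar summary is the mean over retained frames.
#'
#' @param traj a `Trajectory`.
#' @param interval a `SegmentSelection` naming the residue range.
#' @param label `"helix"`, `"strand"` or `"other"`.
#' @param exclude_ns equilibration cutoff (ns) or `NULL`.
#' @return list with `series` (a `MetricSeries`, percent by frame) and
#'   `mean` (scalar percent).
#' @export
percent_sse <- function(traj, interval, label = "helix", exclude_ns = NULL) {
  if (!is.null(exclude_ns)) traj <- exclude_equilibration(traj, exclude_ns)
  resolve_selection(traj, interval)   # errors early when interval is empty
  keys <- paste(interval$chain_id,
                seq(interval$start_residue, interval$end_residue), sep = ":")
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    lab <- assign_ss(get_frame(traj, k))
    present <- keys[keys %in% names(lab)]
    100 * mean(lab[present] == label)
  }, 0)
  series <- metric_series(vals, traj$time_ns, "percent",
                          traj$system_label, traj$replica_index,
                          !is.null(exclude_ns))
  list(series = series, mean = mean(vals))
}
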