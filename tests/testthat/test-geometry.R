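# geometry_metrics: cog, apex angle, shifts, distances, superposition,
# RMSD/RMSF, equilibration exclusion, boxplot summaries.

test_that("centre_of_geometry: identity, midpoint, brute-force oracle", {
  expect_equal(centre_of_geometry(matrix(c(1, 2, 3), 1)), c(1, 2, 3))
  expect_equal(centre_of_geometry(rbind(c(0, 0, 0), c(2, 0, 0))), c(1, 0, 0))
  set.seed(11)
  pts <- matrix(rnorm(150), 50, 3)
  expect_equal(centre_of_geometry(pts), oracle_cog(pts), tolerance = 1e-12)
  expect_error(centre_of_geometry(matrix(0, 0, 3)), "empty")
})

test_that("segment_angle: canonical geometries and degenerate input", {
  mk <- function(a, v, b) {
    top <- atom_table(1:3, rep("CA", 3), rep("ALA", 3), c(250L, 180L, 140L),
                      rep("A", 3))
    new_frame(top, rbind(a, v, b), 0)
  }
  defn <- three_segment_defn()
  expect_equal(segment_angle(mk(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), defn), 90)
  expect_equal(segment_angle(mk(c(1, 0, 0), c(0, 0, 0), c(3, 0, 0)), defn), 0)
  expect_error(segment_angle(mk(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), defn),
               "degenerate")
})

test_that("segment_angle agrees with the law-of-cosines oracle and is
           invariant to rigid motion and atom permutation", {
  set.seed(21)
  defn <- three_segment_defn()
  for (rep in 1:200) {
    fr <- random_three_segment_frame()
    a <- colMeans(fr$coords[1:5, ]); v <- colMeans(fr$coords[6:10, ])
    b <- colMeans(fr$coords[11:15, ])
    expect_equal(segment_angle(fr, defn), oracle_angle_loc(a, v, b),
                 tolerance = 1e-10)
  }
  # rigid motion invariance at 1e-8 degrees
  fr <- random_three_segment_frame()
  ang0 <- segment_angle(fr, defn)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  fr2 <- new_frame(fr$topology, sweep(fr$coords %*% rot, 2, c(4, -2, 9), "+"),
                   0)
  expect_equal(segment_angle(fr2, defn), ang0, tolerance = 1e-8)
  # permutation of atoms within each selection
  perm <- c(sample(1:5), sample(6:10), sample(11:15))
  fr3 <- new_frame(fr$topology, fr$coords[perm, ], 0)
  expect_equal(segment_angle(fr3, defn), ang0, tolerance = 1e-10)
})

test_that("interval_shift_validation: identity at zero, oracle for shifts", {
  h <- make_hinged_trajectory(theta0 = 40, noise = 2, n_frames = 20, seed = 4)
  expect_equal(interval_shift_validation(h$trajectory, h$definition, 0),
               rep(0, 20))
  # oracle: recompute via segment_angle on the shifted definition
  fr <- get_frame(h$trajectory, 3)
  for (shift in c(-5L, 5L)) {
    sel <- h$definition$ray_a
    shifted <- if (shift > 0)
      segment_selection("A", sel$start_residue + shift, sel$end_residue)
    else segment_selection("A", sel$start_residue, sel$end_residue + shift)
    defn2 <- angle_definition(shifted, h$definition$vertex,
                              h$definition$ray_b)
    expect_equal(interval_shift_validation(fr, h$definition, shift),
                 segment_angle(fr, defn2) - segment_angle(fr, h$definition))
  }
  expect_error(interval_shift_validation(h$trajectory, h$definition, -20L))
})

test_that("cog_distance: zero, pure translation, oracle, symmetry,
           triangle inequality over interface triad", {
  d <- make_dimer_trajectory(n_frames = 1)
  fr <- get_frame(d$trajectory, 1)
  ash_a <- segment_selection("A", 250, 264)
  expect_equal(cog_distance(fr, ash_a, ash_a), 0)
  # duplicate chain A's ash translated by (20, 0, 0) A -> 2.0 nm
  idx <- resolve_selection(fr, ash_a)
  top2 <- rbind(fr$topology, transform(fr$topology[idx, ], chain = "C"))
  top2$serial <- seq_len(nrow(top2))
  xyz2 <- rbind(fr$coords, sweep(fr$coords[idx, ], 2, c(20, 0, 0), "+"))
  fr2 <- new_frame(top2, xyz2, 0)
  expect_equal(cog_distance(fr2, ash_a, segment_selection("C", 250, 264)), 2.0)
  # brute-force oracle + symmetry on random frames
  set.seed(31)
  defn <- three_segment_defn()
  for (k in 1:50) {
    fr3 <- random_three_segment_frame()
    sa <- segment_selection("A", 250, 250); sb <- segment_selection("A", 140, 140)
    a <- oracle_cog(fr3$coords[1:5, ]); b <- oracle_cog(fr3$coords[11:15, ])
    expect_equal(cog_distance(fr3, sa, sb), sqrt(sum((a - b)^2)) / 10)
    expect_equal(cog_distance(fr3, sa, sb), cog_distance(fr3, sb, sa))
  }
  # triangle inequality over the three interface intervals
  sels <- default_selections("A")[c("n_lobe", "ash", "alpha_f")]
  selsB <- lapply(sels, function(s) { s$chain_id <- "B"; s })
  d_ab <- cog_distance(fr, sels$n_lobe, selsB$n_lobe)
  d_bc <- cog_distance(fr, selsB$n_lobe, sels$ash)
  d_ac <- cog_distance(fr, sels$n_lobe, sels$ash)
  expect_lte(d_ac, d_ab + d_bc + 1e-12)
})

test_that("superpose: exact recovery and Horn-quaternion oracle", {
  h <- make_hinged_trajectory(theta0 = 40, noise = 0, n_frames = 1, seed = 1)
  ref <- get_frame(h$trajectory, 1)
  ident <- superpose(ref, ref)
  expect_equal(ident$frame$coords, ref$coords, tolerance = 1e-10)
  expect_equal(ident$rotation, diag(3), tolerance = 1e-8)
  # 90-degree rotation about z, exact recovery
  th <- pi / 2
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  mob <- new_frame(ref$topology, ref$coords %*% rot, 0)
  fit <- superpose(mob, ref)
  expect_lt(sqrt(mean(rowSums((fit$frame$coords - ref$coords)^2))), 1e-6)
  # random rigid motion + noise vs Horn oracle
  set.seed(41)
  for (k in 1:20) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); thk <- runif(1, 0, pi)
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    R <- diag(3) + sin(thk) * K + (1 - cos(thk)) * K %*% K
    noisy <- ref$coords %*% R + matrix(rnorm(3), nrow(ref$coords), 3,
                                       byrow = TRUE) +
      matrix(rnorm(length(ref$coords), sd = 0.3), ncol = 3)
    mobk <- new_frame(ref$topology, noisy, 0)
    fitk <- superpose(mobk, ref)
    horn <- oracle_horn_fit(noisy, ref$coords)
    expect_equal(sqrt(mean(rowSums((fitk$frame$coords - ref$coords)^2))),
                 horn$rmsd, tolerance = 1e-8)
  }
  # underdetermined fits
  top3 <- atom_table(1:3, rep("CA", 3), rep("ALA", 3), 1:3, rep("A", 3))
  line <- new_frame(top3, cbind(1:3, 0, 0), 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("rmsd_series: zeros, translations, Kabsch-oracle equivalence,
           and fitting never increases RMSD", {
  h <- make_hinged_trajectory(theta0 = 40, noise = 0, n_frames = 5, seed = 1)
  static <- h$trajectory
  s <- rmsd_series(static, fit = FALSE)
  expect_equal(s$values, rep(0, 5))
  expect_equal(s$unit, "nm")
  # growing offsets, no fit: RMSD equals the offset magnitude
  base <- get_frame(static, 1)
  offs <- seq(0, 2, length.out = 5)        # Angstrom
  coords <- array(NA_real_, c(nrow(base$topology), 3, 5))
  for (k in 1:5) coords[, , k] <- sweep(base$coords, 2, c(offs[k], 0, 0), "+")
  tr <- new_trajectory(base$topology, coords, 0:4)
  expect_equal(rmsd_series(tr, reference = base, fit = FALSE)$values,
               offs / 10, tolerance = 1e-10)
  # noisy rigid motion, fit = TRUE: per-frame equality with the Horn oracle
  set.seed(51)
  ca_idx <- which(base$topology$name == "CA")
  for (k in 1:5) {
    thk <- runif(1, 0, pi / 2)
    R <- matrix(c(cos(thk), sin(thk), 0, -sin(thk), cos(thk), 0, 0, 0, 1),
                3, 3)
    coords[, , k] <- base$coords %*% R +
      matrix(rnorm(length(base$coords), sd = 0.5), ncol = 3)
  }
  tr2 <- new_trajectory(base$topology, coords, 0:4)
  got <- rmsd_series(tr2, reference = base, fit = TRUE)$values
  want <- vapply(1:5, function(k)
    oracle_horn_fit(coords[ca_idx, , k], base$coords[ca_idx, ])$rmsd / 10, 0)
  expect_equal(got, want, tolerance = 1e-8)
  # fitting helps (or at least never hurts) on the fit selection
  unfit <- rmsd_series(tr2, reference = base, fit = FALSE)$values
  expect_true(all(got <= unfit + 1e-12))
})

test_that("rmsf_per_residue: static zero, closed-form jitter, replica
           aggregation oracle", {
  base <- build_peptide(30)
  static <- new_trajectory(base$topology,
                           array(base$coords, c(nrow(base$topology), 3, 4)),
                           0:3)
  r0 <- rmsf_per_residue(static)
  expect_equal(r0$mean, rep(0, 30), tolerance = 1e-12)
  # five replicas with per-replica sigma: aggregation = mean/sd of columns
  reps <- make_jitter_replicas(build_peptide(40), sigma = 0.4,
                               n_replicas = 5, n_frames = 150, seed = 6)
  r <- rmsf_per_residue(reps)
  expect_equal(r$mean, rowMeans(r$per_replica))
  expect_equal(r$sd, apply(r$per_replica, 1, sd))
  expect_true(all(r$per_replica >= 0))
  expect_error(rmsf_per_residue(list(reps[[1]], build_peptide(10))),
               "topology")
})

test_that("exclude_equilibration boundary rules", {
  h <- make_hinged_trajectory(theta0 = 40, noise = 1, n_frames = 1000,
                              seed = 3, frame_dt_ns = 1)
  kept <- exclude_equilibration(h$trajectory, 250)
  expect_equal(n_frames(kept), 750)           # keeps the frame at 250 ns
  expect_equal(kept$time_ns[1], 250)
  expect_equal(n_frames(exclude_equilibration(h$trajectory, 0)), 1000)
  # cutoff between two frame times: first retained frame is >= cutoff
  kept2 <- exclude_equilibration(h$trajectory, 250.5)
  expect_equal(kept2$time_ns[1], 251)
  expect_error(exclude_equilibration(h$trajectory, 1e6), "empty-series")
  s <- angle_series(h$trajectory, h$definition, exclude_ns = 250)
  expect_true(s$equilibration_excluded)
  expect_length(s$values, 750)
})

test_that("boxplot_summary matches the sort-based oracle and pools by
           concatenation", {
  const <- boxplot_summary(rep(3.3, 10))
  expect_equal(const$median, 3.3)
  expect_equal(const$q1, const$q3)
  expect_length(const$outliers, 0)
  b <- boxplot_summary(c(1, 2, 3, 4, 100))
  expect_equal(b$outliers, 100)
  set.seed(61)
  for (k in 1:25) {
    x <- rnorm(sample(5:200, 1), sd = runif(1, 0.1, 10))
    got <- boxplot_summary(x)
    want <- oracle_boxplot(x)
    expect_equal(got$median, want$median)
    expect_equal(got$q1, want$q1)
    expect_equal(got$q3, want$q3)
    expect_equal(got$whisker_low, want$whisker_low)
    expect_equal(got$whisker_high, want$whisker_high)
    expect_equal(got$outliers, want$outliers)
    expect_gte(got$median, got$q1); expect_lte(got$median, got$q3)
  }
  # pooled replicas = concatenation
  s1 <- metric_series(c(1, 2, 3), 0:2, "nm")
  s2 <- metric_series(c(7, 8), 0:1, "nm", replica_index = 2L)
  pooled <- boxplot_summary(list(s1, s2))
  expect_equal(pooled$median, median(c(1, 2, 3, 7, 8)))
  expect_equal(pooled$n, 5)
  expect_error(boxplot_summary(numeric(0)), "empty-series")
})
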