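# contact_analysis: detectors, frequencies, heatmaps, cross-system tables.

test_that("salt bridge: cutoff behaviour, chain qualification, atom-set
           errors", {
  expect_true(detect_salt_bridge(salt_pair_frame(3.0), residue_ref("A", 10),
                                 residue_ref("A", 20)))
  expect_false(detect_salt_bridge(salt_pair_frame(4.5), residue_ref("A", 10),
                                  residue_ref("A", 20)))
  # boundary: cutoff is inclusive
  expect_true(detect_salt_bridge(salt_pair_frame(4.0), residue_ref("A", 10),
                                 residue_ref("A", 20)))
  # same residue number on another chain is a distinct residue
  frB <- salt_pair_frame(3.0, chain_b = "B")
  expect_true(detect_salt_bridge(frB, residue_ref("A", 10),
                                 residue_ref("B", 20)))
  expect_error(detect_salt_bridge(frB, residue_ref("A", 10),
                                  residue_ref("A", 20)), "not found")
  # unphosphorylated serine passed as the acidic partner
  top <- atom_table(1:2, c("NZ", "OG"), c("LYS", "SER"), c(1L, 2L), c("A", "A"))
  fr <- new_frame(top, rbind(c(0, 0, 0), c(3, 0, 0)), 0)
  expect_error(detect_salt_bridge(fr, residue_ref("A", 1),
                                  residue_ref("A", 2)), "atom-set")
  # phospho-serine oxygens count
  top2 <- atom_table(1:3, c("NZ", "O1P", "OG"), c("LYS", "SEP", "SEP"),
                     c(1L, 2L, 2L), c("A", "A", "A"))
  fr2 <- new_frame(top2, rbind(c(0, 0, 0), c(3.5, 0, 0), c(6, 0, 0)), 0)
  expect_true(detect_salt_bridge(fr2, residue_ref("A", 1),
                                 residue_ref("A", 2)))
})

test_that("hydrophobic contact: hydrogens participate, glycine errors,
           strict cutoff", {
  mk <- function(dist, with_h) {
    names_a <- c("CA", "CB", if (with_h) "HB1")
    top <- atom_table(seq_len(length(names_a) + 2),
                      c(names_a, "CA", "CB"),
                      c(rep("LEU", length(names_a)), "VAL", "VAL"),
                      c(rep(1L, length(names_a)), 2L, 2L),
                      rep("A", length(names_a) + 2))
    xyz <- rbind(c(-3, 0, 0), c(-1.5, 0, 0),
                 if (with_h) c(0, 0, 0),
                 c(dist + 2, 0, 0), c(dist, 0, 0))
    new_frame(top, xyz, 0)
  }
  # H...CB at 2.3 A -> contact
  expect_true(detect_hydrophobic(mk(2.3, TRUE), residue_ref("A", 1),
                                 residue_ref("A", 2)))
  # heavy atoms at 3.8 A, no hydrogens -> none
  expect_false(detect_hydrophobic(mk(2.3, FALSE), residue_ref("A", 1),
                                  residue_ref("A", 2)))
  # strictly below: exactly 2.5 A is not a contact
  expect_false(detect_hydrophobic(mk(2.5, TRUE), residue_ref("A", 1),
                                  residue_ref("A", 2)))
  # glycine has no side chain
  topg <- atom_table(1:3, c("N", "CA", "CB"), c("GLY", "GLY", "VAL"),
                     c(1L, 1L, 2L), rep("A", 3))
  frg <- new_frame(topg, rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 0)
  expect_error(detect_hydrophobic(frg, residue_ref("A", 1),
                                  residue_ref("A", 2)), "side chain")
})

test_that("detectors agree with brute-force minimum-distance oracles and
           are symmetric and monotone in cutoff", {
  set.seed(81)
  for (k in 1:100) {
    # random LYS/ASP geometry
    top <- atom_table(1:6, c("NZ", "CE", "CB", "OD1", "OD2", "CB"),
                      c("LYS", "LYS", "LYS", "ASP", "ASP", "ASP"),
                      c(rep(1L, 3), rep(2L, 3)), rep("A", 6))
    xyz <- matrix(rnorm(18, sd = 3), 6, 3)
    fr <- new_frame(top, xyz, 0)
    dmin_salt <- oracle_min_dist(xyz, 1L, 4:5)      # NZ vs OD1/OD2
    got <- detect_salt_bridge(fr, residue_ref("A", 1), residue_ref("A", 2))
    expect_identical(got, dmin_salt <= 4.0)
    # symmetry via the hydrophobic detector on the side-chain sets
    h1 <- detect_hydrophobic(fr, residue_ref("A", 1), residue_ref("A", 2),
                             cutoff = 5)
    h2 <- detect_hydrophobic(fr, residue_ref("A", 2), residue_ref("A", 1),
                             cutoff = 5)
    expect_identical(h1, h2)
    dmin_side <- oracle_min_dist(xyz, 1:3, 4:6)
    expect_identical(h1, dmin_side < 5)
    # monotone in cutoff
    for (cut in c(2, 4, 6, 8)) {
      small <- detect_hydrophobic(fr, residue_ref("A", 1),
                                  residue_ref("A", 2), cutoff = cut)
      big <- detect_hydrophobic(fr, residue_ref("A", 1),
                                residue_ref("A", 2), cutoff = cut + 2)
      expect_true(!small || big)
    }
  }
})

water_bridge_frame <- function(n_extra_waters = 0, far = FALSE) {
  nres <- 2L + 1L + n_extra_waters
  names <- c("O", "N", "O", "H1", "H2")
  top <- atom_table(1:5, names, c("SER", "THR", "HOH", "HOH", "HOH"),
                    c(1L, 2L, 5L, 5L, 5L), c("A", "B", "W", "W", "W"))
  off <- if (far) 30 else 0
  xyz <- rbind(c(-2.8, 0, 0), c(2.8, 0, 0),
               c(off, 0, 0), c(off + 0.76, 0.59, 0), c(off - 0.76, 0.59, 0))
  if (n_extra_waters > 0) {
    wt <- atom_table(6:(5 + 3 * n_extra_waters),
                     rep(c("O", "H1", "H2"), n_extra_waters),
                     rep("HOH", 3 * n_extra_waters),
                     rep(10L + seq_len(n_extra_waters), each = 3),
                     rep("W", 3 * n_extra_waters))
    top <- rbind(top, wt)
    extra <- do.call(rbind, lapply(seq_len(n_extra_waters), function(i) {
      o <- c(runif(1, -10, 10), runif(1, 2, 10), runif(1, -5, 5))
      rbind(o, o + c(0.76, 0.59, 0), o + c(-0.76, 0.59, 0))
    }))
    xyz <- rbind(xyz, extra)
  }
  top$serial <- seq_len(nrow(top))
  new_frame(top, xyz, 0)
}

test_that("water bridge: constructed positive/negative and per-water
           exhaustive oracle", {
  fr <- water_bridge_frame()
  expect_true(detect_water_bridge(fr, residue_ref("A", 1),
                                  residue_ref("B", 2)))
  expect_false(detect_water_bridge(water_bridge_frame(far = TRUE),
                                   residue_ref("A", 1), residue_ref("B", 2)))
  topw <- fr$topology[!fr$topology$is_water, ]
  frw <- new_frame(topw, fr$coords[!fr$topology$is_water, ], 0)
  expect_error(detect_water_bridge(frw, residue_ref("A", 1),
                                   residue_ref("B", 2)), "no water")
  # randomized waters: equals exhaustive per-water distance oracle
  set.seed(91)
  for (k in 1:40) {
    frk <- water_bridge_frame(n_extra_waters = 3,
                              far = sample(c(TRUE, FALSE), 1))
    top <- frk$topology
    got <- detect_water_bridge(frk, residue_ref("A", 1), residue_ref("B", 2),
                               angle_min = NULL)   # pure distance criterion
    want <- FALSE
    waters <- split(which(top$is_water), paste(top$chain[top$is_water],
                                               top$resid[top$is_water]))
    for (w in waters) {
      wo <- w[!top$is_hydrogen[w]]
      da <- oracle_min_dist(frk$coords, wo, 1L)
      db <- oracle_min_dist(frk$coords, wo, 2L)
      if (da <= 3.5 && db <= 3.5) want <- TRUE
    }
    expect_identical(got, want)
  }
})

test_that("pi-pi detector: stacked tryptophans and orthogonal far rings", {
  ring_names <- c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3",
                  "CH2")
  hexagon <- function(z, r = 1.4)
    cbind(r * cos(seq(0, 2 * pi, length.out = 10)[1:9]),
          r * sin(seq(0, 2 * pi, length.out = 10)[1:9]), z)
  top <- atom_table(1:18, rep(ring_names, 2), rep("TRP", 18),
                    rep(c(134L, 534L), each = 9), rep(c("A", "B"), each = 9))
  stacked <- new_frame(top, rbind(hexagon(0), hexagon(3.8)), 0)
  expect_true(detect_pi_pi(stacked, residue_ref("A", 134),
                           residue_ref("B", 534)))
  apart <- new_frame(top, rbind(hexagon(0), hexagon(9)), 0)
  expect_false(detect_pi_pi(apart, residue_ref("A", 134),
                            residue_ref("B", 534)))
})

test_that("contact_frequency: exact recovery of realized Bernoulli draws", {
  ct <- make_contact_trajectory(p = 0.3, n_frames = 300, seed = 12)
  cs <- contact_frequency(ct$trajectory, ct$spec, exclude_ns = NULL)
  expect_identical(cs$occupancy, ct$occupancy)
  expect_equal(cs$frequency_percent, 100 * mean(ct$occupancy))
  # always bonded
  ct1 <- make_contact_trajectory(p = 1, n_frames = 50, seed = 13)
  expect_equal(contact_frequency(ct1$trajectory, ct1$spec,
                                 exclude_ns = NULL)$frequency_percent, 100)
  # zero retained frames
  expect_error(contact_frequency(ct1$trajectory, ct1$spec,
                                 exclude_ns = 1e6), "empty-series")
  # frequency recomputable from occupancy exactly
  expect_equal(cs$frequency_percent, 100 * mean(cs$occupancy))
})

test_that("replica_heatmap counts strict threshold crossings", {
  mk_series <- function(freq, r) {
    occ <- rep(c(TRUE, FALSE), c(round(freq), 100 - round(freq)))
    structure(list(spec = contact_spec(residue_ref("A", 1),
                                       residue_ref("A", 2), "salt_bridge"),
                   occupancy = occ, frequency_percent = freq,
                   n_frames = 100L, system_label = "s", replica_index = r),
              class = "ContactSeries")
  }
  series <- Map(mk_series, c(10, 31, 29, 90, 50), 1:5)
  expect_identical(replica_heatmap(series, 30), 3L)
  expect_identical(replica_heatmap(Map(mk_series, rep(0, 5), 1:5), 30), 0L)
  # exactly at the threshold is not counted
  expect_identical(replica_heatmap(list(mk_series(30.0, 1)), 30), 0L)
  # non-increasing in threshold
  counts <- vapply(c(0, 20, 40, 60, 95), function(th)
    replica_heatmap(series, th), 0L)
  expect_true(all(diff(counts) <= 0))
  bad <- mk_series(50, 1)
  bad$spec <- contact_spec(residue_ref("A", 1), residue_ref("A", 3),
                           "salt_bridge")
  expect_error(replica_heatmap(c(series, list(bad))), "aggregation")
})

test_that("interaction_table filters by cross-system spread", {
  systems <- list(
    up = make_contact_trajectory(p = 0.9, n_frames = 120, seed = 21)$trajectory,
    ps = make_contact_trajectory(p = 0.69, n_frames = 120, seed = 22)$trajectory,
    pt = make_contact_trajectory(p = 0.44, n_frames = 120, seed = 23)$trajectory,
    pp = make_contact_trajectory(p = 0.0, n_frames = 120, seed = 24)$trajectory)
  spec <- make_contact_trajectory(p = 1, n_frames = 2, seed = 1)$spec
  tab <- interaction_table(systems, list(spec), min_reporting_delta = 20,
                           exclude_ns = NULL)
  expect_equal(nrow(tab), 1L)            # delta ~90 > 20: retained
  expect_gt(tab$delta, 20)
  # constant across systems -> filtered out
  same <- lapply(1:4, function(i)
    make_contact_trajectory(p = 0.5, n_frames = 120, seed = 33)$trajectory)
  names(same) <- names(systems)
  tab2 <- interaction_table(same, list(spec), min_reporting_delta = 20,
                            exclude_ns = NULL)
  expect_equal(nrow(tab2), 0L)
  # delta 0 disables the filter
  tab3 <- interaction_table(same, list(spec), min_reporting_delta = 0,
                            exclude_ns = NULL)
  expect_equal(nrow(tab3), 1L)
})
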