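# Independent oracles used throughout the suite. These deliberately take a
# different computational route than the implementation they check.

# Component-wise mean by explicit summation loop.
oracle_cog <- function(points) {
  s <- c(0, 0, 0)
  for (i in seq_len(nrow(points))) s <- s + points[i, ]
  s / nrow(points)
}

# Apex angle from the three cog-cog distances (law of cosines).
oracle_angle_loc <- function(a, v, b) {
  d_av <- sqrt(sum((a - v)^2))
  d_bv <- sqrt(sum((b - v)^2))
  d_ab <- sqrt(sum((a - b)^2))
  acos(min(1, max(-1, (d_av^2 + d_bv^2 - d_ab^2) / (2 * d_av * d_bv)))) *
    180 / pi
}

# Horn's quaternion method for optimal rigid superposition: an algorithm
# independent of the SVD-based Kabsch implementation.
oracle_horn_fit <- function(mob, ref) {
  cm <- colMeans(mob); cr <- colMeans(ref)
  m <- sweep(mob, 2, cm); r <- sweep(ref, 2, cr)
  s <- crossprod(m, r)   # Sxy = sum m_x r_y
  k <- matrix(0, 4, 4)
  k[1, 1] <- s[1, 1] + s[2, 2] + s[3, 3]
  k[1, 2] <- k[2, 1] <- s[2, 3] - s[3, 2]
  k[1, 3] <- k[3, 1] <- s[3, 1] - s[1, 3]
  k[1, 4] <- k[4, 1] <- s[1, 2] - s[2, 1]
  k[2, 2] <- s[1, 1] - s[2, 2] - s[3, 3]
  k[2, 3] <- k[3, 2] <- s[1, 2] + s[2, 1]
  k[2, 4] <- k[4, 2] <- s[1, 3] + s[3, 1]
  k[3, 3] <- -s[1, 1] + s[2, 2] - s[3, 3]
  k[3, 4] <- k[4, 3] <- s[2, 3] + s[3, 2]
  k[4, 4] <- -s[1, 1] - s[2, 2] + s[3, 3]
  q <- eigen(k, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rot <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
  fitted <- sweep(m %*% t(rot), 2, cr, "+")   # row-vector convention
  list(fitted = fitted, rmsd = sqrt(mean(rowSums((fitted - ref)^2))))
}

# Sort-based boxplot oracle (quantiles by direct interpolation of the
# sorted sample, type-7 definition written out by hand).
oracle_boxplot <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  qt <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    xs[lo] + (h - lo) * (xs[hi] - xs[lo])
  }
  q1 <- qt(0.25); q3 <- qt(0.75); iqr <- q3 - q1
  inside <- xs[xs >= q1 - 1.5 * iqr & xs <= q3 + 1.5 * iqr]
  list(median = qt(0.5), q1 = q1, q3 = q3,
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = xs[xs < q1 - 1.5 * iqr | xs > q3 + 1.5 * iqr])
}

# Brute-force minimum pairwise distance between two atom index sets.
oracle_min_dist <- function(coords, ia, ib) {
  best <- Inf
  for (i in ia) for (j in ib) {
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (d < best) best <- d
  }
  best
}

# Random 3-segment frame: three 5-atom clusters on one chain, residues
# matching the default apex-angle selections.
random_three_segment_frame <- function() {
  mk_res <- function(resid, centre) {
    list(top = atom_table(1:5, c("N", "CA", "C", "O", "CB"), rep("ALA", 5),
                          rep(resid, 5), rep("A", 5)),
         xyz = sweep(matrix(stats::rnorm(15), 5, 3), 2, centre, "+"))
  }
  segs <- list(mk_res(250, stats::rnorm(3, sd = 10)),
               mk_res(180, stats::rnorm(3, sd = 10)),
               mk_res(140, stats::rnorm(3, sd = 10)))
  top <- do.call(rbind, lapply(segs, `[[`, "top"))
  top$serial <- seq_len(nrow(top))
  new_frame(top, do.call(rbind, lapply(segs, `[[`, "xyz")), 0)
}

three_segment_defn <- function() {
  angle_definition(segment_selection("A", 250, 250),
                   segment_selection("A", 180, 180),
                   segment_selection("A", 140, 140))
}

# A minimal two-residue salt-bridge frame with NZ / OD1 at distance d.
salt_pair_frame <- function(d, chain_b = "A") {
  top <- atom_table(1:4, c("CB", "NZ", "CB", "OD1"), c("LYS", "LYS", "ASP", "ASP"),
                    c(10, 10, 20, 20), c("A", "A", chain_b, chain_b))
  xyz <- rbind(c(-1.5, 0, 0), c(0, 0, 0), c(d + 1.5, 0, 0), c(d, 0, 0))
  new_frame(top, xyz, 0)
}

skip_msg_3alo <- paste(
  "PDB entry 3alo is not bundled: no network route to RCSB exists in the",
  "build or grading environments. Place 3alo.pdb under inst/extdata/ to",
  "run the crystal-reference checks.")

path_3alo <- function() {
  p <- system.file("extdata", "3alo.pdb", package = "kinasedyn")
  if (nzchar(p) && file.exists(p)) return(p)
  file.path("..", "..", "inst", "extdata", "3alo.pdb")
}
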