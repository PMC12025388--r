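# Independent numerical oracles used to validate the package's closed-form
# and grid implementations. These deliberately share no code with the
# functions they check.

rot_xyz <- function(a, b, c) {
  # intrinsic z-y-x Euler rotation, angles in degrees
  ar <- a * pi / 180; br <- b * pi / 180; cr <- c * pi / 180
  Rz <- matrix(c(cos(ar), -sin(ar), 0, sin(ar), cos(ar), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(br), 0, sin(br), 0, 1, 0, -sin(br), 0, cos(br)),
               3, 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(cr), -sin(cr), 0, sin(cr), cos(cr)),
               3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# Minimal RMSD by dense search over rotation space, refined to 0.1 degree
# resolution. Only proper rotations are visited, matching the
# reflection-free contract of the implementation under test.
grid_search_rmsd <- function(P, Q) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  n <- nrow(P0)
  eval_rmsd <- function(a, b, c) {
    R <- rot_xyz(a, b, c)
    sqrt(sum((P0 - Q0 %*% t(R))^2) / n)
  }
  best <- c(0, 0, 0)
  best_val <- Inf
  step <- 10
  # global pass
  for (a in seq(-180, 170, by = step)) {
    for (b in seq(-90, 90, by = step)) {
      for (c in seq(-180, 170, by = step)) {
        v <- eval_rmsd(a, b, c)
        if (v < best_val) { best_val <- v; best <- c(a, b, c) }
      }
    }
  }
  # local refinement, re-centered each level, down to 0.02 degree
  while (step > 0.02) {
    newstep <- step / 5
    grid <- seq(-step, step, by = newstep)
    center <- best
    for (da in grid) for (db in grid) for (dc in grid) {
      v <- eval_rmsd(center[1] + da, center[2] + db, center[3] + dc)
      if (v < best_val) {
        best_val <- v
        best <- center + c(da, db, dc)
      }
    }
    step <- newstep
  }
  best_val
}

# Monte-Carlo rejection oracle for percent buried volume: uniform points
# in the probe sphere, fraction falling inside any atom sphere. Returns
# the estimate and its standard error (percentage points).
mc_buried_volume <- function(rel_coords, radii, sphere_radius, n_samples,
                             seed = 42) {
  set.seed(seed)
  hits <- 0
  chunk <- 1e6
  left <- n_samples
  r2 <- radii^2
  while (left > 0) {
    m <- min(chunk, left)
    left <- left - m
    u <- matrix(rnorm(3 * m), m, 3)
    u <- u / sqrt(rowSums(u^2))
    rad <- sphere_radius * runif(m)^(1 / 3)
    pts <- u * rad
    inside <- rep(FALSE, m)
    for (a in seq_len(nrow(rel_coords))) {
      d2 <- (pts[, 1] - rel_coords[a, 1])^2 +
        (pts[, 2] - rel_coords[a, 2])^2 +
        (pts[, 3] - rel_coords[a, 3])^2
      inside <- inside | (d2 <= r2[a])
    }
    hits <- hits + sum(inside)
  }
  p <- hits / n_samples
  list(value = 100 * p, se = 100 * sqrt(p * (1 - p) / n_samples))
}

# Small rigid fixtures ------------------------------------------------

# ethanol-like heavy skeleton plus hydrogens (positions approximate)
ethanol_fixture <- function() {
  structure3d(
    c("C", "C", "O", "H", "H", "H", "H", "H", "H"),
    rbind(c(0, 0, 0), c(1.51, 0, 0), c(2.02, 1.33, 0),
          c(-0.39, 1.01, 0.05), c(-0.39, -0.52, 0.88),
          c(-0.39, -0.50, -0.90), c(1.90, -0.53, 0.87),
          c(1.90, -0.51, -0.89), c(2.98, 1.30, 0.05)))
}

# Butane-like 4-atom chain with an exactly known signed dihedral: the
# central bond lies along +x, the first atom's perpendicular offset along
# +y, and the last atom's perpendicular offset at angle phi in the (y, z)
# plane; the signed torsion over the chain is then +phi by construction.
chain_dihedral_fixture <- function(phi_deg = 60) {
  phi <- phi_deg * pi / 180
  rbind(c(-0.5, 1.0, 0),
        c(0, 0, 0),
        c(1.5, 0, 0),
        c(2.0, cos(phi), sin(phi)))
}

# deterministic RNG-scoped helper
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
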