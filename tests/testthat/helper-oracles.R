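# Independent oracles used to cross-check the package implementations.

# Exhaustive global alignment score under affine gaps (gap of length L costs
# open + L * extend), for short sequences only. Recursion over all alignment
# paths, tracking whether each sequence is currently inside a gap.
brute_force_align_score <- function(a, b, submat, open = 10, extend = 0.5) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  rec <- function(i, j, gapA, gapB) {
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b)) {
      best <- max(best, submat[a[i], b[j]] + rec(i + 1, j + 1, FALSE, FALSE))
    }
    if (i <= length(a)) {       # a[i] against a gap in b
      pen <- extend + if (gapB) 0 else open
      best <- max(best, -pen + rec(i + 1, j, FALSE, TRUE))
    }
    if (j <= length(b)) {       # b[j] against a gap in a
      pen <- extend + if (gapA) 0 else open
      best <- max(best, -pen + rec(i, j + 1, TRUE, FALSE))
    }
    best
  }
  rec(1, 1, FALSE, FALSE)
}

# Best rigid-superposition RMSD by scanning rotations on an Euler grid
# (moving set rotated, then optimally translated by centroid matching).
grid_superpose_rmsd <- function(reference, moving, n_steps = 36) {
  ca <- colMeans(reference); cb <- colMeans(moving)
  A <- sweep(reference, 2, ca); B <- sweep(moving, 2, cb)
  angs <- seq(0, 2 * pi, length.out = n_steps + 1)[-(n_steps + 1)]
  half <- seq(0, pi, length.out = n_steps %/% 2 + 1)
  best <- Inf
  for (a1 in angs) for (a2 in half) for (a3 in angs) {
    R1 <- matrix(c(cos(a1), sin(a1), 0, -sin(a1), cos(a1), 0, 0, 0, 1), 3, 3)
    R2 <- matrix(c(1, 0, 0, 0, cos(a2), sin(a2), 0, -sin(a2), cos(a2)), 3, 3)
    R3 <- matrix(c(cos(a3), sin(a3), 0, -sin(a3), cos(a3), 0, 0, 0, 1), 3, 3)
    R <- R1 %*% R2 %*% R3
    r <- sqrt(mean(rowSums((B %*% R - A)^2)))
    if (r < best) best <- r
  }
  best
}

# Analytic solvent-accessible areas of two overlapping spheres with expanded
# radii R1, R2 at center distance d: each loses a spherical cap.
two_sphere_areas <- function(R1, R2, d) {
  if (d >= R1 + R2) return(c(4 * pi * R1^2, 4 * pi * R2^2))
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  x2 <- d - x1
  h1 <- R1 - x1
  h2 <- R2 - x2
  c(4 * pi * R1^2 - 2 * pi * R1 * h1,
    4 * pi * R2^2 - 2 * pi * R2 * h2)
}

# Mass-balance ITC oracle: recomputes the equilibrium complex concentration
# from scratch after every injection by root-finding on the binding
# polynomial, instead of using the closed-form quadratic.
oracle_itc_heats <- function(Kd, n, dH, protocol) {
  V0 <- protocol$cell_volume
  M <- protocol$cell_concentration
  X <- 0
  heats <- numeric(length(protocol$injection_volumes))
  prev <- 0
  for (i in seq_along(protocol$injection_volumes)) {
    f <- protocol$injection_volumes[i] / V0
    M <- M * (1 - f)
    X <- X * (1 - f) + protocol$syringe_concentration * f
    sites <- n * M
    cplx <- if (X == 0 || sites == 0) 0 else
      stats::uniroot(function(c) (sites - c) * (X - c) - Kd * c,
                     lower = 0, upper = min(sites, X) * (1 - 1e-12),
                     tol = 1e-12)$root
    heats[i] <- V0 * dH * (cplx - prev * (1 - f))
    prev <- cplx
  }
  heats
}

# random rigid transform (proper rotation + translation), seeded by caller
random_rigid_transform <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = stats::rnorm(3, sd = 10))
}

apply_rigid <- function(X, tf) sweep(X %*% tf$R, 2, tf$t, "+")
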