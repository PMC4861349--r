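# Independent oracles, implemented in plain R and kept separate from the
# package's C++ search paths.

# plain-R least-squares superposition (independent of cpp_kabsch)
oracle_superpose <- function(P, Q) {
  cP <- colMeans(P)
  cQ <- colMeans(Q)
  Pc <- sweep(P, 2, cP)
  Qc <- sweep(Q, 2, cQ)
  s <- svd(t(Pc) %*% Qc)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = as.numeric(cQ - R %*% cP))
}

oracle_apply <- function(P, tr) sweep(P %*% t(tr$R), 2, -tr$t)

oracle_rmsd_at <- function(P, Q, tr) {
  sqrt(mean(rowSums((oracle_apply(P, tr) - Q)^2)))
}

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

# brute-force minimum RMSD over a dense random quaternion grid with a
# Nelder-Mead polish of the best grid point (translation eliminated by
# centering, which is optimal for any fixed rotation)
oracle_min_rmsd_grid <- function(P, Q, n_grid = 20000) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  rms_of <- function(q) {
    R <- quat_to_rot(q)
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  qs <- matrix(rnorm(4 * n_grid), ncol = 4)
  vals <- apply(qs, 1, rms_of)
  best <- qs[which.min(vals), ]
  opt <- optim(best, rms_of, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

# exhaustive GDT oracle: superpose on every subset of size >= 3 and count
# residues under the threshold; Pd = max count / lref
oracle_gdt_exhaustive <- function(P, Q, lref,
                                  thresholds = c(1, 2, 4, 8)) {
  n <- nrow(P)
  stopifnot(n <= 14)
  best <- setNames(rep(0L, length(thresholds)), thresholds)
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) < 3) next
    tr <- oracle_superpose(P[idx, , drop = FALSE], Q[idx, , drop = FALSE])
    d <- sqrt(rowSums((oracle_apply(P, tr) - Q)^2))
    for (k in seq_along(thresholds))
      best[k] <- max(best[k], sum(d <= thresholds[k]))
  }
  mean(best / lref)
}

oracle_tm_sum <- function(d, d0) sum(1 / (1 + (d / d0)^2))

# dense restart search for the superposition maximizing the TM sum:
# Nelder-Mead over (rotation vector, translation) from many random starts
# plus the global least-squares start
oracle_tm_restart <- function(P, Q, lref, d0, n_starts = 60) {
  rotvec_to_rot <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    a <- v / th
    K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
                3, 3, byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  cP <- colMeans(P)
  cQ <- colMeans(Q)
  obj <- function(par) {
    R <- rotvec_to_rot(par[1:3])
    moved <- sweep(sweep(P, 2, cP) %*% t(R), 2, -(cQ + par[4:6]))
    -oracle_tm_sum(sqrt(rowSums((moved - Q)^2)), d0)
  }
  rot_to_par <- function(R, t) {
    ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
    axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    v <- if (sqrt(sum(axis^2)) > 1e-9 && ang > 1e-9)
      ang * axis / sqrt(sum(axis^2)) else rep(0, 3)
    c(v, t)
  }
  starts <- c(list(rep(0, 6)),
              lapply(seq_len(n_starts), function(i)
                c(runif(3, -pi, pi), rnorm(3, 0, 2))))
  # every pairwise-fragment least-squares fit is also a start, expressed
  # relative to the centroid parametrization of obj()
  n <- nrow(P)
  for (w in c(3, 5, 7)) {
    for (s0 in seq(1, n - w + 1, by = 1)) {
      idx <- s0:(s0 + w - 1)
      tr <- oracle_superpose(P[idx, , drop = FALSE],
                             Q[idx, , drop = FALSE])
      # obj applies: R (x - cP) + cQ + par[4:6]; fragment fit applies
      # R x + tr$t, so par[4:6] = R cP + tr$t - cQ
      starts <- c(starts, list(rot_to_par(
        tr$R, as.numeric(tr$R %*% cP) + tr$t - cQ)))
    }
  }
  best <- Inf
  for (s in starts) {
    opt <- optim(s, obj, method = "Nelder-Mead",
                 control = list(maxit = 4000, reltol = 1e-15))
    if (opt$value < best) best <- opt$value
  }
  -best / lref
}

# second, independent ranking implementation used as the sort oracle
oracle_rank <- function(scores, decreasing) {
  ord <- names(sort(scores, decreasing = decreasing))
  rk <- rank(if (decreasing) -scores else scores, ties.method = "average")
  list(order = ord, ranks = rk[ord])
}

# analytic accessible area of sphere 1 of two intersecting probe-expanded
# spheres (spherical-cap formula)
oracle_two_sphere_area <- function(r1, r2, dist, probe = 1.4) {
  R1 <- r1 + probe
  R2 <- r2 + probe
  if (dist >= R1 + R2) return(4 * pi * R1^2)
  h <- R1 - (dist^2 + R1^2 - R2^2) / (2 * dist)
  4 * pi * R1^2 - 2 * pi * R1 * h
}
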