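# Independent oracles used across the suite. These deliberately use
# different algorithms from the package implementations.

# Minimum RMSD over proper rotations via the quaternion method: the largest
# eigenvalue of the 4x4 key matrix built from the cross-covariance gives
# rmsd = sqrt((G_P + G_Q - 2*lambda_max) / N). Unweighted (unit masses).
quaternion_rmsd <- function(P, Q) {
  P <- sweep(P, 2, colMeans(P))
  Q <- sweep(Q, 2, colMeans(Q))
  M <- t(P) %*% Q
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lambda_max <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lambda_max) / nrow(P)
  sqrt(max(0, msd))
}

# Exhaustive O(N^3)-style scan over all (donor, hydrogen, acceptor) triples,
# written as plain loops with no shared code with count_hbonds().
brute_force_hbonds <- function(xyz, donors, acceptors, max_dist = 0.35,
                               max_angle = 30) {
  pairs <- character(0)
  for (i in seq_len(nrow(donors))) {
    for (a in acceptors) {
      d <- donors[i, 1]; h <- donors[i, 2]
      if (a == d) next
      vda <- xyz[a, ] - xyz[d, ]
      vdh <- xyz[h, ] - xyz[d, ]
      r <- sqrt(sum(vda * vda))
      if (r > max_dist) next
      ct <- sum(vda * vdh) / (r * sqrt(sum(vdh * vdh)))
      ang <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
      if (ang <= max_angle) pairs <- unique(c(pairs, paste(d, a)))
    }
  }
  length(pairs)
}

# Tie-aware ranking by brute force: for each element, 1 + number strictly
# better, averaged over its tie group.
brute_force_ranks <- function(values) {
  vapply(values, function(v) {
    mean(which(sort(values) == v))
  }, numeric(1))
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}
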