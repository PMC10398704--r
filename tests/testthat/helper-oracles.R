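# Independent brute-force oracles used across the test files.

# Gauss series for 2F1(n, 1/2; 1; x), |x| < 1 (slow but direct)
hyp_series_oracle <- function(x, n, terms = 2000) {
  s <- 0; t <- 1
  for (k in 0:terms) {
    s <- s + t
    t <- t * (n + k) * (0.5 + k) / ((1 + k)^2) * x
    if (abs(t) < 1e-16 * abs(s)) break
  }
  s
}

# adaptive quadrature of the one-angle kernel integral
j_theta_oracle <- function(alpha, beta, n) {
  stats::integrate(function(t) (alpha + beta * sin(t / 2)^2)^(-n),
                   0, 2 * pi, rel.tol = 1e-12)$value
}

# deterministic pseudo-random small geometries for oracle-equivalence sweeps
random_small_system <- function(i) {
  set.seed(1000 + i)
  b1 <- runif(1, 4, 15)
  b2 <- runif(1, 1, b1 - 2)
  L <- runif(1, 20, 60)
  d <- runif(1, 2, 10)
  Z <- runif(1, -d, L + d)
  list(system = tube_system(b1 = b1, L = L),
       cluster = cluster_cylinder(b2, d, eps_co = 0.040),
       Z = Z)
}

# brute-force 1-D scan locating the pair-potential minimum
lj_min_scan <- function(A, B, lo = 0.5, hi = 12, n = 400001) {
  rho <- seq(lo, hi, length.out = n)
  v <- -A / rho^6 + B / rho^12
  k <- which.min(v)
  list(rho = rho[k], value = v[k])
}

# golden-angle point set on a sphere surface (for the molecule-as-sphere
# smoke test)
sphere_lattice <- function(radius, n, centre = c(0, 0, 0)) {
  k <- seq_len(n)
  z <- (2 * k - 1) / n - 1
  th <- (2 * pi * (sqrt(5) - 1) / 2) * k
  r_xy <- sqrt(pmax(0, 1 - z^2))
  cbind(x = centre[1] + radius * r_xy * cos(th),
        y = centre[2] + radius * r_xy * sin(th),
        z = centre[3] + radius * z)
}
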