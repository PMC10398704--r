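# Friction model and velocity-Verlet transport.

sys <- tube_system()
cl30 <- cluster_cylinder(10.40, 15, eps_co = 0.040)
W30 <- suction_energy(sys, cl30)

test_that("friction coefficient grows with wettability and radius, smoothly and non-negatively", {
  expect_gt(friction_coefficient(10.40, 0.16), friction_coefficient(10.40, 0.04))
  expect_gt(friction_coefficient(12, 0.08), friction_coefficient(10, 0.08))
  eps <- seq(0.04, 0.40, by = 0.0005)
  lam <- vapply(eps, function(e) friction_coefficient(10.40, e), 0)
  expect_true(all(lam >= 0))
  expect_true(all(abs(diff(lam) / lam[-length(lam)]) < 0.05))
  expect_warning(friction_coefficient(10.40, 0.6), "range")
})

test_that("friction force opposes motion, vanishes at rest, and scales with contact area", {
  m15 <- friction_model(10.40, 15, 0.040)
  m30 <- friction_model(10.40, 30, 0.040)
  expect_equal(m15$A_inter, 4 * pi * 10.40 * 15)
  expect_equal(friction_force(0, m15), 0)
  expect_equal(friction_force(-0.005, m15), -friction_force(0.005, m15))
  expect_lt(friction_force(0.005, m15), 0)
  expect_equal(friction_force(0.005, m30), 2 * friction_force(0.005, m15))
  expect_equal(friction_force(0.005, m15, contact_fraction = 0.5),
               0.5 * friction_force(0.005, m15))
})

test_that("verlet_step reproduces force-free and uniformly accelerated motion", {
  M <- 1e-23
  st <- verlet_step(1, 0.01, function(Z, V) 0, M, dt = 2)
  expect_equal(st$Z, 1.02)
  expect_equal(st$V, 0.01)

  # constant force from rest: Z(t) = (F/M) t^2 / 2 up to O(dt^2)
  Fc <- 5
  a <- Fc * cnt_units$force_si_per_model / M * 1e-20
  Z <- 0; V <- 0
  for (k in 1:500) {
    st <- verlet_step(Z, V, function(Z, V) Fc, M, dt = 1)
    Z <- st$Z; V <- st$V
  }
  expect_equal(Z, 0.5 * a * 500^2, tolerance = 1e-10)
  expect_equal(V, a * 500, tolerance = 1e-10)
})

test_that("verlet integration of a harmonic force shows no secular energy drift", {
  M <- 1e-23
  k_si <- 1e-2          # (kcal/mol)/A per A
  acc <- cnt_units$force_si_per_model / M * 1e-20
  omega <- sqrt(k_si * acc)
  dt <- 2 * pi / omega / 100
  force <- function(Z, V) -k_si * Z
  Z <- 3; V <- 0
  energy <- function(Z, V) 0.5 * k_si * Z^2 +
    0.5 * (V^2 / acc)      # consistent units up to a common factor
  n <- 5e4
  e <- numeric(n)
  for (i in seq_len(n)) {
    st <- verlet_step(Z, V, force, M, dt)
    Z <- st$Z; V <- st$V
    e[i] <- energy(Z, V)
  }
  # average over whole decades of periods so the bounded O(dt^2) energy
  # oscillation cancels and only a secular trend would remain
  w <- 1000
  drift <- abs(mean(e[(n - w + 1):n]) - mean(e[1:w])) / mean(e[1:w])
  expect_lt(drift, 1e-6)
})

test_that("frictionless transport conserves energy and reaches the work-energy peak speed", {
  cfg <- transport_config(t_max = 1.2e5, Z0 = -15, friction_on = FALSE,
                          record_every = 5)
  tr <- simulate_transport(sys, cl30, cfg, eps_co = 0.040, W = W30)
  F0 <- attr(tr, "F0"); M <- attr(tr, "M_kg"); d <- 15; L <- sys$L
  U <- function(Z) -F0 * (pmin(pmax(Z, -d), d) + d) +
    F0 * (pmin(pmax(Z, L - d), L + d) - (L - d))
  KE <- 0.5 * M * (tr$V * cnt_units$velocity_si_per_model)^2 /
    cnt_units$energy_si_per_model
  Etot <- KE + U(tr$Z)
  expect_lt(max(abs(Etot - Etot[1])) / W30, 1e-4)

  v_pred <- sqrt(2 * W30 * cnt_units$energy_si_per_model / M)
  expect_equal(attr(tr, "diagnostics")$V_max_m_s, v_pred, tolerance = 5e-3)
})

test_that("without friction the mouth forces set up a perpetual oscillation", {
  ssys <- tube_system(L = 100)
  scl <- cluster_cylinder(10.40, 10, eps_co = 0.040)
  tr <- simulate_transport(ssys, scl,
                           transport_config(t_max = 1e5, friction_on = FALSE),
                           eps_co = 0.040)
  expect_false(attr(tr, "diagnostics")$reached_far_end &&
                 max(tr$Z) >= ssys$L + scl$d)     # never escapes
  expect_gte(sum(diff(sign(tr$V)) != 0), 3)       # keeps turning around
  expect_gt(max(tr$Z), ssys$L - scl$d)            # reaches the far mouth
})

test_that("with friction the interior velocity decays monotonically", {
  tr <- simulate_transport(sys, cl30, transport_config(t_max = 6e4),
                           eps_co = 0.040, W = W30)
  interior <- tr$Z > 15 & tr$Z < sys$L - 15
  expect_true(all(diff(tr$V[interior]) <= 1e-12))
})

test_that("peak velocity is converged in the time step", {
  d1 <- attr(simulate_transport(sys, cl30, transport_config(t_max = 2e4),
                                eps_co = 0.040, W = W30), "diagnostics")
  d2 <- attr(simulate_transport(sys, cl30,
                                transport_config(dt = 0.5, t_max = 2e4),
                                eps_co = 0.040, W = W30), "diagnostics")
  expect_equal(d1$V_max_m_s, d2$V_max_m_s, tolerance = 1e-3)
})

test_that("shorter clusters peak faster and higher", {
  runs <- lapply(c(15, 30, 60), function(d) {
    cl <- cluster_cylinder(10.40, d, eps_co = 0.040)
    attr(simulate_transport(sys, cl, transport_config(t_max = 4e4),
                            eps_co = 0.040), "diagnostics")
  })
  v <- vapply(runs, `[[`, 0, "V_max_m_s")
  tp <- vapply(runs, `[[`, 0, "t_peak_ps")
  expect_true(all(diff(v) < 0))
  expect_true(all(diff(tp) > 0))
})

test_that("a negative suction energy flags a cluster that never enters", {
  big <- cluster_cylinder(11.5, 15, eps_co = 0.040)  # beyond b2_zero
  expect_warning(
    tr <- simulate_transport(sys, big, transport_config(t_max = 1e3),
                             eps_co = 0.040),
    "not drawn")
  expect_true(attr(tr, "never_enters"))
})

test_that("trajectory diagnostics recover peak and arrival from the series", {
  tr <- simulate_transport(sys, cl30, transport_config(t_max = 1.5e5),
                           eps_co = 0.040, W = W30)
  ana <- analyze_trajectory(tr, L = sys$L, d = 15)
  diag <- attr(tr, "diagnostics")
  expect_equal(ana$V_max_m_s, diag$V_max_m_s, tolerance = 1e-6)
  expect_equal(ana$t_exit_ps, diag$t_exit_ps, tolerance = 0.05)
  expect_true(ana$reached_far_end)
  # a strictly accelerating fragment puts the peak at the last sample
  frag <- tr[tr$t <= 3000, ]
  ana2 <- analyze_trajectory(frag, L = sys$L, d = 15)
  expect_equal(ana2$V_max_m_s, frag$V[nrow(frag)] * 1e5)
  expect_false(ana2$reached_far_end)
})
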