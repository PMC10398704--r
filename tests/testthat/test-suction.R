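# Suction energy, characteristic radii, and the axial force.

sys <- tube_system()   # b1 = 13.56, L = 500

test_that("suction energy is positive at the study geometry and additive in length", {
  w15 <- suction_energy(sys, cluster_cylinder(10.40, 15, eps_co = 0.040))
  expect_gt(w15, 0)
  w30 <- suction_energy(sys, cluster_cylinder(10.40, 30, eps_co = 0.040))
  expect_equal(w30, 2 * w15, tolerance = 0.01)  # interior plateau additivity
})

test_that("zero-suction radius solves W = 0 and barely depends on cluster length", {
  b2z <- find_b2_zero(sys, d = 15, eps_co = 0.040)
  W <- cntflow:::suction_of_b2(sys, 15, 0.040)
  expect_lt(abs(W(b2z)), 1e-2 * abs(W(10.40)))
  b2z_long <- find_b2_zero(sys, d = 30, eps_co = 0.040)
  expect_equal(b2z, b2z_long, tolerance = 0.01)
})

test_that("characteristic radii shrink (weakly) as the wall turns hydrophilic", {
  zeros <- vapply(c(0.04, 0.10, 0.16),
                  function(e) find_b2_zero(sys, 15, e), 0)
  stars <- vapply(c(0.04, 0.10, 0.16),
                  function(e) find_b2_star(sys, 15, e)$b2_star, 0)
  expect_true(all(diff(zeros) <= 0))
  expect_true(all(diff(stars) <= 0))
  # the wall gaps, not the radii, are the invariant of the system
  expect_equal(sys$b1 - zeros[1], 2.7, tolerance = 0.1)
  expect_equal(sys$b1 - stars[1], 3.1, tolerance = 0.1)
})

test_that("root finding demands a sign change and reports a useless bracket", {
  expect_error(find_b2_zero(sys, 15, 0.040, bracket = c(7, 9)), "sign change")
})

test_that("force profile is antisymmetric, mouth-localised, and consistent with the energy", {
  ssys <- tube_system(b1 = 6, L = 60)
  scl <- cluster_cylinder(3, 5, eps_co = 0.040)
  Zg <- seq(-20, 80, by = 0.25)
  suppressWarnings(fp <- force_profile(ssys, scl, Zg))
  mid <- which(Zg == 30)
  expect_equal(fp$F[mid], 0, tolerance = 1e-6 * attr(fp, "F0"))
  # antisymmetry about L/2
  expect_equal(fp$F, -rev(fp$F), tolerance = 1e-4 * attr(fp, "F0"))
  # interior quiet zone (mouth tails reach ~2d into this short tube)
  interior <- Zg > 25 & Zg < 35
  expect_lt(max(abs(fp$F[interior])), 1e-3 * attr(fp, "F0"))
  # work-energy: integral of F over the entry side equals the suction energy
  W <- suction_energy(ssys, scl)
  h <- 0.25
  entry <- fp$F[Zg <= 30]
  impulse <- h * (sum(entry) - 0.5 * (entry[1] + entry[length(entry)]))
  expect_equal(impulse, W, tolerance = 0.01)
  # and integrating the force reproduces the energy drop (round trip)
  E <- attr(fp, "energy")$E
  cumint <- -h * (cumsum(fp$F) - 0.5 * (fp$F + fp$F[1]))
  expect_lt(max(abs((E[1] + cumint) - E)[interior]) / abs(E[mid]), 0.005)
})

test_that("force profile warns when the mouth regions are under-resolved", {
  ssys <- tube_system(b1 = 6, L = 60)
  scl <- cluster_cylinder(3, 5, eps_co = 0.040)
  expect_warning(force_profile(ssys, scl, seq(-20, 80, by = 2)), "0.5 A")
})

test_that("Heaviside force model has matched windows, antisymmetry, and impulse", {
  F0 <- 2.5; L <- 500; d <- 15
  expect_equal(heaviside_force(L / 2, F0, L, d), 0)
  Zs <- seq(-2 * d, L + 2 * d, by = 0.5)
  expect_equal(heaviside_force(Zs, F0, L, d),
               -heaviside_force(L - Zs, F0, L, d))
  expect_equal(heaviside_force(0, F0, L, d), F0)
  expect_equal(heaviside_force(L, F0, L, d), -F0)
  # impulse over the entry window: 2 d F0, i.e. W for F0 = W/(2d)
  zz <- seq(-d - 5, d + 5, by = 0.001)
  imp <- sum(heaviside_force(zz, F0, L, d)) * 0.001
  expect_equal(imp, 2 * d * F0, tolerance = 1e-3)
})

test_that("suction scan summarises the radii and gaps coherently", {
  res <- suction_scan(sys, d = 15, eps_co = 0.040,
                      b2_grid = seq(9, 11, length.out = 5))
  expect_s3_class(res, "suction_result")
  expect_lt(res$b2_star, res$b2_zero)
  expect_lt(res$b2_zero, sys$b1)
  expect_equal(res$delta0, sys$b1 - res$b2_zero)
  expect_equal(res$delta_max, sys$b1 - res$b2_star)
  expect_gte(res$W_max, max(res$scan$W))
})
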