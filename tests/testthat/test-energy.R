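# The continuum energy and its validation oracles.

small_sys <- tube_system(b1 = 6, L = 20)
small_cl <- cluster_cylinder(3, 5, eps_co = 0.040)

test_that("axial integral decays to nothing far outside the tube", {
  # rho^-12 dies within ten tube lengths; the slower rho^-6 within a hundred
  far6 <- cyl_integral_i(small_sys, small_cl, Z = -10 * small_sys$L, n = 6L)
  expect_lt(abs(far6), 1e-12 * abs(cyl_integral_i(small_sys, small_cl, 10, 6L)))
  far3 <- cyl_integral_i(small_sys, small_cl, Z = -100 * small_sys$L, n = 3L)
  expect_lt(abs(far3), 1e-12 * abs(cyl_integral_i(small_sys, small_cl, 10, 3L)))
})

test_that("axial integral is symmetric about the tube midpoint", {
  for (n in c(3L, 6L)) {
    for (x in c(3, 7, 12)) {
      expect_equal(cyl_integral_i(small_sys, small_cl, 10 + x, n),
                   cyl_integral_i(small_sys, small_cl, 10 - x, n),
                   tolerance = 1e-8)
    }
  }
})

test_that("continuum energy equals 4-D quadrature of the primitive integral", {
  # the hypergeometric reduction against the raw double-surface integral
  for (i in 1:20) {
    g <- random_small_system(i)
    e_cont <- total_energy(g$system, g$cluster, g$Z)
    e_quad <- quad4d_energy(g$system, g$cluster, g$Z)
    expect_equal(e_cont, e_quad, tolerance = 1e-5,
                 label = sprintf("continuum energy (system %d)", i))
  }
})

test_that("discrete lattice sums converge to the continuum energy", {
  sys <- tube_system(b1 = 5, L = 12)
  cl <- cluster_cylinder(2.5, 3, eps_co = 0.040)
  e_cont <- total_energy(sys, cl, Z = 6)
  m <- cl$medium
  err <- vapply(c(1.0, 0.5, 0.3), function(spacing) {
    dens <- 1 / spacing^2
    la <- make_lattice(5, 12, dens)
    lb <- make_lattice(2.5, 6, dens)
    lb$coordinates[, 3] <- lb$coordinates[, 3] + 3   # cluster z in [3, 9]
    e <- pairwise_sum(la, lb, m$A_cw, m$B_cw) *
      (sys$eta_c / la$achieved_density) * (m$eta_w / lb$achieved_density)
    abs(e - e_cont) / abs(e_cont)
  }, 0)
  expect_lt(err[3], 0.02)            # within 2% at 0.3 A spacing
  expect_lt(err[2], 0.02)
})

test_that("energy profile is symmetric with a flat, attractive interior", {
  sys <- tube_system()
  cl <- cluster_cylinder(10.40, 30, eps_co = 0.040)
  Zs <- c(200, 250, 300)
  prof <- energy_profile(sys, cl, Zs)
  expect_lt(prof$E[2], 0)                       # attraction-dominated
  expect_equal(prof$E[1], prof$E[3], tolerance = 1e-8)
  expect_lt(abs(prof$E[2] - prof$E[1]) / abs(prof$E[2]), 1e-3)  # plateau
})

test_that("longer clusters and stronger wettability both deepen the interior energy", {
  sys <- tube_system()
  e_short <- total_energy(sys, cluster_cylinder(10.466, 15, eps_co = 0.040), 250)
  e_long <- total_energy(sys, cluster_cylinder(10.466, 60, eps_co = 0.040), 250)
  expect_lt(e_long, e_short)

  e_hydrophobic <- total_energy(sys, cluster_cylinder(10.40, 30, eps_co = 0.040), 250)
  e_hydrophilic <- total_energy(sys, cluster_cylinder(10.40, 30, eps_co = 0.160), 250)
  expect_lt(e_hydrophilic, e_hydrophobic)
})

test_that("near-contact geometries are rejected instead of hitting the singularity", {
  expect_error(total_energy(small_sys, cluster_cylinder(5.8, 5, eps_co = 0.040), 10),
               "singular")
})

test_that("energy profiles round-trip through the CSV contract", {
  prof <- energy_profile(small_sys, small_cl, seq(0, 20, by = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_energy_profile(prof, path)
  expect_identical(readLines(path, n = 1), "Z_angstrom,E_kcal_per_mol")
  back <- read_energy_profile(path)
  expect_equal(back$Z, prof$Z)
  expect_equal(back$E, prof$E, tolerance = 1e-12)
})
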