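test_that("bending energy anchors match closed forms", {
  p <- membrane_params(kappa_kbt = 25, sigma = 0.02)
  # sphere: 8*pi*kappa, independent of radius
  for (R in c(100, 400, 1500)) {
    e <- helfrich_energy(sphere_state(R), p)
    expect_equal(e$bending, 8 * pi * 25, tolerance = 1e-4)
    expect_equal(e$area, 4 * pi * R^2, tolerance = 1e-4)
    expect_equal(e$volume, 4 / 3 * pi * R^3, tolerance = 1e-4)
  }
  # cylinder: pi*kappa*L/r
  p0 <- membrane_params(kappa_kbt = 25, sigma = 0, c_ext_mosm = 0,
                        n_solute = 0)
  cs <- cylinder_state(100, 1000, n = 256, perturb = 0)
  expect_equal(helfrich_energy(cs, p0)$bending, pi * 25 * 1000 / 100,
               tolerance = 1e-9)
  # flat limit: bending energy per unit area vanishes as r grows
  dens <- vapply(c(100, 1000, 10000), function(r) {
    e <- helfrich_energy(cylinder_state(r, 10 * r, n = 64, perturb = 0), p0)
    e$bending / e$area
  }, numeric(1))
  expect_true(all(diff(dens) < 0))
  expect_lt(dens[3] / dens[1], 1e-3)
})

test_that("energy quadrature is refinement-convergent", {
  p <- membrane_params(kappa_kbt = 40, sigma = 0.02)
  e1 <- helfrich_energy(cylinder_state(85, 900, n = 128, perturb = 0.3), p)
  e2 <- helfrich_energy(cylinder_state(85, 900, n = 256, perturb = 0.3), p)
  expect_lt(abs(e2$total - e1$total) / abs(e1$total), 1e-3)
  expect_error(helfrich_energy(
    structure(list(type = "periodic", z = 1:64, r = rep(-1, 64), L = 64,
                   h = 1), class = "shape_state"), p), "positive")
})

test_that("the analytic energy gradient matches finite differences", {
  p <- membrane_params(kappa_kbt = 40, sigma = 0.02, c_ext_mosm = 300)
  st <- cylinder_state(85, 900, n = 64, perturb = 0.1)
  n_sol <- p$c_ext * pi * 85^2 * 900
  eg <- axonpearl:::.tube_energy_grad(st$r, st$h, p, n_sol)
  idx <- c(1, 5, 17, 33, 50)
  d <- 1e-3
  for (i in idx) {
    rp <- st$r; rp[i] <- rp[i] + d
    rm <- st$r; rm[i] <- rm[i] - d
    gnum <- (axonpearl:::.tube_energy_grad(rp, st$h, p, n_sol, FALSE)$energy -
               axonpearl:::.tube_energy_grad(rm, st$h, p, n_sol, FALSE)$energy) /
      (2 * d)
    expect_equal(eg$grad[i], gnum, tolerance = 1e-4)
  }
})

test_that("osmotic pressure follows the van 't Hoff form", {
  p <- membrane_params(c_ext_mosm = 300, n_solute = 1e6)
  viso <- 1e6 / mosm_to_nm3(300)
  expect_equal(osmotic_pressure(viso, p), 0, tolerance = 1e-12)
  # doubling c_ext at fixed V lowers the pressure by exactly kT * c_ext
  v <- 2e7
  p2 <- membrane_params(c_ext_mosm = 600, n_solute = 1e6)
  expect_equal(osmotic_pressure(v, p2) - osmotic_pressure(v, p),
               -mosm_to_nm3(300))
  # V -> infinity: -kT c_ext
  expect_equal(osmotic_pressure(1e18, p), -mosm_to_nm3(300),
               tolerance = 1e-6)
  expect_lt(osmotic_pressure(2 * viso, p), osmotic_pressure(viso, p))
  expect_error(osmotic_pressure(-1, p), "positive")
})

test_that("the equilibrium sphere obeys Young-Laplace", {
  p <- membrane_params(kappa_kbt = 30, sigma = 0.02, c_ext_mosm = 300,
                       n_solute = mosm_to_nm3(300) * 4 / 3 * pi * 200^3)
  eq <- equilibrium_sphere(p)
  expect_equal(eq$delta_p, eq$laplace_p, tolerance = 0.01)
  expect_gt(eq$delta_p, 0)
  # vanishing tension: near-isotonic sphere with zero pressure difference
  p0 <- membrane_params(kappa_kbt = 30, sigma = 0, c_ext_mosm = 300,
                        n_solute = mosm_to_nm3(300) * 4 / 3 * pi * 200^3)
  eq0 <- equilibrium_sphere(p0)
  expect_equal(eq0$radius, 200, tolerance = 0.01)
  expect_equal(eq0$delta_p / mosm_to_nm3(300), 0, tolerance = 1e-4)
})

test_that("a high-tension tube pearls and a bending-dominated tube stays cylindrical", {
  # sigma r0^2 / kappa >> 1: the stability oracle flags the instability and
  # the relaxed modulation is deep
  p <- membrane_params(kappa_kbt = 50, sigma = 0.02, c_ext_mosm = 300)
  st <- pearling_stability(85, 1050, p)
  expect_true(st$unstable)
  rl <- relaxed_control()
  mod <- (max(rl$state$r) - min(rl$state$r)) / 85
  expect_gt(mod, 0.05)
  expect_true(rl$converged)
  expect_false(rl$pinched)
  # kappa-dominated: oracle stable, relaxed modulation < 1%
  p2 <- membrane_params(kappa_kbt = 50, sigma = 1e-4, c_ext_mosm = 300)
  expect_false(pearling_stability(85, 900, p2)$unstable)
  rl2 <- relax_shape(cylinder_state(85, 900, n = 96), p2, tol = 1e-4,
                     max_iter = 20000)
  expect_lt((max(rl2$state$r) - min(rl2$state$r)) / 85, 0.01)
})

test_that("accepted relaxation steps never increase the energy", {
  rl <- relaxed_control()
  expect_true(all(diff(rl$energy_trace) <= 1e-9))
  # and the pressure balance is recomputed from the final volume
  expect_equal(
    osmotic_pressure(rl$energy$volume, rl$params),
    rl$params$n_solute / rl$energy$volume - rl$params$c_ext)
})

test_that("relaxation is deterministic and pinch-off is flagged", {
  p <- membrane_params(kappa_kbt = 50, sigma = 0.02, c_ext_mosm = 300)
  r1 <- relax_shape(cylinder_state(85, 800, n = 64), p, max_iter = 500)
  r2 <- relax_shape(cylinder_state(85, 800, n = 64), p, max_iter = 500)
  expect_identical(r1$state$r, r2$state$r)
  # a harsh r_min threshold turns a deep neck into a flagged termination
  r3 <- relax_shape(cylinder_state(85, 1050, n = 96, perturb = 0.1), p,
                    tol = 0, max_iter = 40000, r_min = 55)
  expect_true(r3$pinched)
  expect_true(min(r3$state$r) < 55 + 5)
})

test_that("relaxed shapes feed straight into morphometry", {
  rl <- relaxed_control()
  prof <- shape_to_profile(rl$state)
  segs <- segment_profile(prof)
  expect_gt(sum(segs$kind == "nsv"), 1)
  nsv <- segs[segs$kind == "nsv", ]
  expect_true(all(nsv$width > 100 & nsv$width < 500))
})

test_that("the selected pearl period is in the experimentally observed range", {
  p <- membrane_params(kappa_kbt = 50, sigma = 0.02, c_ext_mosm = 300)
  lam <- fastest_growing_wavelength(85, p)
  expect_gt(lam, 500); expect_lt(lam, 2000)
  # all modes stable in the bending-dominated regime
  p2 <- membrane_params(kappa_kbt = 50, sigma = 1e-4, c_ext_mosm = 300)
  expect_true(is.na(fastest_growing_wavelength(85, p2,
                                               wavelengths = seq(300, 1500,
                                                                 by = 100))))
})

test_that("osmolarity sweep shrinks NSVs monotonically", {
  sw <- cached("sweep_osm", {
    p <- membrane_params(kappa_kbt = 50, sigma = 0.03, c_ext_mosm = 300)
    sweep_membrane_parameters(p, c_ext_mosm = c(150, 300, 600), tol = 1e-4,
                              max_iter = 40000)
  })
  expect_true(all(sw$converged))
  expect_true(all(diff(sw$nsv_width) < 0))
  expect_true(all(diff(sw$nsv_length) < 0))
})
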