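test_that("pearl chain backbone reproduces the requested dimensions", {
  g <- gen_pearl_profile(pearl_chain_spec(600, 311, 552, 127,
                                          n_periods = 6, seed = 1))
  expect_equal(g$truth$period, 1152)
  expect_equal(max(2 * g$profile$r), 311, tolerance = 1e-10)
  expect_equal(min(2 * g$profile$r), 127, tolerance = 1e-10)
  segs <- g$truth$segments
  expect_true(all(diff(g$truth$boundaries) > 0))
  expect_true(all(segs$kind[-1] != segs$kind[-nrow(segs)]))  # alternation
  full <- segs[!segs$partial, ]
  expect_equal(unique(full$length[full$kind == "nsv"]), 600)
  expect_equal(unique(full$length[full$kind == "connector"]), 552)
})

test_that("generation is deterministic in the seed and spec", {
  s <- pearl_chain_spec(500, 250, 400, 100, n_periods = 4, jitter_cv = 0.08,
                        noise_sd = 2, seed = 42)
  g1 <- gen_pearl_profile(s); g2 <- gen_pearl_profile(s)
  expect_identical(g1, g2)
  g3 <- gen_pearl_profile(pearl_chain_spec(500, 250, 400, 100, n_periods = 4,
                                           jitter_cv = 0.08, noise_sd = 2,
                                           seed = 43))
  expect_false(identical(g1$profile$r, g3$profile$r))
})

test_that("a nearly-inverted spec degenerates to a near-cylinder with exact boundaries", {
  g <- gen_pearl_profile(pearl_chain_spec(600, 127.5, 552, 127,
                                          n_periods = 4, seed = 1))
  expect_lt(diff(range(g$profile$r)), 0.3)
  b <- g$truth$boundaries
  expect_equal(b[1], 552 / 2)          # first inflection at half a connector
  expect_equal(diff(b)[1:2], c(600, 552))
})

test_that("invalid chain specs are rejected", {
  expect_error(pearl_chain_spec(-1, 300, 500, 100), "positive")
  expect_error(pearl_chain_spec(600, 100, 500, 120), "nsv_width")
  expect_error(pearl_chain_spec(600, 300, 500, 100, jitter_cv = -1))
})

test_that("population cohorts match the requested statistics", {
  means <- c(600, 311, 552, 127); sds <- c(60, 30, 60, 12)
  n <- 300
  pop <- gen_population(means, sds, n_axons = n, seed = 5, n_periods = 3)
  nsv <- pop$truth[pop$truth$kind == "nsv", ]
  conn <- pop$truth[pop$truth$kind == "connector" & !pop$truth$partial, ]
  got <- c(mean(tapply(nsv$length, nsv$axon, mean)),
           mean(tapply(nsv$width, nsv$axon, mean)),
           mean(tapply(conn$length, conn$axon, mean)),
           mean(tapply(conn$width, conn$axon, mean)))
  expect_true(all(abs(got - means) < 3 * sds / sqrt(n)))
  # zero sds: every axon identical to the mean spec
  pop0 <- gen_population(means, c(0, 0, 0, 0), n_axons = 3, seed = 5,
                         n_periods = 3)
  expect_equal(pop0$profiles[[1]]$r, pop0$profiles[[2]]$r)
  expect_equal(max(2 * pop0$profiles[[1]]$r), 311)
  expect_error(gen_population(means, sds, n_axons = 0), "at least 1")
})

test_that("synaptic flagging follows the requested fraction", {
  pop <- gen_population(c(600, 311, 552, 127), c(10, 10, 10, 5),
                        n_axons = 200, synaptic_fraction = 0.3, seed = 9,
                        n_periods = 5)
  flags <- pop$truth$is_synaptic[pop$truth$kind == "nsv"]
  n <- length(flags)   # 1000 varicosities
  ci <- 0.3 + c(-1, 1) * 2.58 * sqrt(0.3 * 0.7 / n)
  expect_gt(mean(flags), ci[1])
  expect_lt(mean(flags), ci[2])
})

test_that("STED profiles broaden as Gaussian convolution predicts", {
  # area profile that is itself Gaussian: radius = sqrt(area/pi)
  x <- seq(0, 4000, by = 5)
  w <- 300                                   # area FWHM, nm
  s_area <- w / (2 * sqrt(2 * log(2)))
  area <- 1e4 * exp(-(x - 2000)^2 / (2 * s_area^2)) + 50
  prof <- radius_profile(x, sqrt(area / pi))
  # near-delta PSF: intensity FWHM = area FWHM
  i0 <- gen_sted_profile(prof, psf_fwhm = 1e-3, pixel = 5)
  expect_equal(fwhm_length(i0)[1], w, tolerance = 0.02)
  # finite PSF: quadrature sum of widths
  p <- 200
  i1 <- gen_sted_profile(prof, psf_fwhm = p, pixel = 5)
  expect_equal(fwhm_length(i1)[1], sqrt(w^2 + p^2), tolerance = 0.02)
})

test_that("an organotypic-scale NSV measured by STED matches a convolution oracle", {
  g <- gen_pearl_profile(pearl_chain_spec(326, 177, 652, 52, n_periods = 3,
                                          seed = 2))
  prof <- g$profile
  ii <- gen_sted_profile(prof, psf_fwhm = 50, pixel = 10)
  got <- fwhm_length(ii)
  # oracle: direct quadrature convolution of the area profile on a fine grid
  area <- pi * prof$r^2
  sigma <- 50 / (2 * sqrt(2 * log(2)))
  conv <- vapply(seq_along(prof$x), function(i) {
    k <- stats::dnorm(prof$x - prof$x[i], sd = sigma)
    sum(k * area) / sum(k)
  }, numeric(1))
  oracle <- fwhm_length(list(x = prof$x, intensity = conv))
  expect_equal(length(got), length(oracle))
  expect_true(all(abs(got - oracle) / oracle < 0.1))
  # poisson noise is seeded and deterministic
  in1 <- gen_sted_profile(prof, 50, 10, noise = 500, seed = 3)
  in2 <- gen_sted_profile(prof, 50, 10, noise = 500, seed = 3)
  expect_identical(in1, in2)
  expect_error(gen_sted_profile(prof, 50, pixel = 1e6), "exceeds")
})

test_that("serial-section stacks encode the Pythagorean ground truth", {
  s1 <- gen_serial_sections(300, 2, 40, seed = 1)
  expect_equal(s1$truth_3d_nm, sqrt(300^2 + 40^2))
  expect_equal(reconstruct_3d(s1), s1$truth_3d_nm, tolerance = 1e-12)
  s2 <- gen_serial_sections(0, 6, 40, seed = 1)
  expect_equal(s2$truth_3d_nm, 200)
  expect_equal(reconstruct_3d(s2), 200)
  # any random stack: recomputation reproduces the stored truth exactly
  for (seed in 1:5) {
    s <- gen_serial_sections(runif(1, 50, 2000), sample(2:12, 1), 40,
                             seed = seed)
    expect_equal(reconstruct_3d(s), s$truth_3d_nm, tolerance = 1e-12)
  }
  expect_error(gen_serial_sections(100, 1), "at least 2")
  expect_error(gen_serial_sections(100, 3, thickness = 0), "positive")
})

test_that("profiles and stacks round-trip through their text formats", {
  g <- gen_pearl_profile(pearl_chain_spec(600, 311, 552, 127, n_periods = 3,
                                          noise_sd = 1, seed = 7))
  f <- withr::local_tempfile(fileext = ".txt")
  write_radius_profile(g$profile, f)
  back <- read_radius_profile(f)
  expect_equal(back$x, g$profile$x)
  expect_equal(back$r, g$profile$r, tolerance = 1e-12)
  expect_equal(back$meta$seed, 7L)
  s <- gen_serial_sections(500, 5, 40, seed = 3)
  fs <- withr::local_tempfile(fileext = ".json")
  write_section_stack(s, fs)
  back2 <- read_section_stack(fs)
  expect_equal(back2$truth_3d_nm, s$truth_3d_nm)
  expect_equal(back2$displacements, s$displacements)
})
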