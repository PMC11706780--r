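test_that("inflection boundaries of a cosine chain sit at the analytic positions", {
  lam <- 800
  x <- seq(0, 10 * lam, by = 5)
  prof <- radius_profile(x, 100 + 30 * cos(2 * pi * x / lam))
  segs <- segment_profile(prof, smoothing_nm = 15)
  expect_gt(nrow(segs), 10)
  # boundaries at lam/4 + k*lam/2
  expect_equal(unique(round(segs$length, 6)), lam / 2, tolerance = 1e-3)
  k <- round((segs$start - lam / 4) / (lam / 2))
  expect_equal(segs$start, lam / 4 + k * lam / 2, tolerance = 1e-3)
  expect_true(all(segs$kind[-1] != segs$kind[-nrow(segs)]))
})

test_that("a constant-radius cylinder yields zero segments", {
  prof <- radius_profile(seq(0, 5000, 5), rep(100, 1001))
  expect_identical(nrow(segment_profile(prof)), 0L)
})

test_that("noiseless synthetic profiles are recovered within one sample spacing", {
  g <- gen_pearl_profile(pearl_chain_spec(600, 311, 552, 127, n_periods = 6,
                                          seed = 2))
  segs <- segment_profile(g$profile)
  h <- g$profile$spacing
  nsv <- segs[segs$kind == "nsv", ]
  conn <- segs[segs$kind == "connector", ]
  expect_true(all(abs(nsv$length - 600) <= h))
  expect_true(all(abs(nsv$width - 311) <= h))
  expect_true(all(abs(conn$length - 552) <= h))
  expect_true(all(abs(conn$width - 127) <= h))
  # smoothing must be wider than the sampling
  expect_error(segment_profile(g$profile, smoothing_nm = 5), "twice")
})

test_that("round-trip recovery holds across 200 random chain specs", {
  set.seed(99)
  worst <- 0
  for (i in 1:200) {
    nw <- runif(1, 150, 420)
    cw <- runif(1, 0.15, 0.7) * nw
    nl <- runif(1, 250, 750)
    cl <- runif(1, 220, 700)
    g <- gen_pearl_profile(pearl_chain_spec(nl, nw, cl, cw, n_periods = 3,
                                            seed = i))
    segs <- segment_profile(g$profile)
    nsv <- segs[segs$kind == "nsv", ]
    conn <- segs[segs$kind == "connector", ]
    err <- max(abs(nsv$length - nl), abs(nsv$width - nw),
               abs(conn$length - cl), abs(conn$width - cw))
    worst <- max(worst, err)
  }
  expect_lte(worst, g$profile$spacing)
})

test_that("segmentation is invariant to translation and reflection", {
  g <- gen_pearl_profile(pearl_chain_spec(500, 260, 420, 110, n_periods = 4,
                                          seed = 3))
  segs <- segment_profile(g$profile)
  shifted <- radius_profile(g$profile$x + 777, g$profile$r)
  s2 <- segment_profile(shifted)
  expect_equal(s2$start, segs$start + 777, tolerance = 1e-9)
  expect_equal(s2$width, segs$width)
  mirrored <- radius_profile(g$profile$x, rev(g$profile$r))
  s3 <- segment_profile(mirrored)
  expect_equal(sort(s3$length), sort(segs$length), tolerance = 1e-6)
  expect_equal(sort(s3$width), sort(segs$width), tolerance = 1e-6)
})

test_that("boundary count never grows with the smoothing window on noisy data", {
  g <- gen_pearl_profile(pearl_chain_spec(600, 311, 552, 127, n_periods = 8,
                                          noise_sd = 3, seed = 4))
  counts <- vapply(c(10, 20, 30, 50, 70, 100),
                   function(w) nrow(segment_profile(g$profile, w)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("cohort means shift under mild noise by less than 5%", {
  clean <- measured_cohort(n_axons = 20, noise_sd = 0)$summary
  # noise at 5% of the connector radius (127/2 * 0.05 ~ 3.2 nm), smoothed
  # at a scale a practitioner would pick for noisy traces
  noisy <- measured_cohort(n_axons = 20, noise_sd = 3.1, smoothing = 25)$summary
  shift <- abs(noisy$mean_nm - clean$mean_nm) / clean$mean_nm
  expect_true(all(shift < 0.05))
})

test_that("segment measurement conventions are honoured", {
  # single cosine NSV: width equals the peak diameter exactly
  lam <- 1200
  x <- seq(0, 3 * lam, 5)
  prof <- radius_profile(x, 90 + 40 * cos(2 * pi * x / lam))
  rec <- measure_axon(prof)
  expect_equal(max(rec$nsv$width), 2 * 130, tolerance = 0.05)
  # degenerate flat connector: width = its diameter whatever the estimator
  g <- gen_pearl_profile(pearl_chain_spec(400, 300, 600, 140, n_periods = 4,
                                          seed = 6))
  rec2 <- measure_axon(g$profile)
  expect_equal(unique(round(rec2$connector$width, 6)), 140)
  # s.e.m. = sd/sqrt(n)
  s <- summary(rec2)
  nl <- rec2$nsv$length
  expect_equal(s$sem_nm[s$dimension == "nsv_length"],
               sd(nl) / sqrt(length(nl)))
})

test_that("exclusion rules drop synaptic varicosities and non-axonal structures", {
  rec <- function(n_syn, n_tot, maxd, term) {
    r <- measure_axon(gen_pearl_profile(
      pearl_chain_spec(500, 260, 420, 110, n_periods = n_tot,
                       seed = 1))$profile)
    r$nsv$is_synaptic <- seq_len(nrow(r$nsv)) <= n_syn
    r$max_diameter_nm <- maxd
    r$has_terminal <- term
    r
  }
  out <- apply_exclusions(list(rec(3, 10, 500, TRUE)))
  expect_equal(out$removed_synaptic, 3L)
  expect_equal(nrow(out$records[[1]]$nsv), 7L)
  # 1.2 um structure with no presynaptic terminal is not an axon
  out2 <- apply_exclusions(list(rec(0, 5, 1200, FALSE), rec(0, 5, 1200, TRUE)))
  expect_equal(out2$removed_axons, 1L)
  expect_length(out2$records, 1L)
  # identity when nothing is flagged
  rl <- list(rec(0, 5, 400, TRUE))
  out3 <- apply_exclusions(rl)
  expect_equal(out3$records, rl)
  expect_equal(out3$removed_synaptic, 0L)
})

test_that("FWHM measurement matches closed forms", {
  # unit triangle of base 200 nm on zero background
  x <- seq(0, 1000, 2)
  tri <- pmax(0, 1 - abs(x - 500) / 100)
  expect_equal(fwhm_length(list(x = x, intensity = tri))[1], 100,
               tolerance = 1e-6)
  # Gaussian peak: FWHM = 2.3548 sd
  s <- 80
  gs <- exp(-(x - 500)^2 / (2 * s^2))
  expect_equal(fwhm_length(list(x = x, intensity = gs))[1],
               2 * sqrt(2 * log(2)) * s, tolerance = 0.01)
  # featureless profile: nothing to measure
  expect_length(fwhm_length(list(x = x, intensity = rep(1, length(x)))), 0)
})

test_that("spacing periodicity quantifies proximity to the 190-nm lattice", {
  centers <- 190 * (1:30)
  out <- spacing_periodicity(centers)
  expect_equal(out$fraction_periodic, 1.0)
  # pearl-chain periods (~1152 nm) are nowhere near 190 nm
  g <- gen_pearl_profile(pearl_chain_spec(600, 311, 552, 127, n_periods = 8,
                                          seed = 2))
  segs <- segment_profile(g$profile)
  nsv <- segs[segs$kind == "nsv", ]
  out2 <- spacing_periodicity((nsv$start + nsv$end) / 2)
  expect_equal(out2$fraction_periodic, 0.0)
  # uniform spacings over [0, 1200]: interval proportion 38/1200
  set.seed(1)
  sp <- runif(30000, 0, 1200)
  out3 <- spacing_periodicity(cumsum(sp))
  p <- 38 / 1200
  expect_equal(out3$fraction_periodic, p,
               tolerance = 4 * sqrt(p * (1 - p) / 30000) / p)
  expect_error(spacing_periodicity(100), "at least two")
})

test_that("3D reconstruction applies the Pythagorean correction", {
  s <- gen_serial_sections(300, 2, 40, seed = 1)
  expect_equal(reconstruct_3d(s, 300), sqrt(300^2 + 40^2))
  expect_equal(reconstruct_3d(gen_serial_sections(0, 6, 40, seed = 1)), 200)
  expect_error(reconstruct_3d(s, -5), "non-negative")
})

test_that("cohort summaries have the reported structure and symmetry", {
  one <- measure_axon(gen_pearl_profile(
    pearl_chain_spec(600, 311, 552, 127, n_periods = 1, seed = 1))$profile)
  s1 <- summarize_morphometry(list(one))
  expect_equal(s1$sem_nm[s1$dimension == "nsv_length"], 0)
  expect_equal(s1$mean_nm[s1$dimension == "nsv_length"], 600,
               tolerance = 0.01)
  recs <- measured_cohort()$records
  s2 <- summarize_morphometry(c(recs, recs), groups = rep(c("a", "b"),
                                                          each = length(recs)))
  expect_equal(s2$mean_nm[s2$group == "a"], s2$mean_nm[s2$group == "b"])
  empty_rec <- measure_segments(segment_profile(
    radius_profile(seq(0, 5000, 5), rep(100, 1001))))
  expect_warning(summarize_morphometry(list(one, empty_rec),
                                       groups = c("x", "empty")),
                 "omitted")
})

test_that("an organotypic-style cohort summarizes within 3 s.e.m. of its targets", {
  means <- c(326, 177, 252, 52)
  sds <- c(7, 3, 10, 2) * sqrt(133)   # back-computed from reported s.e.m.
  pop <- gen_population(means, pmin(sds, 0.35 * means), n_axons = 80,
                        seed = 21, n_periods = 4)
  recs <- lapply(pop$profiles, function(p)
    measure_segments(segment_profile(p), p$annotations))
  summ <- summarize_morphometry(recs)
  expect_true(all(abs(summ$mean_nm - means) <= 3 * summ$sem_nm +
                    pop$profiles[[1]]$spacing))
})
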