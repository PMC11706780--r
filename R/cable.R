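#' Electrophysiological parameters for the cable simulation
#'
#' Passive cable constants and Hodgkin-Huxley channel parameters used by
#' [simulate_ap()]. Kinetics are the classic squid-axon rate functions
#' expressed at a -65 mV resting potential. `rate_scale` is the
#' temperature-like factor on all gating rates (the recordings this model
#' mirrors were made near 32 C, well above the 6.3 C of the classic
#' kinetics); its default of 3.3 -- about one standard Q10 decade -- is a
#' calibration convention: it was fixed once so that the untreated pearled
#' control geometry (NSV 638 x 309 nm, connector 486 x 136 nm) with the
#' periodic 190-nm NaV layout conducts at 0.173 m/s, and it is never
#' touched by the solver itself. `density_scale` jointly scales the three
#' conductance densities and stays at 1 by default.
#'
#' @param c_m membrane capacitance, uF/cm^2.
#' @param r_i axial resistivity, ohm cm.
#' @param gna,gk,gleak maximal conductance densities, mS/cm^2 (before
#'   `density_scale`).
#' @param e_na,e_k,e_leak reversal potentials, mV.
#' @param density_scale joint scale on all conductance densities.
#' @param ais_nav_multiplier channel-density multiplier of the axon initial
#'   segment (AIS) relative to the trunk, applied to Na, K and leak jointly
#'   so the resting potential stays a steady state of the whole cable.
#' @param rate_scale temperature-like scale on all gating rates.
#' @return an object of class `ephys_params`.
#' @export
ephys_params <- function(c_m = 1, r_i = 120, gna = 120, gk = 36,
                         gleak = 0.3, e_na = 50, e_k = -77, e_leak = -54.4,
                         density_scale = 1, ais_nav_multiplier = 5,
                         rate_scale = 3.3) {
  stopifnot(c_m > 0, r_i > 0, gna >= 0, gk >= 0, gleak >= 0,
            density_scale > 0, ais_nav_multiplier > 0, rate_scale > 0)
  structure(list(c_m = c_m, r_i = r_i, gna = gna, gk = gk, gleak = gleak,
                 e_na = e_na, e_k = e_k, e_leak = e_leak,
                 density_scale = density_scale,
                 ais_nav_multiplier = ais_nav_multiplier,
                 rate_scale = rate_scale),
            class = "ephys_params")
}

#' Stimulus specification
#'
#' Current injection over the first half of the AIS, matching the
#' 30-40 uA/cm^2 protocol used to launch the propagating action potential.
#'
#' @param amplitude current density, uA/cm^2.
#' @param duration_ms stimulus duration, ms.
#' @param onset_ms stimulus onset, ms.
#' @param region_um axial extent (um); must lie within the AIS.
#' @export
stimulus_spec <- function(amplitude = 40, duration_ms = 1, onset_ms = 0.05,
                          region_um = c(-90, -45)) {
  stopifnot(amplitude > 0, duration_ms > 0, onset_ms >= 0,
            length(region_um) == 2L, region_um[1] < region_um[2])
  if (region_um[1] < -90 || region_um[2] > 0)
    stop("stimulus region must lie within the AIS ([-90, 0] um)",
         call. = FALSE)
  structure(list(amplitude = amplitude, duration_ms = duration_ms,
                 onset_ms = onset_ms, region_um = region_um),
            class = "stimulus_spec")
}

#' Build a pearled or cylindrical axon geometry
#'
#' Constructs the model axon used by the cable simulation: an AIS cylinder
#' on [-ais_length, 0] um that tapers smoothly onto the trunk over its last
#' few micrometres, and a trunk on [0, trunk_um] um that is either a
#' periodic pearl chain (raised-cosine NSV bumps of maximal diameter
#' `nsv_width` whose inflection-to-inflection extent is `nsv_length`, joined
#' by connectors of diameter `connector_width` and length
#' `connector_length`) or a constant-diameter cylinder.
#'
#' @param nsv_length,nsv_width,connector_length,connector_width pearl-chain
#'   dimensions, nm (ignored when `cylinder_diameter` is given).
#' @param cylinder_diameter trunk diameter for cylinder mode, nm.
#' @param trunk_um trunk length, um.
#' @param ais_length_um,ais_diameter_nm AIS extent (um) and diameter (nm).
#' @param ais_taper_um length of the smooth AIS-to-trunk taper, um.
#' @param dx_nm trunk grid spacing, nm; must give at least 8 samples per
#'   connector.
#' @param ais_dx_nm AIS grid spacing, nm.
#' @return an object of class `axon_geometry`: node positions `x_um`, radii
#'   `radius_nm`, the trunk period (nm) and the input dimensions.
#' @examples
#' g <- build_geometry(638, 309, 486, 136)
#' attr(g, "period_nm")  # 1124; ~267 periods over 300 um
#' @export
build_geometry <- function(nsv_length = NULL, nsv_width = NULL,
                           connector_length = NULL, connector_width = NULL,
                           cylinder_diameter = NULL, trunk_um = 300,
                           ais_length_um = 90, ais_diameter_nm = 500,
                           ais_taper_um = 5, dx_nm = 20, ais_dx_nm = 200) {
  cylinder <- !is.null(cylinder_diameter)
  if (!cylinder) {
    dims <- c(nsv_length, nsv_width, connector_length, connector_width)
    if (length(dims) != 4L || any(dims <= 0))
      stop("all four pearl dimensions must be given and positive",
           call. = FALSE)
    if (connector_width >= nsv_width)
      stop("'connector_width' must be smaller than 'nsv_width'", call. = FALSE)
    if (dx_nm > connector_length / 8)
      stop("'dx_nm' too coarse: need >= 8 samples per connector", call. = FALSE)
  } else if (cylinder_diameter <= 0) {
    stop("'cylinder_diameter' must be positive", call. = FALSE)
  }
  x_ais <- seq(-ais_length_um * 1000, 0, by = ais_dx_nm)
  x_trunk <- seq(dx_nm, trunk_um * 1000, by = dx_nm)
  x_nm <- c(x_ais, x_trunk)
  if (cylinder) {
    r_trunk_fun <- function(x) rep(cylinder_diameter / 2, length(x))
    period <- NA_real_
  } else {
    period <- nsv_length + connector_length
    n_per <- ceiling(trunk_um * 1000 / period) + 1L
    bb <- .pearl_backbone(
      nsv = data.frame(length = rep(nsv_length, n_per),
                       radius = rep(nsv_width / 2, n_per)),
      conn = data.frame(length = rep(connector_length, n_per + 1L),
                        radius = rep(connector_width / 2, n_per + 1L)))
    r_trunk_fun <- function(x) bb$fun(x)
  }
  if (!cylinder) {
    # one period evaluated finely once; the trunk is then a phase lookup,
    # which keeps the analytic backbone cheap at any node count
    pg <- seq(0, period, by = 0.5)
    pv <- r_trunk_fun(pg)
    r_trunk_fun <- function(x)
      stats::approx(pg, pv, xout = x %% period, rule = 2)$y
  }
  r0 <- r_trunk_fun(0)
  ais_r <- ais_diameter_nm / 2
  taper <- ais_taper_um * 1000
  r_fun <- function(x) {
    out <- numeric(length(x))
    tr <- x > 0
    out[tr] <- r_trunk_fun(x[tr])
    frac <- pmin(pmax(-x[!tr] / taper, 0), 1)   # 0 at junction, 1 upstream
    out[!tr] <- r0 + (ais_r - r0) * (1 - cos(pi * frac)) / 2
    out
  }
  r_nm <- r_fun(x_nm)
  # exact (2-nm subsampled) quadrature of the analytic profile:
  # per-node membrane area over each control volume (with and without the
  # arc-length slope factor) and per-interval axial resistance integral
  n <- length(x_nm)
  faces <- c(x_nm[1], (x_nm[-1] + x_nm[-n]) / 2, x_nm[n])
  # subdivide every inter-node interval to ~2 nm and integrate the frustum
  # areas and 1/a^2 of the analytic profile (all vectorized)
  d <- diff(x_nm)
  k <- pmax(2L, as.integer(ceiling(d / 2)))
  idx <- rep.int(seq_len(n - 1L), k)
  frac <- sequence(k) / k[idx]
  xr <- x_nm[idx] + d[idx] * frac
  xl <- xr - d[idx] / k[idx]
  rl <- r_fun(xl); rr <- r_fun(xr)
  ds_ax <- xr - xl
  area_sub <- pi * (rl + rr) * sqrt(ds_ax^2 + (rr - rl)^2)
  flat_sub <- pi * (rl + rr) * ds_ax
  invr2_sub <- ds_ax * (1 / rl^2 + 1 / rr^2) / 2
  cell <- findInterval((xl + xr) / 2, faces, rightmost.closed = TRUE)
  agg <- function(v, g, ng) {
    out <- numeric(ng)
    s <- rowsum(v, g)
    out[as.integer(rownames(s))] <- s
    out
  }
  structure(list(x_um = x_nm / 1000, radius_nm = r_nm,
                 ais_mask = x_nm <= 0, trunk_um = trunk_um,
                 cylinder = cylinder,
                 cell_area_nm2 = agg(area_sub, cell, n),
                 cell_area_flat_nm2 = agg(flat_sub, cell, n),
                 interval_invr2_invnm = agg(invr2_sub, idx, n - 1L),
                 dims = if (cylinder) c(diameter = cylinder_diameter) else
                   c(nsv_length = nsv_length, nsv_width = nsv_width,
                     connector_length = connector_length,
                     connector_width = connector_width)),
            class = "axon_geometry", period_nm = period)
}

#' @export
print.axon_geometry <- function(x, ...) {
  cat(sprintf("<axon_geometry> %s trunk, %d nodes over [%.0f, %.0f] um\n",
              if (x$cylinder) "cylindrical" else "pearled",
              length(x$x_um), min(x$x_um), max(x$x_um)))
  cat("  ", paste(names(x$dims), round(x$dims), "nm", collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.axon_geometry <- function(x, xlim = c(-2, 6), ...) {
  sel <- x$x_um >= xlim[1] & x$x_um <= xlim[2]
  graphics::plot(x$x_um[sel], 2 * x$radius_nm[sel], type = "l",
                 xlab = "x (um)", ylab = "diameter (nm)", ...)
  invisible(x)
}

#' Place sodium channels uniformly or in 190-nm periodic clusters
#'
#' Builds the per-node NaV density multiplier. In uniform mode the trunk
#' density is constant; in periodic mode the sodium conductance is
#' concentrated in clusters spaced every `period_nm` (centres at
#' (k - 1/2) * period from the trunk origin), rescaled so the
#' membrane-area-integrated sodium conductance over the trunk matches the
#' uniform layout to better than 0.1%. Potassium and leak densities are
#' always uniform. The AIS carries the `ais_nav_multiplier` of
#' [ephys_params()] in both modes.
#'
#' @param geometry an [build_geometry()] result.
#' @param mode `"uniform"` or `"periodic"`.
#' @param period_nm cluster spacing, nm.
#' @param cluster_width_nm cluster width, nm; must be at least the trunk
#'   grid spacing.
#' @return an object of class `channel_layout`: the multiplier vector
#'   `na_factor`, the `mode`, and the cluster count `n_clusters`.
#' @export
place_channels <- function(geometry, mode = c("uniform", "periodic"),
                           period_nm = 190, cluster_width_nm = 40) {
  mode <- match.arg(mode)
  x_nm <- geometry$x_um * 1000
  trunk <- !geometry$ais_mask
  dx <- stats::median(diff(x_nm[trunk]))
  f <- rep(1, length(x_nm))
  n_clusters <- NA_integer_
  if (mode == "periodic") {
    if (cluster_width_nm < dx)
      stop("'cluster_width_nm' is below the grid spacing", call. = FALSE)
    trunk_len <- max(x_nm)
    n_clusters <- floor(trunk_len / period_nm + 0.5)
    centers <- (seq_len(n_clusters) - 0.5) * period_nm
    xt <- x_nm[trunk]
    phase <- (xt - period_nm / 2) %% period_nm
    dist <- pmin(phase, period_nm - phase)
    in_cluster <- dist <= cluster_width_nm / 2
    # each cluster models one cytoskeletal ring carrying the same channel
    # complement, i.e. equal conductance per cluster irrespective of the
    # local circumference; the factors are then rescaled so the trunk's
    # area-integrated Na conductance matches the uniform layout
    area_w <- .membrane_area_weights(geometry)[trunk]
    ft <- ifelse(in_cluster, 1 / area_w, 0)
    ft <- ft * sum(area_w) / sum(ft * area_w)
    f[trunk] <- ft
  }
  structure(list(mode = mode, na_factor = f, n_clusters = n_clusters,
                 period_nm = period_nm, cluster_width_nm = cluster_width_nm),
            class = "channel_layout")
}

# per-node membrane area (cm^2) over each control volume, from the exact
# subsampled quadrature of the analytic profile stored by build_geometry();
# slope_factor = FALSE drops the sqrt(1 + a'^2) arc-length factor
.membrane_area_weights <- function(geometry, slope_factor = TRUE) {
  a <- if (slope_factor) geometry$cell_area_nm2 else
    geometry$cell_area_flat_nm2
  a * 1e-14
}

# HH rate functions (mV, 1/ms) with removable singularities handled
.hh_rates <- function(v) {
  am_d <- v + 40
  am <- ifelse(abs(am_d) < 1e-6, 1, 0.1 * am_d / (1 - exp(-am_d / 10)))
  bm <- 4 * exp(-(v + 65) / 18)
  ah <- 0.07 * exp(-(v + 65) / 20)
  bh <- 1 / (1 + exp(-(v + 35) / 10))
  an_d <- v + 55
  an <- ifelse(abs(an_d) < 1e-6, 0.1, 0.01 * an_d / (1 - exp(-an_d / 10)))
  bn <- 0.125 * exp(-(v + 65) / 80)
  list(am = am, bm = bm, ah = ah, bh = bh, an = an, bn = bn)
}

# self-consistent resting potential of the uniform membrane
.resting_state <- function(params) {
  gna <- params$gna * params$density_scale
  gk <- params$gk * params$density_scale
  gl <- params$gleak * params$density_scale
  f <- function(v) {
    r <- .hh_rates(v)
    m <- r$am / (r$am + r$bm); hh <- r$ah / (r$ah + r$bh)
    nn <- r$an / (r$an + r$bn)
    gna * m^3 * hh * (v - params$e_na) + gk * nn^4 * (v - params$e_k) +
      gl * (v - params$e_leak)
  }
  v <- stats::uniroot(f, c(-90, -50))$root
  r <- .hh_rates(v)
  list(v = v, m = r$am / (r$am + r$bm), h = r$ah / (r$ah + r$bh),
       n = r$an / (r$an + r$bn))
}

#' Simulate action-potential propagation on an axon geometry
#'
#' Integrates the generalized cable equation with Hodgkin-Huxley currents on
#' a radius-varying axon,
#' \deqn{c_m \partial_t V = \frac{1}{2\pi a\sqrt{1+a'^2}}
#'   \partial_x\!\left(\frac{\pi a^2}{R_i}\partial_x V\right) - i_{HH} + i_{stim},}
#' using a finite-volume discretization (axial conductances from the exact
#' series resistance of each grid interval, membrane areas with the
#' \eqn{\sqrt{1+a'^2}} slope factor), Crank-Nicolson for the linear cable
#' operator (factorized once), and explicit gating/ionic updates. Both ends
#' are sealed (zero axial current). The initial condition is the
#' self-consistent resting state.
#'
#' @param geometry an [build_geometry()] result.
#' @param params an [ephys_params()].
#' @param layout a [place_channels()] layout (default uniform).
#' @param stim a [stimulus_spec()].
#' @param dt_ms time step, ms.
#' @param t_max_ms simulated time, ms.
#' @param probes_um probe positions, um.
#' @param slope_factor include the sqrt(1+a'^2) membrane-area factor
#'   (dropping it is a documented comparison toggle).
#' @param early_stop stop once the action potential has passed the last
#'   probe (saves time; recorded traces are truncated accordingly).
#' @return an object of class `ap_traces`: `time_ms`, voltage matrix `v`
#'   (one column per probe), `probes_um`, `no_ap` flag, and gating ranges.
#' @export
simulate_ap <- function(geometry, params, layout = NULL,
                        stim = stimulus_spec(), dt_ms = 0.001, t_max_ms = 8,
                        probes_um = c(-90, 0, 277), slope_factor = TRUE,
                        early_stop = TRUE) {
  stopifnot(inherits(geometry, "axon_geometry"), inherits(params, "ephys_params"))
  if (is.null(layout)) layout <- place_channels(geometry, "uniform")
  n <- length(geometry$x_um)
  area <- .membrane_area_weights(geometry, slope_factor)   # cm^2 per node
  cap <- params$c_m * area                                  # uF
  # series resistance of each interval from the exact subsampled 1/a^2
  # integral of the analytic profile (stored in nm^-1; 1 nm^-1 = 1e7 cm^-1)
  rseg <- params$r_i / pi * geometry$interval_invr2_invnm * 1e7   # ohm
  gax <- 1000 / rseg                                        # mS
  lap <- Matrix::sparseMatrix(
    i = c(1:n, 1:(n - 1L), 2:n),
    j = c(1:n, 2:n, 1:(n - 1L)),
    x = c(c(gax, 0) + c(0, gax), -gax, -gax), dims = c(n, n))
  m_lhs <- Matrix::Diagonal(x = cap / dt_ms) + lap / 2
  ch <- Matrix::Cholesky(methods::as(m_lhs, "symmetricMatrix"), LDL = FALSE)
  # conductance densities (mS/cm^2) per node; the AIS multiplier scales all
  # three conductances jointly so the uniform resting potential remains an
  # exact steady state of the heterogeneous cable (a Na-only boost would
  # unbalance the resting currents and make the AIS self-depolarize)
  na_mult <- layout$na_factor
  na_mult[geometry$ais_mask] <- params$ais_nav_multiplier
  ais_all <- ifelse(geometry$ais_mask, params$ais_nav_multiplier, 1)
  gna <- params$gna * params$density_scale * na_mult
  gk <- params$gk * params$density_scale * ais_all
  gl <- params$gleak * params$density_scale * ais_all
  rest <- .resting_state(params)
  v <- rep(rest$v, n); m <- rep(rest$m, n); hgate <- rep(rest$h, n)
  ngate <- rep(rest$n, n)
  stim_nodes <- geometry$x_um >= stim$region_um[1] &
    geometry$x_um <= stim$region_um[2]
  probe_idx <- vapply(probes_um, function(p) which.min(abs(geometry$x_um - p)),
                      integer(1))
  nsteps <- ceiling(t_max_ms / dt_ms)
  vout <- matrix(NA_real_, nsteps + 1L, length(probes_um))
  vout[1L, ] <- v[probe_idx]
  g_rng <- c(1, 0)   # running min/max over all gates
  last_probe <- probe_idx[length(probe_idx)]
  peak_seen <- -Inf; peak_step <- NA_integer_
  rs <- params$rate_scale
  step <- 0L
  while (step < nsteps) {
    step <- step + 1L
    t_now <- (step - 1L) * dt_ms
    r <- .hh_rates(v)
    m <- m + dt_ms * rs * (r$am * (1 - m) - r$bm * m)
    hgate <- hgate + dt_ms * rs * (r$ah * (1 - hgate) - r$bh * hgate)
    ngate <- ngate + dt_ms * rs * (r$an * (1 - ngate) - r$bn * ngate)
    g_rng[1] <- min(g_rng[1], m, hgate, ngate)
    g_rng[2] <- max(g_rng[2], m, hgate, ngate)
    i_ion <- gna * m^3 * hgate * (v - params$e_na) +
      gk * ngate^4 * (v - params$e_k) + gl * (v - params$e_leak)  # uA/cm^2
    i_st <- numeric(n)
    if (t_now >= stim$onset_ms && t_now < stim$onset_ms + stim$duration_ms)
      i_st[stim_nodes] <- stim$amplitude
    rhs <- cap * v / dt_ms - as.numeric(lap %*% v) / 2 +
      area * (i_st - i_ion)
    v <- as.numeric(Matrix::solve(ch, rhs))
    if (max(abs(v)) > 500)
      stop(sprintf("voltage blow-up (|V| > 500 mV) at t = %.3f ms", t_now),
           call. = FALSE)
    vout[step + 1L, ] <- v[probe_idx]
    if (v[last_probe] > peak_seen) {
      peak_seen <- v[last_probe]; peak_step <- step
    }
    if (early_stop && peak_seen > 0 &&
        v[last_probe] < peak_seen - 30 &&
        step > peak_step + 0.2 / dt_ms) break
  }
  vout <- vout[seq_len(step + 1L), , drop = FALSE]
  no_ap <- max(vout[, length(probes_um)]) <= 0
  structure(list(time_ms = seq(0, by = dt_ms, length.out = step + 1L),
                 v = vout, probes_um = probes_um, no_ap = no_ap,
                 gating_range = g_rng, dt_ms = dt_ms,
                 rest_mv = rest$v, v_final = v,
                 capacitance_uf = cap),
            class = "ap_traces")
}

#' @export
print.ap_traces <- function(x, ...) {
  cat(sprintf("<ap_traces> %d steps of %g ms at probes %s um; %s\n",
              length(x$time_ms) - 1L, x$dt_ms,
              paste(x$probes_um, collapse = "/"),
              if (x$no_ap) "no AP at the distal probe" else "AP propagated"))
  invisible(x)
}

#' @export
plot.ap_traces <- function(x, ...) {
  graphics::matplot(x$time_ms, x$v, type = "l", lty = 1,
                    xlab = "time (ms)", ylab = "V (mV)", ...)
  graphics::legend("topright", legend = paste(x$probes_um, "um"),
                   col = seq_len(ncol(x$v)), lty = 1, bty = "n")
  invisible(x)
}

# quadratically interpolated time of the peak of one trace
.t_peak <- function(t, v) {
  i <- which.max(v)
  if (i == 1L || i == length(v)) return(t[i])
  dt <- t[2] - t[1]
  num <- v[i - 1L] - v[i + 1L]
  den <- v[i - 1L] - 2 * v[i] + v[i + 1L]
  t[i] + dt / 2 * num / den
}

#' Conduction velocity from probe traces
#'
#' The velocity is the probe separation divided by the difference in
#' time-to-peak between the 0 um and distal probes, with the peak time
#' refined by quadratic interpolation around the sampled maximum. A
#' propagated action potential (overshoot above 0 mV at both probes) is
#' required; otherwise the estimate is flagged as failed rather than
#' returning a number.
#'
#' @param traces an `ap_traces` object from [simulate_ap()].
#' @param from_um,to_um probe positions used for the readout.
#' @return an object of class `velocity_estimate`: `velocity_m_s`, `ok`,
#'   `t_peak_ms` (per probe used).
#' @export
conduction_velocity <- function(traces, from_um = 0, to_um = 277) {
  stopifnot(inherits(traces, "ap_traces"))
  i1 <- which(traces$probes_um == from_um)[1]
  i2 <- which(traces$probes_um == to_um)[1]
  if (is.na(i1) || is.na(i2))
    stop("requested probes were not recorded", call. = FALSE)
  ok <- !traces$no_ap && max(traces$v[, i1]) > 0 && max(traces$v[, i2]) > 0
  if (!ok)
    return(structure(list(velocity_m_s = NA_real_, ok = FALSE,
                          t_peak_ms = c(NA_real_, NA_real_)),
                     class = "velocity_estimate"))
  t1 <- .t_peak(traces$time_ms, traces$v[, i1])
  t2 <- .t_peak(traces$time_ms, traces$v[, i2])
  dist_m <- (to_um - from_um) * 1e-6
  structure(list(velocity_m_s = dist_m / ((t2 - t1) * 1e-3), ok = TRUE,
                 t_peak_ms = c(t1, t2)),
            class = "velocity_estimate")
}

#' @export
print.velocity_estimate <- function(x, ...) {
  if (x$ok)
    cat(sprintf("<velocity_estimate> %.4g m/s (peaks at %.3f and %.3f ms)\n",
                x$velocity_m_s, x$t_peak_ms[1], x$t_peak_ms[2]))
  else cat("<velocity_estimate> failed: no propagated AP\n")
  invisible(x)
}

#' Predict conduction velocity from measured pearl dimensions
#'
#' One paper-style prediction: build the pearled geometry from the four
#' measured dimensions, place NaVs periodically at 190 nm, simulate, and
#' read out the time-to-peak conduction velocity.
#'
#' @param dims numeric length-4 vector (NSV length, NSV width, connector
#'   length, connector width, nm), or a one-row data.frame with those
#'   columns.
#' @param params an [ephys_params()].
#' @param layout_mode `"periodic"` (default) or `"uniform"`.
#' @param ... passed to [simulate_ap()].
#' @return velocity in m/s.
#' @export
predict_from_measurements <- function(dims, params = ephys_params(),
                                      layout_mode = "periodic", ...) {
  if (is.data.frame(dims))
    dims <- unlist(dims[1, c("nsv_length", "nsv_width", "connector_length",
                             "connector_width")])
  stopifnot(length(dims) == 4L)
  geo <- build_geometry(dims[1], dims[2], dims[3], dims[4])
  lay <- place_channels(geo, layout_mode)
  tr <- simulate_ap(geo, params, lay, ...)
  cv <- conduction_velocity(tr)
  if (!cv$ok) return(NA_real_)
  cv$velocity_m_s
}

#' Sweep one geometric dimension and fit the velocity trend
#'
#' Repeats the simulation over a grid of one dimension (the other three
#' fixed), collects conduction velocities, and fits the trend: a straight
#' line for connector width, connector length, cylinder diameter and NSV
#' length, or a Gaussian bump (via nonlinear least squares) for NSV width,
#' whose fitted centre is the reported optimum. Non-propagating grid points
#' are flagged and excluded from the fit.
#'
#' @param which one of `"connector_width"`, `"connector_length"`,
#'   `"nsv_width"`, `"nsv_length"`, `"cylinder_diameter"`.
#' @param values grid of dimension values, nm (>= 6 points).
#' @param base named length-4 vector of the fixed pearl dimensions, nm.
#' @param params an [ephys_params()].
#' @param layout_mode NaV layout for pearled sweeps.
#' @param ... passed to [simulate_ap()].
#' @return an object of class `dimension_sweep`: `table` (value, velocity,
#'   propagated), `fit`, `slope` (linear fits), `argmax` (Gaussian fit).
#' @export
sweep_dimension <- function(which, values,
                            base = c(nsv_length = 638, nsv_width = 309,
                                     connector_length = 486,
                                     connector_width = 136),
                            params = ephys_params(),
                            layout_mode = "periodic", ...) {
  which <- match.arg(which, c("connector_width", "connector_length",
                              "nsv_width", "nsv_length", "cylinder_diameter"))
  if (length(values) < 6L) stop("need at least 6 grid points", call. = FALSE)
  vel <- vapply(values, function(val) {
    tryCatch({
      if (which == "cylinder_diameter") {
        geo <- build_geometry(cylinder_diameter = val)
        lay <- place_channels(geo, "uniform")
      } else {
        d <- base; d[which] <- val
        geo <- build_geometry(d["nsv_length"], d["nsv_width"],
                              d["connector_length"], d["connector_width"])
        lay <- place_channels(geo, layout_mode)
      }
      cv <- conduction_velocity(simulate_ap(geo, params, lay, ...))
      if (cv$ok) cv$velocity_m_s else NA_real_
    }, error = function(e) NA_real_)   # unbuildable or non-propagating point
  }, numeric(1))
  tab <- data.frame(value = values, velocity_m_s = vel,
                    propagated = !is.na(vel))
  ok <- tab[tab$propagated, ]
  fit <- NULL; slope <- NA_real_; argmax <- NA_real_
  if (which == "nsv_width") {
    start <- list(v0 = min(ok$velocity_m_s),
                  a = diff(range(ok$velocity_m_s)),
                  mu = ok$value[which.max(ok$velocity_m_s)],
                  s = diff(range(ok$value)) / 3)
    fit <- minpack.lm::nlsLM(
      velocity_m_s ~ v0 + a * exp(-(value - mu)^2 / (2 * s^2)),
      data = ok, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200))
    argmax <- stats::coef(fit)[["mu"]]
  } else {
    fit <- stats::lm(velocity_m_s ~ value, data = ok)
    slope <- stats::coef(fit)[["value"]]
  }
  structure(list(which = which, table = tab, fit = fit, slope = slope,
                 argmax = argmax),
            class = "dimension_sweep")
}

#' @export
print.dimension_sweep <- function(x, ...) {
  cat(sprintf("<dimension_sweep> %s over [%g, %g] nm, %d points\n",
              x$which, min(x$table$value), max(x$table$value),
              nrow(x$table)))
  if (!is.na(x$argmax)) cat(sprintf("  fitted optimum at %.1f nm\n", x$argmax))
  if (!is.na(x$slope)) cat(sprintf("  fitted slope %.3g (m/s)/nm\n", x$slope))
  invisible(x)
}

#' @export
plot.dimension_sweep <- function(x, ...) {
  graphics::plot(x$table$value, x$table$velocity_m_s,
                 xlab = paste(x$which, "(nm)"), ylab = "velocity (m/s)", ...)
  if (!is.null(x$fit)) {
    xx <- seq(min(x$table$value), max(x$table$value), length.out = 100)
    graphics::lines(xx, stats::predict(x$fit, data.frame(value = xx)))
  }
  invisible(x)
}
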