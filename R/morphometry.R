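# Gaussian smoothing on a uniform grid with replicate padding
.gauss_smooth <- function(y, sd_nm, h) {
  if (sd_nm <= 0.3 * h) return(y)
  m <- ceiling(4 * sd_nm / h)
  k <- stats::dnorm(seq(-m, m) * h, sd = sd_nm)
  k <- k / sum(k)
  n <- length(y)
  padded <- c(rep(y[1], m), y, rep(y[n], m))
  as.numeric(stats::filter(padded, k, sides = 2)[(m + 1):(m + n)])
}

#' Segment a radius profile into NSVs and connectors at inflection points
#'
#' Implements the measurement convention for pearled axons: boundaries
#' between a nonsynaptic varicosity (NSV) and a connector are the inflection
#' points of the (smoothed) diameter function. The diameter is smoothed with
#' a Gaussian kernel, its second derivative is taken by central differences,
#' and boundaries are located as the zero crossings between runs of
#' significantly concave and significantly convex curvature (runs below 5%
#' of the peak curvature magnitude, e.g. flat plateaus, cannot seed a
#' boundary). A crossing from convex to concave opens an NSV (the segment
#' holding a local diameter maximum); concave to convex opens a connector.
#' Coincident crossings within one sample merge at their midpoint. Partial
#' segments at the profile ends are dropped.
#'
#' @param profile a [radius_profile()].
#' @param smoothing_nm standard deviation of the Gaussian smoothing kernel in
#'   nm; must be at least twice the sample spacing. The 15 nm default is well
#'   below the thinnest reported connector widths while suppressing
#'   sampling-scale noise.
#' @return a data.frame of class `axon_segments` with columns `kind`
#'   ("nsv"/"connector"), `start`, `end`, `length`, `width` (all nm). NSV
#'   width is the maximal diameter in the segment; connector width is the
#'   median diameter over the central 50% of the segment. Zero rows when the
#'   profile holds no complete feature.
#' @export
segment_profile <- function(profile, smoothing_nm = 15) {
  stopifnot(inherits(profile, "radius_profile"))
  h <- profile$spacing
  if (smoothing_nm < 2 * h)
    stop("'smoothing_nm' must be at least twice the sample spacing",
         call. = FALSE)
  d <- 2 * profile$r
  ds <- .gauss_smooth(d, smoothing_nm, h)
  n <- length(ds)
  d2 <- c(0, diff(diff(ds)), 0) / h^2   # second difference, zero-padded ends
  # significance floor: 5% of the peak curvature, lifted to 4 sd of the
  # curvature noise propagated from the raw-diameter noise level
  noise_sd <- stats::mad(diff(d, differences = 2)) / sqrt(6)
  m <- max(1L, ceiling(4 * smoothing_nm / h))
  kc <- stats::dnorm(seq(-m, m) * h, sd = smoothing_nm)
  kc <- kc / sum(kc)
  k2 <- diff(diff(c(0, 0, kc, 0, 0))) / h^2
  tau <- max(0.05 * max(abs(d2)),
             min(4 * noise_sd * sqrt(sum(k2^2)), 0.5 * max(abs(d2))))
  sig <- which(abs(d2) > tau)
  empty <- structure(
    data.frame(kind = character(), start = numeric(), end = numeric(),
               length = numeric(), width = numeric()),
    class = c("axon_segments", "data.frame"))
  if (length(sig) < 2L || tau == 0) return(empty)
  sgn <- sign(d2[sig])
  flips <- which(diff(sgn) != 0)
  if (!length(flips)) return(empty)
  boundaries <- numeric(length(flips))
  opens_nsv <- logical(length(flips))
  for (j in seq_along(flips)) {
    i0 <- sig[flips[j]]; i1 <- sig[flips[j] + 1L]
    # all raw zero crossings inside the bracketing gap, merged at midpoint
    seg_idx <- i0:(i1 - 1L)
    cross <- seg_idx[d2[seg_idx] * d2[seg_idx + 1L] <= 0 &
                       (d2[seg_idx] != 0 | d2[seg_idx + 1L] != 0)]
    if (!length(cross)) cross <- seg_idx[which.min(abs(d2[seg_idx]))]
    xc <- vapply(cross, function(i) {
      if (d2[i] == d2[i + 1L]) return(profile$x[i])
      profile$x[i] + h * d2[i] / (d2[i] - d2[i + 1L])
    }, numeric(1))
    boundaries[j] <- mean(range(xc))
    opens_nsv[j] <- sgn[flips[j]] > 0   # convex -> concave opens an NSV
  }
  if (length(boundaries) < 2L) return(empty)
  segs <- data.frame(kind = ifelse(opens_nsv[-length(opens_nsv)], "nsv",
                                   "connector"),
                     start = boundaries[-length(boundaries)],
                     end = boundaries[-1])
  segs$length <- segs$end - segs$start
  # widths are read from the smoothed diameter: NSV plateaus and connector
  # floors are flat, so smoothing leaves the noiseless values untouched while
  # suppressing the upward bias a max-over-noise would incur
  segs$width <- vapply(seq_len(nrow(segs)), function(i) {
    if (segs$kind[i] == "nsv") {
      inside <- profile$x >= segs$start[i] & profile$x <= segs$end[i]
      max(ds[inside])
    } else {
      q <- segs$start[i] + c(0.25, 0.75) * segs$length[i]
      inside <- profile$x >= q[1] & profile$x <= q[2]
      if (!any(inside)) inside <- which.min(abs(profile$x - mean(q)))
      stats::median(ds[inside])
    }
  }, numeric(1))
  class(segs) <- c("axon_segments", "data.frame")
  attr(segs, "spacing") <- h
  attr(segs, "smoothing_nm") <- smoothing_nm
  segs
}

#' Collect per-segment dimensions into a morphometry record
#'
#' Aggregates the output of [segment_profile()] into the per-axon record used
#' for cohort summaries: NSV (length, width) and connector (length, width)
#' tables plus mean and standard error (s.e.m. = sd/sqrt(n)) per dimension.
#' Annotations (synaptic flags in axial NSV order, axon maximal diameter,
#' presence of a presynaptic terminal) are attached for the exclusion rules.
#'
#' @param segments an `axon_segments` data.frame from [segment_profile()].
#' @param annotations optional list as in [radius_profile()].
#' @return an object of class `morphometry_record`.
#' @export
measure_segments <- function(segments, annotations = list()) {
  nsv <- segments[segments$kind == "nsv", , drop = FALSE]
  conn <- segments[segments$kind == "connector", , drop = FALSE]
  syn <- annotations$is_synaptic
  nsv_df <- data.frame(length = nsv$length, width = nsv$width,
                       center = (nsv$start + nsv$end) / 2,
                       is_synaptic = if (!is.null(syn) && length(syn) >= nrow(nsv))
                         syn[seq_len(nrow(nsv))] else rep(FALSE, nrow(nsv)))
  conn_df <- data.frame(length = conn$length, width = conn$width)
  rec <- structure(list(nsv = nsv_df, connector = conn_df,
                        max_diameter_nm = annotations$max_diameter_nm %||% NA_real_,
                        has_terminal = annotations$has_terminal %||% TRUE),
                   class = "morphometry_record")
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.morphometry_record <- function(x, ...) {
  cat(sprintf("<morphometry_record> %d NSVs, %d connectors\n",
              nrow(x$nsv), nrow(x$connector)))
  s <- summary(x)
  print(s, row.names = FALSE)
  invisible(x)
}

#' @export
summary.morphometry_record <- function(object, ...) {
  dims <- list(nsv_length = object$nsv$length, nsv_width = object$nsv$width,
               connector_length = object$connector$length,
               connector_width = object$connector$width)
  data.frame(dimension = names(dims),
             mean_nm = vapply(dims, function(v) mean(v), numeric(1)),
             sem_nm = vapply(dims, function(v)
               if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
               numeric(1)),
             n = vapply(dims, length, integer(1)))
}

#' Convenience wrapper: segment and measure one profile
#' @inheritParams segment_profile
#' @return a `morphometry_record`.
#' @export
measure_axon <- function(profile, smoothing_nm = 15) {
  measure_segments(segment_profile(profile, smoothing_nm),
                   annotations = profile$annotations)
}

#' Apply the cohort exclusion rules
#'
#' Mirrors the inclusion criteria applied to electron-microscopy cohorts:
#' varicosities containing synaptic vesicles are removed from NSV statistics,
#' and structures are only treated as axons if they carry a presynaptic
#' terminal or are thinner than 1 um — records failing both are dropped
#' entirely.
#'
#' @param records a list of [measure_segments()] records.
#' @return list with `records` (filtered), `removed_synaptic` (count of
#'   dropped varicosities) and `removed_axons` (count of dropped records).
#' @export
apply_exclusions <- function(records) {
  removed_syn <- 0L
  keep <- logical(length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    big <- is.finite(r$max_diameter_nm) && r$max_diameter_nm >= 1000
    keep[i] <- !(big && !isTRUE(r$has_terminal))
    if (keep[i]) {
      syn <- r$nsv$is_synaptic
      removed_syn <- removed_syn + sum(syn)
      records[[i]]$nsv <- r$nsv[!syn, , drop = FALSE]
    }
  }
  list(records = records[keep],
       removed_synaptic = removed_syn,
       removed_axons = sum(!keep))
}

#' Full-width-half-maximum lengths of intensity peaks
#'
#' Detects local maxima rising above their surrounding background and
#' measures, for each, the width at half of (peak minus local background),
#' with linear interpolation between samples. The local background of a peak
#' is the higher of the two flanking minima, which guarantees both half-level
#' crossings exist.
#'
#' @param intensity an `intensity_profile` from [gen_sted_profile()], or any
#'   list with numeric `x` and `intensity`.
#' @param min_prominence minimal peak height above local background, as a
#'   fraction of the profile's full dynamic range.
#' @return numeric vector of FWHM values (nm), one per detected peak, with
#'   peak positions as the `"positions"` attribute; length zero when no peak
#'   rises above background.
#' @export
fwhm_length <- function(intensity, min_prominence = 0.05) {
  x <- intensity$x; y <- intensity$intensity
  n <- length(y)
  if (n < 3L) return(numeric(0))
  rng <- diff(range(y))
  if (rng == 0) return(numeric(0))
  is_peak <- which(diff(sign(diff(y))) < 0) + 1L
  out <- numeric(0); pos <- numeric(0)
  for (p in is_peak) {
    # flanking minima: lowest samples between this peak and the neighboring
    # higher ground (search to profile ends)
    li <- which.min(y[1:p])
    ri <- p - 1L + which.min(y[p:n])
    bg <- max(y[li], y[ri])
    if (y[p] - bg < min_prominence * rng) next
    half <- bg + (y[p] - bg) / 2
    il <- p; while (il > 1L && y[il - 1L] > half) il <- il - 1L
    if (il == 1L && y[1] > half) next
    xl <- x[il - 1L] + (x[il] - x[il - 1L]) * (half - y[il - 1L]) / (y[il] - y[il - 1L])
    ir <- p; while (ir < n && y[ir + 1L] > half) ir <- ir + 1L
    if (ir == n && y[n] > half) next
    xr <- x[ir] + (x[ir + 1L] - x[ir]) * (half - y[ir]) / (y[ir + 1L] - y[ir])
    out <- c(out, xr - xl); pos <- c(pos, x[p])
  }
  attr(out, "positions") <- pos
  out
}

#' Spacing statistics of NSV centers versus the 190-nm cytoskeletal period
#'
#' Computes center-to-center spacings of NSVs, a histogram at the stated bin
#' width, and the fraction of spacings falling within +/- 10% of the 190-nm
#' period of the membrane periodic cytoskeleton (i.e. in [171, 209] nm).
#'
#' @param nsv_centers numeric vector of NSV center positions, nm (>= 2).
#' @param bin_width histogram bin width, nm.
#' @param period reference period, nm.
#' @param tol_frac fractional half-window around the reference period.
#' @return list with `spacings`, `histogram` (a [hist()] object) and
#'   `fraction_periodic`.
#' @export
spacing_periodicity <- function(nsv_centers, bin_width = 50, period = 190,
                                tol_frac = 0.1) {
  if (length(nsv_centers) < 2L)
    stop("at least two NSV centers are required", call. = FALSE)
  sp <- diff(sort(nsv_centers))
  breaks <- seq(0, max(sp) + bin_width, by = bin_width)
  hh <- graphics::hist(sp, breaks = breaks, plot = FALSE)
  lo <- period * (1 - tol_frac); hi <- period * (1 + tol_frac)
  list(spacings = sp, histogram = hh,
       fraction_periodic = mean(sp >= lo & sp <= hi))
}

#' Three-dimensional length from a serial-section stack
#'
#' Applies the Pythagorean correction used for serial-section
#' reconstructions: the 3D length is the hypotenuse of the summed in-plane
#' displacement and the axial span of the stack, assuming aligned images and
#' equal section thickness.
#'
#' @param stack a `section_stack` from [gen_serial_sections()].
#' @param inplane_length summed in-plane displacement in nm; defaults to the
#'   value recomputed from the stack's displacement vectors.
#' @return 3D length in nm.
#' @export
reconstruct_3d <- function(stack, inplane_length = NULL) {
  stopifnot(inherits(stack, "section_stack"))
  if (is.null(inplane_length))
    inplane_length <- sum(sqrt(rowSums(stack$displacements^2)))
  if (inplane_length < 0 || stack$thickness <= 0)
    stop("lengths and thickness must be non-negative", call. = FALSE)
  sqrt(inplane_length^2 + ((stack$n_sections - 1) * stack$thickness)^2)
}

#' Cohort summary of morphometry records
#'
#' Produces the standard cohort table: per group, the mean and standard error
#' of the four dimensions (NSV length/width, connector length/width), pooling
#' segments across the group's axons.
#'
#' @param records list of `morphometry_record`s.
#' @param groups character/factor vector, one label per record; a single
#'   label recycles.
#' @return data.frame with columns `group`, `dimension`, `mean_nm`, `sem_nm`,
#'   `n_axons`, `n_segments`. Empty groups are omitted with a warning.
#' @export
summarize_morphometry <- function(records, groups = "all") {
  if (length(groups) == 1L) groups <- rep(groups, length(records))
  stopifnot(length(groups) == length(records))
  out <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    nsv <- do.call(rbind, lapply(records[idx], function(r) r$nsv))
    conn <- do.call(rbind, lapply(records[idx], function(r) r$connector))
    if (is.null(nsv) || (nrow(nsv) == 0 && nrow(conn) == 0)) {
      warning(sprintf("group '%s' has no measured segments; omitted", g))
      next
    }
    dims <- list(nsv_length = nsv$length, nsv_width = nsv$width,
                 connector_length = conn$length, connector_width = conn$width)
    out[[g]] <- data.frame(
      group = g, dimension = names(dims),
      mean_nm = vapply(dims, mean, numeric(1)),
      sem_nm = vapply(dims, function(v)
        if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0, numeric(1)),
      n_axons = length(idx),
      n_segments = vapply(dims, length, integer(1)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a cohort summary as delimited text
#' @param summary data.frame from [summarize_morphometry()].
#' @param path file path.
#' @export
write_morphometry_summary <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
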