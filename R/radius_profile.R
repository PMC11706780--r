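#' Discretized axon radius profile
#'
#' A `radius_profile` is the common currency of the package: the axon radius
#' (nm) sampled on a uniform axial grid (nm). Synthetic generation, membrane
#' relaxation and cable-geometry construction all emit this representation,
#' and the morphometry functions consume it.
#'
#' @param x numeric vector of axial positions in nm, strictly increasing with
#'   uniform spacing.
#' @param r numeric vector of radii in nm, all positive, same length as `x`.
#' @param annotations optional list with per-axon annotation used by the
#'   exclusion rules: `is_synaptic` (logical, one flag per varicosity in
#'   axial order), `has_terminal` (logical scalar), `max_diameter_nm`
#'   (numeric scalar; defaults to `2 * max(r)`).
#' @param meta optional list of provenance fields (seed, generator spec, ...).
#' @return an object of class `radius_profile` with elements `x`, `r`,
#'   `spacing`, `annotations`, `meta`.
#' @seealso [segment_profile()], [write_radius_profile()]
#' @export
radius_profile <- function(x, r, annotations = list(), meta = list()) {
  x <- as.numeric(x); r <- as.numeric(r)
  if (length(x) != length(r))
    stop("'x' and 'r' must have the same length", call. = FALSE)
  if (length(x) < 50L)
    stop("a radius profile needs at least 50 samples", call. = FALSE)
  dx <- diff(x)
  if (any(dx <= 0)) stop("axial positions must be strictly increasing", call. = FALSE)
  h <- mean(dx)
  if (max(abs(dx - h)) > 1e-9 * max(abs(x)) + 1e-12)
    stop("axial positions must be uniformly spaced", call. = FALSE)
  if (any(!is.finite(r)) || any(r <= 0))
    stop("radii must be finite and positive", call. = FALSE)
  if (is.null(annotations$max_diameter_nm))
    annotations$max_diameter_nm <- 2 * max(r)
  structure(list(x = x, r = r, spacing = h,
                 annotations = annotations, meta = meta),
            class = "radius_profile")
}

#' @export
print.radius_profile <- function(x, ...) {
  cat("<radius_profile>\n")
  cat(sprintf("  %d samples, spacing %.3g nm, extent %.4g nm\n",
              length(x$x), x$spacing, diff(range(x$x))))
  cat(sprintf("  diameter range [%.4g, %.4g] nm\n", 2 * min(x$r), 2 * max(x$r)))
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.radius_profile <- function(x, ...) {
  graphics::plot(x$x, 2 * x$r, type = "l", xlab = "axial position (nm)",
                 ylab = "diameter (nm)", ...)
  invisible(x)
}

#' Read and write radius profiles as delimited text
#'
#' Profiles are stored as two-column whitespace-delimited text (axial
#' position nm, radius nm) under a commented header that records units and
#' any seed in `meta`, so files round-trip through `read_radius_profile()`.
#'
#' @param profile a [radius_profile()].
#' @param path file path.
#' @return `read_radius_profile()` returns a [radius_profile()];
#'   `write_radius_profile()` returns `path` invisibly.
#' @export
write_radius_profile <- function(profile, path) {
  stopifnot(inherits(profile, "radius_profile"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# axonpearl radius profile", con)
  writeLines("# columns: axial_nm radius_nm", con)
  if (!is.null(profile$meta$seed))
    writeLines(sprintf("# seed: %d", as.integer(profile$meta$seed)), con)
  utils::write.table(data.frame(profile$x, profile$r), con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_radius_profile
#' @export
read_radius_profile <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  seed <- NULL
  sl <- grep("^# seed:", hdr, value = TRUE)
  if (length(sl)) seed <- as.integer(sub("^# seed:\\s*", "", sl[1]))
  dat <- utils::read.table(text = lines[!grepl("^#", lines)])
  radius_profile(dat[[1]], dat[[2]],
                 meta = if (is.null(seed)) list() else list(seed = seed))
}
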