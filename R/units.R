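#' Unit conversions and physical constants
#'
#' All membrane-mechanics computations in this package use energies in units
#' of \eqn{k_B T} and lengths in nanometres, so pressures come out in
#' \eqn{k_B T / \mathrm{nm}^3} and tensions in \eqn{k_B T / \mathrm{nm}^2}.
#' Osmolarities are supplied in mOsm (mmol/l of osmotically active solute)
#' and converted to number densities per nm^3. These helpers centralize the
#' conversions.
#'
#' @param c_mosm osmolarity in mOsm (mol/m^3).
#' @return `mosm_to_nm3()` returns a number density in particles/nm^3.
#' @examples
#' mosm_to_nm3(300) # physiological saline, ~0.18 particles/nm^3
#' @export
mosm_to_nm3 <- function(c_mosm) {
  # 1 mOsm = 1 mol/m^3 = N_A / 1e27 particles per nm^3
  c_mosm * 6.02214076e-4
}

#' @rdname mosm_to_nm3
#' @param p_kbt_nm3 pressure in k_B T / nm^3.
#' @param temperature_k temperature in kelvin.
#' @return `kbt_nm3_to_pa()` returns the same pressure in pascal.
#' @export
kbt_nm3_to_pa <- function(p_kbt_nm3, temperature_k = 310) {
  kb <- 1.380649e-23            # J/K
  p_kbt_nm3 * kb * temperature_k * 1e27
}

# run `expr` with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a per-stage seed from a global seed; kept below 2^31
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}
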