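#' Synthesize a digitized bacterial accumulation profile
#'
#' Generates `(r, b)` profiles with the statistical structure of digitized
#' microscale data: radii on `[1, r_max]` (uniform or log spacing) and
#' concentrations on the RDF curve perturbed by noise. Multiplicative
#' lognormal noise is the default because digitized cell-count profiles
#' have spread roughly proportional to level; additive Gaussian noise is
#' retained for robustness checks (negative values are clipped at zero with
#' a warning). Pure function of its arguments and the seed.
#'
#' @param params An [rdf_params()] generating set.
#' @param n_points Number of points (`>= 5`).
#' @param r_max Outer extent of the observation window in particle radii.
#' @param noise `"multiplicative_lognormal"` or `"additive_gaussian"`.
#' @param sigma Noise scale (`>= 0`; log-sd for the lognormal kind,
#'   absolute sd for the Gaussian kind).
#' @param seed Integer seed; identical seeds give identical profiles.
#' @param spacing `"uniform"` or `"log"`.
#' @return Tibble with columns `r`, `b` (a valid [fit_rdf()] input).
#' @examples
#' synth_profile(rdf_preset("strong"), n_points = 50, r_max = 6, sigma = 0)
#' @export
synth_profile <- function(params, n_points = 50, r_max = 6,
                          noise = c("multiplicative_lognormal", "additive_gaussian"),
                          sigma = 0, seed = 1,
                          spacing = c("uniform", "log")) {
  noise <- match.arg(noise)
  spacing <- match.arg(spacing)
  stopifnot(inherits(params, "rdf_params"))
  if (n_points < 5) stop("`n_points` must be >= 5", call. = FALSE)
  if (r_max <= 1) stop("`r_max` must be > 1", call. = FALSE)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  r <- switch(spacing,
    uniform = seq(1, r_max, length.out = n_points),
    log = exp(seq(log(1), log(r_max), length.out = n_points))
  )
  b0 <- rdf_evaluate(params, r)
  if (sigma == 0) {
    b <- b0
  } else {
    z <- withr::with_seed(seed, stats::rnorm(n_points))
    b <- switch(noise,
      multiplicative_lognormal = b0 * exp(sigma * z),
      additive_gaussian = b0 + sigma * z
    )
    if (any(b < 0)) {
      warning("additive noise produced negative concentrations; clipped at 0")
      b <- pmax(b, 0)
    }
  }
  tibble::tibble(r = r, b = b)
}

#' Synthesize a particle record table
#'
#' Emulates aggregate size/velocity scatter data: equivalent sphere
#' diameters log-uniform on `esd_range` and sinking velocities following a
#' power law `SV = prefactor * ESD^exponent` with lognormal scatter. The
#' defaults populate the observed axes ranges (ESD 0.05-5 mm, SV up to a
#' few hundred m/d); they are fixtures emulating the shape of published
#' aggregate datasets, not claims about real aggregates. Pure function of
#' its arguments and the seed.
#'
#' @param n Number of records (`>= 1`).
#' @param seed Integer seed.
#' @param prefactor Velocity at ESD = 1 mm, in m/d.
#' @param exponent Power-law exponent.
#' @param log_scatter Lognormal scatter (sd of log SV).
#' @param esd_range Diameter range in mm.
#' @return Tibble with columns `esd_mm`, `sv_m_per_d`, `source_label`.
#' @examples
#' synth_particles(10, seed = 42)
#' @export
synth_particles <- function(n, seed = 1, prefactor = 50, exponent = 0.8,
                            log_scatter = 0.5, esd_range = c(0.05, 5)) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  stopifnot(prefactor > 0, log_scatter >= 0, all(esd_range > 0))
  draws <- withr::with_seed(seed, {
    u <- stats::runif(n)
    z <- stats::rnorm(n)
    list(u = u, z = z)
  })
  esd <- exp(log(esd_range[1]) + draws$u * (log(esd_range[2]) - log(esd_range[1])))
  sv <- prefactor * esd^exponent * exp(log_scatter * draws$z)
  tibble::tibble(esd_mm = esd, sv_m_per_d = sv, source_label = "synthetic")
}
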