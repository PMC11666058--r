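#' Unit conversions used by the dimensional analysis
#'
#' Sinking velocities are quoted in m/d and stored in cm/s; sizes in mm or
#' um and stored in cm; uptake affinities in pL/(cell s) and stored in
#' mL/(cell s).
#' @name units
#' @keywords internal
NULL

m_per_day_to_cm_per_s <- function(v) v * 100 / 86400
cm_per_s_to_m_per_day <- function(v) v * 86400 / 100

#' Dimensional particle scenario
#'
#' A sinking-particle scenario in laboratory units, converted internally to
#' CGS: particle radius, sinking velocity, nutrient diffusivity, ambient
#' bacterial abundance and per-cell uptake affinity, plus seawater density
#' and viscosity for the Reynolds number.
#'
#' @param radius Particle radius; unit given by `radius_unit`.
#' @param velocity Sinking velocity in m/d.
#' @param diffusivity Nutrient diffusivity in cm^2/s (default `1e-5`,
#'   typical of small organic solutes such as amino acids).
#' @param abundance Ambient bacterial abundance in cells/mL (default `1e6`).
#' @param affinity Per-cell uptake affinity in pL/(cell s) (default 1).
#' @param tau_U Optional uptake timescale override in seconds; when set it
#'   wins over the `1/(abundance * affinity)` derivation.
#' @param rho_w Ambient water density in g/cm^3 (default 1.025, seawater).
#' @param mu_w Dynamic viscosity in g/(cm s) (default 0.01).
#' @param radius_unit `"mm"`, `"um"` or `"cm"`.
#' @return An object of class `particle_scenario` (radius stored in cm,
#'   velocity in cm/s).
#' @examples
#' s <- particle_scenario(radius = 0.4, velocity = 36.3, radius_unit = "mm")
#' dimensionless_numbers(s)  # Pe = 168
#' @export
particle_scenario <- function(radius, velocity, diffusivity = 1e-5,
                              abundance = 1e6, affinity = 1, tau_U = NULL,
                              rho_w = 1.025, mu_w = 0.01,
                              radius_unit = c("mm", "um", "cm")) {
  radius_unit <- match.arg(radius_unit)
  vals <- c(radius, velocity, diffusivity, abundance, affinity, rho_w, mu_w)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all scenario quantities must be positive", call. = FALSE)
  }
  if (!is.null(tau_U) && tau_U <= 0) stop("`tau_U` must be > 0", call. = FALSE)
  R_cm <- switch(radius_unit, mm = radius / 10, um = radius / 1e4, cm = radius)
  structure(list(
    R_P = R_cm,                              # cm
    v_inf = m_per_day_to_cm_per_s(velocity), # cm/s
    v_inf_m_per_day = velocity,
    D_Av = diffusivity,                      # cm^2/s
    B_inf = abundance,                       # cells/mL
    alpha_S = affinity,                      # pL/(cell s)
    tau_U_set = tau_U,                       # s or NULL
    rho_w = rho_w, mu_w = mu_w
  ), class = "particle_scenario")
}

#' @export
print.particle_scenario <- function(x, ...) {
  cat(sprintf("<particle_scenario> R_P = %g cm, v = %g m/d, D = %g cm^2/s, tau_U = %g s (%s)\n",
              x$R_P, x$v_inf_m_per_day, x$D_Av, scenario_tau_U(x),
              if (is.null(x$tau_U_set)) "derived from abundance x affinity" else "set directly"))
  invisible(x)
}

scenario_tau_U <- function(s) {
  if (!is.null(s$tau_U_set)) return(s$tau_U_set)
  # affinity pL/(cell s) -> mL/(cell s): 1 pL = 1e-9 mL
  1 / (s$B_inf * s$alpha_S * 1e-9)
}

#' Characteristic timescales of a scenario
#'
#' Diffusion `tau_D = R_P^2/D`, advection `tau_A = R_P/v`, uptake
#' `tau_U = 1/(B_inf alpha_S)` (or the set override), and the undisturbed
#' plume lifetime `tau_PLM = min(tau_A, tau_D)`, all in seconds. An optional
#' chemotaxis timescale is carried through as metadata only.
#'
#' @param s A [particle_scenario()].
#' @param tau_C Optional chemotaxis timescale (s), informational.
#' @return One-row tibble with `tau_D`, `tau_A`, `tau_U`, `tau_PLM`, `tau_C`.
#' @export
timescales <- function(s, tau_C = NA_real_) {
  stopifnot(inherits(s, "particle_scenario"))
  tau_D <- s$R_P^2 / s$D_Av
  tau_A <- s$R_P / s$v_inf
  tibble::tibble(
    tau_D = tau_D, tau_A = tau_A, tau_U = scenario_tau_U(s),
    tau_PLM = pmin(tau_A, tau_D), tau_C = tau_C
  )
}

#' Dimensionless numbers of a scenario
#'
#' `Pe = R_P v / D`, `Da = tau_D / tau_U`, `Re = rho v R_P / mu`. Scenarios
#' with `Re >= 1` violate the creeping-flow assumption of the Stokes
#' velocity field and are flagged.
#'
#' @param s A [particle_scenario()].
#' @return One-row tibble with `Pe`, `Da`, `Re`, `re_flag`.
#' @export
dimensionless_numbers <- function(s) {
  stopifnot(inherits(s, "particle_scenario"))
  ts <- timescales(s)
  Pe <- s$R_P * s$v_inf / s$D_Av
  Da <- ts$tau_D / ts$tau_U
  Re <- s$rho_w * s$v_inf * s$R_P / s$mu_w
  tibble::tibble(Pe = Pe, Da = Da, Re = Re, re_flag = Re >= 1)
}

#' Plume-reshaping screening condition
#'
#' Quick scaling test of whether bacterial uptake can reshape the plume
#' before it dissipates (`tau_U < tau_PLM`): pass iff `Pe/Da < 100` and
#' `Da > 1e-4`. Derived for uniformly distributed bacteria; its validity
#' falls off as clustering strengthens.
#'
#' @param Pe,Da Dimensionless numbers (vectors recycle).
#' @return Tibble with `Pe`, `Da`, `ratio_ok`, `da_ok`, `pass`.
#' @examples
#' reshaping_screen(Pe = c(20, 168), Da = c(1.6, 0.16))
#' @export
reshaping_screen <- function(Pe, Da) {
  if (any(Pe < 0) || any(Da < 0)) stop("`Pe` and `Da` must be >= 0", call. = FALSE)
  n <- max(length(Pe), length(Da))
  Pe <- rep_len(Pe, n); Da <- rep_len(Da, n)
  ratio_ok <- ifelse(Da == 0, FALSE, Pe / Da < 100)
  da_ok <- Da > 1e-4
  tibble::tibble(Pe = Pe, Da = Da, ratio_ok = ratio_ok, da_ok = da_ok,
                 pass = ratio_ok & da_ok)
}
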