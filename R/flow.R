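#' Stokes flow past a rigid sphere
#'
#' Dimensionless velocity components of creeping flow past a rigid sphere
#' in the particle frame of reference:
#' \deqn{v_r = -\left(1 - \frac{3}{2r} + \frac{1}{2r^3}\right)\cos\theta, \quad
#'       v_\theta = \left(1 - \frac{3}{4r} - \frac{1}{4r^3}\right)\sin\theta.}
#' The polar angle is measured from the upstream direction: the free stream
#' enters at `theta = 0` and the wake lies along `theta = pi`. Both
#' components vanish at the surface (`r = 1`, no slip) and approach
#' `(-cos(theta), sin(theta))` far from the sphere. Valid for laminar flow
#' at low Reynolds number; microzone feedback on the flow is neglected.
#'
#' @param r Radial distances in particle radii, all `>= 1`.
#' @param theta Polar angles in `[0, pi]`; recycled against `r`.
#' @return Tibble with columns `r`, `theta`, `v_r`, `v_theta`.
#' @examples
#' stokes_velocity(2, 0)  # v_r = -0.3125 on the upstream axis
#' @export
stokes_velocity <- function(r, theta) {
  if (any(r < 1)) stop("`r` must be >= 1 (particle radii)", call. = FALSE)
  if (any(theta < -1e-12 | theta > pi + 1e-12)) {
    stop("`theta` must lie in [0, pi]", call. = FALSE)
  }
  n <- max(length(r), length(theta))
  r <- rep_len(r, n); theta <- rep_len(theta, n)
  tibble::tibble(
    r = r, theta = theta,
    v_r = stokes_vr(r, theta),
    v_theta = stokes_vtheta(r, theta)
  )
}

# internal scalar-field forms used by the transport solver
stokes_vr <- function(r, theta) {
  -(1 - 3 / (2 * r) + 1 / (2 * r^3)) * cos(theta)
}

stokes_vtheta <- function(r, theta) {
  (1 - 3 / (4 * r) - 1 / (4 * r^3)) * sin(theta)
}
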