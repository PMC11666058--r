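# FV angular weights: integral of sin(theta) over the cell around each node
theta_weights <- function(grid) {
  n_t <- length(grid$theta)
  cf <- cos(c(0, grid$theta_half, pi))
  cf[1:n_t] - cf[2:(n_t + 1)]
}

#' Plume length
#'
#' Distance from the particle center at which the nutrient concentration on
#' the wake ray (`theta = pi`) equals the detection threshold `C_det`. The
#' outermost threshold crossing is taken (at high Pe the profile need not be
#' monotone near the particle), located by linear interpolation between the
#' bracketing nodes.
#'
#' @param field A `plume_field` from [solve_transport()].
#' @param C_det Detection threshold, default 0.1.
#' @param strict If `TRUE` (default), error when the concentration at the
#'   outer boundary of the wake ray still exceeds `C_det` (domain too
#'   small); if `FALSE`, return `R_out` with a flag instead.
#' @return One-row tibble with `L_plm`, `no_plume` (no point on the ray
#'   reaches `C_det`; then `L_plm = 1`), and `truncated`.
#' @export
plume_length <- function(field, C_det = 0.1, strict = TRUE) {
  stopifnot(inherits(field, "plume_field"))
  if (C_det <= 0) stop("`C_det` must be > 0", call. = FALSE)
  r <- field$grid$r
  Cw <- field$C[, ncol(field$C)]   # theta = pi ray
  n <- length(r)
  if (Cw[n] > C_det) {
    if (strict) {
      stop(sprintf("domain too small: C = %.3g > C_det = %g at the outer boundary of the wake ray",
                   Cw[n], C_det), call. = FALSE)
    }
    return(tibble::tibble(L_plm = r[n], no_plume = FALSE, truncated = TRUE))
  }
  above <- which(Cw >= C_det)
  if (length(above) == 0) {
    return(tibble::tibble(L_plm = 1, no_plume = TRUE, truncated = FALSE))
  }
  i <- max(above)
  if (i == n) {
    L <- r[n]
  } else {
    # linear interpolation in C between the bracketing nodes
    L <- r[i] + (C_det - Cw[i]) * (r[i + 1] - r[i]) / (Cw[i + 1] - Cw[i])
  }
  tibble::tibble(L_plm = L, no_plume = FALSE, truncated = FALSE)
}

# integral of H(C - C_det) r^2 dr along one radial line, with linear
# sub-interval interpolation of the threshold crossing
ray_indicator_integral <- function(r, Cray, C_det) {
  n <- length(r)
  seg <- function(a, b) (b^3 - a^3) / 3
  tot <- 0
  above <- Cray >= C_det
  for (i in 1:(n - 1)) {
    a1 <- above[i]; a2 <- above[i + 1]
    if (a1 && a2) {
      tot <- tot + seg(r[i], r[i + 1])
    } else if (a1 || a2) {
      rc <- r[i] + (C_det - Cray[i]) * (r[i + 1] - r[i]) / (Cray[i + 1] - Cray[i])
      tot <- tot + if (a1) seg(r[i], rc) else seg(rc, r[i + 1])
    }
  }
  tot
}

#' Plume volume
#'
#' Volume of the region where the nutrient concentration exceeds the
#' detection threshold, normalized by the particle volume:
#' \deqn{V_{plm} = \frac{3}{4\pi}\int_{V} H(C - C_{det})\, dV}
#' over the whole fluid domain (including upstream of the particle), by
#' axisymmetric quadrature with sub-cell linear interpolation of the
#' threshold crossing along each radial line.
#'
#' @inheritParams plume_length
#' @return One-row tibble with `V_plm` and `truncated`.
#' @export
plume_volume <- function(field, C_det = 0.1, strict = TRUE) {
  stopifnot(inherits(field, "plume_field"))
  r <- field$grid$r
  n_t <- ncol(field$C)
  truncated <- any(field$C[nrow(field$C), ] > C_det)
  if (truncated && strict) {
    stop("domain too small: C > C_det at the outer boundary", call. = FALSE)
  }
  w <- theta_weights(field$grid)
  I <- vapply(seq_len(n_t), function(j) {
    ray_indicator_integral(r, field$C[, j], C_det)
  }, numeric(1))
  tibble::tibble(V_plm = (3 / 2) * sum(w * I), truncated = truncated)
}

#' Quenching factors
#'
#' Length and volume quenching factors of a consumed (quenched) plume
#' relative to the undisturbed zero-uptake reference on the same grid:
#' `E_L = L0/L`, `E_V = V0/V`, with relative changes
#' `delta_L = 1 - 1/E_L` and `delta_V = 1 - 1/E_V` (the volume identity is
#' exact; the length one is the lower bound of the definition).
#'
#' @param quenched,reference `plume_field`s on the same grid; `reference`
#'   must be solved at `Da = 0`.
#' @param C_det Detection threshold.
#' @return One-row tibble with `L0`, `L`, `V0`, `V`, `E_L`, `E_V`,
#'   `delta_L`, `delta_V`, `degenerate`.
#' @export
quench_factors <- function(quenched, reference, C_det = 0.1) {
  stopifnot(inherits(quenched, "plume_field"), inherits(reference, "plume_field"))
  if (reference$problem$Da != 0) stop("`reference` must be a Da = 0 solve", call. = FALSE)
  if (!isTRUE(all.equal(quenched$grid$r, reference$grid$r)) ||
      !isTRUE(all.equal(quenched$grid$theta, reference$grid$theta))) {
    stop("quenched and reference fields must share one grid", call. = FALSE)
  }
  Lq <- plume_length(quenched, C_det)
  L0 <- plume_length(reference, C_det)
  Vq <- plume_volume(quenched, C_det)
  V0 <- plume_volume(reference, C_det)
  degenerate <- Lq$no_plume || Vq$V_plm == 0
  E_L <- if (Lq$no_plume) Inf else L0$L_plm / Lq$L_plm
  E_V <- if (Vq$V_plm == 0) Inf else V0$V_plm / Vq$V_plm
  tibble::tibble(
    L0 = L0$L_plm, L = Lq$L_plm, V0 = V0$V_plm, V = Vq$V_plm,
    E_L = E_L, E_V = E_V,
    delta_L = 1 - 1 / E_L, delta_V = 1 - 1 / E_V,
    degenerate = degenerate
  )
}

# shared shell quadrature over 1 <= r <= R_M: trapezoid on the radial nodes
# (with a partial last interval to R_M) of f(r) weighted by r^2, per theta ray
shell_ray_integral <- function(r, fvals, R_M) {
  keep <- r <= R_M
  n_in <- sum(keep)
  if (n_in < 2) stop("`R_M` too close to the particle surface for the grid", call. = FALSE)
  rs <- r[keep]; fs <- fvals[keep]
  if (rs[n_in] < R_M && n_in < length(r)) {
    f_RM <- fs[n_in] + (fvals[n_in + 1] - fs[n_in]) * (R_M - rs[n_in]) / (r[n_in + 1] - rs[n_in])
    rs <- c(rs, R_M); fs <- c(fs, f_RM)
  }
  g <- fs * rs^2
  sum(diff(rs) * (g[-1] + g[-length(g)]) / 2)
}

#' Microzone-averaged nutrient exposure
#'
#' Bacterial-concentration-weighted average of the nutrient field over the
#' microzone shell `1 <= r <= R_M`:
#' \deqn{c^* = \int_{V_M} B\, C\, dV \Big/ \int_{V_M} B\, dV.}
#' Measures the average nutrient encounter rate of the clustered population.
#'
#' @param field A `plume_field`.
#' @param rdf Bacterial RDF used as the weight; defaults to the one the
#'   field was solved with.
#' @param R_M Microzone radius; defaults to [microzone_radius()] of `rdf`.
#' @return `c_star` (scalar).
#' @export
nutrient_exposure <- function(field, rdf = NULL, R_M = NULL) {
  stopifnot(inherits(field, "plume_field"))
  if (is.null(rdf)) rdf <- field$problem$rdf
  if (is.null(R_M)) R_M <- microzone_radius(rdf)
  if (R_M > field$grid$R_out) stop("`R_M` exceeds the domain radius", call. = FALSE)
  r <- field$grid$r
  B <- rdf_evaluate(rdf, r)
  w <- theta_weights(field$grid)
  num <- sum(w * vapply(seq_len(ncol(field$C)), function(j) {
    shell_ray_integral(r, B * field$C[, j], R_M)
  }, numeric(1)))
  den <- sum(w) * shell_ray_integral(r, B, R_M)
  num / den
}

# combined advective + diffusive radial flux sampled at radius r0 for every
# theta node; C and dC/dr interpolated with 4-point Fornberg stencils
radial_flux_at <- function(field, r0) {
  r <- field$grid$r; theta <- field$grid$theta
  n_r <- length(r)
  if (r0 < 1 || r0 > field$grid$R_out) stop("radius outside the grid", call. = FALSE)
  i0 <- findInterval(r0, r)
  lo <- max(1, min(i0 - 1, n_r - 3))
  stc <- lo:(lo + 3)
  w0 <- fd_weights(r[stc], r0, 0)
  wd <- fd_weights(r[stc], r0, 1)
  Csub <- field$C[stc, , drop = FALSE]
  Cval <- as.numeric(crossprod(w0, Csub))
  dCdr <- as.numeric(crossprod(wd, Csub))
  vr <- stokes_vr(r0, theta)
  field$problem$Pe * vr * Cval - dCdr
}

#' Total nutrient flux through a spherical surface
#'
#' Surface integral of the combined advective and diffusive radial flux
#' `q_r = Pe v_r C - dC/dr` through the sphere of radius `r`, in units of
#' the reference flux times the squared particle radius. For a pure-diffusion
#' field `C = 1/r` this is `4 pi` at every radius.
#'
#' @param field A `plume_field`.
#' @param r Sampling radius (or vector of radii) in `[1, R_out]`.
#' @return Numeric vector `Q_As(r)`.
#' @export
total_flux <- function(field, r) {
  stopifnot(inherits(field, "plume_field"))
  w <- theta_weights(field$grid)
  vapply(r, function(r0) {
    q <- radial_flux_at(field, r0)
    2 * pi * r0^2 * sum(w * q)
  }, numeric(1))
}

#' Sherwood number and dissolution enhancement
#'
#' `Sh_R = Q_As(1) / (4 pi C_S)`: the total surface nutrient flux (advection,
#' diffusion and consumption effects included) over the pure-diffusion flux.
#' The dissolution enhancement `E_dis = Sh_R / Sh_R0` compares against the
#' zero-uptake Sherwood number on the same grid. Defined only for the
#' Dirichlet (prescribed surface concentration) boundary condition.
#'
#' @param field A `plume_field` solved with a Dirichlet surface BC.
#' @param reference Optional `Da = 0` companion field on the same grid; if
#'   missing and `field` has `Da > 0`, one is solved internally.
#' @return One-row tibble with `Sh_R`, `Sh_R0`, `E_dis`.
#' @export
sherwood <- function(field, reference = NULL) {
  stopifnot(inherits(field, "plume_field"))
  if (field$problem$surface$kind != "dirichlet") {
    stop("Sherwood number requires a prescribed surface concentration (Dirichlet BC)",
         call. = FALSE)
  }
  C_S <- field$problem$surface$C_S
  Sh <- total_flux(field, 1) / (4 * pi * C_S)
  if (field$problem$Da == 0) {
    Sh0 <- Sh
  } else {
    if (is.null(reference)) reference <- solve_reference(field)
    Sh0 <- total_flux(reference, 1) / (4 * pi * C_S)
  }
  tibble::tibble(Sh_R = Sh, Sh_R0 = Sh0, E_dis = Sh / Sh0)
}

#' Degradation efficiency profile
#'
#' Fraction of the released nutrient consumed within a spherical shell of
#' outer radius `r`: `E_degr(r) = 1 - Q_As(r) / Q_As(1)`. Zero everywhere
#' at `Da = 0`; approaches 1 far from the particle when uptake consumes the
#' whole release. Values are clipped to `[0, 1]` only against floating
#' noise.
#'
#' @param field A `plume_field`.
#' @param radii Sampling radii within the grid.
#' @return Tibble with columns `r`, `Q_As`, `E_degr`.
#' @export
degradation_efficiency <- function(field, radii) {
  Q <- total_flux(field, radii)
  Q1 <- total_flux(field, 1)
  E <- 1 - Q / Q1
  # clip only floating noise just outside [0, 1]; genuine violations pass through
  E[E < 0 & E > -0.02] <- 0
  E[E > 1 & E < 1.02] <- 1
  tibble::tibble(r = radii, Q_As = Q, E_degr = E)
}

#' All plume metrics for a quenched/reference pair
#'
#' Convenience wrapper computing the full observable set from a quenched
#' solve and its zero-uptake reference: plume length and volume (both
#' fields), quenching factors and relative changes, microzone-averaged
#' nutrient exposure, Sherwood number and dissolution enhancement.
#'
#' @inheritParams quench_factors
#' @param beta_ref Reference excess level defining the microzone radius for
#'   the exposure average.
#' @return One-row tibble.
#' @export
plume_metrics <- function(quenched, reference, C_det = 0.1, beta_ref = 0.1) {
  qf <- quench_factors(quenched, reference, C_det)
  rdf <- quenched$problem$rdf
  c_star <- if (rdf$beta_m > beta_ref) {
    nutrient_exposure(quenched, rdf, microzone_radius(rdf, beta_ref))
  } else {
    # uniform distribution: unweighted average over the reference shell r <= 3.3
    nutrient_exposure(quenched, rdf, 3.3)
  }
  sh <- if (quenched$problem$surface$kind == "dirichlet") {
    sherwood(quenched, reference)
  } else {
    tibble::tibble(Sh_R = NA_real_, Sh_R0 = NA_real_, E_dis = NA_real_)
  }
  dplyr::bind_cols(
    tibble::tibble(Pe = quenched$problem$Pe, Da = quenched$problem$Da),
    qf,
    tibble::tibble(c_star = c_star, C_det = C_det),
    sh
  )
}
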