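#' Uptake kinetics model
#'
#' The per-cell uptake rate is `a(C) * C` with affinity factor `a`.
#' Linear (unsaturable) uptake has `a = 1`; Michaelis-Menten kinetics have
#' `a = K_S / (K_S + C)` with dimensionless half-saturation constant `K_S`.
#'
#' @param kind `"linear"` or `"michaelis_menten"`.
#' @param K_S Dimensionless half-saturation constant (`> 0`), required for
#'   Michaelis-Menten kinetics.
#' @return An object of class `uptake_model`.
#' @export
uptake_model <- function(kind = c("linear", "michaelis_menten"), K_S = NULL) {
  kind <- match.arg(kind)
  if (kind == "michaelis_menten") {
    if (is.null(K_S) || !is.numeric(K_S) || K_S <= 0) {
      stop("Michaelis-Menten uptake requires `K_S` > 0", call. = FALSE)
    }
  } else {
    K_S <- NULL
  }
  structure(list(kind = kind, K_S = K_S), class = "uptake_model")
}

#' Surface boundary condition on the nutrient field
#'
#' Transport-limited dissolution (partition equilibrium) prescribes the
#' surface concentration `C = C_S` (Dirichlet, default `C_S = 1`);
#' reaction-limited dissolution (active exudation) prescribes the surface
#' flux `-dC/dr = q_As`. The far field is always the background value
#' `C = 0` (the field is concentration above background).
#'
#' @param kind `"dirichlet"` or `"flux"`.
#' @param C_S Surface concentration for the Dirichlet kind (`> 0`).
#' @param q_As Prescribed surface flux for the flux kind (`> 0`).
#' @return An object of class `surface_bc`.
#' @export
surface_bc <- function(kind = c("dirichlet", "flux"), C_S = 1, q_As = NULL) {
  kind <- match.arg(kind)
  if (kind == "dirichlet") {
    if (!is.numeric(C_S) || C_S <= 0) stop("`C_S` must be > 0", call. = FALSE)
    q_As <- NULL
  } else {
    if (is.null(q_As) || !is.numeric(q_As) || q_As <= 0) {
      stop("flux BC requires `q_As` > 0", call. = FALSE)
    }
    C_S <- NULL
  }
  structure(list(kind = kind, C_S = C_S, q_As = q_As), class = "surface_bc")
}

#' Dimensionless plume transport problem
#'
#' Bundles everything that defines the steady advection-diffusion-uptake
#' equation
#' \deqn{Pe\, \mathbf{v}\cdot\nabla C = \nabla^2 C - Da\, B(r)\, a(C)\, C}
#' around a Stokes sphere: the Peclet number `Pe` (advection vs diffusion),
#' the Damkohler number `Da` (uptake vs diffusion), the bacterial RDF
#' `B(r)`, the uptake kinetics `a(C)`, and the surface boundary condition.
#'
#' @param Pe Peclet number, `>= 0`.
#' @param Da Damkohler number, `>= 0`.
#' @param rdf An [rdf_params()] object (bacterial distribution).
#' @param uptake An [uptake_model()]; default linear.
#' @param surface A [surface_bc()]; default Dirichlet with `C_S = 1`.
#' @return An object of class `transport_problem`.
#' @examples
#' transport_problem(Pe = 20, Da = 1.6, rdf = rdf_preset("strong"))
#' @export
transport_problem <- function(Pe, Da, rdf, uptake = uptake_model(),
                              surface = surface_bc()) {
  stopifnot(is.numeric(Pe), is.numeric(Da), inherits(rdf, "rdf_params"),
            inherits(uptake, "uptake_model"), inherits(surface, "surface_bc"))
  if (Pe < 0) stop("`Pe` must be >= 0", call. = FALSE)
  if (Da < 0) stop("`Da` must be >= 0", call. = FALSE)
  structure(list(Pe = as.numeric(Pe), Da = as.numeric(Da), rdf = rdf,
                 uptake = uptake, surface = surface),
            class = "transport_problem")
}

#' @export
print.transport_problem <- function(x, ...) {
  cat(sprintf("<transport_problem> Pe = %g, Da = %g, uptake = %s, BC = %s\n",
              x$Pe, x$Da, x$uptake$kind, x$surface$kind))
  print(x$rdf)
  invisible(x)
}

#' Solver configuration
#'
#' Numerical settings for [solve_transport()]: node counts, radial
#' stretching, outer radius (or `NULL` for the adaptive rule), outer
#' boundary treatment, and Picard iteration controls for saturable uptake.
#'
#' @param n_r,n_theta Node counts (each `>= 16`). Radial nodes are
#'   geometrically stretched from the particle surface (finest spacing at
#'   `r = 1`); angular nodes follow a cosine map clustering at both poles,
#'   which refines the wake (`theta = pi`).
#' @param stretch Geometric stretching ratio between successive radial
#'   spacings, `> 1`.
#' @param R_out Outer radius in particle radii, or `NULL` to choose it
#'   adaptively: start from `max(30, 4 * L_est)` with `L_est` the
#'   closed-form plume-length estimate, then keep doubling (re-solving)
#'   until the plume length changes by less than `adapt_tol`.
#' @param outer_bc `"auto"`, `"inflow_outflow"` or `"radiation"`. The
#'   inflow/outflow treatment imposes `C = 0` where the free stream enters
#'   (`v_r < 0`) and zero radial gradient where it exits; the radiation
#'   condition `d(rC)/dr = 0` reproduces the algebraic `1/r` decay exactly
#'   and is the default (`"auto"`) for `Pe < 0.1`.
#' @param adapt_tol Relative change in plume length at which domain
#'   doubling stops.
#' @param picard_tol,picard_max,relax Picard controls for Michaelis-Menten
#'   uptake: tolerance on the max update, iteration cap, under-relaxation.
#' @param theta_spacing `"cosine"` (default) or `"uniform"`.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(n_r = 220, n_theta = 96, stretch = 1.03,
                          R_out = NULL,
                          outer_bc = c("auto", "inflow_outflow", "radiation"),
                          adapt_tol = 0.01,
                          picard_tol = 1e-8, picard_max = 200, relax = 0.7,
                          theta_spacing = c("cosine", "uniform")) {
  outer_bc <- match.arg(outer_bc)
  theta_spacing <- match.arg(theta_spacing)
  if (n_r < 16 || n_theta < 16) stop("node counts must be >= 16", call. = FALSE)
  if (stretch <= 1) stop("`stretch` must be > 1", call. = FALSE)
  if (!is.null(R_out) && R_out <= 1) stop("`R_out` must be > 1", call. = FALSE)
  if (picard_tol <= 0 || adapt_tol <= 0) stop("tolerances must be > 0", call. = FALSE)
  structure(list(n_r = as.integer(n_r), n_theta = as.integer(n_theta),
                 stretch = stretch, R_out = R_out, outer_bc = outer_bc,
                 adapt_tol = adapt_tol, picard_tol = picard_tol,
                 picard_max = as.integer(picard_max), relax = relax,
                 theta_spacing = theta_spacing),
            class = "solver_config")
}

# closed-form plume-length estimate used to seed the adaptive outer radius:
# 1/r decay gives L = C_S/C_det at Pe = 0, Da = 0; uniform uptake screens it
# to the root of exp(-sqrt(Da*beta0)(r-1))/r = C_det; advection lengthens the
# wake plume roughly by the Sherwood factor.
estimate_plume_length <- function(problem, C_det = 0.1) {
  C_S <- if (problem$surface$kind == "dirichlet") problem$surface$C_S else 1
  kappa <- sqrt(problem$Da * problem$rdf$beta0)
  L0 <- C_S / C_det
  if (kappa > 0) {
    f <- function(r) exp(-kappa * (r - 1)) / r - C_det / C_S
    L0 <- if (f(1) <= 0) 1 else stats::uniroot(f, c(1, C_S / C_det), tol = 1e-10)$root
  }
  sh <- max(1, 0.6245 * problem$Pe^(1 / 3))
  L0 * sh
}

#' Build the axisymmetric body-conforming grid
#'
#' Radial nodes are geometrically stretched from the particle surface so the
#' first spacing is the finest; angular nodes cover `[0, pi]` with cosine
#' clustering toward both poles (refining the wake at `theta = pi`). If the
#' configuration leaves `R_out = NULL` the outer radius starts from the
#' closed-form rule `max(30, 4 * L_est)`.
#'
#' @param config A [solver_config()].
#' @param problem A [transport_problem()] (used only for the adaptive
#'   `R_out` rule).
#' @param R_out Optional explicit outer radius overriding the rule.
#' @return An object of class `plume_grid` with fields `r`, `theta`,
#'   `R_out`, and half-node metadata.
#' @export
build_grid <- function(config, problem = NULL, R_out = NULL) {
  stopifnot(inherits(config, "solver_config"))
  if (is.null(R_out)) R_out <- config$R_out
  if (is.null(R_out)) {
    if (is.null(problem)) stop("need `problem` to apply the adaptive R_out rule", call. = FALSE)
    R_out <- max(30, 4 * estimate_plume_length(problem))
  }
  n_r <- config$n_r; n_t <- config$n_theta; g <- config$stretch
  h0 <- (R_out - 1) * (g - 1) / (g^(n_r - 1) - 1)
  r <- 1 + h0 * (g^(0:(n_r - 1)) - 1) / (g - 1)
  r[n_r] <- R_out
  u <- seq(0, 1, length.out = n_t)
  theta <- switch(config$theta_spacing,
    cosine = pi / 2 * (1 - cos(pi * u)),
    uniform = pi * u
  )
  theta[1] <- 0; theta[n_t] <- pi
  structure(list(
    r = r, theta = theta, R_out = R_out,
    r_half = (r[-1] + r[-n_r]) / 2,
    theta_half = (theta[-1] + theta[-n_t]) / 2,
    stretch = g, theta_spacing = config$theta_spacing
  ), class = "plume_grid")
}

#' @export
print.plume_grid <- function(x, ...) {
  cat(sprintf("<plume_grid> %d x %d nodes, r in [1, %.3g], first dr = %.3g\n",
              length(x$r), length(x$theta), x$R_out, x$r[2] - x$r[1]))
  invisible(x)
}

# Fornberg finite-difference weights for the m-th derivative at x0 on nodes x
fd_weights <- function(x, x0, m) {
  n <- length(x)
  w <- matrix(0, n, m + 1)
  c1 <- 1; c4 <- x[1] - x0
  w[1, 1] <- 1
  for (i in 2:n) {
    mn <- min(i, m + 1)
    c2 <- 1; c5 <- c4; c4 <- x[i] - x0
    for (j in 1:(i - 1)) {
      c3 <- x[i] - x[j]; c2 <- c2 * c3
      if (j == i - 1) {
        if (mn >= 2) {
          for (k in mn:2) w[i, k] <- c1 * ((k - 1) * w[i - 1, k - 1] - c5 * w[i - 1, k]) / c2
        }
        w[i, 1] <- -c1 * c5 * w[i - 1, 1] / c2
      }
      if (mn >= 2) {
        for (k in mn:2) w[j, k] <- (c4 * w[j, k] - (k - 1) * w[j, k - 1]) / c3
      }
      w[j, 1] <- c4 * w[j, 1] / c3
    }
    c1 <- c2
  }
  w[, m + 1]
}

# Assemble the steady transport operator (without the uptake diagonal) as a
# sparse matrix plus the right-hand side. Unknown ordering: theta fastest,
# k = (i-1)*n_t + j. Advection is discretized in non-conservative form with
# third-order upwind-biased 4-point stencils (Fornberg weights on the
# non-uniform grid), degrading to first-order upwind at the node layers
# adjacent to boundaries; diffusion uses a conservative flux form with
# r^2 and sin(theta) metric factors at half-nodes, which regularizes the
# polar axis (zero-area faces at theta = 0, pi).
assemble_transport <- function(problem, grid, config) {
  r <- grid$r; theta <- grid$theta
  n_r <- length(r); n_t <- length(theta)
  n <- n_r * n_t
  idx <- function(i, j) (i - 1L) * n_t + j

  Pe <- problem$Pe
  outer_bc <- config$outer_bc
  if (outer_bc == "auto") outer_bc <- if (Pe < 0.1) "radiation" else "inflow_outflow"

  # FV cell measures
  rh <- grid$r_half                      # length n_r - 1
  th <- grid$theta_half                  # length n_t - 1
  # radial cell faces (interior nodes i = 2..n_r-1 use faces rh[i-1], rh[i])
  # angular cell faces for node j: th[j-1], th[j]; pole cells are half cells
  cos_faces <- cos(c(0, th, pi))         # length n_t + 1; face j..j+1 boundaries
  w_theta <- cos_faces[1:n_t] - cos_faces[2:(n_t + 1)]  # integral of sin over cell j
  sin_faces <- sin(th)                   # interior faces only

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(rows, cols, vals) {
    ii <<- c(ii, rows); jj <<- c(jj, cols); xx <<- c(xx, vals)
  }

  int_i <- 2:(n_r - 1)

  ## --- radial diffusion (all interior i, all j) ---
  vol_r <- (rh[int_i]^3 - rh[int_i - 1]^3) / 3
  a_plus <- rh[int_i]^2 / (r[int_i + 1] - r[int_i]) / vol_r
  a_minus <- rh[int_i - 1]^2 / (r[int_i] - r[int_i - 1]) / vol_r
  for (j in 1:n_t) {
    rows <- idx(int_i, j)
    add(rows, idx(int_i + 1L, j), a_plus)
    add(rows, idx(int_i - 1L, j), a_minus)
    add(rows, rows, -(a_plus + a_minus))
  }

  ## --- angular diffusion (flux form; pole faces have sin = 0) ---
  # coefficient independent of r except the 1/r^2 factor
  inv_r2 <- 1 / r[int_i]^2
  for (j in 1:n_t) {
    bp <- if (j < n_t) sin_faces[j] / (theta[j + 1] - theta[j]) / w_theta[j] else 0
    bm <- if (j > 1) sin_faces[j - 1] / (theta[j] - theta[j - 1]) / w_theta[j] else 0
    rows <- idx(int_i, j)
    if (bp > 0) add(rows, idx(int_i, j + 1L), bp * inv_r2)
    if (bm > 0) add(rows, idx(int_i, j - 1L), bm * inv_r2)
    add(rows, rows, -(bp + bm) * inv_r2)
  }

  ## --- radial advection: -Pe * v_r * dC/dr ---
  if (Pe > 0) {
    vr_sign_pos <- cos(theta) < 0        # v_r > 0 (outflow, wake side)
    vr_sign_neg <- cos(theta) > 0        # v_r < 0 (inflow, upstream side)
    for (i in int_i) {
      vr_i <- stokes_vr(r[i], theta)     # length n_t
      # wind from lower r (v_r > 0)
      jsel <- which(vr_sign_pos & abs(vr_i) > 0)
      if (length(jsel)) {
        stc <- if (i >= 3) (i - 2L):(i + 1L) else (i - 1L):i
        wts <- fd_weights(r[stc], r[i], 1)
        for (k in seq_along(stc)) {
          add(idx(i, jsel), idx(stc[k], jsel), -Pe * vr_i[jsel] * wts[k])
        }
      }
      # wind from higher r (v_r < 0)
      jsel <- which(vr_sign_neg & abs(vr_i) > 0)
      if (length(jsel)) {
        stc <- if (i <= n_r - 2) (i - 1L):(i + 2L) else i:(i + 1L)
        wts <- fd_weights(r[stc], r[i], 1)
        for (k in seq_along(stc)) {
          add(idx(i, jsel), idx(stc[k], jsel), -Pe * vr_i[jsel] * wts[k])
        }
      }
    }

    ## --- angular advection: -Pe * (v_theta / r) * dC/dtheta (v_theta >= 0) ---
    for (j in 2:(n_t - 1)) {
      vt_j <- stokes_vtheta(r[int_i], theta[j])
      stc <- if (j >= 3) (j - 2L):(j + 1L) else (j - 1L):j
      wts <- fd_weights(theta[stc], theta[j], 1)
      for (k in seq_along(stc)) {
        add(idx(int_i, j), idx(int_i, stc[k]), -Pe * vt_j / r[int_i] * wts[k])
      }
    }
  }

  ## --- boundary rows ---
  rhs <- numeric(n)
  # surface r = 1
  rows1 <- idx(1L, 1:n_t)
  if (problem$surface$kind == "dirichlet") {
    add(rows1, rows1, rep(1, n_t))
    rhs[rows1] <- problem$surface$C_S
  } else {
    # -dC/dr = q_As  =>  dC/dr = -q_As, one-sided 3-point derivative
    wts <- fd_weights(r[1:3], r[1], 1)
    for (k in 1:3) add(rows1, idx(k, 1:n_t), rep(wts[k], n_t))
    rhs[rows1] <- -problem$surface$q_As
  }
  # outer r = R_out
  rowsN <- idx(n_r, 1:n_t)
  if (outer_bc == "radiation") {
    # d(rC)/dr = 0, conservative two-point form: exact for C ~ 1/r
    add(rowsN, rowsN, rep(r[n_r], n_t))
    add(rowsN, idx(n_r - 1L, 1:n_t), rep(-r[n_r - 1], n_t))
  } else {
    vr_out <- stokes_vr(r[n_r], theta)
    inflow <- vr_out < 0
    if (any(inflow)) add(rowsN[inflow], rowsN[inflow], rep(1, sum(inflow)))
    if (any(!inflow)) {
      add(rowsN[!inflow], rowsN[!inflow], rep(1, sum(!inflow)))
      add(rowsN[!inflow], idx(n_r - 1L, which(!inflow)), rep(-1, sum(!inflow)))
    }
  }

  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  # mask for interior rows where the uptake diagonal applies
  interior <- rep(FALSE, n)
  interior[as.vector(vapply(int_i, function(i) idx(i, 1:n_t), integer(n_t)))] <- TRUE
  list(A = A, rhs = rhs, interior = interior, outer_bc = outer_bc)
}

#' Solve the steady plume transport equation
#'
#' Finite-difference solution of
#' `Pe v.grad(C) = laplacian(C) - Da B(r) a(C) C` in axisymmetric spherical
#' coordinates with the Stokes velocity field, the configured surface
#' boundary condition at `r = 1`, symmetry at the poles, and the configured
#' far-field treatment at `R_out`. Advection uses third-order upwind-biased
#' stencils (first-order next to boundaries); diffusion uses conservative
#' central differences on the stretched grid. The sparse linear system is
#' solved directly, so repeated runs are bitwise identical. Saturable
#' (Michaelis-Menten) uptake is handled by under-relaxed Picard iteration
#' on the affinity factor.
#'
#' When the configuration leaves `R_out = NULL`, the outer radius is chosen
#' adaptively: solve, then double the domain (re-solving) until the plume
#' length at `C_det = 0.1` changes by less than `config$adapt_tol`.
#'
#' @param problem A [transport_problem()].
#' @param config A [solver_config()].
#' @param grid Optional [build_grid()] result; when supplied (e.g. to align
#'   a reference solve with a quenched one) it is used verbatim and no
#'   domain adaptation happens.
#' @return An object of class `plume_field`: list with `grid`, matrix `C`
#'   (`n_r` by `n_theta`), `problem`, `config`, and `diagnostics` (Picard
#'   history, outer BC used, max-principle bounds).
#' @examples
#' \donttest{
#' pr <- transport_problem(Pe = 0, Da = 0, rdf = rdf_preset("uniform"))
#' fld <- solve_transport(pr, solver_config(n_r = 60, n_theta = 24, R_out = 40))
#' }
#' @export
solve_transport <- function(problem, config = solver_config(), grid = NULL) {
  stopifnot(inherits(problem, "transport_problem"), inherits(config, "solver_config"))
  if (!is.null(grid)) {
    return(solve_on_grid(problem, grid, config))
  }
  if (!is.null(config$R_out)) {
    g <- build_grid(config, problem)
    return(solve_on_grid(problem, g, config))
  }
  # adaptive outer radius: double until the plume length stabilizes
  R_out <- max(30, 4 * estimate_plume_length(problem))
  field <- solve_on_grid(problem, build_grid(config, problem, R_out = R_out), config)
  L_prev <- plume_length(field, C_det = 0.1, strict = FALSE)$L_plm
  for (k in 1:4) {
    R_out <- 2 * R_out
    field_new <- solve_on_grid(problem, build_grid(config, problem, R_out = R_out), config)
    L_new <- plume_length(field_new, C_det = 0.1, strict = FALSE)$L_plm
    if (is.finite(L_prev) && is.finite(L_new) &&
        abs(L_new - L_prev) <= config$adapt_tol * L_new) {
      # previous domain was already adequate
      return(field)
    }
    field <- field_new
    L_prev <- L_new
  }
  field
}

solve_on_grid <- function(problem, grid, config) {
  ops <- assemble_transport(problem, grid, config)
  n_r <- length(grid$r); n_t <- length(grid$theta)
  n <- n_r * n_t
  B_r <- rdf_evaluate(problem$rdf, grid$r)
  B_vec <- rep(B_r, each = n_t) * ops$interior   # zero on boundary rows

  picard <- NULL
  if (problem$uptake$kind == "linear" || problem$Da == 0) {
    A <- ops$A - Matrix::Diagonal(n, problem$Da * B_vec)
    C <- as.numeric(Matrix::solve(A, ops$rhs))
  } else {
    K_S <- problem$uptake$K_S
    # start from the linear-uptake solution
    A <- ops$A - Matrix::Diagonal(n, problem$Da * B_vec)
    C <- as.numeric(Matrix::solve(A, ops$rhs))
    hist <- numeric(0)
    for (it in seq_len(config$picard_max)) {
      a_fac <- K_S / (K_S + pmax(C, 0))
      A <- ops$A - Matrix::Diagonal(n, problem$Da * B_vec * a_fac)
      C_new <- as.numeric(Matrix::solve(A, ops$rhs))
      C_next <- config$relax * C_new + (1 - config$relax) * C
      upd <- max(abs(C_next - C))
      hist <- c(hist, upd)
      C <- C_next
      if (upd < config$picard_tol) break
    }
    if (hist[length(hist)] >= config$picard_tol) {
      stop("Picard iteration for Michaelis-Menten uptake did not converge; ",
           "update history: ", paste(signif(utils::tail(hist, 5), 3), collapse = ", "),
           call. = FALSE)
    }
    picard <- hist
  }

  Cm <- matrix(C, nrow = n_r, ncol = n_t, byrow = TRUE)
  structure(list(
    grid = grid, C = Cm, problem = problem, config = config,
    diagnostics = list(
      outer_bc = ops$outer_bc,
      picard_updates = picard,
      C_min = min(Cm), C_max = max(Cm)
    )
  ), class = "plume_field")
}

#' Reference (zero-uptake) solve on the same grid
#'
#' Re-solves the problem with `Da = 0` on the grid of an existing solution
#' (or a supplied grid) so the quenched and undisturbed fields are
#' node-aligned and quenching ratios are not polluted by discretization
#' differences.
#'
#' @param x A `plume_field` (its grid and config are reused) or a
#'   [transport_problem()].
#' @param config,grid Used when `x` is a problem.
#' @return A `plume_field` solved at `Da = 0`.
#' @export
solve_reference <- function(x, config = solver_config(), grid = NULL) {
  if (inherits(x, "plume_field")) {
    problem <- x$problem
    config <- x$config
    grid <- x$grid
  } else {
    problem <- x
  }
  problem$Da <- 0
  solve_transport(problem, config, grid = grid)
}

#' @export
print.plume_field <- function(x, ...) {
  cat(sprintf("<plume_field> Pe = %g, Da = %g, %d x %d grid, R_out = %.3g, C in [%.3g, %.3g]\n",
              x$problem$Pe, x$problem$Da, nrow(x$C), ncol(x$C),
              x$grid$R_out, x$diagnostics$C_min, x$diagnostics$C_max))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.plume_field <- function(x, ...) {
  tibble::tibble(
    r = rep(x$grid$r, times = length(x$grid$theta)),
    theta = rep(x$grid$theta, each = length(x$grid$r)),
    C = as.vector(x$C)
  )
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @exportS3Method generics::tidy
tidy.plume_field <- function(x, ...) as_tibble.plume_field(x)

#' @exportS3Method generics::glance
glance.plume_field <- function(x, ...) {
  tibble::tibble(
    Pe = x$problem$Pe, Da = x$problem$Da,
    n_r = nrow(x$C), n_theta = ncol(x$C), R_out = x$grid$R_out,
    outer_bc = x$diagnostics$outer_bc,
    C_min = x$diagnostics$C_min, C_max = x$diagnostics$C_max,
    picard_iters = length(x$diagnostics$picard_updates %||% integer(0))
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data %||%
NULL

#' Meridional map of a solved nutrient field
#'
#' Plots the concentration in the meridional plane: the particle moves
#' downward, so its wake (the plume) extends upward. The axial coordinate is
#' `z = -r cos(theta)` and the transverse coordinate `x = r sin(theta)`.
#'
#' @param object A `plume_field`.
#' @param C_det Optional detection threshold contour to draw.
#' @param zoom Half-width of the plotting window in particle radii
#'   (default: the plume length plus a margin).
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.plume_field <- function(object, C_det = 0.1, zoom = NULL, ...) {
  df <- as_tibble.plume_field(object)
  df$x <- df$r * sin(df$theta)
  df$z <- -df$r * cos(df$theta)
  if (is.null(zoom)) {
    L <- tryCatch(plume_length(object, C_det, strict = FALSE)$L_plm,
                  error = function(e) NA_real_)
    zoom <- if (is.finite(L)) 1.5 * max(L, 3) else object$grid$R_out / 2
  }
  df <- df[df$r <= zoom * 1.5, , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z, z = .data$C)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$C), size = 0.4) +
    ggplot2::scale_colour_viridis_c(trans = "sqrt") +
    ggplot2::coord_fixed(xlim = c(0, zoom), ylim = c(-zoom / 2, zoom)) +
    ggplot2::labs(x = "x (particle radii)", y = "z (particle radii)",
                  colour = "C",
                  title = sprintf("Pe = %g, Da = %g", object$problem$Pe, object$problem$Da))
  p
}
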