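#' Classify aggregate records into size and velocity classes
#'
#' Size classes by equivalent sphere diameter (ESD): small `[0, 0.3)` mm,
#' medium `[0.3, 0.8)` mm, large `[0.8, Inf)` mm. Velocity classes by
#' sinking velocity (SV): low `[0, 20)`, moderate `[20, 100)`,
#' high `[100, 300)`, very high `[300, Inf)` m/d (half-open intervals make
#' the classification total). Three representative classes mark where plume
#' reshaping is meaningful: `large_slow` (large, SV < 100), `medium_fast`
#' (medium, 20 <= SV < 300), `small_slow` (small, SV < 20). Everything else
#' is `excluded` with a reason: inertial flow effects (large, SV >= 100),
#' low particle counts (medium, SV < 20), low Damkohler number (small,
#' SV >= 20), or negligible reshaping (SV >= 300).
#'
#' @param records Data frame with columns `esd_mm` (> 0) and `sv_m_per_d`
#'   (>= 0).
#' @return The input with columns `size_class`, `velocity_class`,
#'   `representative_class`, `exclusion_reason` appended.
#' @examples
#' classify_particles(data.frame(esd_mm = c(1.2, 2, 0.1), sv_m_per_d = c(50, 250, 100)))
#' @export
classify_particles <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("esd_mm", "sv_m_per_d") %in% names(records)))
  esd <- records$esd_mm; sv <- records$sv_m_per_d
  if (any(esd <= 0) || any(sv < 0)) {
    stop("`esd_mm` must be > 0 and `sv_m_per_d` >= 0", call. = FALSE)
  }
  size_class <- dplyr::case_when(
    esd < 0.3 ~ "small",
    esd < 0.8 ~ "medium",
    TRUE ~ "large"
  )
  velocity_class <- dplyr::case_when(
    sv < 20 ~ "low",
    sv < 100 ~ "moderate",
    sv < 300 ~ "high",
    TRUE ~ "very_high"
  )
  rep_class <- dplyr::case_when(
    sv >= 300 ~ "excluded",
    size_class == "large" & sv < 100 ~ "large_slow",
    size_class == "medium" & sv >= 20 ~ "medium_fast",
    size_class == "small" & sv < 20 ~ "small_slow",
    TRUE ~ "excluded"
  )
  reason <- dplyr::case_when(
    rep_class != "excluded" ~ NA_character_,
    sv >= 300 ~ "negligible reshaping (SV >= 300 m/d)",
    size_class == "large" ~ "inertial flow effects (SV >= 100 m/d)",
    size_class == "medium" ~ "low particle counts (SV < 20 m/d)",
    TRUE ~ "low Damkohler number (small particle, SV >= 20 m/d)"
  )
  dplyr::mutate(tibble::as_tibble(records),
                size_class = size_class,
                velocity_class = velocity_class,
                representative_class = rep_class,
                exclusion_reason = reason)
}

#' Precompute a quenching-factor lookup grid
#'
#' Solves the quenched/reference pair on a log-spaced `(Pe, Da)` grid and
#' stores `log(E_L)` and `log(E_V)` for bilinear interpolation in log space,
#' so batch runs over thousands of records avoid per-record PDE solves.
#'
#' @param Pe_range,Da_range Ranges (length-2, positive) to cover.
#' @param rdf Bacterial RDF used for every solve.
#' @param n_Pe,n_Da Grid sizes. The defaults (9 x 6) keep the
#'   interpolation error against direct solves well under 2%; the Da
#'   direction needs the extra density because log E_L is strongly curved
#'   in log Da at high Pe.
#' @param config Solver configuration.
#' @param C_det Detection threshold.
#' @return An object of class `quench_lookup`: the node vectors and
#'   matrices of `log(E_L)`, `log(E_V)`.
#' @export
quench_lookup <- function(Pe_range, Da_range, rdf, n_Pe = 9, n_Da = 6,
                          config = solver_config(), C_det = 0.1) {
  stopifnot(length(Pe_range) == 2, length(Da_range) == 2,
            all(Pe_range > 0), all(Da_range > 0))
  Pe_nodes <- exp(seq(log(Pe_range[1]), log(Pe_range[2]), length.out = n_Pe))
  Da_nodes <- exp(seq(log(Da_range[1]), log(Da_range[2]), length.out = n_Da))
  logEL <- matrix(NA_real_, n_Pe, n_Da)
  logEV <- matrix(NA_real_, n_Pe, n_Da)
  for (ip in seq_len(n_Pe)) {
    # one reference per Pe; its grid is reused for every Da
    ref_problem <- transport_problem(Pe = Pe_nodes[ip], Da = 0, rdf = rdf)
    ref <- solve_transport(ref_problem, config)
    for (id in seq_len(n_Da)) {
      pr <- transport_problem(Pe = Pe_nodes[ip], Da = Da_nodes[id], rdf = rdf)
      fld <- solve_transport(pr, config, grid = ref$grid)
      qf <- quench_factors(fld, ref, C_det)
      logEL[ip, id] <- log(qf$E_L)
      logEV[ip, id] <- log(qf$E_V)
    }
  }
  structure(list(Pe = Pe_nodes, Da = Da_nodes, logEL = logEL, logEV = logEV,
                 rdf = rdf, C_det = C_det),
            class = "quench_lookup")
}

# tensor-product interpolation in (log Pe, log Da) of a log-quantity matrix:
# natural cubic splines along each dimension (linear when a dimension has
# fewer than 4 nodes). Splines rather than bilinear cells because log E_L
# is visibly curved in log Pe at the default 9-node density.
lookup_interp <- function(lk, Pe, Da, what = c("logEL", "logEV")) {
  what <- match.arg(what)
  M <- lk[[what]]
  lx <- log(lk$Pe); ly <- log(lk$Da)
  x <- log(Pe); y <- log(Da)
  eps <- 1e-9
  if (any(x < lx[1] - eps | x > lx[length(lx)] + eps |
          y < ly[1] - eps | y > ly[length(ly)] + eps)) {
    stop("(Pe, Da) outside the lookup grid; rebuild with wider ranges", call. = FALSE)
  }
  x <- pmin(pmax(x, lx[1]), lx[length(lx)])
  y <- pmin(pmax(y, ly[1]), ly[length(ly)])
  interp1 <- function(xs, vs, xout) {
    if (length(xs) >= 4) {
      stats::spline(xs, vs, xout = xout, method = "natural")$y
    } else {
      stats::approx(xs, vs, xout = xout)$y
    }
  }
  v <- vapply(seq_along(x), function(k) {
    along_y <- vapply(seq_along(ly), function(j) interp1(lx, M[, j], x[k]), numeric(1))
    interp1(ly, along_y, y[k])
  }, numeric(1))
  exp(v)
}

#' Batch quenching over a particle record table
#'
#' Converts each record to dimensionless numbers (with `R_P = ESD/2`) and
#' evaluates the length quenching factor, either by bilinear interpolation
#' on a precomputed log-spaced lookup grid (default; built to cover the
#' records) or by a direct PDE solve per record (`method = "exact"`).
#' Records with `Re >= 1` are processed but flagged.
#'
#' @param records Data frame with `esd_mm` and `sv_m_per_d` columns.
#' @param diffusivity Nutrient diffusivity in cm^2/s.
#' @param tau_U Uptake timescale in s.
#' @param rdf Bacterial RDF (an [rdf_params()]).
#' @param method `"lookup"` or `"exact"`.
#' @param lookup Optional prebuilt [quench_lookup()] (ignored for
#'   `"exact"`).
#' @param config Solver configuration.
#' @param C_det Detection threshold.
#' @return The classified records with `Pe`, `Da`, `Re`, `re_flag`, `E_L`,
#'   `pct_delta_L` appended (`pct_delta_L = 100 (1 - 1/E_L)`).
#' @export
batch_quench <- function(records, diffusivity = 1e-5, tau_U = 1000,
                         rdf = rdf_preset("strong"),
                         method = c("lookup", "exact"), lookup = NULL,
                         config = solver_config(), C_det = 0.1) {
  method <- match.arg(method)
  out <- classify_particles(records)
  if (nrow(out) == 0) {
    return(dplyr::mutate(out, Pe = numeric(0), Da = numeric(0), Re = numeric(0),
                         re_flag = logical(0), E_L = numeric(0),
                         pct_delta_L = numeric(0)))
  }
  scen <- purrr::map2(out$esd_mm, out$sv_m_per_d, function(esd, sv) {
    particle_scenario(radius = esd / 2, velocity = sv, diffusivity = diffusivity,
                      tau_U = tau_U, radius_unit = "mm")
  })
  nums <- purrr::map_dfr(scen, dimensionless_numbers)
  out <- dplyr::bind_cols(out, nums)
  if (method == "lookup") {
    if (is.null(lookup)) {
      lookup <- quench_lookup(
        Pe_range = range(out$Pe) * c(0.95, 1.05),
        Da_range = range(out$Da) * c(0.95, 1.05),
        rdf = rdf, config = config, C_det = C_det
      )
    }
    out$E_L <- lookup_interp(lookup, out$Pe, out$Da, "logEL")
  } else {
    out$E_L <- purrr::map2_dbl(out$Pe, out$Da, function(Pe, Da) {
      ref <- solve_transport(transport_problem(Pe = Pe, Da = 0, rdf = rdf), config)
      fld <- solve_transport(transport_problem(Pe = Pe, Da = Da, rdf = rdf),
                             config, grid = ref$grid)
      quench_factors(fld, ref, C_det)$E_L
    })
  }
  dplyr::mutate(out, pct_delta_L = 100 * (1 - 1 / .data$E_L))
}

#' Per-class summary of quenching statistics
#'
#' Order statistics of the percent relative change in plume length per
#' representative particle class, matching a box-chart layout: sample count,
#' mean, min/max and the {1, 10, 25, 50, 75, 90, 99} percentiles (linear
#' interpolation convention). Empty groups are omitted with a warning.
#'
#' @param quench_table Output of [batch_quench()].
#' @param value Column to summarize (default `pct_delta_L`).
#' @param group Grouping column (default `representative_class`); the
#'   `"excluded"` group is dropped.
#' @return Tibble, one row per class.
#' @export
quench_summary <- function(quench_table, value = "pct_delta_L",
                           group = "representative_class") {
  stopifnot(is.data.frame(quench_table),
            all(c(value, group) %in% names(quench_table)))
  df <- quench_table[quench_table[[group]] != "excluded", , drop = FALSE]
  if (nrow(df) == 0) {
    warning("no records in any representative class")
    return(tibble::tibble())
  }
  probs <- c(0.01, 0.10, 0.25, 0.50, 0.75, 0.90, 0.99)
  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data[[value]]),
      min = min(.data[[value]]),
      p1 = stats::quantile(.data[[value]], 0.01, type = 7, names = FALSE),
      p10 = stats::quantile(.data[[value]], 0.10, type = 7, names = FALSE),
      p25 = stats::quantile(.data[[value]], 0.25, type = 7, names = FALSE),
      p50 = stats::quantile(.data[[value]], 0.50, type = 7, names = FALSE),
      p75 = stats::quantile(.data[[value]], 0.75, type = 7, names = FALSE),
      p90 = stats::quantile(.data[[value]], 0.90, type = 7, names = FALSE),
      p99 = stats::quantile(.data[[value]], 0.99, type = 7, names = FALSE),
      max = max(.data[[value]]),
      .groups = "drop"
    )
}
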