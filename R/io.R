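#' Read a digitized bacterial accumulation profile
#'
#' Comma-separated text with a mandatory header `r,b[,weight]`; lines
#' starting with `#` before the header are metadata and are skipped. Radii
#' are dimensionless (particle radii) unless `particle_radius_um` is given,
#' in which case the `r` column is interpreted as micrometers and
#' normalized.
#'
#' @param path File path.
#' @param particle_radius_um Optional particle radius in um for
#'   normalization of dimensional radii.
#' @return Tibble with columns `r`, `b` (and `weight` if present), a valid
#'   [fit_rdf()] input.
#' @export
read_profile <- function(path, particle_radius_um = NULL) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("r", "b") %in% names(df))) {
    stop("profile file must have header columns `r,b[,weight]`", call. = FALSE)
  }
  if (!is.null(particle_radius_um)) df$r <- df$r / particle_radius_um
  df
}

#' Read a particle record table
#'
#' Comma-separated text with header `esd_mm,sv_m_per_d[,source]`;
#' `#`-prefixed metadata lines are permitted before the header.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_particles <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("esd_mm", "sv_m_per_d") %in% names(df))) {
    stop("particle file must have header columns `esd_mm,sv_m_per_d[,source]`",
         call. = FALSE)
  }
  df
}

problem_metadata <- function(problem, config = NULL) {
  md <- list(
    package = "plumequench",
    version = as.character(utils::packageVersion("plumequench")),
    Pe = problem$Pe, Da = problem$Da,
    rdf = problem$rdf[c("beta0", "beta_m", "d_s", "n")],
    uptake = problem$uptake$kind,
    K_S = problem$uptake$K_S,
    surface_bc = problem$surface$kind,
    C_S = problem$surface$C_S, q_As = problem$surface$q_As
  )
  if (!is.null(config)) {
    md$solver <- config[c("n_r", "n_theta", "stretch", "R_out", "outer_bc",
                          "theta_spacing")]
  }
  md[!vapply(md, is.null, logical(1))]
}

#' Export a solved field as delimited text
#'
#' Writes `#`-prefixed metadata lines (problem and solver parameters,
#' package version) followed by a CSV table with columns `r,theta,C`.
#'
#' @param field A `plume_field`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  md <- problem_metadata(field$problem, field$config)
  hdr <- paste0("# ", gsub("\n", "\n# ", yaml::as.yaml(md)))
  hdr <- sub("\n# $", "", hdr)
  writeLines(hdr, path)
  readr::write_csv(as_tibble.plume_field(field), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' Write a metrics document
#'
#' Structured key/value (YAML) document with all plume metrics plus the
#' resolved problem parameters, so each run is self-describing.
#'
#' @param metrics One-row tibble (e.g. from [plume_metrics()]).
#' @param problem The [transport_problem()] behind it.
#' @param path Output path.
#' @param config Optional [solver_config()] to embed.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, problem, path, config = NULL) {
  doc <- c(problem_metadata(problem, config), list(metrics = as.list(metrics)))
  yaml::write_yaml(doc, path)
  invisible(path)
}

resolve_problem <- function(cfg) {
  rdf <- if (!is.null(cfg$rdf_preset)) {
    rdf_preset(cfg$rdf_preset)
  } else if (!is.null(cfg$rdf)) {
    do.call(rdf_params, cfg$rdf)
  } else {
    stop("config error: missing key `rdf` (give `rdf_preset` or an `rdf` parameter block)",
         call. = FALSE)
  }
  if (!is.null(cfg$Pe) && !is.null(cfg$scenario)) {
    stop("config error: give exactly one of `Pe` or `scenario`", call. = FALSE)
  }
  if (!is.null(cfg$scenario)) {
    s <- do.call(particle_scenario, cfg$scenario)
    nums <- dimensionless_numbers(s)
    Pe <- nums$Pe; Da <- nums$Da
  } else {
    if (is.null(cfg$Pe)) stop("config error: missing key `Pe` (or a `scenario` block)",
                              call. = FALSE)
    Pe <- cfg$Pe
    if (is.null(cfg$Da)) stop("config error: missing key `Da`", call. = FALSE)
    Da <- cfg$Da
  }
  if (!is.null(cfg$Da)) Da <- cfg$Da   # explicit Da wins over scenario derivation
  uptake <- if (is.null(cfg$uptake)) uptake_model() else {
    uptake_model(cfg$uptake$kind %||% "linear", K_S = cfg$uptake$K_S)
  }
  surface <- if (is.null(cfg$surface)) surface_bc() else {
    surface_bc(cfg$surface$kind %||% "dirichlet",
               C_S = cfg$surface$C_S %||% 1, q_As = cfg$surface$q_As)
  }
  transport_problem(Pe = Pe, Da = Da, rdf = rdf, uptake = uptake,
                    surface = surface)
}

resolve_config <- function(cfg) {
  sc <- cfg$solver %||% list()
  do.call(solver_config, sc)
}

#' Run one quenched/reference solve from a configuration
#'
#' Resolves the configuration (a YAML file path or a nested list with
#' `Pe`/`Da` or a dimensional `scenario` block, an `rdf_preset` or `rdf`
#' block, optional `uptake`, `surface`, `solver` and `C_det` entries),
#' solves the quenched problem and its zero-uptake reference on one grid,
#' and writes the field, the metrics document and a resolved-config echo
#' next to `out_prefix`.
#'
#' @param config Path to a YAML config or a named list.
#' @param out_prefix Output path prefix; writes `<prefix>_field.csv`,
#'   `<prefix>_metrics.yml`, `<prefix>_config.yml`. `NULL` skips writing.
#' @return The [plume_metrics()] row, invisibly (with fields attached as
#'   attributes `quenched` and `reference`).
#' @export
run_solve <- function(config, out_prefix = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  problem <- resolve_problem(cfg)
  sconfig <- resolve_config(cfg)
  C_det <- cfg$C_det %||% 0.1
  reference <- solve_transport(transport_problem(problem$Pe, 0, problem$rdf,
                                                 problem$uptake, problem$surface),
                               sconfig)
  quenched <- if (problem$Da == 0) reference else {
    solve_transport(problem, sconfig, grid = reference$grid)
  }
  metrics <- plume_metrics(quenched, reference, C_det = C_det)
  if (!is.null(out_prefix)) {
    write_field(quenched, paste0(out_prefix, "_field.csv"))
    write_metrics(metrics, problem, paste0(out_prefix, "_metrics.yml"), sconfig)
    yaml::write_yaml(cfg, paste0(out_prefix, "_config.yml"))
  }
  attr(metrics, "quenched") <- quenched
  attr(metrics, "reference") <- reference
  invisible(metrics)
}

#' Sweep quenching metrics over Pe and Da lists
#'
#' One metrics row per `(Pe, Da)` combination at a fixed RDF; within each
#' Pe the zero-uptake reference is solved once and its grid reused for
#' every Da, so quenching ratios are discretization-consistent. When `path`
#' is given the sweep is resumable: rows already present (matched on
#' `Pe`, `Da`, `rdf`) are not recomputed.
#'
#' @param Pe,Da Numeric vectors (non-empty).
#' @param rdf An [rdf_params()] (or preset name).
#' @param config Solver configuration.
#' @param C_det Detection threshold.
#' @param path Optional CSV path for resumable output.
#' @param rdf_label Label recorded in the `rdf` column.
#' @return Tibble with one row per combination: `Pe`, `Da`, `rdf`, `L0`,
#'   `L`, `V0`, `V`, `E_L`, `E_V`, `delta_L`, `delta_V`, `c_star`, `Sh_R`,
#'   `E_dis`.
#' @export
run_sweep <- function(Pe, Da, rdf = rdf_preset("strong"),
                      config = solver_config(), C_det = 0.1,
                      path = NULL, rdf_label = NULL) {
  if (is.character(rdf)) {
    rdf_label <- rdf_label %||% rdf
    rdf <- rdf_preset(rdf)
  }
  rdf_label <- rdf_label %||%
    sprintf("rdf(%g,%g,%g,%g)", rdf$beta0, rdf$beta_m, rdf$d_s, rdf$n)
  stopifnot(length(Pe) >= 1, length(Da) >= 1)
  existing <- NULL
  if (!is.null(path) && file.exists(path)) {
    existing <- readr::read_csv(path, show_col_types = FALSE)
  }
  rows <- list()
  for (pe in Pe) {
    ref <- NULL
    for (da in Da) {
      if (!is.null(existing)) {
        hit <- existing[abs(existing$Pe - pe) < 1e-12 &
                        abs(existing$Da - da) < 1e-12 &
                        existing$rdf == rdf_label, , drop = FALSE]
        if (nrow(hit) > 0) {
          rows[[length(rows) + 1]] <- tibble::as_tibble(hit[1, ])
          next
        }
      }
      if (is.null(ref)) {
        ref <- solve_transport(transport_problem(pe, 0, rdf), config)
      }
      fld <- if (da == 0) ref else {
        solve_transport(transport_problem(pe, da, rdf), config, grid = ref$grid)
      }
      m <- plume_metrics(fld, ref, C_det = C_det)
      row <- dplyr::bind_cols(
        tibble::tibble(Pe = pe, Da = da, rdf = rdf_label),
        m[, c("L0", "L", "V0", "V", "E_L", "E_V", "delta_L", "delta_V",
              "c_star", "Sh_R", "E_dis")]
      )
      rows[[length(rows) + 1]] <- row
      if (!is.null(path)) {
        readr::write_csv(row, path, append = file.exists(path))
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Line plot of quenching factors across a sweep
#'
#' @param sweep Output of [run_sweep()].
#' @param y `"E_L"` or `"E_V"`.
#' @return A ggplot.
#' @export
plot_quench_sweep <- function(sweep, y = c("E_L", "E_V")) {
  y <- match.arg(y)
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$Pe, y = .data[[y]],
                                      colour = factor(.data$Da),
                                      group = .data$Da)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Peclet number", y = paste("quenching factor", y),
                  colour = "Da")
}
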