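# synthetic field with a prescribed radially symmetric profile, for oracle
# tests of the metric quadratures without a PDE solve
analytic_field <- function(fun, n_r = 400, n_theta = 32, R_out = 40, Pe = 0) {
  cfg <- solver_config(n_r = n_r, n_theta = n_theta, R_out = R_out)
  pr <- transport_problem(Pe, 0, rdf_preset("uniform"))
  g <- build_grid(cfg, pr)
  fld <- structure(list(
    grid = g,
    C = matrix(fun(g$r), nrow = n_r, ncol = n_theta),
    problem = pr, config = cfg,
    diagnostics = list(outer_bc = "radiation", C_min = 0, C_max = 1)
  ), class = "plume_field")
  fld
}

test_that("plume length finds the outermost threshold crossing", {
  f1 <- analytic_field(function(r) 1 / r)
  expect_equal(plume_length(f1, 0.1)$L_plm, 10, tolerance = 1e-3)
  # screened profile: frozen root of exp(-sqrt(1.6)(r-1))/r = 0.1
  f2 <- analytic_field(function(r) exp(-sqrt(1.6) * (r - 1)) / r)
  expect_equal(plume_length(f2, 0.1)$L_plm, 2.1978, tolerance = 0.01)
  # non-monotone profile: outermost crossing wins
  f3 <- analytic_field(function(r) 0.05 + 0.3 * exp(-(r - 3)^2))
  expect_gt(plume_length(f3, 0.1)$L_plm, 3)
  # no plume
  f4 <- analytic_field(function(r) 0.05 / r)
  pl <- plume_length(f4, 0.1)
  expect_true(pl$no_plume)
  expect_equal(pl$L_plm, 1)
  # domain too small
  f5 <- analytic_field(function(r) rep(0.5, length(r)))
  expect_error(plume_length(f5, 0.1), "domain too small")
})

test_that("plume volume integrates the indicator with sub-cell crossings", {
  f1 <- analytic_field(function(r) 1 / r)
  expect_equal(plume_volume(f1, 0.1)$V_plm, 999, tolerance = 0.01)
  f2 <- analytic_field(function(r) exp(-sqrt(1.6) * (r - 1)) / r)
  expect_equal(plume_volume(f2, 0.1)$V_plm, 9.616, tolerance = 0.03)
  f4 <- analytic_field(function(r) 0.05 / r)
  expect_equal(plume_volume(f4, 0.1)$V_plm, 0)
})

test_that("quench factors obey their defining identities", {
  f0 <- analytic_field(function(r) 1 / r)
  fq <- analytic_field(function(r) exp(-sqrt(1.6) * (r - 1)) / r)
  qf <- quench_factors(fq, f0)
  # frozen ratio of the two closed-form lengths 10 / 2.1978
  expect_equal(qf$E_L, 4.55, tolerance = 0.02)
  expect_equal(qf$delta_V, 1 - 1 / qf$E_V, tolerance = 1e-12)
  expect_equal(qf$delta_L, 1 - 1 / qf$E_L, tolerance = 1e-12)
  # identical fields: no quenching
  qf0 <- quench_factors(f0, f0)
  expect_equal(unlist(qf0[c("E_L", "E_V", "delta_L", "delta_V")]),
               c(E_L = 1, E_V = 1, delta_L = 0, delta_V = 0))
  # reported correspondences between factor and relative change
  expect_equal(1 - 1 / 1.25, 0.20)
  expect_equal(1 - 1 / 10, 0.90)
  # degenerate quenched plume
  fd <- analytic_field(function(r) 0.01 / r)
  qfd <- quench_factors(fd, f0)
  expect_true(qfd$degenerate)
  expect_true(is.infinite(qfd$E_V))
})

test_that("nutrient exposure reproduces analytic averages and orderings", {
  f1 <- analytic_field(function(r) 1 / r)
  # uniform weight, C = 1/r: integral r dr / integral r^2 dr on [1, 3.3]
  expect_equal(nutrient_exposure(f1, rdf_preset("uniform"), 3.3), 0.42462,
               tolerance = 0.01)
  # constant field: weighted average of a constant is the constant
  fc <- analytic_field(function(r) rep(0.37, length(r)))
  expect_equal(nutrient_exposure(fc, rdf_preset("strong"), 3.3), 0.37,
               tolerance = 1e-10)
  # clustering weights the average toward the particle where C is highest
  expect_gt(nutrient_exposure(f1, rdf_preset("strong"), 3.3),
            nutrient_exposure(f1, rdf_preset("uniform"), 3.3))
  expect_error(nutrient_exposure(f1, rdf_preset("strong"), R_M = 1000),
               "domain")
})

test_that("total flux matches 4*pi for the diffusive field and is conserved", {
  f1 <- field_diffusion()
  expect_equal(total_flux(f1, 1), 4 * pi, tolerance = 0.01 * 4 * pi)
  # steady conservation without sinks: flux independent of radius within 2%
  radii <- c(1, 2, 3, 5, 10, 20)
  Q <- total_flux(f1, radii)
  expect_true(all(abs(Q / Q[1] - 1) < 0.02))
  # interior consumption reduces the flux with radius
  f2 <- field_screened()
  expect_lt(total_flux(f2, 3), total_flux(f2, 1))
  expect_error(total_flux(f1, 1000), "outside")
})

test_that("Sherwood number and degradation efficiency match closed forms", {
  f1 <- field_diffusion()
  sh <- sherwood(f1)
  expect_equal(sh$Sh_R, 1, tolerance = 0.01)
  expect_equal(sh$E_dis, 1)
  f2 <- field_screened()
  expect_equal(sherwood(f2, f1)$Sh_R, 1 + sqrt(1.6), tolerance = 0.02 * 2.26)
  # no consumption: efficiency zero everywhere
  dg0 <- degradation_efficiency(f1, c(2, 5, 10))
  expect_true(all(abs(dg0$E_degr) < 0.02))
  # screened field: everything consumed far away
  dgs <- degradation_efficiency(f2, c(3, 20, 39))
  expect_true(all(diff(dgs$E_degr) > 0))
  expect_gt(dgs$E_degr[3], 0.95)
  expect_equal(degradation_efficiency(f2, 1)$E_degr, 0)
})

test_that("shell balance: flux loss equals the volume integral of the sink", {
  fld <- field_pe20_uniform()
  r <- fld$grid$r
  w <- cos(c(0, fld$grid$theta_half, pi))
  w <- w[-length(w)] - w[-1]
  Q1 <- total_flux(fld, 1)
  B <- rdf_evaluate(fld$problem$rdf, r)
  for (rr in c(2, 5, 10)) {
    keep <- r <= rr
    g <- sweep(fld$C[keep, ], 1, fld$problem$Da * B[keep] * r[keep]^2, "*")
    I <- vapply(seq_len(ncol(g)), function(j) {
      sum(diff(r[keep]) * (g[-1, j] + g[-sum(keep), j]) / 2)
    }, numeric(1))
    sink <- 2 * pi * sum(w * I)
    expect_equal(1 - total_flux(fld, rr) / Q1, sink / Q1, tolerance = 0.02)
  }
})

test_that("plume_metrics assembles a consistent one-row summary", {
  m <- plume_metrics(field_pe20_strong(), field_pe20_ref())
  expect_equal(nrow(m), 1)
  expect_gt(m$E_L, 1)
  expect_gt(m$E_V, m$E_L)  # volume quenching exceeds length quenching here
  expect_equal(m$delta_V, 1 - 1 / m$E_V)
  expect_gt(m$Sh_R, 1)
  expect_gt(m$E_dis, 1)    # consumption steepens the surface gradient
  expect_lt(m$c_star, 1)
})
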