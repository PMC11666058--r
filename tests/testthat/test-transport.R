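test_that("grid construction stretches radially and obeys the outer-radius rule", {
  cfg <- solver_config(n_r = 200, n_theta = 32, stretch = 1.03, R_out = 50)
  g <- build_grid(cfg)
  expect_equal(g$r[1], 1)
  expect_equal(g$r[length(g$r)], 50)
  expect_lt(g$r[2] - g$r[1], g$r[200] - g$r[199])  # finest spacing at the surface
  expect_equal(range(g$theta), c(0, pi))
  # adaptive rule: undisturbed diffusive plume reaches r = 10, rule gives >= 20
  pr0 <- transport_problem(0, 0, rdf_preset("uniform"))
  g0 <- build_grid(solver_config(n_r = 64, n_theta = 16), pr0)
  expect_gte(g0$R_out, 20)
  # screened problem decays faster, so the rule admits a smaller domain
  pr1 <- transport_problem(0, 1.6, rdf_preset("uniform"))
  g1 <- build_grid(solver_config(n_r = 64, n_theta = 16), pr1)
  expect_lt(g1$R_out, g0$R_out)
  expect_error(solver_config(n_r = 8), "node counts")
})

test_that("pure diffusion reproduces the 1/r field, its length, volume and flux", {
  fld <- field_diffusion()
  exact <- 1 / fld$grid$r
  err <- max(abs(sweep(fld$C, 1, exact, "-")))
  expect_lt(err, 0.01)  # 1% max error criterion
  expect_equal(plume_length(fld)$L_plm, 10, tolerance = 0.01)
  expect_equal(plume_volume(fld)$V_plm, 999, tolerance = 0.01)
  expect_equal(sherwood(fld)$Sh_R, 1, tolerance = 0.02)
})

test_that("uniform uptake at Pe = 0 matches the screened closed form", {
  fld <- field_screened()
  r <- fld$grid$r
  exact <- exp(-sqrt(1.6) * (r - 1)) / r
  err <- max(abs(sweep(fld$C, 1, exact, "-")))
  expect_lt(err, 0.01)
  # frozen closed-form roots: L = 2.1978, V = L^3 - 1 = 9.616
  expect_equal(plume_length(fld)$L_plm, 2.1978, tolerance = 0.01)
  expect_equal(plume_volume(fld)$V_plm, 9.616, tolerance = 0.03)
  expect_equal(sherwood(fld, field_diffusion())$Sh_R, 1 + sqrt(1.6),
               tolerance = 0.02)
})

test_that("advection enriches the wake and the solution respects bounds", {
  ref <- field_pe20_ref()
  n_r <- nrow(ref$C)
  i2 <- which.min(abs(ref$grid$r - 2))
  expect_gt(ref$C[i2, ncol(ref$C)], ref$C[i2, 1])  # wake > upstream at r = 2
  # discrete maximum principle up to truncation-level noise of the
  # upwind-biased scheme
  expect_gt(min(ref$C), -1e-4)
  expect_lt(max(ref$C), 1 + 1e-4)
})

test_that("solve_reference aligns grids and dominates the quenched field", {
  q <- field_pe20_strong()
  ref <- solve_reference(q)
  expect_identical(ref$grid$r, q$grid$r)
  expect_equal(ref$problem$Da, 0)
  # comparison principle: removing the sink can only raise the field
  expect_true(all(ref$C - q$C >= -1e-4))
  # idempotent on a Da = 0 problem
  f0 <- field_diffusion()
  expect_equal(solve_reference(f0)$C, f0$C, tolerance = 1e-12)
})

test_that("concentration decreases pointwise with Da and with clustering", {
  cfg <- test_config()
  strong <- rdf_preset("strong")
  flds <- lapply(c(0, 0.16, 0.8, 1.6), function(da) {
    solve_transport(transport_problem(20, da, strong), cfg)
  })
  for (k in 1:3) {
    expect_true(all(flds[[k]]$C - flds[[k + 1]]$C >= -1e-4))
  }
  fs <- field_pe20_strong()
  fu <- field_pe20_uniform()
  fw <- solve_transport(transport_problem(20, 1.6, rdf_preset("weak")),
                        test_config(), grid = fs$grid)
  expect_true(all(fw$C - fs$C >= -1e-4))  # strong <= weak
  expect_true(all(fu$C - fw$C >= -1e-4))  # weak <= uniform
})

test_that("Michaelis-Menten uptake converges and weakens the sink", {
  cfg <- test_config()
  fmm <- solve_transport(
    transport_problem(20, 1.6, rdf_preset("strong"),
                      uptake = uptake_model("michaelis_menten", K_S = 1)),
    cfg
  )
  expect_gt(length(fmm$diagnostics$picard_updates), 0)
  expect_lt(min(utils::tail(fmm$diagnostics$picard_updates, 1)), 1e-8)
  # saturation reduces the affinity factor below 1, so C is higher than linear
  expect_true(all(fmm$C - field_pe20_strong()$C >= -1e-4))
})

test_that("flux surface boundary condition imposes the prescribed gradient", {
  pr <- transport_problem(0, 0, rdf_preset("uniform"),
                          surface = surface_bc("flux", q_As = 1))
  fld <- solve_transport(pr, diffusion_config())
  # for pure diffusion with -dC/dr = 1 at r = 1 the solution is again 1/r
  expect_equal(max(abs(sweep(fld$C, 1, 1 / fld$grid$r, "-"))), 0,
               tolerance = 0.02)
  expect_error(sherwood(fld), "Dirichlet")
})

test_that("repeated solves are bitwise identical", {
  cfg <- solver_config(n_r = 80, n_theta = 24, R_out = 40)
  pr <- transport_problem(5, 0.5, rdf_preset("weak"))
  f1 <- solve_transport(pr, cfg)
  f2 <- solve_transport(pr, cfg)
  expect_identical(f1$C, f2$C)
})

test_that("plume metrics are grid-converged at the headline conditions", {
  # quenched solve at Pe = 20, Da = 1.6, strong clustering; doubling node
  # counts changes L and V by < 1%
  qf <- lapply(list(c(160, 64), c(320, 128)), function(nn) {
    cfg <- solver_config(n_r = nn[1], n_theta = nn[2], R_out = 70)
    ref <- solve_transport(transport_problem(20, 0, rdf_preset("strong")), cfg)
    q <- solve_transport(transport_problem(20, 1.6, rdf_preset("strong")), cfg,
                         grid = ref$grid)
    quench_factors(q, ref)
  })
  expect_lt(abs(qf[[2]]$L - qf[[1]]$L) / qf[[2]]$L, 0.01)
  expect_lt(abs(qf[[2]]$V - qf[[1]]$V) / qf[[2]]$V, 0.01)
})
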