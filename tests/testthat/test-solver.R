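test_that("zero pressure produces the undeformed stress-free state", {
  mesh <- build_cross_section(dissection_geometry("mid"), h = 0.45)
  st <- pressurize(mesh, mats_for("mid"), 0)
  expect_equal(max(abs(st$u)), 0)
  expect_equal(max(abs(st$sys$sigma_centroid)), 0, tolerance = 1e-10)
  expect_equal(st$work_pressure, 0)
})

test_that("thin-ring pressurization matches the Laplace relation and
           conserves energy", {
  rg <- acc_ring_test()
  expect_lt(abs(rg$fe_hoop / rg$laplace - 1), 0.02)
  expect_lt(abs(rg$work / rg$energy - 1), 0.01)
})

test_that("a pre-apposed flap at zero aortic pressure needs no radial
           pressure", {
  mesh <- build_cross_section(dissection_geometry("mid"), h = 0.45)
  st <- pressurize(mesh, mats_for("mid"), 0)
  res <- expand_member(st, make_expansion_member(radius = 2))
  expect_lt(res$radial_pressure, 0.5)
})

test_that("member contact averaging follows its definition", {
  # uniform pressure over the contacting surface -> that pressure
  mem <- list(pressure = rep(100, 5), trib = rep(0.2, 5), n_active = 5)
  expect_equal(reappose:::member_avg_pressure(mem, 1, "contacting"), 100)
  # contact over half the surface at q, zero elsewhere, equal weights:
  # the full-surface average halves it
  mem2 <- list(pressure = rep(100, 5), trib = rep(0.2, 5), n_active = 5)
  expect_equal(reappose:::member_avg_pressure(mem2, 2 / pi, "full",
                                              half = TRUE), 50)
  empty <- list(pressure = numeric(0), trib = numeric(0), n_active = 0)
  expect_equal(reappose:::member_avg_pressure(empty, 1, "contacting"), 0)
})

test_that("the full simulation is deterministic and physically admissible", {
  geom <- dissection_geometry("mid")
  opts <- solver_options(g_tol = 0.05)
  r1 <- run_reapposition(geom, mats_for("mid"), 70, h = 0.6, options = opts)
  r2 <- run_reapposition(geom, mats_for("mid"), 70, h = 0.6, options = opts)
  expect_identical(r1$radial_pressure, r2$radial_pressure)
  expect_identical(r1$u, r2$u)

  expect_true(r1$converged)
  expect_gte(r1$radial_pressure, 0)
  expect_gte(r1$final_diameter, 2 * geom$inner_radius)
  # near-incompressibility at the volumetric quadrature points
  expect_lt(r1$maxJdev, 1e-3)
  # no interpenetration beyond a tenth of the re-apposition tolerance
  g <- reappose:::flap_gaps(r1$model, r1$u)
  expect_gt(min(g), -r1$g_tol_abs / 10)
  # quasi-static external work accounts for the stored energy
  expect_lt(abs(r1$work_external /
                (r1$strain_energy + r1$contact_energy) - 1), 0.01)
  # the average contact pressure is recoverable from the stored state
  expect_equal(radial_pressure_from_contact(r1), r1$radial_pressure,
               tolerance = 1e-12)
})

test_that("solver options are validated", {
  expect_error(solver_options(g_tol = 0.06), "g_tol")
  expect_error(solver_options(load_steps = 0))
  expect_error(solver_options(member_step = -1))
  o <- solver_options(avg_over = "full")
  expect_equal(o$avg_over, "full")
})
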