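test_that("degenerate dissection fractions are rejected", {
  expect_error(dissection_geometry("mid", flap_fraction = 0), "no dissection")
  expect_error(dissection_geometry("mid", flap_fraction = 0.3), "bounds")
  expect_silent(dissection_geometry("mid", flap_fraction = 0.45,
                                    f_bounds = c(0.4, 0.6)))
})

test_that("intact-ring mesh area matches the annulus analytically", {
  geom <- ring_geometry(inner_radius = 10, thickness = 1.5)
  mesh <- build_cross_section(geom, h = 0.3)
  a <- sum(mesh_layer_areas(mesh))
  exact <- pi * (11.5^2 - 10^2)
  expect_lt(abs(a - exact) / exact, 0.005)
})

test_that("default mid mesh satisfies the structural invariants", {
  geom <- dissection_geometry("mid")
  mesh <- build_cross_section(geom, h = 0.3)
  areas <- reappose:::elem_areas(mesh$nodes, mesh$elems)
  expect_true(all(areas > 0))
  # at least two element rows through the flap
  flap_elems <- sum(mesh$layer == "flap")
  flap_cols <- nrow(mesh$sets$flap_tl_side)
  expect_gte(flap_elems / flap_cols, 2)
  sym <- unique(as.vector(mesh$sets$symmetry_plane))
  expect_lt(max(abs(mesh$nodes[sym, 1])), 1e-9)
  # element count regression fixture for the default discretization
  expect_equal(nrow(mesh$elems), 609)
  # flap area ~ flap fraction x annulus of flap thickness
  la <- mesh_layer_areas(mesh)
  exp_flap <- 0.55 * pi * ((geom$inner_radius + geom$flap_thickness)^2 -
                           geom$inner_radius^2) / 2
  expect_lt(abs(la[["flap"]] - exp_flap) / exp_flap, 0.01)
})

test_that("boundary edge sets exactly tile their surfaces", {
  mesh <- build_cross_section(dissection_geometry("distal"), h = 0.3)
  for (nm in c("tl_lumen_surface", "flap_tl_side", "flap_fl_side",
               "fl_wall_inner")) {
    ed <- mesh$sets[[nm]]
    # consecutive chain with no gaps or repeats
    expect_true(all(ed[-1, 1] == ed[-nrow(ed), 2]))
    expect_false(any(duplicated(ed[, 1])))
  }
  # the two crack faces are conforming: same number of edges
  expect_equal(nrow(mesh$sets$flap_fl_side), nrow(mesh$sets$fl_wall_inner))
  # crack faces are coincident in the reference configuration
  a <- mesh$nodes[mesh$sets$flap_fl_side[, 1], ]
  b <- mesh$nodes[mesh$sets$fl_wall_inner[, 1], ]
  expect_lt(max(abs(a - b)), 1e-9)
})

test_that("mesh refinement changes per-layer areas below 0.2%", {
  geom <- dissection_geometry("mid")
  a1 <- mesh_layer_areas(build_cross_section(geom, h = 0.3))
  a2 <- mesh_layer_areas(build_cross_section(geom, h = 0.15))
  expect_lt(max(abs(a1 / a2 - 1)), 0.002)
})

test_that("expansion member guards hold", {
  expect_error(make_expansion_member(n_segments = 4), "n_segments")
  mesh <- build_cross_section(dissection_geometry("mid"), h = 0.3)
  m <- make_expansion_member(radius = 1)
  # undeformed flap is apposed on its mural arc: the closest structure
  # point to the member center is the lumen surface at the inner radius
  expect_equal(member_first_contact_radius(mesh, m),
               mesh$geom$inner_radius, tolerance = 1e-9)
  st <- structure(list(model = reappose:::fe_model(mesh, mats_for("mid"),
                                                   solver_options()),
                       u = numeric(2 * nrow(mesh$nodes)), p_aorta = 0,
                       sys = NULL, work_pressure = 0, work_member = 0,
                       f_press_prev = numeric(2 * nrow(mesh$nodes)),
                       f_mem_prev = numeric(2 * nrow(mesh$nodes)),
                       u_prev = numeric(2 * nrow(mesh$nodes)), log = list()),
                  class = "pressurized_state")
  big <- make_expansion_member(radius = mesh$geom$inner_radius + 0.5)
  expect_error(expand_member(st, big), "interpenetrat")
})

test_that("mesh coarseness against the flap is refused", {
  geom <- dissection_geometry("mid", flap_thickness = 0.58)
  expect_s3_class(build_cross_section(geom, h = 5), "cross_section_mesh")
  # two rows are always enforced; even a very coarse h keeps them
  m <- build_cross_section(geom, h = 1.2)
  expect_gte(sum(m$layer == "flap") / nrow(m$sets$flap_tl_side), 2)
})

test_that("VTK export writes a parsable legacy file", {
  mesh <- build_cross_section(ring_geometry(8, 1), h = 0.5)
  f <- tempfile(fileext = ".vtk")
  write_vtk(mesh, f)
  ln <- readLines(f)
  expect_equal(ln[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^POINTS", ln)))
  expect_true(any(grepl("^CELLS", ln)))
  unlink(f)
})
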