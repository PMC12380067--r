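test_that("geometries carry the stated sites and glial shells", {
  tis <- tissue_model()
  fl <- build_geometry("flexible_array", tis)
  expect_length(fl$sites, 8L)
  expect_equal(fl$glial_thickness_um, 0)
  expect_true(all(vapply(fl$sites, function(s) s$type, "") == "rect"))
  # 16 x 12 um sites at 30 um pitch
  expect_equal(fl$sites[[1]]$hx * 2, 16)
  expect_equal(fl$sites[[1]]$hy * 2, 12)
  centers <- vapply(fl$sites, function(s) s$cx, numeric(1))
  expect_equal(diff(centers), rep(30, 7))
  rg <- build_geometry("rigid_array", tis)
  expect_equal(rg$glial_thickness_um, 40)
  expect_equal(lapply(rg$sites, `[[`, "cx"), lapply(fl$sites, `[[`, "cx"))
  mw <- build_geometry("microwire", tis)
  expect_length(mw$sites, 1L)
  expect_equal(mw$sites[[1]]$r * 2, 100)
  expect_equal(mw$glial_thickness_um, 40)
  expect_error(build_geometry("planar"), "arg")
})

test_that("solved fields conserve current and scale linearly", {
  tis <- tissue_model()
  geom <- build_geometry("microwire", tis)
  grid <- coarse_grid(geom)
  s5 <- solve_field(geom, tis, 5, grid = grid)
  s10 <- solve_field(geom, tis, 10, grid = grid)
  # Laplace linearity, nodewise
  expect_equal(s10$V, 2 * s5$V, tolerance = 1e-9)
  expect_equal(s10$J, 2 * s5$J, tolerance = 1e-9)
  # global conservation: boundary outflow equals injection
  expect_lt(abs(s5$boundary_outflow_A - s5$injected_A) / s5$injected_A, 1e-8)
  # flux through a hemispheric-equivalent box around the electrode
  fl <- flux_through_box(s5, 400)
  expect_lt(abs(fl - 4 * s5$injected_A) / (4 * s5$injected_A), 0.02)
})

test_that("bare-microwire on-axis density matches the analytic disc source", {
  sol <- unit_field("microwire", glial = 0)
  for (z in c(20, 40, 60, 100, 150)) {
    k <- which.min(abs(sol$zc - z))
    ana <- disc_axis_J(sol$zc[k], 50, sol$current_uA)
    expect_lt(abs(sol$J[1, 1, k] - ana) / ana, 0.10)
  }
})

test_that("activated counts integrate density over supra-threshold tissue", {
  # hand-built field: uniform 2000 A/m^2 over a known sub-volume
  vol_cell <- 1e-15                            # 0.001 mm^3 over 1000 cells... 1 um^3 scale
  field <- structure(list(
    J = array(c(rep(2000, 250), rep(1, 750)), dim = c(10, 10, 10)),
    glia = array(FALSE, dim = c(10, 10, 10)),
    cell_vol_m3 = array(1e-12, dim = c(10, 10, 10)),  # 0.000001 mm^3 cells
    symmetry_factor = 1), class = "field_solution")
  model <- activation_model(neuron_density = 1e9)
  cnt <- activated_count(field, model)
  expect_equal(as.numeric(cnt), 1e9 * 250 * 1e-12)
  expect_equal(attr(cnt, "volume_mm3"), 250 * 1e-12 * 1e9)
  # doubling the density doubles the count
  cnt2 <- activated_count(field, activation_model(neuron_density = 2e9))
  expect_equal(as.numeric(cnt2), 2 * as.numeric(cnt))
  # everywhere below threshold: zero
  field$J[] <- 10
  expect_equal(as.numeric(activated_count(field, model)), 0)
  # glial cells are excluded from the tissue volume
  field$J[] <- 2000
  field$glia[1:5, , ] <- TRUE
  cnt3 <- activated_count(field, model)
  expect_equal(as.numeric(cnt3), 1e9 * 500 * 1e-12)
})

test_that("activation curves are monotone and the linear rescale is exact", {
  tis <- tissue_model()
  geom <- build_geometry("rigid_array", tis)
  grid <- coarse_grid(geom)
  f1 <- solve_field(geom, tis, 1, grid = grid)
  sw <- sweep_current(geom, tis, currents_uA = c(0, 1, 2, 5, 10, 20, 50, 100),
                      field = f1)
  expect_true(all(diff(sw$count) >= 0))
  expect_equal(sw$count[sw$current_uA == 0], 0)
  # rescaling shortcut agrees with independent re-solves
  for (I in c(2, 10, 50)) {
    sI <- solve_field(geom, tis, I, grid = grid)
    direct <- activated_count(sI, activation_model())
    expect_equal(sw$count[sw$current_uA == I], as.numeric(direct))
  }
  expect_error(sweep_current(geom, tis, currents_uA = c(5, 1)), "ascending")
})

test_that("matching a geometry against itself returns the probe current", {
  tis <- tissue_model()
  geom <- build_geometry("flexible_array", tis)
  grid <- coarse_grid(geom)
  f1 <- solve_field(geom, tis, 1, grid = grid)
  ref <- sweep_current(geom, tis, currents_uA = 5, field = f1)$count
  m <- matching_current(geom, tis, reference_count = ref, field = f1)
  expect_lt(abs(m - 5), 0.11)
  expect_error(matching_current(geom, tis, reference_count = ref * 1e6,
                                field = f1), "out-of-range")
  expect_error(matching_current(geom, tis, reference_count = -1, field = f1),
               "reference_count")
})

test_that("glial encapsulation never lowers the matching current", {
  act <- activation_model()
  flex <- unit_field("flexible_array")
  rig <- unit_field("rigid_array")
  tis <- tissue_model()
  ref <- sweep_current(build_geometry("flexible_array", tis), tis, act,
                       currents_uA = 5, field = flex)$count
  m_rigid <- matching_current(build_geometry("rigid_array", tis), tis, act,
                              ref, field = rig)
  expect_gte(m_rigid, 5)
})

test_that("matching currents are stable under one level of mesh refinement", {
  tis <- tissue_model(); act <- activation_model()
  ref0 <- sweep_current(build_geometry("flexible_array", tis), tis, act,
                        currents_uA = 5, field = unit_field("flexible_array"))$count
  m0 <- matching_current(build_geometry("microwire", tis), tis, act, ref0,
                         field = unit_field("microwire"))
  ref1 <- sweep_current(build_geometry("flexible_array", tis), tis, act,
                        currents_uA = 5,
                        field = unit_field("flexible_array", refine = 1.25))$count
  m1 <- matching_current(build_geometry("microwire", tis), tis, act, ref1,
                         field = unit_field("microwire", refine = 1.25))
  expect_lt(abs(m1 - m0) / m0, 0.10)
})
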