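test_that("wall profile is the Gaussian bump with its symmetry", {
  g <- default_parameters(H = 0.5, d = 0.4)
  expect_equal(wall_profile(0, g), 0.5)
  expect_equal(wall_profile(0.4, g), 0.5 * exp(-0.5), tolerance = 1e-12)
  expect_equal(wall_profile(0.8, g), wall_profile(-0.8, g))
  expect_error(wall_profile(-3, g), "outside")
  ## profile decays to numerically nothing at the domain ends
  expect_lt(wall_profile(2 * g$Lx / 3, g), 1e-8 * g$H)
})

test_that("mesh satisfies geometric closure and area invariants", {
  p <- default_parameters(H = 0.5, d = 0.4, Lx = 3)
  mesh <- build_mesh(p, 24)
  chk <- mesh_check(mesh)
  expect_lt(chk$max_closure_defect, 1e-12)
  expect_true(all(mesh$area > 0))
  ## total meshed area matches the quadrature of the lumen within 0.5%
  aref <- stats::integrate(function(x) p$Ly - wall_profile(x, p),
                           -p$Lx / 3, 2 * p$Lx / 3, rel.tol = 1e-10)$value
  expect_equal(sum(mesh$area), aref, tolerance = 5e-3)
  ## boundary patches partition the boundary
  expect_setequal(unique(mesh$b_patch), 1:4)
  expect_equal(sum(mesh$b_patch == 1), mesh$ny)
  expect_equal(sum(mesh$b_patch == 4), mesh$nx)
  ## lower wall faces sit on the profile, upper on y = Ly
  low <- mesh$b_patch == 4
  ymid <- 0.5 * (wall_profile(mesh$b_fcx[low] - 1e-9, p) +
                 wall_profile(mesh$b_fcx[low] + 1e-9, p))
  expect_lt(max(abs(mesh$b_fcy[low] - ymid)) , 2e-3)
  expect_lt(max(abs(mesh$b_fcy[mesh$b_patch == 3] - p$Ly)), 1e-12)
})

test_that("unstenosed mesh is rectangular and refinement scales cell count", {
  p <- default_parameters(H = 0, Lx = 2)
  m1 <- build_mesh(p, 16, bl_factor = 1)
  expect_lt(diff(range(m1$area)), 1e-12 * max(m1$area))
  m2 <- build_mesh(p, 32, bl_factor = 1)
  expect_equal(m2$ncell / m1$ncell, 4, tolerance = 0.1)
  expect_error(build_mesh(default_parameters(H = 0.999), 4), "at least 8 cells")
})

test_that("boundary-layer grading thins the wall cells", {
  p <- default_parameters(H = 0, Lx = 1)
  mesh <- build_mesh(p, 16, bl_factor = 0.3)
  heights <- diff(mesh$node_y[1, ])
  expect_lte(heights[1] / max(heights), 0.3 + 1e-6)
  expect_equal(heights[1], heights[length(heights)], tolerance = 1e-9)
})

test_that("wall-normal gradients are exact for linear fields", {
  p <- default_parameters(H = 0, Lx = 1)
  mesh <- build_mesh(p, 16)
  g <- wall_normal_gradient(mesh$cy, mesh, "wall_lower")
  expect_equal(g$dfdn, rep(1, nrow(g)), tolerance = 1e-10)
  gc <- wall_normal_gradient(rep(3.5, mesh$ncell), mesh, "wall_upper")
  expect_equal(gc$dfdn, rep(0, nrow(gc)))
  ## x^2 varies only tangentially on a flat wall
  gx <- wall_normal_gradient(mesh$cx^2, mesh, "wall_lower")
  expect_equal(gx$dfdn, rep(0, nrow(gx)), tolerance = 1e-10)
  expect_error(wall_normal_gradient(mesh$cy, mesh, "lid"), "unknown patch")
})
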