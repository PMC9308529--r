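test_that("midpoint conductivity is the harmonic mean with insulating limit", {
  expect_equal(midpointConductivity(0.503, 0.503), 0.503)
  expect_equal(midpointConductivity(0.503, 0.6),
               2 * 0.503 * 0.6 / (0.503 + 0.6))
  expect_equal(midpointConductivity(0.503, 0), 0)
  expect_equal(midpointConductivity(0, 0), 0)
  expect_error(midpointConductivity(-0.1, 0.5), "non-negative")
  # vectorized over matrices
  m <- matrix(c(0.5, 0.6, 0, 0.503), 2)
  expect_equal(dim(midpointConductivity(m, m)), dim(m))
})

test_that("a uniform field at arterial temperature with no sources is a fixed point", {
  map <- uniformMap(8, "WM")
  props <- tissuePropertyTable()
  props$WM$qm <- 0
  blood <- bloodProperties()
  grids <- propertyGrids(map, props)
  cfg <- solverConfig(dx = 0.002, t_boundary = blood$t_a)
  t0 <- matrix(blood$t_a, 8, 8)
  expect_equal(fdmStep(t0, grids, blood, cfg), t0)
})

test_that("one sweep on a uniform field reproduces the scalar source update", {
  map <- uniformMap(10, "WM")
  props <- tissuePropertyTable()
  blood <- bloodProperties()
  grids <- propertyGrids(map, props)
  cfg <- solverConfig(dx = 0.002)
  t0 <- matrix(37, 10, 10)
  t1 <- fdmStep(t0, grids, blood, cfg)
  wm <- props$WM
  # diffusion term vanishes on a uniform field; only perfusion + source act
  expected <- 37 + cfg$dt / (wm$rho * wm$cp) *
    (wm$wb * blood$rho_b * blood$cp_b * (blood$t_a - 37) + wm$qm)
  interior <- t1[3:8, 3:8]   # away from the Dirichlet border
  expect_equal(interior, matrix(expected, 6, 6))
})

test_that("diffusion conserves discrete heat content away from boundaries", {
  # single hot pixel in a zero-perfusion, zero-source tissue (CSF-like)
  map <- uniformMap(7, "CSF")
  props <- tissuePropertyTable()
  blood <- bloodProperties()
  grids <- propertyGrids(map, props)
  cfg <- solverConfig(dx = 0.002, t_boundary = 37)
  t0 <- matrix(37, 7, 7); t0[4, 4] <- 38
  t1 <- fdmStep(t0, grids, blood, cfg)
  rhocp <- props$CSF$rho * props$CSF$cp
  # heat content of the 5-point neighbourhood is unchanged (no flux has
  # reached the border yet)
  nb <- rbind(c(4, 4), c(3, 4), c(5, 4), c(4, 3), c(4, 5))
  h0 <- sum(rhocp * t0[nb]); h1 <- sum(rhocp * t1[nb])
  expect_equal(h1, h0, tolerance = 1e-12)
})

test_that("fdmStep validates shapes and finiteness", {
  map <- uniformMap(6)
  grids <- propertyGrids(map)
  blood <- bloodProperties()
  cfg <- solverConfig(dx = 0.002)
  expect_error(fdmStep(matrix(37, 5, 5), grids, blood, cfg), "shape")
  bad <- matrix(37, 6, 6); bad[2, 2] <- NaN
  expect_error(fdmStep(bad, grids, blood, cfg), "non-finite")
})

test_that("compiled sweeps match the reference R step exactly", {
  set.seed(21)
  lab <- matrix(sample(0:5, 81, TRUE), 9, 9)
  map <- TissueLabelMap(lab)
  props <- tissuePropertyTable()
  blood <- bloodProperties()
  grids <- propertyGrids(map, props)
  fixed <- grids$background
  fixed[c(1, 9), ] <- TRUE; fixed[, c(1, 9)] <- TRUE
  t0 <- matrix(37, 9, 9); t0[5, 5] <- 37.5; t0[fixed] <- 37
  cfg <- solverConfig(dx = 0.002)
  rstep <- fdmStep(t0, grids, blood, cfg, fixed)
  cstep <- thermobrain:::solve_bioheat_cpp(
    t0, grids$k, grids$rho * grids$cp, grids$qm,
    grids$wb * blood$rho_b * blood$cp_b, fixed,
    cfg$dt, cfg$dx, cfg$t_boundary, blood$t_a, 1e300, 1L, 0L)
  expect_identical(cstep$temps, rstep)
})

test_that("iterative solve matches a dense steady-state solve on small grids", {
  set.seed(42)
  for (n in c(6, 8)) {
    lab <- matrix(sample(0:5, n * n, TRUE), n, n)
    map <- TissueLabelMap(lab)
    props <- tissuePropertyTable()
    blood <- bloodProperties()
    cfg <- solverConfig(tol = 1e-13, dx = 0.002)
    fld <- solveBioheat(map, props, blood, cfg)
    dense <- denseSteadyState(propertyGrids(map, props), blood, cfg)
    expect_lt(max(abs(tempMatrix(fld) - dense)), 1e-9)
  }
})

test_that("homogeneous steady state matches the closed-form temperature", {
  # large uniform WM block: at the center the diffusion term vanishes and
  # T = Ta + Qm / (wb * rho_b * cp_b)
  map <- uniformMap(61, "WM")
  props <- tissuePropertyTable()
  blood <- bloodProperties()
  fld <- solveBioheat(map, props, blood, solverConfig(tol = 1e-9))
  closed <- blood$t_a + props$WM$qm / (props$WM$wb * blood$rho_b * blood$cp_b)
  expect_lt(abs(tempMatrix(fld)[31, 31] - closed), 0.01)
  expect_true(converged(fld))
  expect_lt(finalDelta(fld), 1e-9)
})

test_that("no sources and uniform boundary give a uniform 37 degC field", {
  props <- tissuePropertyTable()
  for (nm in names(props)) { props[[nm]]$qm <- 0; props[[nm]]$wb <- 0 }
  map <- uniformMap(12, "WM")
  fld <- solveBioheat(map, props,
                      cfg = solverConfig(t_init = 38, tol = 1e-10))
  expect_equal(tempMatrix(fld), matrix(37, 12, 12), tolerance = 1e-5)
})

test_that("mirror-symmetric phantoms give mirror-symmetric fields", {
  map <- symmetricLesionMap()
  fld <- solveBioheat(map, cfg = solverConfig(tol = 1e-7))
  temps <- tempMatrix(fld)
  expect_lt(max(abs(temps - temps[, ncol(temps):1])), 1e-9)
})

test_that("an all-background map converges immediately to the boundary value", {
  lab <- matrix(0L, 8, 8)
  fld <- solveBioheat(TissueLabelMap(lab))
  expect_identical(iterations(fld), 1L)
  expect_true(converged(fld))
  expect_equal(tempMatrix(fld), matrix(37, 8, 8))
})

test_that("non-convergence returns a flagged field with a warning", {
  map <- uniformMap(16, "WM")
  expect_warning(
    fld <- solveBioheat(map, cfg = solverConfig(tol = 1e-12, max_iters = 5)),
    "did not converge")
  expect_false(converged(fld))
  expect_identical(iterations(fld), 5L)
  expect_gte(finalDelta(fld), 1e-12)
})

test_that("stability check computes the explicit-Euler time-step bound", {
  map <- uniformMap(10, "WM")
  props <- tissuePropertyTable()
  blood <- bloodProperties()
  grids <- propertyGrids(map, props)
  st <- stabilityCheck(grids, blood, solverConfig(dx = 0.002))
  # independent evaluation of the bound: the limiting pixels are the WM
  # pixels facing the (CSF-like) background, whose interface conductivity
  # is the harmonic mean of the two
  wm <- props$WM
  kFace <- 2 * wm$k * props$background$k / (wm$k + props$background$k)
  bound <- (wm$rho * wm$cp) /
    (4 * kFace / 0.002^2 + wm$wb * blood$rho_b * blood$cp_b)
  expect_equal(st$dt_max, bound)
  expect_true(st$pass)                       # dt = 0.1 s is comfortably stable
  expect_false(stabilityCheck(grids, blood,
                              solverConfig(dt = 100, dx = 0.002))$pass)
  # no dynamics at all: any dt passes
  for (nm in names(props)) { props[[nm]]$k <- 1e-300; props[[nm]]$wb <- 0 }
  props$background$k <- 1e-300
  g0 <- propertyGrids(map, props)
  g0$k[] <- 0
  st0 <- stabilityCheck(g0, blood, solverConfig(dt = 1e6, dx = 0.002))
  expect_true(st0$pass)
  # and solveBioheat refuses an unstable configuration
  expect_error(solveBioheat(map, cfg = solverConfig(dt = 100)), "unstable")
})

test_that("line profiles expose the lesion thermal signature", {
  map <- symmetricLesionMap()
  fld <- solveBioheat(map, cfg = solverConfig(tol = 1e-7))
  row <- 24                                  # passes through the lesion center
  prof <- lineProfile(fld, row)
  expect_identical(nrow(prof), ncol(tempMatrix(fld)))
  expect_equal(prof$position, (seq_len(nrow(prof)) - 1) * 2)
  # the profile has a local minimum inside the core relative to the
  # penumbra ring, and penumbra maxima above the flanking white matter
  lab <- labelMatrix(map)[row, ]
  core <- which(lab == 5); pen <- which(lab == 4); wm <- which(lab == 3)
  expect_lt(min(prof$temperature[core]), max(prof$temperature[pen]))
  expect_gt(max(prof$temperature[pen]), max(prof$temperature[wm]))
  expect_error(lineProfile(fld, 0), "out of range")
  expect_error(lineProfile(fld, 1000), "out of range")
  # uniform field gives a constant profile
  flat <- solveBioheat(TissueLabelMap(matrix(0L, 8, 8)))
  expect_equal(sd(lineProfile(flat, 4)$temperature), 0)
})
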