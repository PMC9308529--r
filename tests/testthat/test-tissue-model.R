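test_that("baseline property table carries the reference tissue constants", {
  tab <- baselineProperties()
  wm <- tab$WM
  expect_equal(wm$k, 0.503)
  expect_equal(wm$rho, 1027.4)
  expect_equal(wm$cp, 3600)
  expect_equal(wm$qm, 4517.9)
  expect_equal(wm$wb, 0.0036956)
  expect_equal(tab$CSF$qm, 0)     # CSF is a pure-diffusion tissue
  expect_equal(tab$CSF$wb, 0)
  expect_equal(tab$GM$qm, 16229)
  expect_equal(tab$GM$wb, 0.013289)
})

test_that("property table values are overridable via config", {
  tab <- baselineProperties(list(WM = list(qm = 4000), CSF = list(k = 0.55)))
  expect_equal(tab$WM$qm, 4000)
  expect_equal(tab$WM$k, 0.503)   # untouched fields keep defaults
  expect_equal(tab$CSF$k, 0.55)
  expect_error(baselineProperties(list(bone = list(k = 1))), "unknown tissue")
  expect_error(baselineProperties(list(WM = list(kk = 1))), "unknown property")
})

test_that("blood properties validate their physiological ranges", {
  b <- bloodProperties()
  expect_equal(b$t_a, 36.7)
  expect_error(bloodProperties(t_a = 45), "t_a")
  expect_error(bloodProperties(rho_b = -1), "rho_b")
})

test_that("lesion properties derive from white matter by factor scaling", {
  wm <- baselineProperties()$WM
  pen <- deriveLesionProperties(wm, 0.4, 0.7, "penumbra")
  expect_equal(pen$wb, 0.00147824)
  expect_equal(pen$qm, 3162.53)
  core <- deriveLesionProperties(wm, 0.2, 0, "core")
  expect_equal(core$wb, 0.00073912)
  expect_equal(core$qm, 0)
  # conductive properties are inherited unchanged
  for (f in c("k", "rho", "cp")) {
    expect_identical(pen[[f]], wm[[f]])
    expect_identical(core[[f]], wm[[f]])
  }
  # identity factors reproduce the baseline
  same <- deriveLesionProperties(wm, 1, 1)
  expect_equal(same[c("k", "rho", "cp", "qm", "wb")],
               wm[c("k", "rho", "cp", "qm", "wb")])
  expect_error(deriveLesionProperties(wm, 1.2, 0.5), "perfusionFactor")
  expect_error(deriveLesionProperties(wm, 0.5, -0.1), "metabolismFactor")
})

test_that("lesion derivation is linear in each reduction factor", {
  wm <- baselineProperties()$WM
  for (f in c(0.8, 0.4, 0.1)) {
    full <- deriveLesionProperties(wm, f, f)
    half <- deriveLesionProperties(wm, f / 2, f)
    expect_equal(half$wb, full$wb / 2)
    expect_equal(deriveLesionProperties(wm, f, f / 2)$qm, full$qm / 2)
  }
})

test_that("phantom generation is deterministic and anatomically complete", {
  ph1 <- generateBrainPhantom(96, 110, 2, seed = 1)
  ph2 <- generateBrainPhantom(96, 110, 2, seed = 1)
  expect_identical(labelMatrix(ph1), labelMatrix(ph2))
  lab <- labelMatrix(ph1)
  legend <- tissueLegend()
  for (tis in c("background", "CSF", "GM", "WM"))
    expect_gt(sum(lab == legend[[tis]]), 0)
  # full outer border is background
  expect_true(all(lab[1, ] == 0) && all(lab[96, ] == 0))
  expect_true(all(lab[, 1] == 0) && all(lab[, 110] == 0))
  expect_true(validObject(ph1))
  expect_error(generateBrainPhantom(10, 110), "too small")
})

test_that("phantom brain pixels match an independent ellipse rasterization", {
  ph <- generateBrainPhantom(16, 16, 2, seed = 7)
  g <- ph@geometry
  brain <- 0L
  for (i in 1:16) for (j in 1:16)
    if (((i - g$ci) / g$a)^2 + ((j - g$cj) / g$b)^2 <= 1) brain <- brain + 1L
  expect_identical(sum(labelMatrix(ph) != 0), brain)
})

test_that("lesion embedding matches a brute-force distance classification", {
  ph <- generateBrainPhantom(96, 110, 2, seed = 1)
  center <- c(round(ph@geometry$ci), round(ph@geometry$cj))
  les <- lesionSpec(center = center, core_diameter = 10,
                    penumbra_thickness = 5)
  out <- embedLesion(ph, les)
  lab0 <- labelMatrix(ph); lab <- labelMatrix(out)
  # exhaustive per-pixel distance check (mm between pixel centers)
  nCore <- 0L; nPen <- 0L
  for (i in 1:96) for (j in 1:110) {
    d <- 2 * sqrt((i - center[1])^2 + (j - center[2])^2)
    if (d <= 5) nCore <- nCore + 1L
    else if (d <= 10) nPen <- nPen + 1L
  }
  masks <- lesionMasks(out)
  expect_identical(as.integer(sum(masks$core)), nCore)
  expect_identical(as.integer(sum(masks$penumbra)), nPen)
  # total pixel count conserved; background and CSF never relabelled
  expect_identical(dim(lab), dim(lab0))
  expect_identical(lab[lab0 <= 1], lab0[lab0 <= 1])
})

test_that("lesion embedding is idempotent and concentric", {
  ph <- generateBrainPhantom(48, 48, 2, seed = 3)
  les <- lesionSpec()
  once <- embedLesion(ph, les)
  twice <- embedLesion(once, les)
  expect_identical(labelMatrix(once), labelMatrix(twice))
  # zero-thickness penumbra leaves no penumbra pixels
  bare <- embedLesion(ph, lesionSpec(penumbra_thickness = 0))
  expect_equal(sum(lesionMasks(bare)$penumbra), 0)
  # concentric: every core pixel is closer to the center than every
  # penumbra pixel's outer boundary
  m <- lesionMasks(once)
  center <- c(round(ph@geometry$ci), round(ph@geometry$cj))
  dist <- function(mask) {
    w <- which(mask == 1, arr.ind = TRUE)
    2 * sqrt((w[, 1] - center[1])^2 + (w[, 2] - center[2])^2)
  }
  expect_lt(max(dist(m$core)), min(dist(m$penumbra)))
  expect_lte(max(dist(m$penumbra)),
             les$core_diameter / 2 + les$penumbra_thickness)
})

test_that("lesion embedding rejects invalid placement", {
  ph <- generateBrainPhantom(48, 48, 2, seed = 3)
  # center on background
  expect_error(embedLesion(ph, lesionSpec(center = c(1, 1))), "white-matter")
  # disk spilling over CSF/background
  expect_error(embedLesion(ph, lesionSpec(core_diameter = 200)),
               "exceeds the brain extent")
})

test_that("property grids expand labels and round-trip the legend", {
  ph <- embedLesion(generateBrainPhantom(32, 32, 2, seed = 2))
  props <- tissuePropertyTable()
  grids <- propertyGrids(ph, props)
  lab <- labelMatrix(ph)
  legend <- labelLegend(ph)
  expect_identical(dim(grids$wb), dim(lab))
  # grid value at every pixel equals the property of its label
  for (tis in names(legend)) {
    px <- lab == legend[[tis]]
    if (!any(px)) next
    for (f in c("k", "rho", "cp", "qm", "wb"))
      expect_true(all(grids[[f]][px] == props[[tis]][[f]]))
  }
  # a single penumbra pixel lights up exactly once in the wb grid
  lab1 <- labelMatrix(uniformMap(8))
  lab1[4, 4] <- tissueLegend()[["penumbra"]]
  g1 <- propertyGrids(TissueLabelMap(lab1), props)
  expect_identical(sum(g1$wb == props$penumbra$wb), 1L)
  expect_equal(props$penumbra$wb, 0.00147824, tolerance = 1e-12)
  # uniform map gives constant grids
  gu <- propertyGrids(uniformMap(6, "WM"), props)
  inner <- gu$qm[2:5, 2:5]
  expect_true(all(inner == props$WM$qm))
  # unknown label is named in the error
  expect_error(propertyGrids(ph, props[c("WM", "CSF")]), "GM")
})
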