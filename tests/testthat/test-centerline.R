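objectAndSeed <- function(volume) {
  m <- BinaryMask3D(voxelData(volume) > 0, volume)
  objs <- connectedComponents(m)
  secs <- middleSliceSections(objs, volume)
  list(object = objs[[1]], seed = secs[[1]])
}

test_that("straight vertical tube: centerline stays on the true axis", {
  tube <- straightTubeVolume(radius = 2)
  os <- objectAndSeed(tube)
  cl <- extractCenterline(os$object, os$seed, tube)
  axis <- (dim(tube)[1:2] - 1) * spacing(tube)[1:2] / 2
  dev <- sqrt((coords(cl)[, 1] - axis[1])^2 + (coords(cl)[, 2] - axis[2])^2)
  expect_lt(max(dev), 0.5 * max(spacing(tube)))
})

test_that("phantom VA centerline is close to ground truth (Hausdorff)", {
  ph <- fxPhantom(1)
  r <- fxLabeling(1)
  for (lab in c("LVA", "RVA")) {
    l <- r$labeling$labels[[lab]]
    cl <- extractCenterline(l$object, l$section, ph$volume, label = lab)
    p <- coords(cl); q <- coords(ph$truth$centerlines[[lab]])
    h1 <- max(vapply(seq_len(nrow(p)), function(i)
      sqrt(min(colSums((t(q) - p[i, ])^2))), 0))
    expect_lt(h1, 1.5 * max(spacing(ph$volume)))
  }
})

test_that("carotid centerline follows the ICA limb, not the ECA branch", {
  ph <- fxPhantom(1)
  r <- fxLabeling(1)
  for (lab in c("LICA", "RICA")) {
    l <- r$labeling$labels[[lab]]
    cl <- extractCenterline(l$object, l$section, ph$volume, label = lab)
    p <- coords(cl)
    above <- p[p[, 3] > ph$truth$spec$ecaBifurcation + 5, , drop = FALSE]
    qIca <- coords(ph$truth$centerlines[[lab]])
    qEca <- coords(ph$truth$centerlines[[sub("ICA", "ECA", lab)]])
    dIca <- vapply(seq_len(nrow(above)), function(i)
      sqrt(min(colSums((t(qIca) - above[i, ])^2))), 0)
    dEca <- vapply(seq_len(nrow(above)), function(i)
      sqrt(min(colSums((t(qEca) - above[i, ])^2))), 0)
    expect_lt(max(dIca), 1.5 * max(spacing(ph$volume)))
    # above the bifurcation the polyline must hug the ICA, not the ECA
    expect_gt(mean(dEca > dIca), 0.9)
  }
})

test_that("too-short objects are rejected", {
  arr <- array(0, dim = c(12, 12, 12))
  arr[5:6, 5:6, 5:6] <- 1
  v <- Volume3D(arr + 1e-3)
  objs <- connectedComponents(BinaryMask3D(arr > 0, v))
  fakeSeed <- list(objectLabel = 1, centroid = c(4, 4), size = 4,
                   voxels = cbind(5:6, 5:6))
  expect_error(extractCenterline(objs[[1]], fakeSeed, v), "too short")
})

test_that("derivative profile of straight lines is the line slope", {
  z <- seq(0, 45, by = 0.5)
  vert <- .makeTestCenterline(cbind(10, 20, z))
  pv <- profileValues(derivativeProfile(vert, dz = 1.5))
  expect_equal(pv, rep(0, length(pv)))

  obl <- .makeTestCenterline(cbind(10, 20 + 0.5 * z, z))
  po <- profileValues(derivativeProfile(obl, axis = "AP", dz = 1.5))
  expect_equal(po, rep(0.5, length(po)), tolerance = 1e-9)
  # LR axis sees no slope for this line
  pl <- profileValues(derivativeProfile(obl, axis = "LR", dz = 1.5))
  expect_equal(pl, rep(0, length(pl)))
})

test_that("phantom VA profile shows slope bands at the bend heights", {
  ph <- fxPhantom(1)
  r <- fxLabeling(1)
  l <- r$labeling$labels$LVA
  cl <- extractCenterline(l$object, l$section, ph$volume, label = "LVA")
  pr <- derivativeProfile(cl, dz = spacing(ph$volume)[3])
  bf <- bruteForceTurns(profileValues(pr))
  kTrue <- round((ph$truth$spec$vaTurnHeights - pr@z0) / pr@dz) + 1
  expect_lte(max(abs(bf$k - kTrue)), 2)
})

test_that("profiles are invariant to rigid volume translation", {
  ph <- fxPhantom(2)
  r <- fxLabeling(2)
  l <- r$labeling$labels$RVA
  cl <- extractCenterline(l$object, l$section, ph$volume, label = "RVA")
  shifted <- Volume3D(voxelData(ph$volume), spacing = spacing(ph$volume),
                      origin = c(5, -3, 10))
  body <- otsuBodyMask(shifted)
  rs <- adaptiveArteryThreshold(shifted, body)
  ls <- rs$labeling$labels$RVA
  cls <- extractCenterline(ls$object, ls$section, shifted, label = "RVA")
  expect_equal(coords(cls), sweep(coords(cl), 2, c(5, -3, 10), "+"),
               tolerance = 1e-9)
  p1 <- derivativeProfile(cl, dz = 1.5)
  p2 <- derivativeProfile(cls, dz = 1.5)
  expect_equal(profileValues(p1), profileValues(p2), tolerance = 1e-9)
})

test_that("x-mirrored VA gives the identical A-P profile", {
  z <- seq(0, 45, by = 0.5)
  y <- 20 + pmin(pmax(z - 15, 0), 10) * 0.6
  a <- .makeTestCenterline(cbind(10 + 0.1 * z, y, z))
  b <- .makeTestCenterline(cbind(50 - 0.1 * z, y, z))   # x-flipped
  expect_equal(profileValues(derivativeProfile(a, axis = "AP", dz = 1.5)),
               profileValues(derivativeProfile(b, axis = "AP", dz = 1.5)))
})

test_that("halving the sampling step and decimating reproduces the profile", {
  z <- seq(0, 45, by = 0.25)
  obl <- .makeTestCenterline(cbind(10 + 0.2 * z, 20 + 0.5 * z, z))
  p1 <- profileValues(derivativeProfile(obl, dz = 1.5))
  p2 <- profileValues(derivativeProfile(obl, dz = 0.75))
  expect_equal(p1[2:(length(p1) - 1)],
               p2[seq(3, 2 * length(p1) - 3, by = 2)], tolerance = 1e-6)
})

test_that("short z spans are rejected", {
  z <- seq(0, 10, by = 0.5)
  cl <- .makeTestCenterline(cbind(10, 20, z))
  expect_error(derivativeProfile(cl, dz = 1.5), "z-span")
})
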