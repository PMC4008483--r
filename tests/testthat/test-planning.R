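mkProfile <- function(values, dz = 1.5, z0 = 0, turns = c(NA, NA)) {
  new("DerivativeProfile", values = as.numeric(values), dz = dz, z0 = z0,
      axis = "AP", turns = as.integer(turns))
}

test_that("averaging identical profiles reproduces them, turns preserved", {
  base <- mkProfile(sin(seq(0, 3, length.out = 40)), turns = c(12, 25))
  tpl <- buildTemplate(rep(list(base), 10), side = "left")
  expect_equal(profileValues(tpl), profileValues(base))
  expect_identical(turningIndices(tpl), c(12L, 25L))
})

test_that("profiles offset by a shift align on their turning midpoints", {
  v <- c(rep(0, 10), seq(0, 1, length.out = 6), rep(1, 14))
  a <- mkProfile(c(v, rep(1, 4)), turns = c(10, 16))
  b <- mkProfile(c(rep(0, 4), v), turns = c(14, 20))    # same shape, +4
  tpl <- buildTemplate(list(a, b), side = "left")
  ia <- turningIndices(a); mid <- floor(mean(ia))
  # template turns sit at the common aligned positions
  expect_identical(diff(turningIndices(tpl)), diff(ia))
})

test_that("template building rejects mismatched inputs", {
  a <- mkProfile(rnorm(30), turns = c(10, 20))
  b <- mkProfile(rnorm(30), dz = 2.0, turns = c(10, 20))
  expect_error(buildTemplate(list(a, b), side = "left"), "mismatched dz")
  expect_error(buildTemplate(list(a), side = "left"), ">= 2 profiles")
  noTurns <- mkProfile(rnorm(30))
  expect_error(buildTemplate(list(a, noTurns), side = "left"), "annotated")
})

test_that("cross-correlation recovers offsets and is affine invariant", {
  g <- sin(seq(0, 4 * pi, length.out = 30)) * exp(-seq(0, 2, length.out = 30))
  tpl <- new("Template", values = g, dz = 1.5, turnLower = 8L,
             turnUpper = 20L, padding = 10L, side = "left", axis = "AP")
  # exact copy: m = 0, R = 1
  cc0 <- crossCorrelate(mkProfile(g), tpl)
  expect_identical(cc0$m, 0L)
  expect_equal(cc0$score, 1)
  # shifted copy with zero padding: m = +7
  cc7 <- crossCorrelate(mkProfile(c(rep(0, 7), g, rep(0, 5))), tpl)
  expect_identical(cc7$m, 7L)
  # affine transform of the profile: same argmax
  ccA <- crossCorrelate(mkProfile(0.5 * c(rep(0, 7), g, rep(0, 5)) + 3), tpl)
  expect_identical(ccA$m, 7L)
})

test_that("degenerate all-constant overlap raises", {
  tpl <- new("Template", values = rep(1, 12), dz = 1.5, turnLower = 3L,
             turnUpper = 8L, padding = 2L, side = "left", axis = "AP")
  expect_error(crossCorrelate(mkProfile(rep(2, 20)), tpl), "degenerate")
})

test_that("rough region arithmetic, clipping and failure status", {
  g <- rnorm(40)
  tpl <- new("Template", values = g, dz = 1.5, turnLower = 21L,
             turnUpper = 36L, padding = 10L, side = "left", axis = "AP")
  pr <- mkProfile(rnorm(60))
  r <- roughRegion(pr, tpl, m = 0)
  expect_identical(c(r$lo, r$hi), c(11L, 46L))
  # m pushing the region below the start clips at 1
  r2 <- roughRegion(pr, tpl, m = -25)
  expect_identical(r2$lo, 1L)
  expect_identical(r2$status, "ok")
  # clipped so short it fails
  prShort <- mkProfile(rnorm(10))
  r3 <- roughRegion(prShort, tpl, m = -44)
  expect_identical(r3$status, "failed")
  expect_match(r3$reason, "outside profile")
})

test_that("turning points of a piecewise-constant segment are exact", {
  tp <- detectTurningPoints(c(0, 0, 0, 5, 5, 5, 0, 0, 0))
  expect_identical(c(tp@k1, tp@k2), c(3L, 6L))
  expect_equal(tp@vTotal, 0)
})

test_that("a constant segment resolves ties lexicographically", {
  tp <- detectTurningPoints(rep(2.5, 12), Lmin = 2)
  expect_identical(c(tp@k1, tp@k2), c(2L, 4L))
  expect_equal(tp@vTotal, 0)
})

test_that("the offset argument maps indices to full-profile coordinates", {
  tp <- detectTurningPoints(c(0, 0, 0, 5, 5, 5, 0, 0, 0), offset = 10L)
  expect_identical(c(tp@k1, tp@k2), c(13L, 16L))
})

test_that("DP solution equals exhaustive search on random segments", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(12:80, 1)
    x <- rnorm(n) + c(rep(0, n %/% 3), rep(3, n %/% 3),
                      rep(0, n - 2 * (n %/% 3))) * sample(0:1, 1)
    tp <- detectTurningPoints(x)
    bf <- bruteForceTurns(x)
    expect_identical(c(tp@k1, tp@k2), as.integer(bf$k))
    expect_equal(tp@vTotal, bf$v, tolerance = 1e-9)
  }
})

test_that("segment too short for three subregions errors", {
  expect_error(detectTurningPoints(rnorm(5), Lmin = 2), "too short")
})

test_that("VA plane of a vertical tube is axial through the midpoint", {
  z <- seq(0, 45, by = 1.5)
  cl <- .makeTestCenterline(cbind(10, 20, z))
  pr <- mkProfile(rep(0, length(z)))
  tp <- new("TurningPointPair", k1 = 3L, k2 = 9L, vTotal = 0)
  vol <- straightTubeVolume()
  pl <- planVaPlane(cl, pr, tp, volume = vol)
  expect_equal(pl@center, c(10, 20, (6 - 1) * 1.5))   # index floor((3+9)/2)=6
  expect_equal(pl@normal, c(0, 0, 1))
  expect_equal(pl@angulation, c(0, 0, 0))
})

test_that("oblique tube gives the analytic tangent and angulation", {
  z <- seq(0, 45, by = 1.5)
  cl <- .makeTestCenterline(cbind(10, 20 + 0.5 * z, z))
  pr <- mkProfile(rep(0.5, length(z)))
  tp <- new("TurningPointPair", k1 = 8L, k2 = 16L, vTotal = 0)
  pl <- planVaPlane(cl, pr, tp, volume = straightTubeVolume())
  want <- c(0, 0.5, 1) / sqrt(1.25)
  expect_equal(pl@normal, want, tolerance = 1e-9)
  expect_equal(pl@angulation[1], atan(0.5) * 180 / pi, tolerance = 1e-6)
  expect_equal(pl@angulation[2], 0, tolerance = 1e-9)
  # the documented rotation applied to (0,0,1) reproduces the normal
  a <- pl@angulation[1] * pi / 180; b <- pl@angulation[2] * pi / 180
  expect_equal(c(cos(a) * sin(b), sin(a), cos(a) * cos(b)), pl@normal,
               tolerance = 1e-9)
})

test_that("plane normal is invariant to reversing the centerline order", {
  ph <- fxPhantom(1)
  r <- fxLabeling(1)
  l <- r$labeling$labels$LVA
  cl <- extractCenterline(l$object, l$section, ph$volume, label = "LVA")
  pr <- derivativeProfile(cl, dz = 1.5)
  tp <- new("TurningPointPair", k1 = 18L, k2 = 28L, vTotal = 0)
  pl <- planVaPlane(cl, pr, tp, volume = ph$volume)
  rev <- coords(cl)[nrow(coords(cl)):1, ]
  # reversed order breaks the class invariant, so probe the tangent helper
  pc1 <- prcomp(coords(cl)[15:25, ])$rotation[, 1]
  pc2 <- prcomp(rev[(nrow(rev) - 24):(nrow(rev) - 14), ])$rotation[, 1]
  expect_lt(dirAngle(pc1, pc2), 1e-6)
})

test_that("ICA plane sits at the VA upper-turn level on the ICA axis", {
  z <- seq(0, 45, by = 1.5)
  cl <- .makeTestCenterline(cbind(12, 18, z))
  pl <- planIcaPlane(cl, upperTurn = c(30, 40, 21.7),
                     volume = straightTubeVolume())
  expect_equal(pl@center, c(12, 18, 21.7))
  expect_equal(pl@normal, c(0, 0, 1))
  # out-of-span level clamps to the nearest endpoint with a message
  expect_message(pl2 <- planIcaPlane(cl, upperTurn = c(0, 0, 99),
                                     volume = straightTubeVolume()),
                 "nearest endpoint")
  expect_equal(pl2@center[3], 45)
})

test_that("planAll: full phantom gives four planes; drop rules respected", {
  ph <- fxPhantom(1)
  res <- planAll(ph$volume, fxTemplates())
  expect_identical(res$overall, "ok")
  expect_identical(sum(vapply(res$arteries, function(a) !is.null(a$plane),
                              TRUE)), 4L)
  expect_identical(res$provenance$j, 5L)

  oneVA <- generatePhantom(phantomSpec(dropArteries = "RVA"), seed = 21)
  r1 <- planAll(oneVA$volume, fxTemplates())
  expect_identical(r1$overall, "ok")
  expect_identical(sum(vapply(r1$arteries, function(a) !is.null(a$plane),
                              TRUE)), 3L)
  # RICA fell back to the left VA's upper turn for its level
  expect_identical(r1$arteries$RICA$status, "ok")

  noVA <- generatePhantom(phantomSpec(dropArteries = c("LVA", "RVA")),
                          seed = 21)
  r0 <- planAll(noVA$volume, fxTemplates())
  expect_identical(r0$overall, "aborted")
})

test_that("planConfig rejects unknown keys", {
  expect_error(planConfig(jHgh = 4), "unknown config keys")
  cfg <- planConfig(jHigh = 4L)
  expect_identical(cfg$jHigh, 4L)
  expect_identical(cfg$Lmin, 2L)
})

test_that("templates survive a JSON round-trip", {
  tpl <- fxTemplates()$left
  path <- file.path(withr::local_tempdir(), "tpl.json")
  writeTemplate(tpl, path)
  back <- readTemplate(path)
  expect_equal(profileValues(back), profileValues(tpl))
  expect_identical(turningIndices(back), turningIndices(tpl))
  expect_identical(back@side, tpl@side)
})
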