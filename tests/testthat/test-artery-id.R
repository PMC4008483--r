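maskFromArray <- function(arr) {
  v <- Volume3D(array(0, dim(arr)) + 1e-3 + arr)   # parent volume (values unused)
  BinaryMask3D(arr > 0, v)
}

test_that("disjoint cubes are separate objects; corner contact joins them", {
  arr <- array(0, dim = c(12, 12, 12))
  arr[2:4, 2:4, 2:4] <- 1
  arr[8:10, 8:10, 8:10] <- 1
  objs <- connectedComponents(maskFromArray(arr))
  expect_length(objs, 2)
  expect_equal(vapply(objs, `[[`, 0, "count"), c(27, 27))

  # touching only at one corner: one object under 26-connectivity
  arr2 <- array(0, dim = c(12, 12, 12))
  arr2[2:4, 2:4, 2:4] <- 1
  arr2[5:7, 5:7, 5:7] <- 1
  objs2 <- connectedComponents(maskFromArray(arr2))
  expect_length(objs2, 1)
  expect_equal(objs2[[1]]$count, 54)
})

test_that("empty mask yields an empty object list", {
  expect_length(connectedComponents(maskFromArray(array(0, c(8, 8, 8)))), 0)
})

test_that("selectCandidates keeps the k largest with deterministic ties", {
  mk <- function(count, zmin, label) list(label = label,
                                          voxels = matrix(1, count, 3),
                                          count = count,
                                          zRange = c(zmin, zmin + 1))
  objs <- c(lapply(1:10, function(i) mk(100 - i, 1, i)))
  sel <- selectCandidates(objs, k = 8)
  expect_length(sel, 8)
  expect_equal(vapply(sel, `[[`, 0, "count"), 99:92)
  # fewer than k: all returned
  expect_length(selectCandidates(objs[1:3], k = 8), 3)
  # tie at rank k: smaller minimal z wins, then smaller label
  tied <- list(mk(50, 5, 1), mk(50, 2, 2), mk(50, 2, 3))
  sel2 <- selectCandidates(tied, k = 2)
  expect_equal(vapply(sel2, `[[`, 0, "label"), c(2, 3))
})

test_that("middle-slice sections: counts, centroids, branch splitting", {
  ph <- fxPhantom(1)
  r <- fxLabeling(1)
  objs <- selectCandidates(connectedComponents(r$mask))
  secs <- middleSliceSections(objs, ph$volume)
  byObj <- table(vapply(secs, `[[`, 0, "objectLabel"))
  # the two carotid objects carry an ECA branch: 2 sections each;
  # the two VAs: 1 section each
  expect_equal(sort(unname(as.vector(byObj)), decreasing = TRUE)[1:4],
               c(2, 2, 1, 1))
  # a vertical tube object yields exactly one centered section
  tube <- straightTubeVolume(radius = 2)
  m <- BinaryMask3D(voxelData(tube) > 0, tube)
  s <- middleSliceSections(connectedComponents(m), tube)
  expect_length(s, 1)
  ctr <- (dim(tube)[1:2] - 1) * spacing(tube)[1:2] / 2
  expect_equal(s[[1]]$centroid, ctr, tolerance = 1e-6,
               ignore_attr = TRUE)
  # an object entirely below the middle slice contributes no section
  arr <- array(0, dim = c(16, 16, 16))
  arr[4:6, 4:6, 2:4] <- 1
  s2 <- middleSliceSections(connectedComponents(maskFromArray(arr)),
                            Volume3D(arr + 1e-3))
  expect_length(s2, 0)
})

test_that("all four arteries are labeled correctly on the default phantom", {
  ph <- fxPhantom(1)
  r <- fxLabeling(1)
  expect_identical(r$labeling$overall, "ok")
  truthVox <- ph$truth$arteryVoxels
  d <- dim(ph$volume)
  for (lab in c("LICA", "RICA", "LVA", "RVA")) {
    obj <- r$labeling$labels[[lab]]$object
    lin <- obj$voxels[, 1] + d[1] * (obj$voxels[, 2] - 1) +
      d[1] * d[2] * (obj$voxels[, 3] - 1)
    overlap <- mean(lin %in% truthVox[[lab]])
    expect_gt(overlap, 0.95)
  }
})

test_that("mirror reflection in x swaps left/right labels exactly", {
  ph <- fxPhantom(1)
  r <- fxLabeling(1)
  flipped <- Volume3D(voxelData(ph$volume)[dim(ph$volume)[1]:1, , ],
                      spacing = spacing(ph$volume))
  body <- otsuBodyMask(flipped)
  rf <- adaptiveArteryThreshold(flipped, body)
  expect_identical(rf$labeling$overall, "ok")
  d1 <- dim(ph$volume)[1]
  for (pair in list(c("LICA", "RICA"), c("LVA", "RVA"))) {
    a <- r$labeling$labels[[pair[1]]]$object$voxels
    b <- rf$labeling$labels[[pair[2]]]$object$voxels
    a[, 1] <- d1 + 1 - a[, 1]            # reflect
    expect_setequal(paste(a[, 1], a[, 2], a[, 3]),
                    paste(b[, 1], b[, 2], b[, 3]))
  }
})

test_that("no object receives two labels", {
  r <- fxLabeling(1)
  labs <- Filter(Negate(is.null), r$labeling$labels)
  ids <- vapply(labs, function(l) l$object$label, 0)
  expect_identical(anyDuplicated(ids), 0L)
})

test_that("missing VAs trigger the abort rule; one missing VA does not", {
  phBoth <- generatePhantom(phantomSpec(dropArteries = c("LVA", "RVA")),
                            seed = 9)
  body <- otsuBodyMask(phBoth$volume)
  r <- adaptiveArteryThreshold(phBoth$volume, body)
  expect_identical(r$labeling$overall, "aborted")

  phOne <- generatePhantom(phantomSpec(dropArteries = "LVA"), seed = 9)
  body1 <- otsuBodyMask(phOne$volume)
  r1 <- adaptiveArteryThreshold(phOne$volume, body1)
  expect_identical(r1$labeling$overall, "ok")
  expect_identical(unname(r1$labeling$status["LVA"]), "not_found")
  expect_identical(sum(r1$labeling$status == "found"), 3L)
})
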