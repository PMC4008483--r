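# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fxPhantom <- function(seed = 1L, spec = phantomSpec()) {
  key <- paste0("ph_", seed, "_", rlang::hash(unclass(spec)))
  if (is.null(.fx[[key]])) .fx[[key]] <- generatePhantom(spec, seed = seed)
  .fx[[key]]
}

fxTemplates <- function() {
  if (is.null(.fx$templates)) .fx$templates <- defaultTemplates()
  .fx$templates
}

fxLabeling <- function(seed = 1L) {
  key <- paste0("lab_", seed)
  if (is.null(.fx[[key]])) {
    ph <- fxPhantom(seed)
    body <- otsuBodyMask(ph$volume)
    .fx[[key]] <- adaptiveArteryThreshold(ph$volume, body)
  }
  .fx[[key]]
}

# independent brute-force minimizer of the three-segment variance
# objective (plain sums and means; no prefix sums, no DP structure)
bruteForceTurns <- function(x, Lmin = 2L) {
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  best <- c(NA, NA); bestV <- Inf
  for (k1 in Lmin:(n - 2 * Lmin)) {
    for (k2 in (k1 + Lmin):(n - Lmin)) {
      v <- ssd(x[1:k1]) + ssd(x[(k1 + 1):k2]) + ssd(x[(k2 + 1):n])
      if (v < bestV) { bestV <- v; best <- c(k1, k2) }
    }
  }
  list(k = best, v = bestV)
}

.makeTestCenterline <- function(pts, label = "test") {
  al <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  new("Centerline", label = label, points = pts, arcLength = al)
}

# angle in degrees between two directions (sign-agnostic)
dirAngle <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  acos(pmin(1, abs(sum(u * v)))) * 180 / pi
}

# straight-tube volume along a given direction, for analytic checks
straightTubeVolume <- function(dirXY = c(0, 0), radius = 2,
                               dim = c(32L, 32L, 31L),
                               spacing = c(0.8, 0.8, 1.5),
                               background = 0, value = 100) {
  arr <- array(background, dim)
  cx <- (dim[1] - 1) * spacing[1] / 2
  cy <- (dim[2] - 1) * spacing[2] / 2
  xs <- (seq_len(dim[1]) - 1) * spacing[1]
  ys <- (seq_len(dim[2]) - 1) * spacing[2]
  for (k in seq_len(dim[3])) {
    z <- (k - 1) * spacing[3]
    x0 <- cx + dirXY[1] * z
    y0 <- cy + dirXY[2] * z
    d2 <- outer((xs - x0)^2, (ys - y0)^2, "+")
    arr[, , k] <- ifelse(d2 < radius^2, value, background)
  }
  Volume3D(arr, spacing = spacing)
}
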