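#' Run configuration for the positioning pipeline
#'
#' All tunables with their defaults: the adaptive-threshold search
#' bounds (`jHigh` 5 down to `jLow` 3), the z-coverage acceptance
#' fraction (0.6), the number of candidate objects (8), the transverse
#' axis of the derivative profiles ("AP"), the minimum subregion length
#' `Lmin` (2) and the tangent window (5 points). Unknown keys are
#' rejected.
#'
#' @param ... overrides of the defaults.
#' @return a validated `PlanConfig` list.
#' @export
planConfig <- function(...) {
  cfg <- list(jHigh = 5L, jLow = 3L, lengthFraction = 0.6,
              candidates = 8L, axis = "AP", dz = NULL, Lmin = 2L,
              window = 5L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "PlanConfig"
  cfg
}

#' Plan all four PC-MRI scan planes from an angiogram
#'
#' Runs the full pipeline: Otsu body mask, adaptive artery threshold,
#' identification of the four arteries on the middle slice, centerline
#' extraction, template-guided VA turning-point detection, and plane
#' construction (VA planes between the two turns, ICA planes at the
#' upper-turn level). Failures never raise: each artery carries a
#' status and the overall run is `ok` only when at least three planes,
#' among them at least one VA plane, were produced. When the same-side
#' VA is unavailable an ICA plane falls back to the other VA's
#' upper-turn level (one VA suffices to fix the foramen-magnum level).
#'
#' @param volume a [Volume3D] (TOF angiogram).
#' @param templates list with `left` and `right` [Template].
#' @param config a [planConfig()].
#' @return a `PositioningResult` list: `arteries` (per label: `status`,
#'   `plane` ([ScanPlane] or NULL), `reason`, and for VAs `turns`),
#'   `provenance` (chosen j, threshold, config hash, package version)
#'   and `overall` ("ok"/"aborted").
#' @examples
#' \donttest{
#' ph <- generatePhantom(phantomSpec(), seed = 1)
#' tpl <- defaultTemplates()
#' res <- planAll(ph$volume, tpl)
#' res$overall
#' }
#' @export
planAll <- function(volume, templates, config = planConfig()) {
  stopifnot(is(volume, "Volume3D"))
  if (!all(c("left", "right") %in% names(templates))) {
    stop("templates must be a list with elements 'left' and 'right'")
  }
  dz <- if (is.null(config$dz)) spacing(volume)[3] else config$dz
  arteries <- stats::setNames(
    rep(list(list(status = "not_found", plane = NULL, reason = NA_character_)),
        4), c("LICA", "RICA", "LVA", "RVA"))
  fail <- function(res, reason) {
    res$status <- "failed"; res$reason <- reason; res
  }

  body <- otsuBodyMask(volume)
  thr <- adaptiveArteryThreshold(volume, body, jHigh = config$jHigh,
                                 jLow = config$jLow,
                                 lengthFraction = config$lengthFraction,
                                 candidates = config$candidates)
  labeling <- thr$labeling
  provenance <- list(j = thr$j, threshold = thr$threshold,
                     thresholdStatus = thr$status,
                     configHash = rlang::hash(unclass(planConfig())),
                     version = as.character(utils::packageVersion("pcmriplan")))

  finish <- function() {
    nPlanes <- sum(vapply(arteries, function(a) !is.null(a$plane), TRUE))
    nVA <- sum(vapply(arteries[c("LVA", "RVA")],
                      function(a) !is.null(a$plane), TRUE))
    out <- list(arteries = arteries, provenance = provenance,
                overall = if (nPlanes >= 3L && nVA >= 1L) "ok" else "aborted")
    class(out) <- "PositioningResult"
    out
  }
  if (labeling$overall == "aborted") {
    for (lab in names(arteries)) {
      arteries[[lab]]$reason <- "fewer than three arteries / no VA identified"
    }
    return(finish())
  }

  ## centerlines
  centerlines <- list()
  for (lab in names(arteries)) {
    l <- labeling$labels[[lab]]
    if (is.null(l)) {
      arteries[[lab]]$reason <- "artery not identified"
      next
    }
    cl <- tryCatch(extractCenterline(l$object, l$section, volume, label = lab),
                   error = function(e) e)
    if (inherits(cl, "error")) {
      arteries[[lab]] <- fail(arteries[[lab]], conditionMessage(cl))
    } else {
      centerlines[[lab]] <- cl
    }
  }

  ## VA turning points and planes
  upperTurns <- list()
  for (lab in c("LVA", "RVA")) {
    if (is.null(centerlines[[lab]])) next
    side <- if (lab == "LVA") "left" else "right"
    res <- tryCatch({
      pr <- derivativeProfile(centerlines[[lab]], axis = config$axis, dz = dz)
      cc <- crossCorrelate(pr, templates[[side]])
      reg <- roughRegion(pr, templates[[side]], cc$m, Lmin = config$Lmin)
      if (reg$status != "ok") stop(reg$reason)
      tp <- detectTurningPoints(pr@values[reg$lo:reg$hi],
                                Lmin = config$Lmin, offset = reg$lo - 1L)
      tp@points <- rbind(
        .centerlineAt(centerlines[[lab]], pr@z0 + (tp@k1 - 1) * pr@dz),
        .centerlineAt(centerlines[[lab]], pr@z0 + (tp@k2 - 1) * pr@dz))
      list(plane = planVaPlane(centerlines[[lab]], pr, tp,
                               window = config$window, volume = volume),
           turns = tp, m = cc$m)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      arteries[[lab]] <- fail(arteries[[lab]], conditionMessage(res))
    } else {
      arteries[[lab]]$status <- "ok"
      arteries[[lab]]$plane <- res$plane
      arteries[[lab]]$turns <- res$turns
      arteries[[lab]]$offset <- res$m
      upperTurns[[lab]] <- res$turns@points[2, ]
    }
  }

  ## ICA planes at the upper-turn level (same side, else the other)
  for (lab in c("LICA", "RICA")) {
    if (is.null(centerlines[[lab]])) next
    same <- paste0(substr(lab, 1, 1), "VA")
    turn <- upperTurns[[same]]
    if (is.null(turn)) turn <- upperTurns[[setdiff(c("LVA", "RVA"), same)]]
    if (is.null(turn)) {
      arteries[[lab]] <- fail(arteries[[lab]],
                              "no VA turning point available for the z level")
      next
    }
    res <- tryCatch(planIcaPlane(centerlines[[lab]], turn,
                                 window = config$window, volume = volume),
                    error = function(e) e)
    if (inherits(res, "error")) {
      arteries[[lab]] <- fail(arteries[[lab]], conditionMessage(res))
    } else {
      arteries[[lab]]$status <- "ok"
      arteries[[lab]]$plane <- res
    }
  }
  finish()
}

#' @export
print.PositioningResult <- function(x, ...) {
  cat("PositioningResult (", x$overall, "), j = ", x$provenance$j, "\n", sep = "")
  for (lab in names(x$arteries)) {
    a <- x$arteries[[lab]]
    if (!is.null(a$plane)) {
      cat(sprintf("  %s: off-center (%.1f, %.1f, %.1f) mm, angulation (%.1f, %.1f, 0) deg\n",
                  lab, a$plane@offcenter[1], a$plane@offcenter[2],
                  a$plane@offcenter[3], a$plane@angulation[1],
                  a$plane@angulation[2]))
    } else {
      cat(sprintf("  %s: %s (%s)\n", lab, a$status, a$reason))
    }
  }
  invisible(x)
}

#' Serialize templates and positioning results as JSON
#'
#' @param template a [Template].
#' @param path output/input JSON path.
#' @return `writeTemplate` the path invisibly; `readTemplate` a
#'   [Template].
#' @export
writeTemplate <- function(template, path) {
  stopifnot(is(template, "Template"))
  jsonlite::write_json(list(values = template@values, dz = template@dz,
                            turnLower = template@turnLower,
                            turnUpper = template@turnUpper,
                            padding = template@padding,
                            side = template@side, axis = template@axis),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTemplate
#' @export
readTemplate <- function(path) {
  if (!file.exists(path)) stop("template file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("Template", values = as.numeric(x$values), dz = as.numeric(x$dz),
      turnLower = as.integer(x$turnLower), turnUpper = as.integer(x$turnUpper),
      padding = as.integer(x$padding), side = x$side, axis = x$axis)
}

#' Default left/right VA templates
#'
#' Templates shipped with the package, built by [buildTemplate()] from
#' a synthetic population of ten phantom VA derivative profiles per
#' side (see `inst/extdata/`); they stand in for templates averaged
#' from typical subjects.
#'
#' @return list with `left` and `right` [Template].
#' @export
defaultTemplates <- function() {
  list(left = readTemplate(system.file("extdata", "template_left_synthetic.json",
                                       package = "pcmriplan", mustWork = TRUE)),
       right = readTemplate(system.file("extdata", "template_right_synthetic.json",
                                        package = "pcmriplan", mustWork = TRUE)))
}
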