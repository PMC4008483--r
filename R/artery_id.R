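## Connected-component labelling on a set of voxel coordinates via an
## adjacency graph (igraph). `offsets` is a matrix of half-neighbourhood
## integer offsets; returns an integer membership vector.
.labelComponents <- function(vox, dims, offsets) {
  n <- nrow(vox)
  if (n == 0L) return(integer(0))
  mult <- cumprod(c(1, dims[-length(dims)]))
  lin <- as.vector(1 + (vox - 1) %*% mult)
  lookup <- integer(prod(dims))
  lookup[lin] <- seq_len(n)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offsets))) {
    nb <- sweep(vox, 2, offsets[r, ], "+")
    ok <- rep(TRUE, n)
    for (a in seq_along(dims)) ok <- ok & nb[, a] >= 1 & nb[, a] <= dims[a]
    if (!any(ok)) next
    nbLin <- as.vector(1 + (nb[ok, , drop = FALSE] - 1) %*% mult)
    j <- lookup[nbLin]
    hit <- j > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, j[hit])
  }
  g <- igraph::make_graph(as.vector(rbind(from, to)), n = n,
                          directed = FALSE)
  igraph::components(g)$membership
}

.offsets3d26 <- function() {
  o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  o <- o[rowSums(abs(o)) > 0, ]
  o[seq_len(13), , drop = FALSE]            # half neighbourhood
}

.offsets2d8 <- function() {
  o <- as.matrix(expand.grid(-1:1, -1:1))
  o <- o[rowSums(abs(o)) > 0, ]
  o[seq_len(4), , drop = FALSE]
}

#' Connected objects of a binary mask (26-connectivity)
#'
#' @param mask a [BinaryMask3D].
#' @return list of connected objects sorted by voxel count (descending;
#'   ties by smaller minimal z, then discovery order), each a list with
#'   `label` (rank), `voxels` (n x 3 integer matrix of 1-based indices),
#'   `count` and `zRange`.
#' @export
connectedComponents <- function(mask) {
  stopifnot(is(mask, "BinaryMask3D"))
  vox <- which(mask@data, arr.ind = TRUE)
  if (nrow(vox) == 0L) return(list())
  memb <- .labelComponents(vox, dim(mask@data), .offsets3d26())
  objs <- lapply(seq_len(max(memb)), function(m) {
    v <- vox[memb == m, , drop = FALSE]
    list(label = m, voxels = v, count = nrow(v),
         zRange = range(v[, 3]))
  })
  ord <- order(-vapply(objs, `[[`, 0, "count"),
               vapply(objs, function(o) o$zRange[1], 0),
               vapply(objs, `[[`, 0, "label"))
  objs <- objs[ord]
  for (i in seq_along(objs)) objs[[i]]$label <- i
  objs
}

#' Keep the k largest connected objects as artery candidates
#'
#' @param objects output of [connectedComponents()].
#' @param k maximum number of candidates (default 8).
#' @return up to `k` objects, largest first (ties: smaller minimal z,
#'   then smaller label).
#' @export
selectCandidates <- function(objects, k = 8L) {
  if (length(objects) == 0L) return(objects)
  ord <- order(-vapply(objects, `[[`, 0, "count"),
               vapply(objects, function(o) o$zRange[1], 0),
               vapply(objects, `[[`, 0, "label"))
  objects[ord][seq_len(min(k, length(objects)))]
}

#' Middle-slice cross-sections of candidate objects
#'
#' Takes the volume's middle axial slice and, for every candidate
#' object, every 8-connected 2-D region of its voxels on that slice.
#' One object can contribute several sections (branches, e.g. ICA+ECA);
#' objects absent from the slice contribute none.
#'
#' @param objects candidate objects ([selectCandidates()]).
#' @param volume the parent [Volume3D] (for slice index and mm geometry).
#' @return list of cross-sections, each a list with `objectLabel`,
#'   `voxels` (m x 2, in-slice x/y indices), `size`, and `centroid`
#'   (x, y in mm).
#' @export
middleSliceSections <- function(objects, volume) {
  d <- dim(volume)
  mid <- floor(d[3] / 2) + 1L
  sp <- spacing(volume); o <- origin(volume)
  out <- list()
  for (obj in objects) {
    v <- obj$voxels[obj$voxels[, 3] == mid, , drop = FALSE]
    if (nrow(v) == 0L) next
    xy <- v[, 1:2, drop = FALSE]
    memb <- .labelComponents(xy, d[1:2], .offsets2d8())
    for (m in seq_len(max(memb))) {
      reg <- xy[memb == m, , drop = FALSE]
      cen <- o[1:2] + (colMeans(reg) - 1) * sp[1:2]
      out[[length(out) + 1L]] <- list(objectLabel = obj$label, voxels = reg,
                                      size = nrow(reg), centroid = cen)
    }
  }
  out
}

#' Label the four brain-feeding arteries
#'
#' Middle-slice heuristics: the VAs are the candidates with exactly one
#' cross-section, the most posterior (largest y centroid) in each
#' image half (left VA at x < image centre, right VA at x > centre).
#' From the remaining sectioned objects the carotids are the largest in
#' each half; within a carotid with several sections (ICA + ECA branch)
#' the ICA seed is the section whose centroid lies closest to the
#' in-plane image centre. The labelling is `ok` only when at least
#' three arteries, among them at least one VA, are found; otherwise the
#' run is `aborted` (the foramen-magnum level cannot be determined
#' without a VA).
#'
#' @param candidates candidate objects ([selectCandidates()]).
#' @param sections their middle-slice sections ([middleSliceSections()]).
#' @param volume the parent [Volume3D].
#' @return an `ArteryLabeling` list: `labels` (per label NULL or a list
#'   with `object` and `section`), `status` (named character,
#'   found/not_found), `overall` ("ok"/"aborted").
#' @export
labelArteries <- function(candidates, sections, volume) {
  d <- dim(volume); sp <- spacing(volume); o <- origin(volume)
  centre <- o[1:2] + (d[1:2] - 1) * sp[1:2] / 2
  byObj <- split(sections,
                 vapply(sections, `[[`, 0, "objectLabel"))
  labels <- list(LICA = NULL, RICA = NULL, LVA = NULL, RVA = NULL)
  objByLabel <- stats::setNames(candidates,
                                vapply(candidates, `[[`, 0, "label"))

  ## VAs: single-section objects, most posterior per half
  single <- names(byObj)[vapply(byObj, length, 0L) == 1L]
  pickVA <- function(half) {
    best <- NULL; bestY <- -Inf
    for (lab in single) {
      s <- byObj[[lab]][[1]]
      onHalf <- if (half == "L") s$centroid[1] < centre[1]
                else s$centroid[1] > centre[1]
      if (onHalf && s$centroid[2] > bestY) {
        bestY <- s$centroid[2]
        best <- list(object = objByLabel[[lab]], section = s)
      }
    }
    best
  }
  labels["LVA"] <- list(pickVA("L"))
  labels["RVA"] <- list(pickVA("R"))
  taken <- vapply(Filter(Negate(is.null), labels[c("LVA", "RVA")]),
                  function(l) l$object$label, 0)

  ## carotids: largest remaining sectioned object per half; ICA seed =
  ## centre-closest section
  remaining <- setdiff(names(byObj), as.character(taken))
  pickICA <- function(half) {
    best <- NULL; bestCount <- -Inf
    for (lab in remaining) {
      obj <- objByLabel[[lab]]
      secs <- byObj[[lab]]
      allVox <- do.call(rbind, lapply(secs, `[[`, "voxels"))
      cx <- o[1] + (mean(allVox[, 1]) - 1) * sp[1]
      onHalf <- if (half == "L") cx < centre[1] else cx > centre[1]
      if (onHalf && obj$count > bestCount) {
        dists <- vapply(secs, function(s) sum((s$centroid - centre)^2), 0)
        bestCount <- obj$count
        best <- list(object = obj, section = secs[[which.min(dists)]])
      }
    }
    best
  }
  labels["LICA"] <- list(pickICA("L"))
  labels["RICA"] <- list(pickICA("R"))

  found <- !vapply(labels, is.null, TRUE)
  status <- ifelse(found, "found", "not_found")
  names(status) <- names(labels)
  nVA <- sum(found[c("LVA", "RVA")])
  overall <- if (sum(found) >= 3L && nVA >= 1L) "ok" else "aborted"
  out <- list(labels = labels, status = status, overall = overall)
  class(out) <- "ArteryLabeling"
  out
}

#' @export
print.ArteryLabeling <- function(x, ...) {
  cat("ArteryLabeling (", x$overall, "):\n", sep = "")
  for (lab in names(x$labels)) {
    l <- x$labels[[lab]]
    if (is.null(l)) {
      cat(sprintf("  %s: not found\n", lab))
    } else {
      cat(sprintf("  %s: object %d (%d voxels), seed centroid (%.1f, %.1f) mm\n",
                  lab, l$object$label, l$object$count,
                  l$section$centroid[1], l$section$centroid[2]))
    }
  }
  invisible(x)
}
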