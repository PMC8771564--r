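# ROI geometry: polygon rasterization (even-odd rule), JSON and label-mask
# TIFF readers.

# Even-odd (crossing-number) point-in-polygon test, vectorized over points.
# Polygon vertices are (row, col); points are pixel centers.
pointInPolygon <- function(pr, pc, vr, vc) {
  n <- length(vr)
  inside <- rep(FALSE, length(pr))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vr[i] > pr) != (vr[j] > pr)) &
      (pc < (vc[j] - vc[i]) * (pr - vr[i]) / (vr[j] - vr[i]) + vc[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize a polygon into an ROI mask
#'
#' A pixel belongs to the ROI when its center lies inside the polygon under
#' the even-odd rule.
#'
#' @param vertices numeric matrix with columns (row, col), 1-based pixel
#'   coordinates.
#' @param dim frame dimensions c(rows, cols).
#' @param name ROI label.
#' @return An \linkS4class{ROI}.
#' @export
roiFromPolygon <- function(vertices, dim, name = "roi") {
  vertices <- as.matrix(vertices)
  stopIfNot(nrow(vertices) >= 3, "a polygon needs at least 3 vertices")
  pr <- rep(seq_len(dim[1]), times = dim[2])
  pc <- rep(seq_len(dim[2]), each = dim[1])
  mask <- matrix(pointInPolygon(pr, pc, vertices[, 1], vertices[, 2]),
                 dim[1], dim[2])
  ROI(name, mask)
}

#' Read ROI definitions from JSON
#'
#' The file holds an array of objects \code{{"name": ..., "vertices":
#' [[r, c], ...]}} with vertices in 1-based pixel coordinates; each polygon
#' is rasterized with the even-odd rule.
#'
#' @param path JSON file.
#' @param dim frame dimensions c(rows, cols).
#' @return Named list of \linkS4class{ROI} objects.
#' @export
readRoiJSON <- function(path, dim) {
  stopIfNot(file.exists(path), "ROI file '", path, "' does not exist")
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(spec)) spec <- split(spec, seq_len(nrow(spec)))
  rois <- lapply(seq_along(spec), function(i) {
    s <- spec[[i]]
    v <- s$vertices
    if (is.list(v) && !is.data.frame(v)) v <- do.call(rbind, v)
    if (is.list(v)) v <- as.matrix(v)
    roiFromPolygon(v, dim, name = as.character(s$name))
  })
  names(rois) <- vapply(rois, roiName, character(1))
  rois
}

#' Write ROI polygons to JSON
#'
#' @param rois named list of polygon vertex matrices (columns row, col).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeRoiJSON <- function(rois, path) {
  spec <- lapply(names(rois), function(nm) {
    list(name = nm, vertices = unname(apply(rois[[nm]], 1, as.list)))
  })
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ROIs from a label-mask TIFF
#'
#' Each distinct nonzero integer label in the image becomes one ROI named
#' \code{"roi<label>"}.
#'
#' @param path single-page TIFF of integer labels.
#' @return Named list of \linkS4class{ROI} objects.
#' @export
readRoiMaskTIFF <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  labs <- sort(setdiff(unique(as.vector(img)), 0))
  stopIfNot(length(labs) > 0, "label mask '", path, "' has no nonzero labels")
  rois <- lapply(labs, function(l) ROI(paste0("roi", l), img == l))
  names(rois) <- vapply(rois, roiName, character(1))
  rois
}

#' Build an elliptical ROI mask
#'
#' Convenience constructor used for chamber ROIs over synthetic videos.
#'
#' @param center (row, col) of the ellipse center, pixels.
#' @param semiAxes (row semi-axis, col semi-axis), pixels.
#' @param dim frame dimensions c(rows, cols).
#' @param name ROI label.
#' @return An \linkS4class{ROI}.
#' @export
roiFromEllipse <- function(center, semiAxes, dim, name = "roi") {
  r <- matrix(seq_len(dim[1]), dim[1], dim[2])
  c_ <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  mask <- ((r - center[1]) / semiAxes[1])^2 +
    ((c_ - center[2]) / semiAxes[2])^2 <= 1
  ROI(name, mask)
}
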