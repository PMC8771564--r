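# Image-stack IO: multi-page TIFF in/out, dual-view splitting, and
# integer-pixel inter-channel registration.

#' Read a fluorescence image stack
#'
#' Reads a multi-page TIFF, or a directory of equally-shaped single-frame
#' TIFFs sorted lexicographically, into a \linkS4class{ChannelStack}.
#' 16-bit integer data are preserved losslessly. If \code{frameInterval} or
#' \code{pixelSize} is NULL the JSON metadata sidecar written by
#' \code{\link{writeStack}} (\code{<path>.json}) is consulted.
#'
#' @param path multi-page TIFF file or a directory of per-frame TIFFs.
#' @param frameInterval seconds per frame; NULL to read from the sidecar.
#' @param pixelSize micrometers per pixel; NULL to read from the sidecar.
#' @param channelLabel channel label for the result.
#' @return A \linkS4class{ChannelStack} with frames in acquisition order.
#' @export
readStack <- function(path, frameInterval = NULL, pixelSize = NULL,
                      channelLabel = "generic") {
  stopIfNot(file.exists(path), "cannot read '", path, "': no such file or directory")
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tif{1,2}$", ignore.case = TRUE,
                             full.names = TRUE))
    stopIfNot(length(files) > 0, "directory '", path, "' contains no TIFF frames")
    pages <- lapply(files, function(f) {
      img <- tiff::readTIFF(f, as.is = TRUE)
      stopIfNot(length(dim(img)) == 2L, "frame '", f, "' is not single-channel")
      img
    })
    names(pages) <- basename(files)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    names(pages) <- sprintf("page %d", seq_along(pages))
  }
  dims <- lapply(pages, dim)
  ref <- dims[[1]]
  bad <- which(!vapply(dims, function(d) identical(d, ref), logical(1)))
  stopIfNot(length(bad) == 0,
            "inconsistent frame shapes: '", names(pages)[bad[1]],
            "' differs from the first frame")
  side <- jsonSidecarPath(path)
  meta <- if ((is.null(frameInterval) || is.null(pixelSize)) && file.exists(side))
    jsonlite::read_json(side) else list()
  if (is.null(frameInterval)) frameInterval <- meta$frame_interval_s
  if (is.null(pixelSize)) pixelSize <- meta$pixel_size_um
  stopIfNot(!is.null(frameInterval), "frameInterval not given and no sidecar found")
  stopIfNot(!is.null(pixelSize), "pixelSize not given and no sidecar found")
  stopIfNot(is.numeric(frameInterval) && frameInterval > 0,
            "nonpositive frameInterval")
  stopIfNot(is.numeric(pixelSize) && pixelSize > 0, "nonpositive pixelSize")
  ChannelStack(pages, frameInterval = as.numeric(frameInterval),
               pixelSize = as.numeric(pixelSize), channelLabel = channelLabel)
}

jsonSidecarPath <- function(path) paste0(sub("/+$", "", path), ".json")

#' Write a stack as 16-bit multi-page TIFF plus a JSON metadata sidecar
#'
#' Integer intensities in [0, 65535] survive a write/read round trip
#' bit-identically. The sidecar \code{<path>.json} records
#' \code{frame_interval_s} and \code{pixel_size_um} (plus optional layout
#' fields for split-view stacks).
#'
#' @param stack a \linkS4class{ChannelStack}.
#' @param path output TIFF path.
#' @param layout,donorSide optional split-view annotations stored in the
#'   sidecar.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path, layout = NULL, donorSide = NULL) {
  f <- frames(stack)
  stopIfNot(max(f) <= 65535, "intensities exceed the 16-bit range")
  pages <- lapply(seq_len(dim(f)[1]), function(i) f[i, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(frame_interval_s = frameInterval(stack),
               pixel_size_um = pixelSize(stack))
  if (!is.null(layout)) meta$layout <- layout
  if (!is.null(donorSide)) meta$donor_side <- donorSide
  jsonlite::write_json(meta, jsonSidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Split a dual-view stack into donor and FRET channels
#'
#' Image splitters project donor and acceptor emission onto the two halves
#' of the camera field; this separates the halves into two stacks of equal
#' shape with metadata copied and channel labels set.
#'
#' @param stack a \linkS4class{ChannelStack} holding split-view frames.
#' @param layout \code{"left-right"} (split along columns) or
#'   \code{"top-bottom"} (split along rows).
#' @param donorSide which half holds the donor image: \code{"left"}/
#'   \code{"right"} for left-right layout, \code{"top"}/\code{"bottom"} for
#'   top-bottom.
#' @param splitAt optional explicit split coordinate: the first
#'   \code{splitAt} pixels along the split axis form the first half.
#'   Required when the split axis has odd length. Both halves are cropped
#'   to the smaller half's extent so their shapes match.
#' @return list with elements \code{donor} and \code{fret}.
#' @export
splitDualView <- function(stack, layout = c("left-right", "top-bottom"),
                          donorSide = NULL, splitAt = NULL) {
  layout <- match.arg(layout)
  if (is.null(donorSide)) donorSide <- if (layout == "left-right") "left" else "top"
  f <- frames(stack)
  n <- if (layout == "left-right") dim(f)[3] else dim(f)[2]
  if (is.null(splitAt)) {
    stopIfNot(n %% 2L == 0L,
              "split axis has odd length ", n, "; give an explicit splitAt")
    splitAt <- n %/% 2L
  }
  stopIfNot(splitAt >= 1 && splitAt < n, "splitAt outside the frame")
  w <- min(splitAt, n - splitAt)
  if (layout == "left-right") {
    first <- f[, , seq_len(w), drop = FALSE]
    second <- f[, , splitAt + seq_len(w), drop = FALSE]
    donorFirst <- donorSide == "left"
  } else {
    first <- f[, seq_len(w), , drop = FALSE]
    second <- f[, splitAt + seq_len(w), , drop = FALSE]
    donorFirst <- donorSide == "top"
  }
  mk <- function(arr, label) ChannelStack(arr, frameInterval(stack),
                                          pixelSize(stack), label)
  if (donorFirst)
    list(donor = mk(first, "donor"), fret = mk(second, "fret"))
  else
    list(donor = mk(second, "donor"), fret = mk(first, "fret"))
}

# Cross-correlation surface of two mean-subtracted images over integer
# shifts |dy|,|dx| <= maxShift, via zero-padded FFTs. C[dy,dx] =
# sum_r a(r) * b(r + (dy,dx)) for the displacement of b relative to a.
xcorrSurface <- function(a, b, maxShift) {
  a <- a - mean(a); b <- b - mean(b)
  pr <- nrow(a) + maxShift; pc <- ncol(a) + maxShift
  pa <- matrix(0, pr, pc); pb <- matrix(0, pr, pc)
  pa[seq_len(nrow(a)), seq_len(ncol(a))] <- a
  pb[seq_len(nrow(b)), seq_len(ncol(b))] <- b
  cc <- Re(stats::fft(Conj(stats::fft(pa)) * stats::fft(pb), inverse = TRUE)) /
    (pr * pc)
  shifts <- (-maxShift):maxShift
  idx <- function(s, n) ((s %% n) + 1L)
  surf <- cc[idx(shifts, pr), idx(shifts, pc), drop = FALSE]
  dimnames(surf) <- list(dy = shifts, dx = shifts)
  norm <- sqrt(sum(a^2) * sum(b^2))
  surf / norm
}

#' Estimate and correct the inter-channel pixel shift
#'
#' Dual-view optics introduce a small translation between the donor and
#' FRET half-images. The shift is estimated as the integer-pixel peak of
#' the normalized cross-correlation of the two time-averaged images, and
#' the FRET stack is translated back onto the donor stack with edge pixels
#' filled by nearest-edge replication.
#'
#' @param donor,fret equally-shaped \linkS4class{ChannelStack}s.
#' @param maxShift maximum shift searched, pixels (default 10).
#' @return list with \code{shift} (a \linkS4class{ShiftVector}) and
#'   \code{fret} (the aligned FRET stack).
#' @export
registerChannels <- function(donor, fret, maxShift = 10L) {
  stopIfNot(identical(dim(frames(donor)), dim(frames(fret))),
            "donor and fret stacks must have the same shape")
  stopIfNot(maxShift >= 0, "maxShift must be >= 0")
  avgD <- apply(frames(donor), c(2, 3), mean)
  avgF <- apply(frames(fret), c(2, 3), mean)
  stopIfNot(stats::sd(avgD) > 0 && stats::sd(avgF) > 0,
            "no registration signal: a time-averaged image is uniform")
  if (maxShift == 0L) {
    sv <- new("ShiftVector", dy = 0L, dx = 0L, score = 1)
    return(list(shift = sv, fret = fret))
  }
  surf <- xcorrSurface(avgD, avgF, as.integer(maxShift))
  k <- arrayInd(which.max(surf), dim(surf))
  shifts <- (-maxShift):maxShift
  dy <- shifts[k[1]]; dx <- shifts[k[2]]
  if (abs(dy) == maxShift || abs(dx) == maxShift)
    warning("estimated shift lies on the maxShift boundary (", dy, ", ", dx,
            "); the true shift may be larger")
  sv <- new("ShiftVector", dy = as.integer(dy), dx = as.integer(dx),
            score = max(surf))
  list(shift = sv, fret = translateStack(fret, dy, dx))
}

# Translate every frame so that aligned[r, c] = frames[r + dy, c + dx],
# replicating the nearest edge where the source index leaves the frame.
translateStack <- function(stack, dy, dx) {
  f <- frames(stack)
  ri <- clamp(seq_len(dim(f)[2]) + dy, 1L, dim(f)[2])
  ci <- clamp(seq_len(dim(f)[3]) + dx, 1L, dim(f)[3])
  ChannelStack(f[, ri, ci, drop = FALSE], frameInterval(stack),
               pixelSize(stack), channelLabel(stack))
}
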