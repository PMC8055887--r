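#' Post-processing configuration
#'
#' Converts a predicted density map into cell centers: per channel the map
#' is thresholded, a Euclidean distance transform scores interior pixels,
#' the negated transform becomes the watershed relief, and each watershed
#' basin yields one detection at its distance-transform maximum.
#'
#' @param threshold Density threshold `T` (> 0); pixels with value `>= T`
#'   are foreground. Default `0.4 * peak` for unit-peak encodings: a fixed
#'   fraction of the kernel peak survives amplitude rescaling.
#' @param connectivity 4 or 8 (default) for regions and flooding.
#' @param min_region_area Segments smaller than this many pixels are
#'   dropped as noise; default 4.
#' @return A `postprocess_config` list.
#' @export
postprocess_config <- function(threshold = 0.4, connectivity = 8L,
                               min_region_area = 4L) {
  if (threshold <= 0) abort("`threshold` must be > 0")
  if (!connectivity %in% c(4L, 8L)) abort("`connectivity` must be 4 or 8")
  structure(list(threshold = threshold,
                 connectivity = as.integer(connectivity),
                 min_region_area = as.integer(min_region_area)),
            class = "postprocess_config")
}

#' Threshold one density channel
#'
#' Values `>= T` map to 255, the rest to 0 (the binary image convention of
#' the pipeline).
#'
#' @param channel `H x W` numeric matrix.
#' @param T Threshold (> 0).
#' @return Integer matrix of 0/255.
#' @export
threshold_map <- function(channel, T) {
  if (T <= 0) abort("`T` must be > 0")
  out <- matrix(0L, nrow(channel), ncol(channel))
  out[channel >= T] <- 255L
  out
}

#' Euclidean distance transform
#'
#' For each foreground pixel, the distance to the nearest background pixel;
#' background stays 0.
#'
#' @param binary `H x W` matrix; non-zero means foreground.
#' @return `H x W` numeric matrix of distances.
#' @export
distance_transform <- function(binary) {
  b <- matrix(as.numeric(binary != 0), nrow(binary), ncol(binary))
  if (!any(b > 0)) return(b)
  d <- unclass(EBImage::distmap(b, metric = "euclidean"))
  # a frame with no background pixels has unbounded distances; cap them at
  # the image diagonal so downstream arithmetic stays finite
  d[!is.finite(d)] <- sqrt(nrow(b)^2 + ncol(b)^2)
  d
}

#' Priority-flood watershed
#'
#' Floods the relief from its regional minima (plateau-aware); each pixel
#' joins the basin of its lowest labeled neighbour when it is popped from a
#' deterministic priority queue ordered by `(value, row, col)`, so ties are
#' bit-reproducible. Pixels outside `mask` keep label 0.
#'
#' @param relief `H x W` numeric matrix of finite values.
#' @param connectivity 4 or 8 (default).
#' @param mask Optional logical matrix restricting the flood (e.g. the
#'   thresholded foreground).
#' @return Integer label matrix: 0 = outside mask, `1..K` = basins.
#' @examples
#' watershed_labels(matrix(c(0, 1, 2, 3, 2, 1, 0), 1))  # two basins
#' @export
watershed_labels <- function(relief, connectivity = 8L, mask = NULL) {
  relief <- as.matrix(relief)
  if (!all(is.finite(relief))) abort("`relief` must be finite")
  if (is.null(mask))
    mask <- matrix(TRUE, nrow(relief), ncol(relief))
  watershed_pf(relief, as.integer(connectivity), mask)
}

#' Extract cell centers from a density map
#'
#' Per channel: threshold at `cfg$threshold`, Euclidean distance transform,
#' negate (watershed floods minima), watershed restricted to the foreground,
#' then one detection per basin at the basin's distance-transform argmax
#' (ties broken by row, then column). Basins smaller than
#' `cfg$min_region_area` pixels are dropped.
#'
#' @param map A `density_map` (or `H x W x 3` array).
#' @param cfg A [postprocess_config()].
#' @param image_id Id for the returned [detection_set()].
#' @return A [detection_set()] of predicted centers.
#' @export
extract_centers <- function(map, cfg = postprocess_config(),
                            image_id = "prediction") {
  stopifnot(inherits(cfg, "postprocess_config"))
  m <- unclass(map)
  H <- dim(m)[1]; W <- dim(m)[2]
  det <- list()
  for (ch in 1:3) {
    bin <- threshold_map(m[, , ch], cfg$threshold)
    if (!any(bin > 0)) next
    D <- distance_transform(bin)
    lab <- watershed_labels(-D, cfg$connectivity, mask = bin > 0)
    K <- max(lab)
    if (K == 0L) next
    pix <- which(lab > 0)
    seg <- lab[pix]
    areas <- tabulate(seg, nbins = K)
    # argmax of D per segment, ties broken by (row, col)
    o <- order(seg, -D[pix], (pix - 1L) %% H, (pix - 1L) %/% H)
    first <- o[!duplicated(seg[o])]
    centers <- pix[first]
    keep <- areas[seg[first]] >= cfg$min_region_area
    centers <- centers[keep]
    if (!length(centers)) next
    rows <- (centers - 1L) %% H
    cols <- (centers - 1L) %/% H
    det[[length(det) + 1L]] <- tibble(x = as.integer(cols),
                                      y = as.integer(rows),
                                      class = ch - 1L)
  }
  pts <- if (length(det)) bind_rows(det)
         else tibble(x = integer(), y = integer(), class = integer())
  detection_set(pts, image_id, width = W, height = H)
}
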