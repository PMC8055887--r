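#' Parameters of the synthetic IHC tile generator
#'
#' The generator emulates the structure of Ki-67 stained breast-biopsy tiles:
#' three cell classes with distinct chromatic appearance (DAB-brown
#' immunopositive nuclei, hematoxylin-blue immunonegative nuclei, small dark
#' lymphocytes) drawn as filled ellipses on a pale background, with exact
#' ground-truth centers. Defaults mirror the published dataset's structure:
#' 256x256 tiles averaging 69 cells with class mix roughly 22/43/4 and a
#' modest fraction of touching cells.
#'
#' @param width,height Tile size in pixels.
#' @param n_per_class Integer triple: cells per class
#'   (immunopositive, immunonegative, lymphocyte).
#' @param radius_range List of three `(min, max)` cell radii in pixels;
#'   lymphocytes are smaller than the tumor classes.
#' @param color_mean 3x3 matrix of per-class mean RGB (rows = classes,
#'   0-255 scale).
#' @param color_sd Per-class std of the cell color (RGB channels, 0-255).
#' @param overlap_fraction Target fraction of cells placed so their disk
#'   intersects a previously placed cell, in `[0, 1)`.
#' @param background_rgb Background color (0-255).
#' @param noise_std Per-pixel Gaussian noise std (0-255 scale).
#' @param min_center_separation Minimum distance between any two cell
#'   centers, pixels.
#' @param seed Integer seed; identical parameters give byte-identical tiles.
#' @return A `synth_params` list.
#' @export
synth_params <- function(width = 256, height = 256,
                         n_per_class = c(22L, 43L, 4L),
                         radius_range = list(c(5, 9), c(5, 9), c(2.5, 4.5)),
                         color_mean = rbind(c(140, 95, 55),
                                            c(70, 90, 160),
                                            c(45, 45, 100)),
                         color_sd = c(12, 12, 8),
                         overlap_fraction = 0.15,
                         background_rgb = c(233, 226, 230),
                         noise_std = 4,
                         min_center_separation = 4,
                         seed = 1L) {
  n_per_class <- as.integer(n_per_class)
  if (length(n_per_class) != 3L || any(is.na(n_per_class)) || any(n_per_class < 0L))
    abort("`n_per_class` must be three non-negative integers")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    abort("`overlap_fraction` must be in [0, 1)")
  if (any(vapply(radius_range, min, 0) <= 0))
    abort("cell radii must be positive")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_per_class = n_per_class, radius_range = radius_range,
                 color_mean = color_mean, color_sd = color_sd,
                 overlap_fraction = overlap_fraction,
                 background_rgb = background_rgb, noise_std = noise_std,
                 min_center_separation = min_center_separation,
                 seed = as.integer(seed)),
            class = "synth_params")
}

# run expr under a private RNG stream, restoring the caller's state
with_private_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate one synthetic IHC tile with ground truth
#'
#' Cells are placed by rejection sampling (at most 1000 retries per cell)
#' honoring `min_center_separation`; an `overlap_fraction` share of cells is
#' deliberately placed to intersect an earlier cell. Each cell is a filled,
#' randomly oriented ellipse in its class color; later cells paint over
#' earlier ones, as overlapping nuclei do. The returned truth records every
#' drawn center.
#'
#' @param params A [synth_params()].
#' @param image_id Identifier stored in the truth set.
#' @param patient_id Optional patient grouping label.
#' @return A list with `image` (`height x width x 3` array in `[0, 1]`,
#'   8-bit quantized) and `truth` (an [annotation_set()]).
#' @examples
#' s <- generate_image(synth_params(width = 64, height = 64,
#'                                  n_per_class = c(2, 3, 1), seed = 7))
#' class_counts(s$truth)
#' @export
generate_image <- function(params, image_id = "synthetic",
                           patient_id = NULL) {
  stopifnot(inherits(params, "synth_params"))
  with_private_seed(params$seed, generate_image_impl(params, image_id, patient_id))
}

generate_image_impl <- function(params, image_id, patient_id) {
  W <- params$width; H <- params$height
  n_total <- sum(params$n_per_class)
  cls <- rep(0:2, params$n_per_class)
  if (n_total > 0) cls <- sample(cls)
  # which placements should deliberately overlap an earlier cell
  n_overlap <- round(params$overlap_fraction * n_total)
  overlap_flag <- rep(FALSE, n_total)
  if (n_overlap > 0 && n_total > 1)
    overlap_flag[sample(2:n_total, min(n_overlap, n_total - 1L))] <- TRUE

  xs <- ys <- ra <- rb <- th <- numeric(n_total)
  rmaj <- numeric(n_total)
  min_sep <- params$min_center_separation
  for (i in seq_len(n_total)) {
    rng <- params$radius_range[[cls[i] + 1L]]
    a <- runif(1, rng[1], rng[2])            # semi-major axis
    b <- a * runif(1, 0.7, 1)                # semi-minor axis
    placed <- FALSE
    for (try in seq_len(1000L)) {
      if (overlap_flag[i] && i > 1L) {
        j <- sample.int(i - 1L, 1L)
        dmax <- 0.9 * (rmaj[j] + a)
        d <- runif(1, max(min_sep, 0.4 * dmax), max(min_sep + 0.1, dmax))
        ang <- runif(1, 0, 2 * pi)
        cx <- xs[j] + d * cos(ang); cy <- ys[j] + d * sin(ang)
      } else {
        cx <- runif(1, 2, W - 3); cy <- runif(1, 2, H - 3)
      }
      if (cx < 2 || cx > W - 3 || cy < 2 || cy > H - 3) next
      if (i > 1L) {
        dx <- xs[seq_len(i - 1L)] - cx; dy <- ys[seq_len(i - 1L)] - cy
        dist <- sqrt(dx^2 + dy^2)
        if (any(dist < min_sep)) next
        if (!overlap_flag[i] &&
            any(dist < rmaj[seq_len(i - 1L)] + a + 1)) next
      }
      xs[i] <- cx; ys[i] <- cy; ra[i] <- a; rb[i] <- b
      th[i] <- runif(1, 0, pi); rmaj[i] <- a
      placed <- TRUE
      break
    }
    if (!placed)
      abort(sprintf(paste0("packing error: could not place cell %d of %d ",
                           "under min_center_separation=%.1f after 1000 retries"),
                    i, n_total, min_sep))
  }

  img <- array(rep(params$background_rgb, each = H * W), dim = c(H, W, 3))
  for (i in seq_len(n_total)) {
    col <- params$color_mean[cls[i] + 1L, ] +
      rnorm(3, 0, params$color_sd[cls[i] + 1L])
    r0 <- max(1L, floor(ys[i] - ra[i])):min(H, ceiling(ys[i] + ra[i]))
    c0 <- max(1L, floor(xs[i] - ra[i])):min(W, ceiling(xs[i] + ra[i]))
    dy <- (r0 - 1) - ys[i]; dx <- (c0 - 1) - xs[i]
    u <- outer(dy, dx, function(yy, xx)  xx * cos(th[i]) + yy * sin(th[i]))
    v <- outer(dy, dx, function(yy, xx) -xx * sin(th[i]) + yy * cos(th[i]))
    inside <- (u / ra[i])^2 + (v / rb[i])^2 <= 1
    for (ch in 1:3) {
      sl <- img[r0, c0, ch]
      sl[inside] <- col[ch]
      img[r0, c0, ch] <- sl
    }
  }
  img <- img + array(rnorm(H * W * 3, 0, params$noise_std), dim = c(H, W, 3))
  img <- round(pmin(pmax(img, 0), 255)) / 255

  pts <- tibble(x = as.integer(round(xs)), y = as.integer(round(ys)),
                class = cls)
  pts$x <- pmin(pmax(pts$x, 0L), W - 1L)
  pts$y <- pmin(pmax(pts$y, 0L), H - 1L)
  truth <- annotation_set(pts, image_id, W, H, patient_id)
  list(image = img, truth = truth)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` PNG tiles with paired JSON annotations, assigning tiles
#' round-robin to `patients` synthetic patient ids (mirroring how biopsy
#' crops group by patient), and a JSON manifest with per-class totals and
#' per-patient membership.
#'
#' @param params A [synth_params()]; image `i` uses a stream derived from
#'   `params$seed` and `i`.
#' @param n_images Number of tiles (>= `patients`).
#' @param out_dir Output directory (created if missing).
#' @param patients Number of synthetic patients (>= 1).
#' @return The manifest, invisibly: a list with `images` (tibble: file,
#'   annotation file, image_id, patient_id, per-class counts), `totals` and
#'   `patients`.
#' @export
generate_dataset <- function(params, n_images, out_dir, patients = 1L) {
  stopifnot(inherits(params, "synth_params"))
  n_images <- as.integer(n_images); patients <- as.integer(patients)
  if (n_images < patients || patients < 1L)
    abort("need n_images >= patients >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    p <- params
    p$seed <- derive_seed(params$seed, i)
    pid <- sprintf("P%02d", ((i - 1L) %% patients) + 1L)
    iid <- sprintf("img_%04d", i)
    s <- generate_image(p, image_id = iid, patient_id = pid)
    img_file <- paste0(iid, ".png")
    ann_file <- paste0(iid, ".json")
    write_image_png(s$image, file.path(out_dir, img_file))
    save_annotations(s$truth, file.path(out_dir, ann_file))
    cc <- class_counts(s$truth)
    rows[[i]] <- tibble(file = img_file, annotation = ann_file,
                        image_id = iid, patient_id = pid,
                        immunopositive = cc[[1]], immunonegative = cc[[2]],
                        lymphocyte = cc[[3]])
  }
  images <- bind_rows(rows)
  manifest <- list(
    images = images,
    totals = as.list(colSums(images[, CLASS_NAMES])),
    patients = lapply(split(images$image_id, images$patient_id), as.list))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

# per-image RNG stream; kept below 2^31
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 10007) %% 2147483647)
}

#' Build a density-map fixture from listed modes
#'
#' Convenience wrapper for tests of the post-processing stage: places the
#' given modes as point annotations and encodes them with [encode_density()],
#' so fixtures and network targets share one implementation.
#'
#' @param modes Data frame with columns `x`, `y`, `class` (0-based pixels).
#' @param shape `(height, width)` of the map.
#' @param sigma Gaussian std in pixels.
#' @param ... Further arguments to [density_config()].
#' @return A `density_map`.
#' @export
generate_density_fixture <- function(modes, shape, sigma = 3, ...) {
  set <- annotation_set(modes, "fixture", width = shape[2], height = shape[1])
  encode_density(set, density_config(sigma = sigma, ...))
}
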