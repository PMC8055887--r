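#' Pipeline configuration
#'
#' Bundles the stage configurations of the full tile-to-scores pipeline.
#'
#' @param density A [density_config()].
#' @param network A [network_config()].
#' @param train A [train_config()].
#' @param post A [postprocess_config()].
#' @param match A [match_config()].
#' @param tile_size Tile edge for processing large images; default 256.
#' @param seed Integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(density = density_config(),
                            network = network_config(),
                            train = train_config(),
                            post = postprocess_config(),
                            match = match_config(),
                            tile_size = 256L, seed = 1L) {
  structure(list(density = density, network = network, train = train,
                 post = post, match = match,
                 tile_size = as.integer(tile_size), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `density`, `network`, `train`, `post`, `match`,
#' `tile_size`, `seed`; each section holds arguments of the matching
#' `*_config()` constructor and missing values keep their defaults.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  call1 <- function(fn, args) do.call(fn, if (is.null(args)) list() else args)
  pipeline_config(
    density = call1(density_config, y$density),
    network = call1(network_config, y$network),
    train = call1(train_config, y$train),
    post = call1(postprocess_config, y$post),
    match = call1(match_config, y$match),
    tile_size = y$tile_size %||% 256L,
    seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cut a large image into non-overlapping tiles
#'
#' Right/bottom remainder tiles are padded to `tile_size` with the
#' background value; `valid_w`/`valid_h` record the unpadded extent so
#' detections falling in the padding can be discarded.
#'
#' @param image `H x W x 3` array, at least `tile_size` in both dimensions.
#' @param tile_size Tile edge in pixels.
#' @param background Pad value; default 1 (white background).
#' @return A `tile_grid`: list of `list(x_offset, y_offset, tile, valid_w,
#'   valid_h)` with 0-based offsets.
#' @export
tile_image <- function(image, tile_size = 256L, background = 1) {
  d <- dim(image)
  if (d[1] < tile_size || d[2] < tile_size)
    abort(sprintf("image (%dx%d) is smaller than the tile size %d",
                  d[2], d[1], tile_size))
  tile_size <- as.integer(tile_size)
  ys <- as.integer(seq(0L, d[1] - 1L, by = tile_size))
  xs <- as.integer(seq(0L, d[2] - 1L, by = tile_size))
  tiles <- list()
  for (y0 in ys) for (x0 in xs) {
    vh <- min(tile_size, as.integer(d[1]) - y0)
    vw <- min(tile_size, as.integer(d[2]) - x0)
    tile <- array(background, dim = c(tile_size, tile_size, 3))
    tile[seq_len(vh), seq_len(vw), ] <-
      image[y0 + seq_len(vh), x0 + seq_len(vw), , drop = FALSE]
    tiles[[length(tiles) + 1L]] <-
      list(x_offset = x0, y_offset = y0, tile = tile,
           valid_w = vw, valid_h = vh)
  }
  structure(tiles, class = "tile_grid")
}

#' Reassemble a tile grid into the original image
#'
#' Inverse of [tile_image()]: places each tile at its offset and crops the
#' padding.
#'
#' @param grid A `tile_grid`.
#' @param height,width Dimensions of the original image.
#' @return `height x width x 3` array.
#' @export
untile_image <- function(grid, height, width) {
  out <- array(0, dim = c(height, width, 3))
  for (t in grid)
    out[t$y_offset + seq_len(t$valid_h), t$x_offset + seq_len(t$valid_w), ] <-
      t$tile[seq_len(t$valid_h), seq_len(t$valid_w), ]
  out
}

#' Run the detection pipeline on one image
#'
#' Density prediction ([predict_density()]) followed by center extraction
#' ([extract_centers()]). Images larger than the network input are processed
#' as independent non-overlapping tiles and the detections mapped back
#' through the tile offsets; detections in the padded margin are discarded.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param model A trained `density_net`.
#' @param cfg A [pipeline_config()].
#' @param image_id Id for the returned set.
#' @return A [detection_set()] in the frame of `image`.
#' @export
run_pipeline <- function(image, model, cfg = pipeline_config(),
                         image_id = "image") {
  d <- dim(image)
  ts <- cfg$tile_size
  if (d[1] == ts && d[2] == ts) {
    dm <- predict_density(model, image)
    det <- extract_centers(dm, cfg$post, image_id)
    return(det)
  }
  grid <- tile_image(image, ts)
  pts <- list()
  for (t in grid) {
    dm <- predict_density(model, t$tile)
    det <- extract_centers(dm, cfg$post, image_id)
    p <- det$points
    p <- p[p$x < t$valid_w & p$y < t$valid_h, , drop = FALSE]
    p$x <- p$x + t$x_offset
    p$y <- p$y + t$y_offset
    pts[[length(pts) + 1L]] <- p
  }
  pts <- bind_rows(pts)
  if (nrow(pts) == 0L)
    pts <- tibble(x = integer(), y = integer(), class = integer())
  detection_set(pts, image_id, width = d[2], height = d[1])
}

#' Evaluate predictions against ground truth
#'
#' Matches each prediction/truth pair of sets (by `image_id`), accumulates
#' TP/FP/FN per class over all images (micro accumulation, so rates equal
#' the support-weighted convention), and computes the detection metrics,
#' per-image and per-patient Ki-67/TILs scores, their RMSE against the truth
#' scores, and patient-level cut-off accuracy.
#'
#' @param pred List of [detection_set()]s.
#' @param truth List of [annotation_set()]s covering the same image ids.
#' @param cfg A [match_config()].
#' @return A `cell_eval_report` list; see [tidy.cell_eval_report()].
#' @export
evaluate_detections <- function(pred, truth, cfg = match_config()) {
  tid <- vapply(truth, function(s) s$image_id, character(1))
  pid <- vapply(pred, function(s) s$image_id, character(1))
  common <- intersect(pid, tid)
  missing <- setdiff(tid, pid)
  if (length(missing))
    warn(sprintf("no predictions for %d image(s): %s", length(missing),
                 paste(utils::head(missing, 5L), collapse = ", ")))
  if (!length(common)) abort("no image ids shared between pred and truth")
  acc <- NULL
  img_rows <- list()
  for (id in common) {
    p <- pred[[match(id, pid)]]
    t <- truth[[match(id, tid)]]
    m <- match_detections(p, t, cfg)
    acc <- if (is.null(acc)) m$counts else {
      a <- acc
      a$tp <- a$tp + m$counts$tp
      a$fp <- a$fp + m$counts$fp
      a$fn <- a$fn + m$counts$fn
      a
    }
    ccp <- class_counts(p); cct <- class_counts(t)
    img_rows[[id]] <- tibble(
      image_id = id,
      patient_id = t$patient_id %||% NA_character_,
      pred_pos = ccp[[1]], pred_neg = ccp[[2]], pred_lym = ccp[[3]],
      true_pos = cct[[1]], true_neg = cct[[2]], true_lym = cct[[3]])
  }
  images <- bind_rows(img_rows)
  total_m <- structure(list(counts = acc,
                            pairs = tibble(class = integer(),
                                           pred_index = integer(),
                                           truth_index = integer(),
                                           distance = numeric())),
                       class = "match_result")
  report <- score_report(total_m)

  safe_ratio <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  images <- images %>%
    mutate(pred_ki67 = safe_ratio(.data$pred_pos,
                                  .data$pred_pos + .data$pred_neg),
           true_ki67 = safe_ratio(.data$true_pos,
                                  .data$true_pos + .data$true_neg),
           pred_til = safe_ratio(.data$pred_lym,
                                 .data$pred_lym + .data$pred_pos + .data$pred_neg),
           true_til = safe_ratio(.data$true_lym,
                                 .data$true_lym + .data$true_pos + .data$true_neg))
  ok_k <- !is.na(images$pred_ki67) & !is.na(images$true_ki67)
  ok_t <- !is.na(images$pred_til) & !is.na(images$true_til)

  per_patient <- NULL
  cutoff_acc <- NULL
  rmse_patient <- NULL
  if (!all(is.na(images$patient_id))) {
    # per-patient ratio of summed counts; a patient with no counted cells on
    # one side gets NA scores (and counts as a cut-off miss) instead of
    # aborting the whole evaluation
    agg <- function(prefix) {
      images %>%
        group_by(.data$patient_id) %>%
        summarise(n_images = n(),
                  pos = sum(.data[[paste0(prefix, "_pos")]]),
                  neg = sum(.data[[paste0(prefix, "_neg")]]),
                  lym = sum(.data[[paste0(prefix, "_lym")]]),
                  .groups = "drop") %>%
        mutate(ki67 = safe_ratio(.data$pos, .data$pos + .data$neg),
               til = safe_ratio(.data$lym,
                                .data$lym + .data$pos + .data$neg),
               ki67_cat = ifelse(is.na(.data$ki67), NA_character_,
                                 as.character(classify_ki67_cutoff(
                                   100 * pmin(pmax(.data$ki67, 0), 1)))),
               til_cat = ifelse(is.na(.data$til), NA_character_,
                                as.character(classify_til_cutoff(
                                  100 * pmin(pmax(.data$til, 0), 1)))))
    }
    ap <- agg("pred"); at <- agg("true")
    per_patient <- left_join(
      ap %>% select("patient_id", "n_images",
                    pred_ki67 = "ki67", pred_til = "til",
                    pred_ki67_cat = "ki67_cat", pred_til_cat = "til_cat"),
      at %>% select("patient_id",
                    true_ki67 = "ki67", true_til = "til",
                    true_ki67_cat = "ki67_cat", true_til_cat = "til_cat"),
      by = "patient_id")
    hit <- function(a, b) mean(!is.na(a) & !is.na(b) & a == b)
    cutoff_acc <- list(
      ki67 = hit(per_patient$pred_ki67_cat, per_patient$true_ki67_cat),
      til = hit(per_patient$pred_til_cat, per_patient$true_til_cat))
    okk <- !is.na(per_patient$pred_ki67) & !is.na(per_patient$true_ki67)
    okt <- !is.na(per_patient$pred_til) & !is.na(per_patient$true_til)
    rmse_patient <- list(
      ki67 = if (any(okk)) rmse(per_patient$pred_ki67[okk],
                                per_patient$true_ki67[okk]) else NA_real_,
      til = if (any(okt)) rmse(per_patient$pred_til[okt],
                               per_patient$true_til[okt]) else NA_real_)
  }
  structure(list(
    per_class = report$per_class,
    weighted = report$weighted,
    images = images,
    per_patient = per_patient,
    rmse_image = list(
      ki67 = if (any(ok_k)) rmse(images$pred_ki67[ok_k],
                                 images$true_ki67[ok_k]) else NA_real_,
      til = if (any(ok_t)) rmse(images$pred_til[ok_t],
                                images$true_til[ok_t]) else NA_real_),
    rmse_patient = rmse_patient,
    cutoff_accuracy = cutoff_acc),
    class = "cell_eval_report")
}

#' Evaluate prediction and truth directories
#'
#' Reads every `*.json` annotation in `truth_dir` and the same-named files
#' in `pred_dir` (the JSON schema is shared between annotations and
#' detections) and calls [evaluate_detections()]. Unmatched image ids are
#' listed in a warning and excluded.
#'
#' @param pred_dir,truth_dir Directories of JSON files.
#' @param cfg A [match_config()].
#' @return A `cell_eval_report`.
#' @export
evaluate_dataset <- function(pred_dir, truth_dir, cfg = match_config()) {
  tf <- list.files(truth_dir, pattern = "\\.json$", full.names = TRUE)
  tf <- tf[basename(tf) != "manifest.json"]
  if (!length(tf)) abort(sprintf("no annotation JSON found in %s", truth_dir))
  truth <- lapply(tf, load_annotations)
  pf <- file.path(pred_dir, basename(tf))
  keep <- file.exists(pf)
  if (any(!keep))
    warn(sprintf("no prediction file for %d image(s), excluded: %s",
                 sum(!keep),
                 paste(utils::head(basename(tf)[!keep], 5L), collapse = ", ")))
  if (!any(keep)) abort(sprintf("no prediction JSON found in %s", pred_dir))
  pred <- lapply(pf[keep], load_annotations)
  evaluate_detections(pred, truth[keep], cfg)
}

#' @export
print.cell_eval_report <- function(x, ...) {
  cat(sprintf("<cell_eval_report> %d image(s)\n", nrow(x$images)))
  print(x$per_class %>% select("class_name", "tp", "fp", "fn",
                               "precision", "recall", "f1"))
  cat(sprintf("  weighted: P %.4f  R %.4f  F1 %.4f\n",
              x$weighted$precision, x$weighted$recall, x$weighted$f1))
  cat(sprintf("  per-image RMSE: Ki-67 %.5f, TILs %.5f\n",
              x$rmse_image$ki67, x$rmse_image$til))
  if (!is.null(x$cutoff_accuracy))
    cat(sprintf("  patient cut-off accuracy: Ki-67 %.4f, TILs %.4f\n",
                x$cutoff_accuracy$ki67, x$cutoff_accuracy$til))
  invisible(x)
}

#' Write an evaluation report to CSV and JSON
#'
#' The CSV holds the per-class precision/recall/F1 rows; the JSON holds the
#' full report (per-class table, weighted averages, per-image and
#' per-patient scores, RMSE, cut-off accuracy).
#'
#' @param report A `cell_eval_report`.
#' @param csv_path,json_path Output files (`NULL` to skip one).
#' @return `report`, invisibly.
#' @export
write_eval_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "cell_eval_report"))
  if (!is.null(csv_path))
    utils::write.csv(report$per_class, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    obj <- report
    class(obj) <- NULL
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", factor = "string", null = "null",
                         na = "null")
  }
  invisible(report)
}
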