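#' Matching configuration
#'
#' A predicted center counts as a true positive when it lies strictly within
#' `radius` pixels of an unmatched ground-truth center of the same class;
#' candidate pairs are accepted greedily in ascending distance.
#'
#' @param radius Matching radius R in pixels (> 0). Default 10 px at the
#'   256x256 tile scale, roughly a nucleus radius.
#' @return A `match_config` list.
#' @export
match_config <- function(radius = 10) {
  if (radius <= 0) abort("`radius` must be > 0")
  structure(list(radius = radius), class = "match_config")
}

#' Match detections to ground truth within a radius
#'
#' Per class independently: all (prediction, truth) pairs of that class with
#' Euclidean distance `< radius` are candidates; they are accepted greedily
#' in globally ascending distance (ties by prediction index, then truth
#' index), each prediction and each truth used at most once. Unmatched
#' predictions are false positives, unmatched truths false negatives. When
#' several detections fall within the radius of one truth center, only the
#' closest becomes the true positive — the rest count as false positives.
#'
#' @param pred A [detection_set()] (or any [annotation_set()]).
#' @param truth An [annotation_set()].
#' @param cfg A [match_config()].
#' @return A `match_result`: list with `counts` (tibble: class, class_name,
#'   tp, fp, fn) and `pairs` (tibble: class, pred_index, truth_index,
#'   distance; indices are 1-based row numbers within each set).
#' @export
match_detections <- function(pred, truth, cfg = match_config()) {
  stopifnot(inherits(pred, "annotation_set"), inherits(truth, "annotation_set"))
  R <- cfg$radius
  counts <- vector("list", 3L)
  pairs <- vector("list", 3L)
  for (ch in 0:2) {
    pi <- which(pred$points$class == ch)
    ti <- which(truth$points$class == ch)
    np <- length(pi); nt <- length(ti)
    acc <- tibble(class = integer(), pred_index = integer(),
                  truth_index = integer(), distance = numeric())
    if (np > 0L && nt > 0L) {
      dx <- outer(pred$points$x[pi], truth$points$x[ti], "-")
      dy <- outer(pred$points$y[pi], truth$points$y[ti], "-")
      dmat <- sqrt(dx^2 + dy^2)
      cand <- which(dmat < R, arr.ind = TRUE)
      if (nrow(cand)) {
        d <- dmat[cand]
        o <- order(d, cand[, 1], cand[, 2])
        used_p <- logical(np); used_t <- logical(nt)
        sel <- integer(0)
        for (k in o) {
          p <- cand[k, 1]; t <- cand[k, 2]
          if (!used_p[p] && !used_t[t]) {
            used_p[p] <- TRUE; used_t[t] <- TRUE
            sel <- c(sel, k)
          }
        }
        if (length(sel))
          acc <- tibble(class = ch,
                        pred_index = pi[cand[sel, 1]],
                        truth_index = ti[cand[sel, 2]],
                        distance = dmat[cand[sel, , drop = FALSE]])
      }
    }
    tp <- nrow(acc)
    counts[[ch + 1L]] <- tibble(class = ch, class_name = CLASS_NAMES[ch + 1L],
                                tp = tp, fp = np - tp, fn = nt - tp)
    pairs[[ch + 1L]] <- acc
  }
  structure(list(counts = bind_rows(counts), pairs = bind_rows(pairs)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result>\n"); print(x$counts); invisible(x)
}

rate0 <- function(num, den, what) {
  out <- ifelse(den > 0, num / den, 0)
  if (any(den == 0))
    warn(sprintf("%s undefined (0/0) for %d class(es); reported as 0",
                 what, sum(den == 0)))
  out
}

#' Per-class precision and recall
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`; a 0/0 rate is
#' reported as 0 with a warning so batch evaluation stays total.
#'
#' @param m A `match_result` from [match_detections()].
#' @return Tibble: class, class_name, tp, fp, fn, precision, recall, f1.
#' @export
precision_recall <- function(m) {
  stopifnot(inherits(m, "match_result"))
  m$counts %>%
    mutate(precision = rate0(.data$tp, .data$tp + .data$fp, "precision"),
           recall = rate0(.data$tp, .data$tp + .data$fn, "recall"),
           f1 = f1_score(.data$precision, .data$recall))
}

#' F1 score (harmonic mean of precision and recall)
#'
#' `F1 = 2 P R / (P + R)`, defined as 0 when `P + R = 0`.
#'
#' @param precision,recall Rates in `[0, 1]` (vectorized).
#' @return F1 values.
#' @examples
#' f1_score(0.8436, 0.8611)  # 0.8523 to 4 decimals
#' @export
f1_score <- function(precision, recall) {
  s <- precision + recall
  ifelse(s > 0, 2 * precision * recall / s, 0)
}

#' Support-weighted average of per-class scores
#'
#' `sum(value_i * support_i) / sum(support_i)` — the convention behind
#' "average" columns of per-class detection tables, with the test-set class
#' counts as supports.
#'
#' @param values Numeric vector of per-class scores.
#' @param support Non-negative supports (e.g. truth counts), not all zero.
#' @return The weighted mean.
#' @export
weighted_average <- function(values, support) {
  if (length(values) != length(support))
    abort("`values` and `support` must have equal length")
  if (all(support == 0)) abort("`support` must not be all zero")
  sum(values * support) / sum(support)
}

#' Ki-67 proliferation index
#'
#' Fraction of tumor cells that are Ki-67 immunopositive:
#' `pos / (pos + neg)`. Lymphocytes are excluded.
#'
#' @param n_pos,n_neg Immunopositive / immunonegative cell counts.
#' @return Index in `[0, 1]`.
#' @export
ki67_index <- function(n_pos, n_neg) {
  if (n_pos + n_neg <= 0)
    abort("Ki-67 index undefined: no tumor cells counted")
  n_pos / (n_pos + n_neg)
}

#' TILs score
#'
#' Fraction of all counted cells that are lymphocytes:
#' `lym / (lym + pos + neg)`.
#'
#' @param n_lym,n_pos,n_neg Class counts.
#' @return Score in `[0, 1]`.
#' @export
til_score <- function(n_lym, n_pos, n_neg) {
  if (n_lym + n_pos + n_neg <= 0)
    abort("TILs score undefined: no cells counted")
  n_lym / (n_lym + n_pos + n_neg)
}

#' Clinical cut-off category for the Ki-67 index
#'
#' Below 16 percent: low proliferation; 16 to 30 inclusive: intermediate;
#' above 30: high.
#'
#' @param score_percent Ki-67 index in percent, `[0, 100]` (vectorized).
#' @return Factor with levels low, intermediate, high.
#' @export
classify_ki67_cutoff <- function(score_percent) {
  stopifnot(all(score_percent >= 0 & score_percent <= 100))
  factor(ifelse(score_percent < 16, "low",
                ifelse(score_percent <= 30, "intermediate", "high")),
         levels = c("low", "intermediate", "high"))
}

#' Clinical cut-off category for the TILs score
#'
#' Up to 10 percent: low; above 10 and below 40: intermediate; 40 and
#' above: high (the published 11-39 band is closed to cover all scores).
#'
#' @param score_percent TILs score in percent, `[0, 100]` (vectorized).
#' @return Factor with levels low, intermediate, high.
#' @export
classify_til_cutoff <- function(score_percent) {
  stopifnot(all(score_percent >= 0 & score_percent <= 100))
  factor(ifelse(score_percent <= 10, "low",
                ifelse(score_percent < 40, "intermediate", "high")),
         levels = c("low", "intermediate", "high"))
}

#' Root mean squared error between score vectors
#'
#' @param predicted,true Equal-length, non-empty numeric vectors.
#' @return `sqrt(mean((predicted - true)^2))`.
#' @export
rmse <- function(predicted, true) {
  if (length(predicted) == 0L || length(predicted) != length(true))
    abort("`predicted` and `true` must be non-empty and of equal length")
  sqrt(mean((predicted - true)^2))
}

#' Aggregate per-image cell counts to patient level
#'
#' Sums the class counts of each patient's tiles, then applies the Ki-67 and
#' TILs formulas to the summed counts (ratio of sums, not mean of per-tile
#' ratios) and classifies them with the clinical cut-offs.
#'
#' @param counts Data frame with columns `patient_id`, `immunopositive`,
#'   `immunonegative`, `lymphocyte` (one row per image).
#' @return Tibble: one row per patient with summed counts, `ki67_index`,
#'   `til_score` (fractions), and cut-off categories.
#' @export
aggregate_patients <- function(counts) {
  stopifnot(all(c("patient_id", CLASS_NAMES) %in% names(counts)))
  if (nrow(counts) == 0L) abort("`counts` must have at least one image")
  as_tibble(counts) %>%
    group_by(.data$patient_id) %>%
    summarise(n_images = n(),
              immunopositive = sum(.data$immunopositive),
              immunonegative = sum(.data$immunonegative),
              lymphocyte = sum(.data$lymphocyte),
              .groups = "drop") %>%
    mutate(ki67_index = mapply(ki67_index, .data$immunopositive,
                               .data$immunonegative),
           til_score = mapply(til_score, .data$lymphocyte,
                              .data$immunopositive, .data$immunonegative),
           ki67_category = classify_ki67_cutoff(100 * .data$ki67_index),
           til_category = classify_til_cutoff(100 * .data$til_score))
}

#' Full score report from a matching result
#'
#' Combines the detection metrics (per-class precision/recall/F1 and their
#' support-weighted averages, supports = truth counts) with the clinical
#' scores computed from the predicted class counts.
#'
#' @param m A `match_result`.
#' @return A `score_report` list with `per_class` (tibble), `weighted`
#'   (named list), `ki67_index`, `til_score` (fractions) and the cut-off
#'   categories.
#' @export
score_report <- function(m) {
  stopifnot(inherits(m, "match_result"))
  pc <- precision_recall(m)
  support <- pc$tp + pc$fn
  npred <- pc$tp + pc$fp
  ki <- if (npred[1] + npred[2] > 0) ki67_index(npred[1], npred[2]) else {
    warn("no tumor cells detected; Ki-67 index reported as NA")
    NA_real_
  }
  ti <- if (sum(npred) > 0) til_score(npred[3], npred[1], npred[2]) else {
    warn("no cells detected; TILs score reported as NA")
    NA_real_
  }
  structure(list(
    per_class = pc,
    weighted = list(
      precision = weighted_average(pc$precision, support),
      recall = weighted_average(pc$recall, support),
      f1 = weighted_average(pc$f1, support)),
    ki67_index = ki,
    til_score = ti,
    ki67_category = if (is.na(ki)) NA else classify_ki67_cutoff(100 * ki),
    til_category = if (is.na(ti)) NA else classify_til_cutoff(100 * ti)),
    class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat("<score_report>\n")
  print(x$per_class)
  cat(sprintf("  weighted: P %.4f  R %.4f  F1 %.4f\n",
              x$weighted$precision, x$weighted$recall, x$weighted$f1))
  cat(sprintf("  Ki-67 index %.4f (%s)   TILs score %.4f (%s)\n",
              x$ki67_index, x$ki67_category, x$til_score, x$til_category))
  invisible(x)
}

#' Published summary statistics of the SHIDC-B-Ki-67 dataset
#'
#' Per-class annotated-cell counts of the public SHIDC-B-Ki-67 breast-cancer
#' benchmark (total / training / test splits) together with the image counts
#' of each split, as released with the dataset. Useful as supports for
#' weighted averages and for dataset-scale arithmetic.
#'
#' @return Tibble: `set`, `images`, `class_name`, `cells`.
#' @export
shidc_cell_counts <- function() {
  tibble(
    set = rep(c("total", "train", "test"), each = 3L),
    images = rep(c(2357L, 1656L, 701L), each = 3L),
    class_name = rep(CLASS_NAMES, 3L),
    cells = c(50861L, 107647L, 4490L,
              35106L, 75008L, 3112L,
              15755L, 32639L, 1378L))
}
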