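test_that("matching handles identity, near misses and the closest-wins rule", {
  truth <- random_annotation_set(12, seed = 1)
  m <- match_detections(truth, truth, match_config(10))
  expect_identical(sum(m$counts$tp), 12L)
  expect_identical(sum(m$counts$fp) + sum(m$counts$fn), 0L)
  expect_true(all(m$pairs$distance == 0))

  # one truth point, two same-class predictions at distances 2 and 5:
  # the closer is the TP, the other an FP
  truth1 <- annotation_set(data.frame(x = 50L, y = 50L, class = 0L),
                           "t", 128, 128)
  pred2 <- detection_set(data.frame(x = c(52L, 55L), y = 50L, class = 0L),
                         "t", 128, 128)
  m2 <- match_detections(pred2, truth1, match_config(10))
  r0 <- m2$counts[m2$counts$class == 0L, ]
  expect_identical(c(r0$tp, r0$fp, r0$fn), c(1L, 1L, 0L))
  expect_identical(m2$pairs$pred_index, 1L)

  # strict inequality: a prediction exactly R away does not match
  predR <- detection_set(data.frame(x = 60L, y = 50L, class = 0L),
                         "t", 128, 128)
  mR <- match_detections(predR, truth1, match_config(10))
  expect_identical(mR$counts$tp[mR$counts$class == 0L], 0L)

  # class mismatch never matches, regardless of distance
  predC <- detection_set(data.frame(x = 50L, y = 50L, class = 1L),
                         "t", 128, 128)
  mC <- match_detections(predC, truth1, match_config(10))
  expect_identical(sum(mC$counts$tp), 0L)
})

test_that("greedy matching equals the exhaustive oracle on random instances", {
  withr::with_seed(77, {
    for (i in 1:120) {
      np <- sample(0:6, 1); nt <- sample(0:6, 1)
      R <- runif(1, 2, 15)
      px <- sample(0:39, np, TRUE); py <- sample(0:39, np, TRUE)
      tx <- sample(0:39, nt, TRUE); ty <- sample(0:39, nt, TRUE)
      pred <- detection_set(data.frame(x = px, y = py,
                                       class = rep(1L, np)), "i", 40, 40)
      truth <- annotation_set(data.frame(x = tx, y = ty,
                                         class = rep(1L, nt)), "i", 40, 40)
      m <- match_detections(pred, truth, match_config(R))
      o <- oracle_match(px, py, tx, ty, R)
      row <- m$counts[m$counts$class == 1L, ]
      expect_identical(c(row$tp, row$fp, row$fn), c(o$tp, o$fp, o$fn))
      if (o$tp > 0) {
        got <- m$pairs[order(m$pairs$pred_index),
                       c("pred_index", "truth_index")]
        want <- o$pairs[order(o$pairs[, 1]), , drop = FALSE]
        expect_identical(as.integer(got$pred_index), as.integer(want[, 1]))
        expect_identical(as.integer(got$truth_index), as.integer(want[, 2]))
      }
      # bookkeeping identities
      expect_identical(row$tp + row$fp, np)
      expect_identical(row$tp + row$fn, nt)
    }
  })
})

test_that("precision and recall follow their definitions with 0/0 -> 0", {
  mk <- function(tp, fp, fn) structure(list(
    counts = tibble::tibble(class = 0:2,
                            class_name = cell_classes(),
                            tp = tp, fp = fp, fn = fn),
    pairs = NULL), class = "match_result")
  expect_warning(
    pr <- precision_recall(mk(c(5L, 3L, 0L), c(0L, 1L, 0L), c(0L, 2L, 4L))),
    "undefined")  # class 2 has no predictions: 0/0 precision
  expect_equal(pr$precision[1:2], c(1, 0.75))
  expect_equal(pr$recall[1:2], c(1, 0.6))
  expect_warning(
    pr0 <- precision_recall(mk(c(0L, 0L, 0L), c(0L, 0L, 0L), c(4L, 0L, 0L))),
    "undefined")
  expect_equal(pr0$precision, c(0, 0, 0))
  expect_equal(pr0$recall[1], 0)
})

test_that("F1 reproduces published worked examples and its bounds", {
  expect_equal(f1_score(1, 1), 1)
  expect_equal(round(f1_score(0.8436, 0.8611), 4), 0.8523)
  expect_equal(round(f1_score(0.7466, 0.8198), 4), 0.7815)
  expect_equal(f1_score(0, 0), 0)
  withr::with_seed(10, {
    p <- runif(200); r <- runif(200)
    f <- f1_score(p, r)
    expect_equal(f, f1_score(r, p))                # symmetry
    expect_true(all(f <= (p + r) / 2 + 1e-12))     # <= arithmetic mean
    expect_true(all(f <= 2 * pmin(p, r) + 1e-12))
    expect_true(all(f >= 0 & f <= 1))
  })
})

test_that("support-weighted averages reproduce the published table", {
  expect_equal(weighted_average(c(0.5, 0.5, 0.5), c(1, 2, 3)), 0.5)
  support <- shidc_cell_counts()
  support <- support$cells[support$set == "test"]
  expect_equal(round(weighted_average(c(0.8523, 0.7815, 0.379), support), 4),
               0.7928)
  expect_equal(round(weighted_average(c(0.8611, 0.8198, 0.4246), support), 4),
               0.8219)
  expect_error(weighted_average(c(1, 1, 1), c(0, 0, 0)), "support")
  expect_error(weighted_average(c(1, 1), c(1, 1, 1)), "equal length")
})

test_that("Ki-67 index and TILs score follow their defining ratios", {
  expect_equal(ki67_index(0, 50), 0)
  expect_equal(ki67_index(100, 300), 0.25)
  for (k in c(1, 7, 500)) expect_equal(ki67_index(k, k), 0.5)
  expect_error(ki67_index(0, 0), "undefined")

  expect_equal(til_score(0, 10, 10), 0)
  expect_equal(til_score(10, 45, 45), 0.1)
  expect_equal(til_score(33, 0, 0), 1)
  expect_error(til_score(0, 0, 0), "undefined")
})

test_that("clinical cut-off classification matches the published bands", {
  expect_identical(as.character(classify_ki67_cutoff(10.66)), "low")
  expect_identical(as.character(classify_ki67_cutoff(16)), "intermediate")
  expect_identical(as.character(classify_ki67_cutoff(30)), "intermediate")
  expect_identical(as.character(classify_ki67_cutoff(30.0001)), "high")
  expect_identical(as.character(classify_ki67_cutoff(15.999)), "low")

  expect_identical(as.character(classify_til_cutoff(9.58)), "low")
  expect_identical(as.character(classify_til_cutoff(10)), "low")
  expect_identical(as.character(classify_til_cutoff(25)), "intermediate")
  expect_identical(as.character(classify_til_cutoff(40)), "high")
})

test_that("rmse matches direct arithmetic", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0.2, 0.4), c(0.2, 0.5)), sqrt(0.005))
  expect_equal(rmse(c(1, 2, 3) + 0.3, c(1, 2, 3)), 0.3)
  expect_error(rmse(numeric(0), numeric(0)), "non-empty")
  expect_error(rmse(1:3, 1:2), "equal length")
})

test_that("patient aggregation is a ratio of summed counts", {
  one <- data.frame(patient_id = "P1", immunopositive = 10,
                    immunonegative = 30, lymphocyte = 0)
  a1 <- aggregate_patients(one)
  expect_equal(a1$ki67_index, 0.25)
  expect_equal(a1$til_score, 0)

  two <- rbind(one, data.frame(patient_id = "P1", immunopositive = 30,
                               immunonegative = 30, lymphocyte = 20))
  a2 <- aggregate_patients(two)
  expect_equal(a2$immunopositive, 40)
  expect_equal(a2$ki67_index, 0.4)
  expect_equal(a2$til_score, 1 / 6)
  expect_identical(as.character(a2$ki67_category), "high")

  # order invariance over image permutations
  a3 <- aggregate_patients(two[2:1, ])
  expect_equal(a2, a3)

  # ratio of sums differs from mean of per-image ratios
  expect_false(isTRUE(all.equal(a2$ki67_index, mean(c(0.25, 0.5)))))
})

test_that("tidiers expose per-class and summary views", {
  truth <- random_annotation_set(30, seed = 5)
  m <- match_detections(truth, truth, match_config(10))
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 3L)
  gl <- glance(m)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$f1, 1)
  sr <- score_report(m)
  expect_equal(glance(sr)$ki67_index,
               ki67_index(sum(truth$points$class == 0),
                          sum(truth$points$class == 1)))
})
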