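test_that("confusion metrics follow the three ratio definitions", {
  m <- confusion_metrics(tp = 5, fp = 0, tn = 10, fn = 5)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 1.0)
  expect_equal(m$precision, 1.0)
  expect_length(m$undefined, 0)
  # degenerate: no positive calls -> precision flagged, reported 0
  m2 <- confusion_metrics(tp = 0, fp = 0, tn = 5, fn = 3)
  expect_equal(m2$precision, 0)
  expect_true("precision" %in% m2$undefined)
  expect_error(confusion_metrics(0, 0, 0, 0), "zero")
  expect_error(confusion_metrics(-1, 1, 1, 1), "non-negative")
})

test_that("confusion metrics match direct arithmetic on random counts", {
  set.seed(17)
  for (i in 1:50) {
    cc <- as.list(rpois(4, 20) + 1)
    names(cc) <- c("tp", "fp", "tn", "fn")
    m <- confusion_metrics(cc)
    expect_equal(m$sensitivity, cc$tp / (cc$tp + cc$fn))
    expect_equal(m$specificity, cc$tn / (cc$tn + cc$fp))
    expect_equal(m$precision, cc$tp / (cc$tp + cc$fp))
    # Eq identity on integer counts
    expect_equal(m$sensitivity * (cc$tp + cc$fn), cc$tp)
  }
})

test_that("MCC closed forms hold, including the degenerate convention", {
  expect_equal(mcc(tp = 5, fp = 0, tn = 5, fn = 0), 1.0)
  expect_equal(mcc(tp = 5, fp = 5, tn = 5, fn = 5), 0.0)
  expect_equal(mcc(tp = 6, fp = 1, tn = 8, fn = 2), 46 / sqrt(5040))
  expect_equal(mcc(tp = 0, fp = 0, tn = 10, fn = 5), 0)  # zero factor -> 0
  expect_equal(mcc(tp = 0, fp = 5, tn = 10, fn = 5), mcc(list(tp = 0, fp = 5, tn = 10, fn = 5)))
  set.seed(23)
  for (i in 1:50) {
    v <- rpois(4, 15)
    expect_gte(mcc(v[1], v[2], v[3], v[4]), -1)
    expect_lte(mcc(v[1], v[2], v[3], v[4]), 1)
  }
})

test_that("MCC arithmetic does not overflow on genome-scale counts", {
  expect_equal(mcc(tp = 1e5, fp = 1e5, tn = 1e5, fn = 1e5), 0)
  expect_equal(mcc(tp = 1e6, fp = 10, tn = 1e6, fn = 10),
               (1e12 - 100) / sqrt((1e6 + 10)^4))
})

test_that("term averages are unweighted means over evaluated terms", {
  df <- data.frame(term_id = c("a", "b", "c"), status = c("ok", "ok", "skipped"),
                   sensitivity = c(0.2, 0.4, NA), specificity = c(1, 0.5, NA),
                   precision = c(0.1, 0.3, NA), mcc = c(0, 0.2, NA))
  av <- average_over_terms(df)
  expect_equal(av$sensitivity, 0.3)
  expect_equal(av$specificity, 0.75)
  expect_equal(av$precision, 0.2)
  expect_equal(av$n_terms, 2)
  expect_equal(av$n_skipped, 1)
  expect_equal(average_over_terms(df[1, ])$sensitivity, 0.2)
  expect_error(average_over_terms(df[df$status == "none", ]), "no evaluated")
})

test_that("better-than-random compares TPR with FPR", {
  expect_true(better_than_random(0.5, 0.9))
  expect_false(better_than_random(0.25, 0.75))  # on the random line
  expect_false(better_than_random(0.05, 0.9))
  expect_true(better_than_random(list(sensitivity = 0.5, specificity = 0.9,
                                      precision = 1, undefined = character(0))))
})

test_that("test-set sampling is a seeded partition with default size 105", {
  ids <- sprintf("i%04d", 1:500)
  s <- sample_test_set(ids, seed = 9)
  expect_length(s$test, 105)
  expect_length(intersect(s$test, s$train), 0)
  expect_setequal(c(s$test, s$train), ids)
  expect_identical(s$test, sample_test_set(ids, seed = 9)$test)
  expect_false(identical(s$test, sample_test_set(ids, seed = 10)$test))
  expect_error(sample_test_set(ids[1:50], n = 50), "smaller")
})

test_that("PR analysis handles perfect and empty prediction sets", {
  known <- list(r1 = c("t1", "t2"))
  pred <- data.frame(idr_id = "r1", term_id = c("t1", "t2"),
                     probability = c(1, 1))
  curve <- pr_analysis(pred, known, test_ids = "r1",
                       prob_grid = c(0, 0.5, 1))
  expect_true(all(curve$points$overall_precision == 1))
  expect_true(all(curve$points$average_recall == 1))
  # threshold above every emitted probability
  pred2 <- data.frame(idr_id = "r1", term_id = "t1", probability = 0.4)
  c2 <- pr_analysis(pred2, known, test_ids = "r1", prob_grid = c(0.9))
  expect_equal(c2$points$overall_precision, 0)
  expect_equal(c2$points$average_recall, 0)
  expect_equal(c2$points$n_correct, 0)
  expect_error(pr_analysis(pred, known, test_ids = character(0)), "empty")
  expect_error(pr_analysis(pred, known, test_ids = "r1", prob_grid = c(-1)),
               "0, 1")
})

test_that("PR analysis equals the brute-force set-comparison oracle", {
  set.seed(29)
  grid <- seq(0, 1, by = 0.05)
  for (trial in 1:40) {
    n_idr <- sample(1:10, 1)
    terms <- paste0("t", 1:sample(2:8, 1))
    ids <- paste0("r", 1:n_idr)
    known <- lapply(ids, function(i) sample(terms, sample(1:length(terms), 1)))
    names(known) <- ids
    pred <- expand.grid(idr_id = ids, term_id = terms,
                        stringsAsFactors = FALSE)
    pred <- pred[runif(nrow(pred)) < 0.8, , drop = FALSE]
    pred$probability <- round(runif(nrow(pred)), 2)
    curve <- pr_analysis(pred, known, test_ids = ids, prob_grid = grid)
    orc <- oracle_pr(pred, known, ids, grid)
    expect_equal(curve$points$overall_precision, orc$overall_precision)
    expect_equal(curve$points$average_recall, orc$average_recall)
    expect_equal(curve$points$mean_idr_precision, orc$mean_idr_precision)
    expect_equal(curve$points$n_correct, orc$n_correct)
  }
})

test_that("average recall and n_correct are non-increasing in the threshold", {
  set.seed(37)
  ids <- paste0("r", 1:20)
  terms <- paste0("t", 1:6)
  known <- lapply(ids, function(i) sample(terms, sample(1:4, 1)))
  names(known) <- ids
  pred <- expand.grid(idr_id = ids, term_id = terms, stringsAsFactors = FALSE)
  pred$probability <- runif(nrow(pred))
  curve <- pr_analysis(pred, known, test_ids = ids)
  expect_true(all(diff(curve$points$average_recall) <= 1e-12))
  expect_true(all(diff(curve$points$n_correct) <= 0))
  expect_true(all(curve$points$overall_precision >= 0 &
                  curve$points$overall_precision <= 1))
})

test_that("term_metrics attaches per-term metrics and keeps skipped rows NA", {
  cv <- data.frame(term_id = c("a", "b"), family = "f",
                   status = c("ok", "skipped"), reason = c(NA, "few"),
                   n_train_pos = c(30, 2), tp = c(6, NA), fp = c(1, NA),
                   tn = c(8, NA), fn = c(2, NA))
  met <- term_metrics(cv)
  expect_equal(met$mcc[1], 46 / sqrt(5040))
  expect_equal(met$sensitivity[1], 0.75)
  expect_true(is.na(met$mcc[2]))
})
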