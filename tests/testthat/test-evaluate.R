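test_that("AUROC matches worked examples and handles ties", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))$auroc, 0.75)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auroc, 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4))$auroc, 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("AUROC equals brute-force pair counting and its own curve area", {
  set.seed(1)
  for (rep in 1:30) {
    n <- sample(10:200, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, runif(1, 0.2, 0.8)))
    probs <- round(runif(n), sample(1:2, 1))  # coarse -> many ties
    r <- roc_auc(labels, probs)
    expect_equal(r$auroc, oracle_auc(labels, probs), tolerance = 1e-12)
    # trapezoidal area under the returned curve
    fpr <- 1 - r$curve$specificity; tpr <- r$curve$sensitivity
    area <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    expect_equal(area, r$auroc, tolerance = 1e-12)
  }
})

test_that("operating point equals the exhaustive threshold sweep", {
  expect_equal(operating_point(roc_auc(c(0, 0, 1, 1),
                                       c(0.1, 0.2, 0.8, 0.9))$curve),
               list(sensitivity = 1, specificity = 1, threshold = 0.8))
  set.seed(2)
  for (rep in 1:30) {
    n <- 50
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    probs <- round(runif(n), 2)
    op <- operating_point(roc_auc(labels, probs)$curve)
    oracle <- oracle_operating_point(labels, probs)
    expect_equal(op$sensitivity + op$specificity - 1, oracle$j,
                 tolerance = 1e-12)
    expect_equal(op$sensitivity, oracle$sens, tolerance = 1e-12)
    expect_equal(op$threshold, oracle$t, tolerance = 1e-12)
  }
})

test_that("random scores give a near-zero Youden J", {
  set.seed(3)
  js <- replicate(50, {
    labels <- rbinom(200, 1, 0.5)
    probs <- runif(200)
    op <- operating_point(roc_auc(labels, probs)$curve)
    op$sensitivity + op$specificity - 1
  })
  expect_gte(min(js), 0)      # J at the maximizer is never negative
  expect_lt(mean(js), 0.3)    # but stays small without signal
})

test_that("AUPRC baseline equals positive prevalence; perfect ranking gives 1", {
  labels <- c(rep(1, 54), rep(0, 67))
  r <- auprc_with_baseline(labels, seq_along(labels) * -1)
  expect_equal(r$baseline, 54 / 121)
  expect_equal(round(r$baseline, 2), 0.45)
  perfect <- auprc_with_baseline(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(perfect$auprc, 1)
  expect_error(auprc_with_baseline(rep(1, 5), runif(5)), "both classes")
})

test_that("AUPRC of random scores converges to the baseline", {
  set.seed(4)
  res <- replicate(200, {
    labels <- c(rep(1, 40), rep(0, 120))
    r <- auprc_with_baseline(labels, runif(160))
    r$auprc
  })
  expect_lt(abs(mean(res) - 0.25), 0.03)
})

test_that("DeLong interval contains the AUROC and matches a bootstrap", {
  set.seed(5)
  labels <- rep(c(1, 0), each = 300)
  probs <- c(rnorm(300, 1), rnorm(300, 0))
  auc <- roc_auc(labels, probs)$auroc
  ci <- delong_ci(labels, probs)
  expect_lte(ci[1], auc); expect_gte(ci[2], auc)
  boot <- oracle_bootstrap_ci(labels, probs, n_boot = 1000)
  expect_lt(abs(ci[1] - boot[1]), 0.03)
  expect_lt(abs(ci[2] - boot[2]), 0.03)
  # degenerate separation collapses the interval with a warning
  expect_warning(ci0 <- delong_ci(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)),
                 "separation")
  expect_equal(ci0, c(1, 1))
  expect_error(delong_ci(c(0, 1, 1), c(0.1, 0.5, 0.9)), "2 samples")
})

test_that("tenfold larger samples shrink the DeLong interval", {
  set.seed(6)
  width <- function(n) {
    mean(replicate(10, {
      labels <- rep(c(1, 0), each = n)
      probs <- c(rnorm(n, 0.8), rnorm(n))
      diff(delong_ci(labels, probs))
    }))
  }
  expect_lt(width(400), width(40))
})

test_that("confusion counts and accuracy match a direct recount", {
  set.seed(7)
  labels <- rbinom(80, 1, 0.4)
  probs <- runif(80)
  cm <- confusion_accuracy(labels, probs, 0.5)
  expect_equal(sum(cm$matrix), 80)
  expect_equal(cm$matrix["1", "1"], sum(labels == 1 & probs >= 0.5))
  expect_equal(cm$matrix["0", "0"], sum(labels == 0 & probs < 0.5))
  expect_equal(cm$accuracy, mean((probs >= 0.5) == labels))
  allneg <- confusion_accuracy(labels, probs, 2)
  expect_equal(sum(allneg$matrix[, "1"]), 0)
  perfect <- confusion_accuracy(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9), 0.5)
  expect_equal(perfect$matrix["0", "1"] + perfect$matrix["1", "0"], 0)
})

test_that("calibration errors behave as mean and max of the same curve", {
  set.seed(8)
  p <- runif(300)
  y <- rbinom(300, 1, p)
  r <- calibration_report(y, p)
  expect_gte(r$emax, r$ici)
  expect_gte(r$ici, 0)
  expect_error(calibration_report(y[1:10], p[1:10]), "20")
  # miscalibrated (doubled odds) probabilities score worse
  odds <- p / (1 - p) * 4
  p_bad <- odds / (1 + odds)
  r_bad <- calibration_report(y, p_bad)
  expect_gt(r_bad$ici, r$ici)
})

test_that("signal relevance follows the top-k counting rules", {
  rounds <- lapply(1:10, function(r) {
    gains <- c(HR__mean = 1, HR__sd = 0.9, RR__mean = 0.8, RR__sd = 0.7,
               MAP__mean = 0.6, MAP__sd = 0.5)
    # HR into the top-5 in 3 of 10 rounds: otherwise push both HR features
    # below five other columns
    if (r > 3) {
      gains <- c(RR__mean = 1, RR__sd = 0.9, MAP__mean = 0.8,
                 MAP__sd = 0.7, SPO2__mean = 0.6, HR__mean = 0.1,
                 HR__sd = 0.05)
    }
    make_round(sprintf("P%02d", r), gains)
  })
  rel <- signal_relevance(make_cv(rounds), k = 5)
  expect_equal(rel$relevance[rel$signal == "HR"], 0.3)
  expect_equal(rel$times_used[rel$signal == "HR"], 10)
  # two features of one signal in the top-5 count once per round
  expect_equal(rel$times_in_topk[rel$signal == "RR"], 10)
  expect_true(all(rel$times_in_topk <= rel$times_used))
  expect_error(signal_relevance(make_cv(rounds), k = 0), "k")
})

test_that("unused signals are excluded and relevance is rank-invariant", {
  r1 <- make_round("P01", c(HR__mean = 1, RR__mean = 0.5))
  rel <- signal_relevance(make_cv(list(r1)), k = 1)
  expect_false("MAP" %in% rel$signal)
  # monotone transform of the gains leaves relevance unchanged
  r2 <- make_round("P01", c(HR__mean = exp(1), RR__mean = exp(0.5)))
  expect_equal(signal_relevance(make_cv(list(r1)), k = 1)$relevance,
               signal_relevance(make_cv(list(r2)), k = 1)$relevance)
})

test_that("the evaluation report is internally consistent", {
  set.seed(9)
  n <- 60
  label <- rbinom(n, 1, 0.4)
  prob <- plogis(2 * label + rnorm(n) - 1)
  cv <- structure(list(
    predictions = tibble::tibble(sample_id = sprintf("S%02d", 1:n),
                                 patient_id = sprintf("P%02d", 1:n),
                                 label = label, prob = prob, round = 1:n),
    rounds = list(make_round("P01", c(HR__mean = 1, RR__mean = 0.5))),
    skipped = tibble::tibble(), config = NULL), class = "nv_cv")
  ev <- evaluate_cv(cv)
  expect_s3_class(ev, "nv_eval")
  expect_true(ev$ci_low <= ev$auroc && ev$auroc <= ev$ci_high)
  expect_equal(sum(ev$confusion), n)
  expect_equal(ev$n_pos + ev$n_neg, n)
  expect_gte(ev$calibration$emax, ev$calibration$ici)
  g <- glance(ev)
  expect_equal(nrow(g), 1)
  expect_equal(g$auroc, ev$auroc)
  td <- tidy(ev)
  expect_true(all(c("signal", "relevance") %in% names(td)))
})
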