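test_that("summary metrics match hand arithmetic and degenerate rules", {
  m <- summary_metrics(confusion_counts(tp = 8, fp = 2, fn = 2, tn = 88))
  expect_equal(m$precision, 0.8)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$f_score, 0.8)
  expect_equal(m$accuracy, 0.96)
  perfect <- summary_metrics(pixel_confusion(c(1, 0, 1), c(1, 0, 1)))
  expect_true(all(as.numeric(perfect[1, ]) == 1))
  # no predicted positives: precision undefined (flagged), F defined as 0
  d <- summary_metrics(confusion_counts(tp = 0, fp = 0, fn = 5, tn = 95))
  expect_true(is.na(d$precision))
  expect_match(paste(attr(d, "notes"), collapse = "; "), "precision")
  expect_equal(d$f_score, 0)
  expect_error(summary_metrics(confusion_counts(0, 0, 0, 0)), "zero")
})

test_that("pixel confusion equals the pixel-loop oracle", {
  expect_equal(
    unclass(pixel_confusion(matrix(c(rep(1, 10), rep(0, 90)), 10),
                            matrix(c(rep(1, 10), rep(0, 90)), 10)))[1:4],
    list(tp = 10L, fp = 0L, fn = 0L, tn = 90L))
  set.seed(44)
  for (rep in 1:20) {
    p <- matrix(as.integer(runif(150) < 0.3), 10)
    t <- matrix(as.integer(runif(150) < 0.3), 10)
    got <- pixel_confusion(p, t)
    want <- oracle_confusion(as.vector(p), as.vector(t))
    expect_equal(unclass(got)[c("tp", "fp", "fn", "tn")], want)
  }
  expect_error(pixel_confusion(matrix(0, 2, 3), matrix(0, 3, 2)),
               "shapes differ")
})

test_that("detection evaluation counts volumes and is swap-symmetric", {
  pred <- c(rep(TRUE, 86), rep(FALSE, 14), rep(FALSE, 94), rep(TRUE, 6))
  truth <- c(rep(TRUE, 100), rep(FALSE, 100))
  ev <- detection_eval(pred, truth)
  expect_equal(ev$metrics$sensitivity, 0.86)
  expect_equal(ev$metrics$specificity, 0.94)
  sw <- detection_eval(truth, pred)
  expect_equal(sw$counts$fp, ev$counts$fn)
  expect_equal(sw$counts$fn, ev$counts$fp)
  agree <- detection_eval(truth, truth)
  expect_equal(agree$metrics$accuracy, 1)
  expect_error(detection_eval(logical(0), logical(0)), "non-empty")
})

test_that("accuracy is the prevalence-weighted mix of sens and spec", {
  set.seed(13)
  for (rep in 1:10) {
    pred <- runif(200) < 0.4
    truth <- runif(200) < runif(1, 0.2, 0.8)
    m <- detection_eval(pred, truth)$metrics
    prev <- mean(truth)
    expect_equal(m$accuracy,
                 prev * m$sensitivity + (1 - prev) * m$specificity)
  }
})

test_that("pearson agreement reproduces exact and formula values", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_agreement(2 * x + 1, x)$r, 1)
  expect_equal(pearson_agreement(-x, x)$r, -1)
  set.seed(9)
  a <- rnorm(10); b <- 0.5 * a + rnorm(10)
  got <- pearson_agreement(a, b)
  expect_equal(got$r, oracle_pearson(a, b), tolerance = 1e-12)
  # p-value via the explicit t transform on n - 2 df
  tstat <- got$r * sqrt(8 / (1 - got$r^2))
  expect_equal(got$p_value, 2 * stats::pt(-abs(tstat), 8), tolerance = 1e-12)
  expect_error(pearson_agreement(rep(1, 5), 1:5), "constant")
  expect_error(pearson_agreement(1:2, 1:2), "at least 3")
})

test_that("icc agreement matches the ANOVA mean-squares oracle", {
  # identical vectors -> perfect agreement
  v <- c(3, 7, 1, 9, 4, 6, 2, 8)
  expect_equal(icc_agreement(v, v)$icc, 1)
  # fixed 8-pair table vs the from-scratch aov decomposition
  x <- c(9, 6, 8, 7, 10, 6, 5, 8)
  y <- c(2, 1, 4, 1, 5, 2, 1, 3)
  got <- icc_agreement(x, y)
  expect_equal(got$icc, oracle_icc_a1(x, y), tolerance = 1e-10)
  expect_lte(got$ci_low, got$icc)
  expect_gte(got$ci_high, got$icc)
  expect_lte(got$icc, 1)
  # independent noise at n = 200 gives near-zero agreement
  set.seed(77)
  a <- rnorm(200); b <- rnorm(200)
  expect_lt(abs(icc_agreement(a, b)$icc), 0.2)
  # consistency ICC equals pearson r exactly when the two vectors share
  # mean and variance (the agreement form differs by the rater-mean term)
  p <- c(1, 4, 2, 6, 5, 3, 8, 7)
  q <- rev(p)  # same mean and variance by construction
  expect_equal(icc_agreement(p, q, variant = "consistency")$icc,
               oracle_pearson(p, q), tolerance = 1e-12)
  expect_error(icc_agreement(1:4, 1:4), "at least 5")
  expect_error(icc_agreement(rep(2, 6), rep(2, 6)), "degenerate")
})

test_that("icc consistency variant ignores a constant rater offset", {
  set.seed(15)
  a <- rnorm(50)
  b <- a + 5
  expect_equal(icc_agreement(a, b, variant = "consistency")$icc, 1,
               tolerance = 1e-9)
  expect_lt(icc_agreement(a, b)$icc, 0.5)
})

test_that("roc curve matches the sweep oracle and pROC", {
  truth <- c(rep(1, 20), rep(0, 30))
  perfect <- roc_curve(truth, truth)
  expect_equal(perfect$auc, 1)
  set.seed(23)
  conf <- runif(500)
  lab <- as.integer(runif(500) < plogis(4 * conf - 2))
  rc <- roc_curve(conf, lab)
  expect_equal(rc$auc, oracle_roc_auc(conf, lab), tolerance = 1e-12)
  expect_true(all(diff(rc$points$tpr) >= 0))
  expect_true(all(diff(rc$points$fpr) >= 0))
  expect_equal(rc$points$tpr[1], 0)
  expect_equal(utils::tail(rc$points$fpr, 1), 1)
  skip_if_not_installed("pROC")
  pr <- pROC::roc(lab, conf, quiet = TRUE, direction = "<")
  expect_equal(rc$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
})

test_that("auc is invariant under strictly monotone confidence transforms", {
  set.seed(31)
  conf <- runif(400)
  lab <- as.integer(runif(400) < conf)
  base <- roc_curve(conf, lab)$auc
  expect_equal(roc_curve(conf^3, lab)$auc, base, tolerance = 1e-12)
  expect_equal(roc_curve(plogis(5 * conf - 2), lab)$auc, base,
               tolerance = 1e-12)
  # uninformative confidences sit near the diagonal
  set.seed(32)
  conf2 <- runif(10000)
  lab2 <- as.integer(runif(10000) < 0.3)
  expect_equal(roc_curve(conf2, lab2)$auc, 0.5, tolerance = 0.05)
  expect_error(roc_curve(conf2, rep(1, 10000)), "single class")
})
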