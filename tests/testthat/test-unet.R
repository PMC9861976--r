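desk_tiny <- function(seed = 1) {
  train_config(input_size = 16, depth = 2, base_filters = 2,
               samples_per_epoch = 8, batch_size = 4, max_epochs = 3,
               seed = seed)
}

test_that("model output matches input shape with confidences in [0, 1]", {
  m <- build_model(desk_tiny())
  img <- matrix(rnorm(32 * 24), 32, 24)  # non-square, off-grid size
  p <- predict(m, img)
  expect_equal(dim(p), c(32, 24))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("configuration invariants are enforced", {
  expect_error(train_config(input_size = 100, depth = 3), "divisible")
  expect_error(train_config(kernel_width = 4), "kernel_width")
  expect_error(train_config(early_stop_patience = 0), "early_stop_patience")
})

test_that("the paper-scale architecture has on the order of 2e7 parameters", {
  m <- build_model(train_config("paper_scale"))
  np <- n_parameters(m)
  expect_gte(np, 1e7)
  expect_lte(np, 3e7)
})

test_that("backpropagated gradients match finite differences", {
  cfg <- train_config(input_size = 8, depth = 1, base_filters = 2, seed = 3)
  m <- build_model(cfg)
  withr::with_seed(4, {
    x <- rnorm(64)
    y <- as.numeric(runif(64) < 0.3)
  })
  fw <- gaquant:::unet_forward(m, x, cache = TRUE)
  g <- gaquant:::unet_backward(m, fw, y)
  loss_at <- function(mm) gaquant:::bce_loss(gaquant:::unet_forward(mm, x)$p, y)
  eps <- 1e-6
  set.seed(5)
  for (ci in seq_along(m$convs)) {
    i <- sample(length(m$convs[[ci]]$W), 1)
    mp <- m; mp$convs[[ci]]$W[i] <- mp$convs[[ci]]$W[i] + eps
    mm2 <- m; mm2$convs[[ci]]$W[i] <- mm2$convs[[ci]]$W[i] - eps
    num <- (loss_at(mp) - loss_at(mm2)) / (2 * eps)
    expect_equal(g$gW[[ci]][i], num, tolerance = 1e-4)
  }
})

test_that("training is deterministic given the seed and restores best weights", {
  set.seed(60)
  items <- lapply(1:8, function(i) {
    y <- matrix(0L, 16, 16)
    y[4:9, (i %% 3 + 2):(i %% 3 + 8)] <- 1L
    list(x = y + matrix(rnorm(256, sd = 0.2), 16, 16), y = y)
  })
  cfg <- desk_tiny(seed = 8)
  f1 <- fit_unet(build_model(cfg), items[1:6], items[7:8])
  f2 <- fit_unet(build_model(cfg), items[1:6], items[7:8])
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$convs, f2$model$convs)
  expect_true(f1$model$trained)
  h <- f1$history
  expect_equal(min(h$val_loss), h$val_loss[attr(h, "best_epoch")])
  expect_s3_class(glance(h), "tbl_df")
  expect_error(fit_unet(build_model(cfg), items[1:6], list()), "validation")
  bad <- items; bad[[1]]$y[1] <- 0.5
  expect_error(fit_unet(build_model(cfg), bad[1:2], items[7:8]), "binary")
})

test_that("early stopping fires after patience epochs without improvement", {
  run_rule <- function(losses, patience, max_epochs) {
    st <- NULL
    for (l in losses[seq_len(max_epochs)]) {
      st <- gaquant:::stop_state_update(st, l, patience)
      if (st$stop) break
    }
    st
  }
  # strictly decreasing losses never trip the rule: run to max epochs
  st <- run_rule(seq(2, 0.1, length.out = 20), 7, 20)
  expect_false(st$stop)
  expect_equal(st$epoch, 20)
  expect_equal(st$best_epoch, 20)
  # flat after epoch 3 with patience 7: stop at epoch 10
  st <- run_rule(c(0.5, 0.4, 0.3, rep(0.3, 17)), 7, 20)
  expect_true(st$stop)
  expect_equal(st$epoch, 10)
  expect_equal(st$best_epoch, 3)
  # a late improvement resets the counter
  st <- run_rule(c(0.5, 0.4, 0.45, 0.44, 0.3, rep(0.31, 7)), 3, 12)
  expect_true(st$stop)
  expect_equal(st$epoch, 8)
  expect_equal(st$best_epoch, 5)
})

test_that("hard-example selection duplicates exactly the sub-percentile items", {
  # mining selection on controlled F-score configurations
  sel <- gaquant:::mining_selection(rep(0.7, 10), rep(0.7, 50), 30)
  expect_equal(sel$threshold, 0.7)
  expect_length(sel$duplicated_idx, 0)
  f <- seq(0, 0.99, by = 0.01)
  sel2 <- gaquant:::mining_selection(f, f, 30)
  expect_equal(sel2$threshold, oracle_percentile(f, 30), tolerance = 1e-12)
  expect_equal(sel2$duplicated_idx, which(f < oracle_percentile(f, 30)))
  set.seed(40)
  for (rep in 1:30) {
    fs <- runif(sample(5:60, 1))
    fa <- runif(sample(5:80, 1))
    p <- runif(1, 5, 95)
    sel3 <- gaquant:::mining_selection(fs, fa, p)
    expect_equal(sel3$threshold, oracle_percentile(fs, p),
                 tolerance = 1e-12)
    expect_equal(sel3$duplicated_idx, which(fa < sel3$threshold))
  }
})

test_that("mining augments without removing and at most doubles the set", {
  set.seed(62)
  items <- lapply(1:10, function(i) {
    y <- matrix(0L, 16, 16)
    if (i %% 2 == 0) y[3:10, 3:10] <- 1L
    list(x = y + matrix(rnorm(256, sd = 0.3), 16, 16), y = y)
  })
  f <- fit_unet(build_model(desk_tiny(9)), items[1:8], items[9:10])
  aug <- mine_hard_examples(f$model, items[1:8], sample_n = 5, seed = 3)
  n_dup <- length(attr(aug, "duplicated_idx"))
  expect_equal(length(aug), 8 + n_dup)
  expect_lte(length(aug), 16)
  expect_identical(aug[1:8], items[1:8])  # originals retained, order stable
  expect_identical(aug[8 + seq_len(n_dup)],
                   items[attr(aug, "duplicated_idx")])
  expect_error(mine_hard_examples(build_model(desk_tiny()), items),
               "not been trained")
  # retraining continues from the trained weights
  f2 <- retrain_unet(f$model, aug, items[9:10])
  expect_true(f2$model$trained)
  expect_equal(nrow(f2$history) >= 1, TRUE)
})

test_that("binarize thresholding of predictions is monotone", {
  m <- build_model(desk_tiny())
  p <- predict(m, matrix(rnorm(256), 16, 16))
  expect_true(all(binarize(p, 0.9) <= binarize(p, 0.1)))
  expect_equal(sum(binarize(matrix(0.3, 4, 4), 0.5)), 0)
})
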