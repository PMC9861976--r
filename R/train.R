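#' Patient-grouped train/validation/test split
#'
#' Assigns every patient -- and therefore every one of their timepoints --
#' to exactly one of the train/validation/test sets, so no patient's scans
#' leak between training and testing. Patients are shuffled with the seed
#' and allocated contiguously; per-split patient counts come from the
#' largest-remainder rule, so each realized count is within one patient of
#' its target fraction.
#'
#' @param patients A data frame with a `patient_id` column (repeated rows,
#'   e.g. one per timepoint, are fine and inherit the patient's split).
#' @param fractions Named numeric vector summing to 1; defaults to
#'   80/10/10 train/val/test.
#' @param seed Integer seed for the shuffle.
#' @return The input data frame with a `split` factor column appended.
#' @examples
#' pts <- tibble::tibble(patient_id = rep(1:10, each = 3),
#'                       timepoint_id = rep(1:3, 10))
#' table(patient_split(pts, seed = 1)$split) / 3
#' @export
patient_split <- function(patients,
                          fractions = c(train = 0.8, val = 0.1, test = 0.1),
                          seed = 1L) {
  if (!"patient_id" %in% names(patients)) {
    stop("`patients` needs a patient_id column", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  ids <- unique(patients$patient_id)
  n <- length(ids)
  if (n < sum(fractions > 0)) {
    stop("fewer patients than nonempty splits", call. = FALSE)
  }
  withr::local_seed(seed)
  ids <- sample(ids)
  base <- floor(fractions * n)
  remainder <- n - sum(base)
  if (remainder > 0) {
    extra <- order(fractions * n - base, decreasing = TRUE)[seq_len(remainder)]
    base[extra] <- base[extra] + 1
  }
  split_of <- rep(names(fractions), times = base)
  assignment <- stats::setNames(split_of, ids)
  out <- patients
  out$split <- factor(assignment[as.character(out$patient_id)],
                      levels = names(fractions))
  out
}

#' Build training items from phantoms
#'
#' Converts simulated volumes into (input image, binary target) pairs for
#' the two model flavors. The `"enface"` flavor pairs the mean-projection
#' en face intensity image with the en face GA truth map (one item per
#' volume); the `"bscan"` flavor pairs each intensity B-scan with its
#' dilated BM-band ground-truth mask (one item per B-scan). Images keep
#' their native resolution; resizing to the model grid happens inside
#' [fit_unet()]/[predict.ga_unet()].
#'
#' @param phantoms List of `oct_phantom` objects (rendered with
#'   intensity).
#' @param flavor `"enface"` or `"bscan"`.
#' @param tol_px,thickness_px Ground-truth mask parameters (bscan flavor).
#' @return List of items, each `list(x = matrix, y = binary matrix)`.
#' @export
make_training_items <- function(phantoms, flavor = c("enface", "bscan"),
                                tol_px = 0.5, thickness_px = 10) {
  flavor <- match.arg(flavor)
  items <- list()
  for (ph in phantoms) {
    if (is.null(ph$intensity)) {
      stop("phantom has no intensity cube; simulate with render = TRUE",
           call. = FALSE)
    }
    if (flavor == "enface") {
      x <- unclass(enface_intensity(ph$intensity, ph$geometry))
      y <- ph$truth_enface
      items[[length(items) + 1]] <- list(x = x, y = y)
    } else {
      masks <- mask_volume(ph$layers, ph$geometry, tol_px, thickness_px)
      for (b in seq_along(masks)) {
        items[[length(items) + 1]] <-
          list(x = ph$intensity[[b]], y = masks[[b]]$mask * 1L)
      }
    }
  }
  items
}

prep_items <- function(items, input_size) {
  lapply(items, function(it) {
    # area-style downsampling of the binary target (bilinear then majority)
    # keeps boundary labels faithful where nearest-neighbour would pick an
    # arbitrary corner pixel of each block
    yb <- resize_bilinear((unclass(it$y) > 0) * 1, input_size, input_size)
    list(
      x = as.numeric(standardize_image(
        resize_bilinear(it$x, input_size, input_size))),
      y = as.numeric((yb >= 0.5) * 1)
    )
  })
}

#' Train the segmentation model
#'
#' Mini-batch RMSProp on binary cross-entropy. Each epoch draws
#' `samples_per_epoch` items from the training set with replacement (so a
#' duplicated item is seen twice as often in expectation), processes them
#' in batches of `batch_size`, and then evaluates the mean validation
#' loss. Training stops when the validation loss has not improved for
#' `early_stop_patience` consecutive epochs, or at `max_epochs`; the
#' weights of the best validation epoch are restored. The run is
#' deterministic given the config seed.
#'
#' @param model A `ga_unet` from [build_model()] (or a trained one, to
#'   continue training).
#' @param train_items,val_items Lists of `list(x, y)` items (see
#'   [make_training_items()]); targets must be binary.
#' @param config Optional [train_config()]; defaults to the model's.
#' @param seed Optional override for the epoch-sampling seed.
#' @return List with `model` (trained) and `history` (a
#'   `training_history` tibble: `epoch`, `train_loss`, `val_loss`, plus
#'   `best_epoch` / `stopped_epoch` attributes).
#' @export
fit_unet <- function(model, train_items, val_items, config = model$config,
                     seed = config$seed) {
  stopifnot(inherits(model, "ga_unet"))
  if (length(train_items) == 0) stop("empty training set", call. = FALSE)
  if (length(val_items) == 0) {
    stop("empty validation set with early stopping enabled", call. = FALSE)
  }
  for (it in c(train_items, val_items)) {
    if (!all(unclass(it$y) %in% c(0, 1))) {
      stop("targets must be binary", call. = FALSE)
    }
  }
  s <- config$input_size
  tr <- prep_items(train_items, s)
  va <- prep_items(val_items, s)
  withr::local_seed(seed)
  vW <- lapply(model$convs, function(cv) cv$W * 0)
  vb <- lapply(model$convs, function(cv) cv$b * 0)
  nconv <- length(model$convs)
  best_convs <- model$convs
  stop_state <- NULL
  hist <- list()
  for (ep in seq_len(config$max_epochs)) {
    idx <- sample.int(length(tr), config$samples_per_epoch, replace = TRUE)
    ep_losses <- numeric(0)
    for (bstart in seq(1, config$samples_per_epoch, by = config$batch_size)) {
      bidx <- idx[bstart:min(bstart + config$batch_size - 1,
                             config$samples_per_epoch)]
      accW <- NULL
      for (ii in bidx) {
        fw <- unet_forward(model, tr[[ii]]$x, cache = TRUE)
        ep_losses <- c(ep_losses, bce_loss(fw$p, tr[[ii]]$y))
        g <- unet_backward(model, fw, tr[[ii]]$y)
        if (is.null(accW)) {
          accW <- g$gW
          accb <- g$gb
        } else {
          for (ci in seq_len(nconv)) {
            accW[[ci]] <- accW[[ci]] + g$gW[[ci]]
            accb[[ci]] <- accb[[ci]] + g$gb[[ci]]
          }
        }
      }
      nb <- length(bidx)
      for (ci in seq_len(nconv)) {
        gWc <- accW[[ci]] / nb
        gbc <- accb[[ci]] / nb
        vW[[ci]] <- config$rho * vW[[ci]] + (1 - config$rho) * gWc^2
        vb[[ci]] <- config$rho * vb[[ci]] + (1 - config$rho) * gbc^2
        model$convs[[ci]]$W <- model$convs[[ci]]$W -
          config$learning_rate * gWc / (sqrt(vW[[ci]]) + config$epsilon)
        model$convs[[ci]]$b <- model$convs[[ci]]$b -
          config$learning_rate * gbc / (sqrt(vb[[ci]]) + config$epsilon)
      }
    }
    val_loss <- mean(vapply(va, function(it) {
      bce_loss(unet_forward(model, it$x)$p, it$y)
    }, 0))
    hist[[ep]] <- c(train_loss = mean(ep_losses), val_loss = val_loss)
    improved <- is.null(stop_state) || val_loss < stop_state$best
    stop_state <- stop_state_update(stop_state, val_loss,
                                    config$early_stop_patience)
    if (improved) best_convs <- model$convs
    if (stop_state$stop) break
  }
  model$convs <- best_convs
  model$trained <- TRUE
  history <- tibble::tibble(
    epoch = seq_along(hist),
    train_loss = vapply(hist, `[[`, 0, "train_loss"),
    val_loss = vapply(hist, `[[`, 0, "val_loss")
  )
  class(history) <- c("training_history", class(history))
  attr(history, "best_epoch") <- stop_state$best_epoch
  attr(history, "stopped_epoch") <- length(hist)
  list(model = model, history = history)
}

# Early-stopping bookkeeping: track the best validation loss and the
# number of consecutive non-improving epochs; stop once that count
# reaches the patience.
stop_state_update <- function(state, val_loss, patience) {
  if (is.null(state)) state <- list(best = Inf, best_epoch = 0L,
                                    bad = 0L, epoch = 0L, stop = FALSE)
  state$epoch <- state$epoch + 1L
  if (val_loss < state$best) {
    state$best <- val_loss
    state$best_epoch <- state$epoch
    state$bad <- 0L
  } else {
    state$bad <- state$bad + 1L
    if (state$bad >= patience) state$stop <- TRUE
  }
  state
}

# Hard-example selection rule: the percentile-th percentile (linear
# interpolation) of the sampled F-scores is the threshold; items strictly
# below it are duplicated. All-ties therefore duplicate nothing.
mining_selection <- function(sampled_f, all_f, percentile) {
  threshold <- unname(stats::quantile(sampled_f, percentile / 100, type = 7))
  list(threshold = threshold, duplicated_idx = which(all_f < threshold))
}

# Pixel F-score of a binarized prediction against a binary target.
# 0/0 (no positives anywhere) is read as a perfect empty prediction -> 1.
f_score_pixels <- function(pred_bin, truth) {
  tp <- sum(pred_bin & truth)
  fp <- sum(pred_bin & !truth)
  fn <- sum(!pred_bin & truth)
  if (2 * tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

item_f_scores <- function(model, items) {
  s <- model$config$input_size
  thr <- model$config$binarize_threshold
  pp <- prep_items(items, s)
  vapply(pp, function(it) {
    p <- unet_forward(model, it$x)$p
    f_score_pixels(p >= thr, it$y > 0)
  }, 0)
}

#' Mine hard training examples by F-score percentile
#'
#' Implements the automatic-retraining selection rule: score a seeded
#' sample of `sample_n` training items by pixel F-score, take the
#' `percentile`-th percentile of those scores (linear interpolation) as
#' the threshold, then run the whole training set through the model and
#' duplicate -- once, originals retained, order stable -- every item whose
#' F-score is strictly below the threshold. When all sampled scores tie,
#' the threshold equals that value and nothing is duplicated.
#'
#' @param model A trained `ga_unet`.
#' @param train_items Training items.
#' @param sample_n Size of the profiling sample (capped at the set size).
#' @param percentile Percentile (0-100) of sampled F-scores.
#' @param seed Seed for the profiling sample.
#' @return The augmented item list (originals first, duplicates appended
#'   in original order), with attributes `f_threshold`, `f_scores`, and
#'   `duplicated_idx`.
#' @export
mine_hard_examples <- function(model, train_items, sample_n = 100,
                               percentile = 30, seed = model$config$seed) {
  if (!model$trained) stop("model has not been trained", call. = FALSE)
  n <- length(train_items)
  withr::local_seed(seed)
  sample_idx <- if (sample_n >= n) seq_len(n)
                else sort(sample.int(n, sample_n))
  sampled_f <- item_f_scores(model, train_items[sample_idx])
  all_f <- item_f_scores(model, train_items)
  sel <- mining_selection(sampled_f, all_f, percentile)
  thr <- sel$threshold
  dup_idx <- sel$duplicated_idx
  out <- c(train_items, train_items[dup_idx])
  attr(out, "f_threshold") <- thr
  attr(out, "f_scores") <- all_f
  attr(out, "duplicated_idx") <- dup_idx
  out
}

#' Calibrate the binarization threshold on validation data
#'
#' The training recipe's low learning rate leaves the sigmoid outputs
#' under-saturated long after the model discriminates lesion from
#' background well, so a fixed 0.5 cut can sit far from the optimal
#' operating point. Following the standard threshold-sweep practice for
#' segmentation confidence maps, this picks the threshold that maximizes
#' the pooled pixel F-score on the *validation* items (never the test
#' set). Assign the result to `model$config$binarize_threshold`, or pass
#' it to [binarize()].
#'
#' @param model A trained `ga_unet`.
#' @param val_items Validation items (`list(x, y)` pairs).
#' @param grid Candidate thresholds.
#' @return The F-maximizing threshold (scalar).
#' @export
tune_threshold <- function(model, val_items,
                           grid = seq(0.05, 0.95, by = 0.05)) {
  if (!model$trained) stop("model has not been trained", call. = FALSE)
  preds <- lapply(val_items, function(it) predict(model, it$x))
  truths <- lapply(val_items, function(it) unclass(it$y) > 0)
  f_at <- function(th) {
    tp <- fp <- fn <- 0
    for (i in seq_along(preds)) {
      pb <- preds[[i]] >= th
      tp <- tp + sum(pb & truths[[i]])
      fp <- fp + sum(pb & !truths[[i]])
      fn <- fn + sum(!pb & truths[[i]])
    }
    if (2 * tp + fp + fn == 0) return(1)
    2 * tp / (2 * tp + fp + fn)
  }
  grid[which.max(vapply(grid, f_at, 0))]
}

#' One retraining round on the augmented set
#'
#' Continues training from the round-one weights with the same procedure
#' and parameters, on the hard-example-augmented training set.
#'
#' @param model A trained `ga_unet`.
#' @param augmented_items Output of [mine_hard_examples()].
#' @inheritParams fit_unet
#' @return As [fit_unet()].
#' @export
retrain_unet <- function(model, augmented_items, val_items,
                         config = model$config, seed = config$seed + 1L) {
  fit_unet(model, augmented_items, val_items, config, seed = seed)
}
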