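# Independent brute-force oracles used across the suite. These deliberately
# take the slow, literal route (per-pixel loops, explicit ANOVA sums,
# recursive flood fill) so they share no code path with the implementation.

tiny_geometry <- function(nb = 12, nx = 48, nd = 40, fx = 6, fy = 6) {
  oct_geometry(NULL, n_bscans = nb, n_ascans = nx, n_depth = nd,
               field_x_mm = fx, field_y_mm = fy)
}

# Column-by-column confluence oracle: both gap conditions tested
# independently per column.
oracle_confluence <- function(ez, rpe, bm, tol) {
  out <- logical(length(ez))
  for (j in seq_along(ez)) {
    if (is.na(ez[j]) || is.na(rpe[j]) || is.na(bm[j])) {
      out[j] <- FALSE
    } else {
      out[j] <- (rpe[j] - ez[j]) <= tol && (bm[j] - rpe[j]) <= tol
    }
  }
  out
}

# Pixel-loop confusion oracle.
oracle_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] > 0 && truth[i] > 0) tp <- tp + 1L
    else if (pred[i] > 0) fp <- fp + 1L
    else if (truth[i] > 0) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Stack-based flood fill (no shared code with the BFS in C++).
oracle_label <- function(m, connectivity) {
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8) {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  for (j in 1:W) for (i in 1:H) {
    if (m[i, j] > 0 && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j))
      lab[i, j] <- cur
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (t in seq_len(nrow(nb))) {
          ni <- p[1] + nb[t, 1]; nj <- p[2] + nb[t, 2]
          if (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
              m[ni, nj] > 0 && lab[ni, nj] == 0L) {
            lab[ni, nj] <- cur
            stack[[length(stack) + 1]] <- c(ni, nj)
          }
        }
      }
    }
  }
  lab
}

# Partition of labels into pixel sets, order-free comparison helper.
label_partition <- function(lab) {
  pos <- which(lab > 0)
  unname(lapply(split(pos, lab[pos]), sort))
}

# Explicit two-way ANOVA mean squares via stats::aov on long data.
oracle_icc_a1 <- function(x, y) {
  n <- length(x)
  d <- data.frame(score = c(x, y),
                  subject = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(score ~ subject + rater, data = d))[[1]]
  msr <- ms["subject", "Mean Sq"]
  msc <- ms["rater", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
}

# Covariance-formula Pearson oracle.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Literal threshold-sweep ROC oracle with trapezoid AUC.
oracle_roc_auc <- function(conf, truth) {
  ths <- sort(unique(conf), decreasing = TRUE)
  tpr <- 0; fpr <- 0; auc <- 0
  np <- sum(truth == 1); nn <- sum(truth == 0)
  for (th in ths) {
    tpr2 <- sum(conf >= th & truth == 1) / np
    fpr2 <- sum(conf >= th & truth == 0) / nn
    auc <- auc + (fpr2 - fpr) * (tpr2 + tpr) / 2
    tpr <- tpr2; fpr <- fpr2
  }
  auc + (1 - fpr) * (1 + tpr) / 2
}

# Linear-interpolation percentile oracle (the R default definition,
# written out longhand).
oracle_percentile <- function(f, p) {
  f <- sort(f)
  n <- length(f)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  f[lo] + (h - lo) * (f[hi] - f[lo])
}

# Block-maximum horizontal resize oracle.
oracle_block_max <- function(row, target) {
  W <- length(row)
  out <- integer(target)
  for (x in 0:(target - 1)) {
    src <- which(floor((0:(W - 1)) * target / W) == x)
    out[x + 1] <- max(row[src])
  }
  out
}
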