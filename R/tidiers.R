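#' Tidiers for gaquant result objects
#'
#' broom-style accessors: `tidy()` returns the per-unit table of a result
#' (per lesion, per ROC point, per epoch, per metric), `glance()` a
#' one-row summary.
#'
#' @param x A `lesion_report`, `roc_curve`, `metrics_report`,
#'   `confusion_counts`, or `training_history`.
#' @param ... Unused.
#' @return A tibble.
#' @name gaquant-tidiers
NULL

#' @rdname gaquant-tidiers
#' @export
tidy.lesion_report <- function(x, ...) x$lesions

#' @rdname gaquant-tidiers
#' @export
glance.lesion_report <- function(x, ...) {
  tibble::tibble(
    n_lesions = nrow(x$lesions),
    n_crora = sum(x$lesions$cam_class == "cRORA"),
    n_irora = sum(x$lesions$cam_class == "iRORA"),
    area_percent_all = x$area_percent_all,
    area_percent_crora_only = x$area_percent_crora_only,
    threshold_um = x$threshold_um
  )
}

#' @rdname gaquant-tidiers
#' @export
tidy.roc_curve <- function(x, ...) x$points

#' @rdname gaquant-tidiers
#' @export
glance.roc_curve <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname gaquant-tidiers
#' @export
tidy.metrics_report <- function(x, ...) {
  tibble::tibble(metric = names(x), value = as.numeric(x[1, ]))
}

#' @rdname gaquant-tidiers
#' @export
tidy.confusion_counts <- function(x, ...) {
  tibble::tibble(count = c("tp", "fp", "fn", "tn"),
                 value = c(x$tp, x$fp, x$fn, x$tn))
}

#' @rdname gaquant-tidiers
#' @export
glance.training_history <- function(x, ...) {
  tibble::tibble(
    epochs_run = attr(x, "stopped_epoch"),
    best_epoch = attr(x, "best_epoch"),
    best_val_loss = min(x$val_loss),
    final_train_loss = x$train_loss[nrow(x)]
  )
}
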