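#' Leave-one-out cross-validated identification rate for one channel
#'
#' For every subject: a CNN is trained from a fresh seeded initialization on
#' all other subjects' feature series for this channel, then predicts the
#' held-out subject. The channel's identification rate is the fraction of
#' correct fold predictions. Fold seeds are derived deterministically from
#' `(base_seed, channel, fold)`, so each fold re-initializes independently
#' and the whole scan is reproducible.
#'
#' @param cohort an `fnirs_cohort`.
#' @param channel channel index.
#' @param config a [cnn_config()]; its `init_seed` is replaced per fold.
#' @param base_seed integer seed the fold seeds are derived from.
#' @param ... preprocessing parameters passed to [cohort_features()].
#' @return an object of class `channel_result`: `channel`, `channel_label`,
#'   `fold_predictions` (data.frame with subject, true label, predicted
#'   label and class probabilities) and `accuracy`.
#' @export
loocv_channel <- function(cohort, channel, config = cnn_config(),
                          base_seed = 1L, ...) {
  stopifnot(inherits(cohort, "fnirs_cohort"), inherits(config, "cnn_config"))
  feats <- cohort_features(cohort, channel, ...)
  res <- loocv_matrix(feats$x, feats$labels, config, base_seed, channel)
  res$fold_predictions <- cbind(subject = feats$subjects,
                                res$fold_predictions)
  res$channel <- as.integer(channel)
  res$channel_label <- cohort$recordings[[1]]$channel_labels[channel]
  class(res) <- "channel_result"
  res
}

# internal: LOOCV over the rows of a feature matrix
loocv_matrix <- function(x, labels, config, base_seed, channel_tag) {
  n <- nrow(x)
  check_that(sum(labels == 0) >= 2 && sum(labels == 1) >= 2,
             "each class needs at least 2 subjects so every training fold contains both classes")
  pred <- integer(n); p0 <- numeric(n); p1 <- numeric(n)
  for (s in seq_len(n)) {
    fold_cfg <- config
    fold_cfg$init_seed <- mix_seed(base_seed, channel_tag, s)
    fit <- cnn_train(x[-s, , drop = FALSE], labels[-s], fold_cfg)
    out <- cnn_predict(fit, x[s, ])
    pred[s] <- out$label
    p0[s] <- out$probs[1]; p1[s] <- out$probs[2]
  }
  list(fold_predictions = data.frame(true = labels, predicted = pred,
                                     p0 = p0, p1 = p1),
       accuracy = mean(pred == labels))
}

#' @export
print.channel_result <- function(x, ...) {
  cat(sprintf("channel_result %s: LOOCV identification rate %.3f over %d folds\n",
              x$channel_label, x$accuracy, nrow(x$fold_predictions)))
  invisible(x)
}

#' Per-channel LOOCV scan of a cohort
#'
#' Runs [loocv_channel()] on every requested channel.
#'
#' @param cohort an `fnirs_cohort`.
#' @param channels channel indices; default all.
#' @param config a [cnn_config()].
#' @param base_seed seed from which per-channel, per-fold seeds derive.
#' @param verbose print per-channel progress.
#' @param ... preprocessing parameters passed to [cohort_features()].
#' @return list of `channel_result`, one per channel.
#' @export
scan_channels <- function(cohort, channels = NULL, config = cnn_config(),
                          base_seed = 1L, verbose = FALSE, ...) {
  stopifnot(inherits(cohort, "fnirs_cohort"))
  if (is.null(channels)) channels <- seq_len(cohort$config$n_channels)
  results <- lapply(channels, function(ch) {
    r <- loocv_channel(cohort, ch, config, base_seed, ...)
    if (verbose) message(sprintf("  %s: accuracy %.3f", r$channel_label,
                                 r$accuracy))
    r
  })
  results
}

#' Rank channels by identification rate
#'
#' Stable descending sort by LOOCV accuracy; ties break by ascending channel
#' index, so the ranking is deterministic.
#'
#' @param results list of `channel_result` from [scan_channels()].
#' @return an object of class `roi_report`: `ranked` (data.frame with
#'   channel, channel_label, accuracy in rank order), plus empty `selected`
#'   and `strategy` fields filled by [select_roi()].
#' @export
rank_channels <- function(results) {
  check_that(is.list(results) && length(results) >= 1 &&
               all(vapply(results, inherits, logical(1), "channel_result")),
             "'results' must be a non-empty list of channel_result")
  tab <- data.frame(
    channel = vapply(results, function(r) r$channel, integer(1)),
    channel_label = vapply(results, function(r) as.character(r$channel_label),
                           character(1)),
    accuracy = vapply(results, function(r) r$accuracy, numeric(1)))
  tab <- tab[order(-tab$accuracy, tab$channel), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(ranked = tab, selected = integer(0), strategy = NULL,
                 results = results),
            class = "roi_report")
}

#' Select the region of interest from ranked channels
#'
#' Either the top `k` channels by identification rate (default `k = 5`,
#' with all channels tied at the k-th accuracy included, so the set may
#' exceed `k`) or every channel whose accuracy meets a threshold.
#'
#' @param report an `roi_report` from [rank_channels()].
#' @param strategy `"topk"` or `"threshold"`.
#' @param param `k` for `"topk"` (positive integer) or the accuracy
#'   threshold in `[0, 1]` for `"threshold"`.
#' @return the updated `roi_report` with `selected` (sorted channel indices)
#'   and `strategy` filled in.
#' @export
select_roi <- function(report, strategy = c("topk", "threshold"), param = 5) {
  stopifnot(inherits(report, "roi_report"))
  strategy <- match.arg(strategy)
  tab <- report$ranked
  if (strategy == "topk") {
    check_scalar(param, "param", positive = TRUE, integerish = TRUE)
    k <- min(as.integer(param), nrow(tab))
    cut <- tab$accuracy[k]
    sel <- tab$channel[tab$accuracy >= cut]
  } else {
    check_scalar(param, "param", nonneg = TRUE)
    check_that(param <= 1, "'param' must be an accuracy threshold in [0, 1]")
    sel <- tab$channel[tab$accuracy >= param]
  }
  report$selected <- sort(as.integer(sel))
  report$strategy <- list(name = strategy, param = param)
  report
}

#' @export
print.roi_report <- function(x, ...) {
  cat("roi_report: channels by LOOCV identification rate\n")
  print(x$ranked, row.names = FALSE)
  if (length(x$selected)) {
    cat(sprintf("selected ROI (%s, param %g): {%s}\n", x$strategy$name,
                x$strategy$param, paste(x$selected, collapse = ", ")))
  }
  invisible(x)
}

#' Write an ROI report to disk
#'
#' `report.json` holds the ranked channels, accuracies, selection strategy
#' and selected set; `accuracy_by_channel.tsv` is a delimited table (one row
#' per channel in index order) suitable for bar plotting.
#'
#' @param report an `roi_report`.
#' @param dir output directory.
#' @return invisibly, the JSON path.
#' @export
write_roi_report <- function(report, dir) {
  stopifnot(inherits(report, "roi_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- report$ranked[order(report$ranked$channel), , drop = FALSE]
  utils::write.table(tab, file.path(dir, "accuracy_by_channel.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  obj <- list(ranked = report$ranked, selected = report$selected,
              strategy = report$strategy)
  path <- file.path(dir, "report.json")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
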