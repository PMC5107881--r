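# interpretability exports: learned kernel profiles, class-mean pooling-layer
# activations, and pooling outputs weighted by the dense layer

# internal: coerce feature input to a matrix + labels pair
as_feature_matrix <- function(x, labels) {
  if (is.list(x) && !is.matrix(x) && all(vapply(x, inherits, logical(1),
                                                "feature_series"))) {
    if (is.null(labels)) labels <- vapply(x, function(f) f$label, integer(1))
    x <- do.call(rbind, lapply(x, function(f) f$values))
  }
  x <- as.matrix(x)
  check_that(!is.null(labels) && length(labels) == nrow(x),
             "one label per feature row is required")
  list(x = x, labels = as.integer(labels))
}

#' Learned convolution kernel profiles
#'
#' The K kernels as an m x K matrix in kernel index order — the weight
#' profile each filter applies along the time axis.
#'
#' @param model a `cnn_model`.
#' @return m x K numeric matrix with columns `kernel1..K`.
#' @export
export_kernels <- function(model) {
  stopifnot(inherits(model, "cnn_model"))
  out <- model$kernels
  colnames(out) <- paste0("kernel", seq_len(ncol(out)))
  out
}

#' Class-mean pooling-layer outputs
#'
#' For each kernel and each class, the elementwise mean over that class's
#' subjects of the max-pooled activation sequence — the per-class summary of
#' what each filter passes on to the dense layer.
#'
#' @param model a `cnn_model`.
#' @param x subjects x N feature matrix or list of [feature_series()].
#' @param labels 0/1 labels (taken from the series when `x` is a list).
#' @return numeric array of dimension P x K x 2 (pooled position, kernel,
#'   class), with class dimnames `"class0"`, `"class1"`.
#' @export
pooled_outputs <- function(model, x, labels = NULL) {
  stopifnot(inherits(model, "cnn_model"))
  fm <- as_feature_matrix(x, labels)
  check_that(all(fm$labels %in% 0:1), "labels must be 0 or 1")
  check_that(all(0:1 %in% fm$labels), "both classes must be present")
  p <- model$dims$p_pool; k <- model$config$n_kernels
  pooled_all <- lapply(seq_len(nrow(fm$x)),
                       function(s) cnn_forward(model, fm$x[s, ])$pooled)
  out <- array(0, dim = c(p, k, 2),
               dimnames = list(NULL, paste0("kernel", seq_len(k)),
                               c("class0", "class1")))
  for (cl in 0:1) {
    members <- which(fm$labels == cl)
    acc <- Reduce(`+`, pooled_all[members]) / length(members)
    out[, , cl + 1] <- acc
  }
  out
}

#' Pooling output weighted by the dense layer
#'
#' The class-mean pooled sequence of one kernel multiplied elementwise by
#' the dense weights that connect those pooled units to a chosen output
#' neuron: how much each pooled time point pushes the network toward that
#' class, per group.
#'
#' @param model a `cnn_model`.
#' @param x subjects x N feature matrix or list of [feature_series()].
#' @param labels 0/1 labels.
#' @param kernel_index which kernel, in `1..K`.
#' @param output_neuron which output class's weights to use, 0 or 1.
#' @return P x 2 matrix (columns `class0`, `class1`).
#' @export
weighted_pooled_output <- function(model, x, labels = NULL, kernel_index,
                                   output_neuron = 1) {
  stopifnot(inherits(model, "cnn_model"))
  k <- model$config$n_kernels; p <- model$dims$p_pool
  check_scalar(kernel_index, "kernel_index", positive = TRUE, integerish = TRUE)
  check_that(kernel_index <= k, "'kernel_index' out of range")
  check_that(output_neuron %in% 0:1, "'output_neuron' must be 0 or 1")
  pooled <- pooled_outputs(model, x, labels)
  # dense rows for kernel k occupy the k-th block of the kernel-major flat
  rows <- (kernel_index - 1) * p + seq_len(p)
  w <- model$dense_weights[rows, output_neuron + 1]
  out <- cbind(class0 = pooled[, kernel_index, 1] * w,
               class1 = pooled[, kernel_index, 2] * w)
  out
}

#' Most group-discriminative kernel
#'
#' Ranks kernels by a separation score: the sum over pooled positions of the
#' absolute class-mean difference of the dense-weighted pooled outputs. The
#' score is symmetric in the class labeling; ties break toward the lower
#' kernel index.
#'
#' @inheritParams weighted_pooled_output
#' @return list with `kernel` (index), `score`, and `scores` (all K).
#' @export
most_discriminative_kernel <- function(model, x, labels = NULL,
                                       output_neuron = 1) {
  stopifnot(inherits(model, "cnn_model"))
  k <- model$config$n_kernels
  scores <- vapply(seq_len(k), function(ki) {
    wp <- weighted_pooled_output(model, x, labels, ki, output_neuron)
    sum(abs(wp[, 1] - wp[, 2]))
  }, numeric(1))
  best <- which.max(scores) # first maximum: ties go to the lower index
  list(kernel = as.integer(best), score = scores[best], scores = scores)
}

#' Class-mean input feature series
#'
#' The elementwise mean feature vector of each class — the raw-input
#' counterpart of the pooling-layer summaries.
#'
#' @param x subjects x N feature matrix or list of [feature_series()].
#' @param labels 0/1 labels.
#' @return N x 2 matrix (columns `class0`, `class1`).
#' @export
class_mean_inputs <- function(x, labels = NULL) {
  fm <- as_feature_matrix(x, labels)
  check_that(all(0:1 %in% fm$labels), "both classes must be present")
  cbind(class0 = colMeans(fm$x[fm$labels == 0, , drop = FALSE]),
        class1 = colMeans(fm$x[fm$labels == 1, , drop = FALSE]))
}

#' Build the full interpretation bundle for a trained model
#'
#' Collects the kernel profiles, class-mean pooled outputs, the
#' dense-weighted pooled output of the most discriminative kernel (or a
#' chosen one), and the class-mean inputs.
#'
#' @inheritParams weighted_pooled_output
#' @param kernel_index kernel to export the weighted pooled output for;
#'   `NULL` (default) picks [most_discriminative_kernel()].
#' @return an object of class `interpretation_bundle`.
#' @export
interpretation_bundle <- function(model, x, labels = NULL, kernel_index = NULL,
                                  output_neuron = 1) {
  fm <- as_feature_matrix(x, labels)
  best <- most_discriminative_kernel(model, fm$x, fm$labels, output_neuron)
  if (is.null(kernel_index)) kernel_index <- best$kernel
  structure(
    list(kernel_profiles = export_kernels(model),
         pooled_by_class = pooled_outputs(model, fm$x, fm$labels),
         weighted_pooled = weighted_pooled_output(model, fm$x, fm$labels,
                                                  kernel_index, output_neuron),
         inputs_by_class = class_mean_inputs(fm$x, fm$labels),
         kernel_index = as.integer(kernel_index),
         output_neuron = as.integer(output_neuron),
         kernel_scores = best$scores),
    class = "interpretation_bundle")
}

#' @export
print.interpretation_bundle <- function(x, ...) {
  cat(sprintf(
    "interpretation_bundle: %d kernels of length %d, pooled length %d\n",
    ncol(x$kernel_profiles), nrow(x$kernel_profiles),
    dim(x$pooled_by_class)[1]))
  cat(sprintf("  weighted pooled output for kernel %d (output neuron %d)\n",
              x$kernel_index, x$output_neuron))
  invisible(x)
}

#' Write an interpretation bundle as delimited tables plus JSON metadata
#'
#' Emits `kernels.tsv` (m x K), `pooled_class0.tsv` / `pooled_class1.tsv`
#' (P x K), `weighted_pooled.tsv` (P x 2), `inputs_by_class.tsv` (N x 2) and
#' `interpretation.json` (kernel scores and indices).
#'
#' @param bundle an `interpretation_bundle`.
#' @param dir output directory.
#' @return invisibly, the metadata path.
#' @export
write_interpretation <- function(bundle, dir) {
  stopifnot(inherits(bundle, "interpretation_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, file) utils::write.table(
    as.data.frame(x), file.path(dir, file), sep = "\t", row.names = FALSE,
    quote = FALSE)
  wt(bundle$kernel_profiles, "kernels.tsv")
  wt(bundle$pooled_by_class[, , 1], "pooled_class0.tsv")
  wt(bundle$pooled_by_class[, , 2], "pooled_class1.tsv")
  wt(bundle$weighted_pooled, "weighted_pooled.tsv")
  wt(bundle$inputs_by_class, "inputs_by_class.tsv")
  meta <- list(kernel_index = bundle$kernel_index,
               output_neuron = bundle$output_neuron,
               kernel_scores = bundle$kernel_scores)
  path <- file.path(dir, "interpretation.json")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
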