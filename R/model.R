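#' Model architecture configuration
#'
#' Describes the convolutional profile+quantity network: two convolutional
#' layers (64 filters of width 8 with exponential-linear activation, then 128
#' filters of width 4 with rectified-linear activation), a tower of 9
#' exponentially dilated convolutions (64 filters, width 3, dilations 1, 2,
#' 4, ..., 512) separated by skip connections, batch normalization after
#' every convolution, max pooling (width 2) after each of the first two
#' convolutions and after the tower, and two heads: a fully connected
#' profile head emitting a base-resolution track of length
#' `2 * output_length` (plus strand then minus strand) and a quantity head
#' (average pooling then one fully connected layer) emitting a scalar.
#' Batch normalization and ReLU follow each fully connected layer, so both
#' heads are nonnegative.
#'
#' `scale_factor` multiplies all filter counts, allowing a desk-scale model
#' (e.g. `scale_factor = 0.25`) that trains on a single CPU while keeping
#' the architecture shape intact.
#'
#' @param input_length Input window width in bp (default 1000); odd
#'   intermediate lengths are floored by the width-2 max pools.
#' @param output_length Output track width in bp (default 500); the output
#'   window is centered within the input window.
#' @param scale_factor Positive multiplier applied to all filter counts.
#' @param n_tower Number of dilated tower layers (dilation doubles per layer).
#' @return A `dipcap_arch` list understood by [build_model()].
#' @export
model_config <- function(input_length = 1000L, output_length = 500L,
                         scale_factor = 1, n_tower = 9L) {
  input_length <- as.integer(input_length)
  output_length <- as.integer(output_length)
  stopifnot(input_length > 0, output_length > 0, scale_factor > 0, n_tower >= 1)
  if (output_length > input_length) {
    stop("output_length must not exceed input_length")
  }
  if (input_length < 8L) {
    stop("input_length must be at least 8 (three width-2 max pools)")
  }
  arch <- list(
    input_length = input_length,
    output_length = output_length,
    scale_factor = scale_factor,
    n_filters1 = max(1L, as.integer(round(64 * scale_factor))),
    n_filters2 = max(1L, as.integer(round(128 * scale_factor))),
    n_filters_tower = max(1L, as.integer(round(64 * scale_factor))),
    kernel1 = 8L, kernel2 = 4L, kernel_tower = 3L,
    n_tower = as.integer(n_tower),
    bn_eps = 1e-3, bn_momentum = 0.9
  )
  class(arch) <- "dipcap_arch"
  arch
}

trunk_length <- function(arch) {
  l <- arch$input_length
  for (i in 1:3) l <- l %/% 2L
  l
}

#' Build (initialize) a profile+quantity model
#'
#' Allocates and randomly initializes all weights for the architecture in
#' `arch`. Convolution weights use He-style initialization, dense heads use
#' Glorot; batch-norm scales start at 1 and shifts at 0. Initialization is a
#' deterministic function of `seed`.
#'
#' @param arch A [model_config()] object.
#' @param seed Integer seed for weight initialization.
#' @return A `dipcap_model` object (architecture + named parameter list).
#' @export
build_model <- function(arch = model_config(), seed = 1L) {
  stopifnot(inherits(arch, "dipcap_arch"))
  set.seed(as.integer(seed))
  he <- function(nrow, ncol) {
    matrix(rnorm(nrow * ncol, sd = sqrt(2 / ncol)), nrow = nrow)
  }
  glorot <- function(nrow, ncol) {
    matrix(rnorm(nrow * ncol, sd = sqrt(2 / (nrow + ncol))), nrow = nrow)
  }
  bn <- function(f) {
    list(gamma = rep(1, f), beta = rep(0, f), mean = rep(0, f), var = rep(1, f))
  }
  p <- list()
  add_bn <- function(p, tag, f) {
    b <- bn(f)
    p[[paste0(tag, "_gamma")]] <- b$gamma
    p[[paste0(tag, "_beta")]] <- b$beta
    p[[paste0(tag, "_mean")]] <- b$mean
    p[[paste0(tag, "_var")]] <- b$var
    p
  }
  p$conv1_W <- he(arch$n_filters1, 4L * arch$kernel1)
  p$conv1_b <- rep(0, arch$n_filters1)
  p <- add_bn(p, "bn1", arch$n_filters1)
  p$conv2_W <- he(arch$n_filters2, arch$n_filters1 * arch$kernel2)
  p$conv2_b <- rep(0, arch$n_filters2)
  p <- add_bn(p, "bn2", arch$n_filters2)
  cin <- arch$n_filters2
  for (i in seq_len(arch$n_tower)) {
    tag <- paste0("tw", i)
    p[[paste0(tag, "_W")]] <- he(arch$n_filters_tower, cin * arch$kernel_tower)
    p[[paste0(tag, "_b")]] <- rep(0, arch$n_filters_tower)
    p <- add_bn(p, paste0(tag, "_bn"), arch$n_filters_tower)
    cin <- arch$n_filters_tower
  }
  l3 <- trunk_length(arch)
  pdim <- 2L * arch$output_length
  p$prof_W <- glorot(pdim, arch$n_filters_tower * l3)
  p$prof_b <- rep(0, pdim)
  p <- add_bn(p, "bnp", pdim)
  p$quant_W <- glorot(1L, arch$n_filters_tower)
  p$quant_b <- 0
  p <- add_bn(p, "bnq", 1L)
  structure(
    list(arch = arch, params = p, masked_inputs = FALSE, history = NULL,
         lr_log = numeric(0), init_seed = as.integer(seed)),
    class = "dipcap_model"
  )
}

# parameter names updated by the optimizer (running BN stats excluded)
trainable_names <- function(params) {
  nm <- names(params)
  nm[!grepl("_(mean|var)$", nm)]
}

# x: L x 4 two-hot matrix or B x L x 4 array -> cube layout (4, L, B)
as_input_cube <- function(x, input_length) {
  if (is.matrix(x)) x <- array(x, dim = c(1L, dim(x)))
  stopifnot(length(dim(x)) == 3L, dim(x)[3] == 4L)
  if (dim(x)[2] != input_length) {
    stop(sprintf("input length %d does not match model input_length %d",
                 dim(x)[2], input_length))
  }
  aperm(x, c(3L, 2L, 1L))
}

#' Predict profile and quantity
#'
#' Runs the network in inference mode (batch-norm uses frozen running
#' statistics, so predictions are deterministic and independent of batch
#' composition).
#'
#' @param object A `dipcap_model`.
#' @param x An `L x 4` two-hot matrix or a `B x L x 4` array of encoded
#'   windows.
#' @param ... Unused.
#' @return A `pq_prediction`: list with `profile` (`B x 2*output_length`
#'   matrix, plus-strand half then minus-strand half, nonnegative) and
#'   `quantity` (length-`B` nonnegative vector).
#' @export
predict.dipcap_model <- function(object, x, ...) {
  xc <- as_input_cube(x, object$arch$input_length)
  out <- nn_forward_cpp(object$params, unclass(object$arch), xc, FALSE)
  structure(list(profile = out$profile, quantity = as.numeric(out$quantity)),
            class = "pq_prediction")
}

#' Multiscale profile+quantity loss
#'
#' `-cos(p_obs, y_profile) + lambda * (log(sum(p_obs) + alpha) -
#' log(y_quantity + alpha))^2` with natural logarithms. The cosine of a
#' zero-norm vector (either side) is defined as 0. For matrix inputs the
#' mean over rows (batch) is returned.
#'
#' @param p_obs Observed track, vector of length `2 * output_length` or a
#'   batch matrix.
#' @param y_profile Predicted profile, same shape as `p_obs`.
#' @param y_quantity Predicted total quantity (scalar or vector).
#' @param lambda Quantity balancing weight, default `1/500`.
#' @param alpha Pseudocount, default `1e-6`.
#' @return Scalar loss (mean over the batch). Bounded below by -1.
#' @export
multiscale_loss <- function(p_obs, y_profile, y_quantity,
                            lambda = 1 / 500, alpha = 1e-6) {
  if (is.null(dim(p_obs))) p_obs <- matrix(p_obs, nrow = 1)
  if (is.null(dim(y_profile))) y_profile <- matrix(y_profile, nrow = 1)
  if (!all(dim(p_obs) == dim(y_profile))) {
    stop("p_obs and y_profile must have identical dimensions")
  }
  stopifnot(lambda > 0, alpha > 0)
  y_quantity <- as.numeric(y_quantity)
  if (length(y_quantity) != nrow(p_obs)) {
    stop("y_quantity length must match the batch size")
  }
  multiscale_loss_cpp(p_obs, y_profile, y_quantity, lambda, alpha)
}

#' Combine the two heads into one coverage-scale track
#'
#' Rescales the predicted profile to sum to 1 and multiplies by the
#' predicted quantity, producing a single track in coverage units (the
#' representation used for QTL effect scoring). An all-zero profile falls
#' back to a uniform profile, with a logged note.
#'
#' @param prediction A `pq_prediction` (or list with `profile`, `quantity`).
#' @return A matrix (`B x 2*output_length`) of predicted tracks; each row
#'   sums to the corresponding quantity.
#' @export
predicted_track <- function(prediction) {
  prof <- prediction$profile
  if (is.null(dim(prof))) prof <- matrix(prof, nrow = 1)
  q <- as.numeric(prediction$quantity)
  stopifnot(length(q) == nrow(prof))
  sums <- rowSums(prof)
  zero <- sums <= 0
  if (any(zero)) {
    dipcap_log("track", sprintf(
      "%d all-zero profile(s); falling back to uniform", sum(zero)))
    prof[zero, ] <- 1
    sums[zero] <- ncol(prof)
  }
  prof / sums * q
}

#' Save / load a model
#'
#' The checkpoint is an RDS file holding the full parameter list; a JSON
#' sidecar (`<path>.json`) records the architecture for interoperability.
#'
#' @param model A `dipcap_model`.
#' @param path File path for the checkpoint.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dipcap_model"))
  saveRDS(model, path)
  jsonlite::write_json(unclass(model$arch), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "dipcap_model"))
  model
}

#' @export
print.dipcap_model <- function(x, ...) {
  a <- x$arch
  cat(sprintf(
    "<dipcap_model> input %d bp -> profile %d + quantity; filters %d/%d/%dx%d%s\n",
    a$input_length, 2L * a$output_length, a$n_filters1, a$n_filters2,
    a$n_filters_tower, a$n_tower,
    if (isTRUE(x$masked_inputs)) "; trained on masked (reference) inputs" else ""
  ))
  invisible(x)
}
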