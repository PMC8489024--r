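#' Configuration of the compact hourglass segmentation network
#'
#' The network is a constant-width U-Net variant: every hidden convolution
#' has `width` (16) `kernel_size` x `kernel_size` (3x3) kernels with ReLU and
#' same-shape padding. The encoder halves the spatial resolution
#' `depth - 1` times via 2x2 max pooling; the decoder upsamples by 2
#' (parameter-free nearest neighbour) per level and fuses with the
#' same-resolution encoder map by channel concatenation followed by
#' convolutions. A 1x1 convolution produces the per-pixel pupil logit map; a
#' separate branch applies global average pooling to the bottleneck map and
#' a two-output fully connected layer for the eye/blink logits.
#'
#' @param input_size Input side in pixels; must be divisible by
#'   `2^(depth - 1)`.
#' @param channels_in Input channels (grayscale: 1).
#' @param width Kernels per convolutional layer.
#' @param kernel_size Convolution kernel side (fixed at 3).
#' @param depth Number of resolution levels (bottleneck included).
#' @param convs_per_level Convolutions per encoder/decoder level.
#' @return An object of class `segmenter_config`.
#' @export
segmenter_config <- function(input_size = 128, channels_in = 1, width = 16,
                             kernel_size = 3, depth = 3,
                             convs_per_level = 2) {
  if (kernel_size != 3) stop("only 3x3 kernels are supported")
  if (width < 1) stop("width must be >= 1")
  if (depth < 2) stop("depth must be >= 2")
  if (convs_per_level < 1) stop("convs_per_level must be >= 1")
  if (input_size %% 2^(depth - 1) != 0)
    stop("input_size must be divisible by 2^(depth - 1)")
  structure(list(input_size = as.integer(input_size),
                 channels_in = as.integer(channels_in),
                 width = as.integer(width),
                 kernel_size = as.integer(kernel_size),
                 depth = as.integer(depth),
                 convs_per_level = as.integer(convs_per_level)),
            class = "segmenter_config")
}

is_default_topology <- function(config) {
  config$channels_in == 1 && config$width == 16 && config$depth == 3 &&
    config$convs_per_level == 2
}

# He-normal weight init for one conv/fc weight matrix
init_w <- function(nin, nout) matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)

#' Build the segmentation network
#'
#' Instantiates randomly initialized (He-normal, seeded) parameters for the
#' architecture described in [segmenter_config()]. For the default topology
#' (width 16, depth 3, 2 convolutions per level, single input channel) the
#' trainable parameter count is asserted to round to 0.03 M at build time —
#' the architecture's published budget.
#'
#' @param config A [segmenter_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `segmenter`: list with `config` and `params`
#'   (flat named list of weight matrices and bias vectors).
#' @export
build_segmenter <- function(config = segmenter_config(), seed = 1) {
  stopifnot(inherits(config, "segmenter_config"))
  w <- config$width
  with_seed(seed, {
    params <- list()
    cin <- config$channels_in
    for (l in seq_len(config$depth)) {
      for (j in seq_len(config$convs_per_level)) {
        key <- sprintf("enc%d_%d", l, j)
        params[[paste0(key, ".W")]] <- init_w(9 * cin, w)
        params[[paste0(key, ".b")]] <- numeric(w)
        cin <- w
      }
    }
    for (l in seq_len(config$depth - 1)) {
      for (j in seq_len(config$convs_per_level)) {
        key <- sprintf("dec%d_%d", l, j)
        nin <- if (j == 1) 9 * 2 * w else 9 * w
        params[[paste0(key, ".W")]] <- init_w(nin, w)
        params[[paste0(key, ".b")]] <- numeric(w)
      }
    }
    params[["head.W"]] <- init_w(w, 1) / sqrt(2) # Xavier-ish for sigmoid head
    params[["head.b"]] <- numeric(1)
    params[["fc.W"]] <- init_w(w, 2) / sqrt(2)
    params[["fc.b"]] <- numeric(2)
    model <- structure(list(config = config, params = params),
                       class = "segmenter")
    if (is_default_topology(config)) {
      stopifnot(round(count_parameters(model) / 1e6, 2) == 0.03)
    }
    model
  })
}

#' Count trainable parameters
#'
#' @param model A `segmenter`.
#' @return Total number of trainable scalars (weights plus biases).
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "segmenter"))
  sum(vapply(model$params, length, integer(1)))
}

cfg_list <- function(model) {
  model$config[c("depth", "convs_per_level", "width", "channels_in")]
}

check_image_input <- function(model, image) {
  n <- model$config$input_size
  if (!is.matrix(image) || nrow(image) != n || ncol(image) != n)
    stop(sprintf("image must be a %dx%d matrix", n, n))
  invisible(TRUE)
}

#' Run the network on one frame
#'
#' @param model A `segmenter`.
#' @param image Square gray matrix in `[0, 1]` of side
#'   `config$input_size`.
#' @return A `prediction`: list with `pupil_map` (matrix of per-pixel pupil
#'   probabilities), `eye_prob` and `blink_prob` (scalars in `[0, 1]`); all
#'   obtained by element-wise sigmoid on the network outputs.
#' @export
predict_frame <- function(model, image) {
  check_image_input(model, image)
  res <- predict_batch(model, list(image))
  structure(list(pupil_map = res$maps[, , 1], eye_prob = res$eye[1],
                 blink_prob = res$blink[1]), class = "prediction")
}

#' Run the network on a list of frames
#'
#' @param model A `segmenter`.
#' @param images List of square gray matrices (or a 3-D array H x W x N).
#' @return List with `maps` (H x W x N array), `eye`, `blink` (vectors).
#' @export
predict_batch <- function(model, images) {
  n <- model$config$input_size
  if (is.list(images)) {
    arr <- array(0, dim = c(n, n, length(images)))
    for (i in seq_along(images)) {
      check_image_input(model, images[[i]])
      arr[, , i] <- images[[i]]
    }
  } else {
    arr <- images
    stopifnot(length(dim(arr)) == 3, dim(arr)[1] == n, dim(arr)[2] == n)
  }
  unet_predict_cpp(model$params, cfg_list(model), arr)
}

#' Save / load network weights
#'
#' Checkpoints use R's standard serialized container (RDS) holding the
#' config and the flat parameter list.
#'
#' @param model A `segmenter`.
#' @param path Checkpoint file path.
#' @return `load_segmenter` returns the restored `segmenter`.
#' @export
save_segmenter <- function(model, path) {
  stopifnot(inherits(model, "segmenter"))
  saveRDS(list(config = unclass(model$config), params = model$params), path)
  invisible(path)
}

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  x <- readRDS(path)
  structure(list(config = do.call(segmenter_config, x$config),
                 params = x$params), class = "segmenter")
}

#' @export
print.segmenter <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Hourglass pupil segmenter: %dx%d input, width %d, depth %d, %d convs/level\n",
    cfg$input_size, cfg$input_size, cfg$width, cfg$depth,
    cfg$convs_per_level))
  cat(sprintf("Trainable parameters: %d (%.2f M)\n", count_parameters(x),
              count_parameters(x) / 1e6))
  w <- vapply(x$params, length, integer(1))
  for (nm in unique(sub("\\.(W|b)$", "", names(w))))
    cat(sprintf("  %-8s %6d weights + %d biases\n", nm,
                w[paste0(nm, ".W")], w[paste0(nm, ".b")]))
  invisible(x)
}
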