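#' Specify a synthetic labeled image dataset
#'
#' Describes a multi-class grayscale image dataset with controllable mean
#' brightness and intensity-histogram shape. Two histogram regimes are
#' supported: `"near_binary"` (almost all pixel mass at 0 and one bright peak,
#' like handwritten-character datasets) and `"graded"` (intensities spread over
#' the whole \[0, 255\] range, like photographic datasets). Mean brightness and
#' histogram shape are the two dataset properties that shift, respectively, the
#' offset and the shape of the slope-versus-decay-time curve downstream.
#'
#' @param n_samples number of images.
#' @param image_side side length in pixels (images are square).
#' @param n_classes number of classes (>= 2).
#' @param target_mean_brightness desired mean pixel intensity on \[0, 255\].
#'   Default 33, the mean brightness of MNIST-like handwritten digits.
#' @param intensity_mode `"near_binary"` or `"graded"`.
#' @param noise_sd per-pixel Gaussian noise SD on the \[0, 255\] scale
#'   (clipped after addition). Default 8.
#' @param shift_px maximum per-sample template translation in pixels (each
#'   sample's template is shifted circularly by independent uniform integer
#'   offsets in `[-shift_px, shift_px]` per axis). This is the within-class
#'   variability that keeps the classification task from being trivially
#'   separable, as pattern position varies in real digit data; a circular
#'   shift moves the pattern without changing the pixel-intensity alphabet or
#'   the sample's mean brightness. Default 2.
#' @param seed integer RNG seed; the dataset is bit-identical given the spec.
#' @return an object of class `dataset_spec`.
#' @export
dataset_spec <- function(n_samples, image_side = 12L, n_classes = 4L,
                         target_mean_brightness = 33,
                         intensity_mode = c("near_binary", "graded"),
                         noise_sd = 8, shift_px = 2L, seed = 1L) {
  intensity_mode <- match.arg(intensity_mode)
  .assert(is.numeric(n_samples) && n_samples >= 1, "n_samples must be >= 1")
  .assert(is.numeric(image_side) && image_side >= 2, "image_side must be >= 2")
  .assert(is.numeric(n_classes) && n_classes >= 2, "n_classes must be >= 2")
  .assert(is.numeric(target_mean_brightness) &&
            target_mean_brightness > 0 && target_mean_brightness < 255,
          "target_mean_brightness must lie strictly inside (0, 255)")
  .assert(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  .assert(is.numeric(shift_px) && shift_px >= 0 && shift_px < image_side,
          "shift_px must be in [0, image_side)")
  structure(list(n_samples = as.integer(n_samples),
                 image_side = as.integer(image_side),
                 n_classes = as.integer(n_classes),
                 target_mean_brightness = target_mean_brightness,
                 intensity_mode = intensity_mode,
                 noise_sd = noise_sd,
                 shift_px = as.integer(shift_px),
                 seed = as.integer(seed)),
            class = "dataset_spec")
}

# Smooth a white-noise field with a small Gaussian kernel so class templates
# are spatially correlated blobs/strokes rather than salt-and-pepper noise.
.smooth_field <- function(side, sigma) {
  z <- matrix(rnorm(side * side), side, side)
  r <- max(1L, ceiling(2 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad <- function(m, n) m[pmin(pmax(seq_len(nrow(m) + 2 * n) - n, 1), nrow(m)), , drop = FALSE]
  # separable convolution with edge replication
  conv1 <- function(m) {
    mp <- pad(m, r)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + nrow(m) - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(z))))
}

# Near-binary template: a fixed fraction of "on" pixels (the brightest field
# pixels) at a single peak value chosen so the template mean equals the
# target exactly. The default on-fraction 0.19 mirrors handwritten-digit
# images, where ~19% of pixels are ink at a mean intensity of ~175/255: the
# encoded channels then spike stochastically (p ~ 0.7) rather than on every
# step, which is the regime rate coding assumes. If the target mean is too
# high for the fraction (peak would exceed 255), the fraction grows just
# enough to keep the peak at 255.
.template_near_binary <- function(field, target, on_fraction = 0.19) {
  npix <- length(field)
  n_on <- max(1L, as.integer(round(npix * on_fraction)),
              as.integer(ceiling(npix * target / 255)))
  peak <- target * npix / n_on     # <= 255 by choice of n_on
  thr <- sort(as.vector(field), decreasing = TRUE)[n_on]
  tmpl <- matrix(0, nrow(field), ncol(field))
  on <- which(field >= thr)[seq_len(n_on)]  # deterministic tie handling
  tmpl[on] <- peak
  tmpl
}

# Graded template: positive part of the field above its 60% quantile, scaled
# multiplicatively (with clipping) so the mean matches the target.
.template_graded <- function(field, target) {
  v <- field - quantile(field, 0.6, names = FALSE)
  v[v < 0] <- 0
  v <- v / max(v) * 255
  .scale_to_mean(v, target, tol = 1e-6)$pixels
}

# Multiplicative brightness scaling with clipping to [0,255]; the post-clip
# mean is monotone in the scale factor, so bisection converges.
.scale_to_mean <- function(pixels, target, tol, max_iter = 60L) {
  cur <- mean(pixels)
  if (identical(cur, target)) return(list(pixels = pixels, scale = 1))
  sup <- 255 * mean(pixels > 0)
  .assert(sup > 0 || target == 0,
          "cannot reach a positive target mean: dataset has no nonzero pixel",
          class = "spikemode_unachievable_error")
  .assert(target <= sup + tol,
          sprintf("target mean %.3f exceeds the maximum reachable mean %.3f",
                  target, sup),
          class = "spikemode_unachievable_error")
  clip_mean <- function(s) mean(pmin(pmax(s * pixels, 0), 255))
  lo <- 0; hi <- 1
  while (clip_mean(hi) < target && hi < 1e9) hi <- hi * 2
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (clip_mean(mid) < target) lo <- mid else hi <- mid
  }
  s <- (lo + hi) / 2
  out <- pmin(pmax(s * pixels, 0), 255)
  .assert(abs(mean(out) - target) <= tol,
          sprintf("bisection stalled %.4f away from the target mean",
                  abs(mean(out) - target)),
          class = "spikemode_unachievable_error")
  list(pixels = out, scale = s)
}

#' Generate a synthetic labeled grayscale image dataset
#'
#' Each class gets a fixed spatial template (a thresholded smooth random
#' field); samples are the class template, translated by a small per-sample
#' offset (within-class variability), plus clipped Gaussian pixel noise.
#' Labels are balanced to within one sample and the whole dataset is
#' bit-identical given the spec's seed.
#'
#' @param spec a [dataset_spec()].
#' @return an object of class `image_dataset` with fields `pixels`
#'   (array `n_samples x side x side`, intensities on \[0, 255\]), `labels`
#'   (0-based integer codes) and `meta`.
#' @export
make_dataset <- function(spec) {
  .assert(inherits(spec, "dataset_spec"), "spec must be a dataset_spec")
  set.seed(spec$seed)
  side <- spec$image_side
  K <- spec$n_classes
  templates <- vector("list", K)
  for (k in seq_len(K)) {
    field <- .smooth_field(side, sigma = side / 6)
    templates[[k]] <-
      if (spec$intensity_mode == "near_binary")
        .template_near_binary(field, spec$target_mean_brightness)
      else
        .template_graded(field, spec$target_mean_brightness)
  }
  n <- spec$n_samples
  labels <- rep(seq_len(K) - 1L, length.out = n)[sample.int(n)]
  pixels <- array(0, dim = c(n, side, side))
  sft <- spec$shift_px
  for (i in seq_len(n)) {
    img <- templates[[labels[i] + 1L]]
    if (sft > 0) {
      img <- .shift_image(img,
                          sample.int(2L * sft + 1L, 1L) - sft - 1L,
                          sample.int(2L * sft + 1L, 1L) - sft - 1L)
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(rnorm(side * side, sd = spec$noise_sd), side, side)
      img <- pmin(pmax(img, 0), 255)
    }
    pixels[i, , ] <- img
  }
  structure(list(pixels = pixels, labels = labels,
                 meta = list(spec = unclass(spec), generator = "spikemode")),
            class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_dataset> %d samples, %dx%d px, %d classes, mean brightness %.2f\n",
              d[1], d[2], d[3], length(unique(x$labels)), mean(x$pixels)))
  invisible(x)
}

#' Adjust the mean brightness of an image dataset
#'
#' Rescales all pixel intensities multiplicatively, with clipping to
#' \[0, 255\], so that the post-clip mean intensity matches `target_mean`
#' within `tol`. The scale factor is found by bisection (at most 60
#' iterations). This mirrors matching the average brightness of datasets
#' before comparing their slope curves; the default tolerance 0.045 on the
#' \[0, 255\] scale is the brightness-difference bound used for that matching.
#'
#' @param ds an `image_dataset`.
#' @param target_mean desired mean intensity in \[0, 255\].
#' @param tol acceptable |mean - target| after adjustment (default 0.045).
#' @return the adjusted `image_dataset` (unchanged if already exactly on
#'   target).
#' @export
adjust_brightness <- function(ds, target_mean, tol = 0.045) {
  .assert(inherits(ds, "image_dataset"), "ds must be an image_dataset")
  .assert(is.numeric(target_mean) && target_mean >= 0 && target_mean <= 255,
          "target_mean must lie in [0, 255]")
  cur <- mean(ds$pixels)
  if (identical(cur, target_mean)) return(ds)
  res <- .scale_to_mean(ds$pixels, target_mean, tol)
  ds$pixels <- array(res$pixels, dim = dim(ds$pixels))
  ds$meta$brightness_adjusted <- list(target = target_mean, scale = res$scale)
  ds
}

#' Build a deterministic spike-train fixture from an event list
#'
#' Constructs a single-sample binary spike train with exactly the listed
#' events set to 1 — the synthetic input used to demonstrate single-neuron
#' coincidence-versus-integration behaviour.
#'
#' @param events a data.frame with columns `step` and `channel` (1-based), or
#'   a 2-column matrix; may be empty.
#' @param n_steps,n_channels dimensions of the train.
#' @param dt step size in ms (default 5).
#' @return a [spike_train_batch()] with one sample.
#' @export
make_spike_fixture <- function(events, n_steps, n_channels, dt = 5) {
  if (is.matrix(events)) events <- data.frame(step = events[, 1], channel = events[, 2])
  if (is.null(events) || nrow(events) == 0)
    events <- data.frame(step = integer(0), channel = integer(0))
  .assert(all(c("step", "channel") %in% names(events)),
          "events needs columns 'step' and 'channel'")
  .assert(all(events$step >= 1 & events$step <= n_steps),
          "event step out of range")
  .assert(all(events$channel >= 1 & events$channel <= n_channels),
          "event channel out of range")
  sp <- array(0, dim = c(1L, n_steps, n_channels))
  if (nrow(events) > 0)
    sp[cbind(1L, events$step, events$channel)] <- 1  # duplicates stay binary
  spike_train_batch(sp, dt = dt)
}

# ---- plain-text dataset container (CSV pixels + CSV labels + JSON meta) ----

#' Write / read an image dataset as a plain-text container
#'
#' The container is a directory holding `pixels.csv` (one row per sample,
#' columns are row-major flattened pixels), `labels.csv` (columns `sample`,
#' `label`) and `meta.json`. Any externally converted MNIST-like dataset in
#' this layout is accepted by [read_dataset()].
#'
#' @param ds an `image_dataset`.
#' @param dir directory to create/fill.
#' @return `dir`, invisibly (for `write_dataset`); an `image_dataset`
#'   (for `read_dataset`).
#' @export
write_dataset <- function(ds, dir) {
  .assert(inherits(ds, "image_dataset"), "ds must be an image_dataset")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- .flatten_rowmajor(ds$pixels)
  utils::write.csv(as.data.frame(flat), file.path(dir, "pixels.csv"), row.names = FALSE)
  utils::write.csv(data.frame(sample = seq_along(ds$labels), label = ds$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  meta <- ds$meta
  meta$image_side <- dim(ds$pixels)[2]
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  .assert(file.exists(file.path(dir, "pixels.csv")), "pixels.csv not found")
  flat <- as.matrix(utils::read.csv(file.path(dir, "pixels.csv")))
  lab <- utils::read.csv(file.path(dir, "labels.csv"))$label
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  side <- meta$image_side %||% as.integer(sqrt(ncol(flat)))
  n <- nrow(flat)
  px <- array(0, dim = c(n, side, side))
  for (r in seq_len(side))
    px[, r, ] <- flat[, ((r - 1) * side + 1):(r * side), drop = FALSE]
  structure(list(pixels = px, labels = as.integer(lab), meta = meta),
            class = "image_dataset")
}

# translate an image by (dr, dc) pixels, circularly: the pixel multiset — and
# with it the sample's mean brightness and intensity alphabet — is preserved
# exactly, which keeps the generator's brightness contract tight under
# per-sample jitter
.shift_image <- function(m, dr, dc) {
  side <- nrow(m)
  m[(seq_len(side) - 1L - dr) %% side + 1L,
    (seq_len(side) - 1L - dc) %% side + 1L]
}

# sample x row x col  ->  sample x (row-major flat channel)
.flatten_rowmajor <- function(pixels) {
  d <- dim(pixels)
  matrix(aperm(pixels, c(1, 3, 2)), nrow = d[1])
}
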