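#' Binary spike-train batch
#'
#' Container for binary spike tensors of shape `sample x time step x channel`,
#' produced by the Poisson encoder and by each LIF layer. Values are strictly
#' 0/1 and independent of the step size `dt`.
#'
#' @param spikes 3-d array `sample x step x channel` with values in \{0, 1\}.
#' @param dt step size in ms (default 5).
#' @return an object of class `spike_train_batch`.
#' @export
spike_train_batch <- function(spikes, dt = 5) {
  .assert(is.array(spikes) && length(dim(spikes)) == 3,
          "spikes must be a 3-d array (sample x step x channel)")
  .assert(dim(spikes)[2] >= 1, "n_steps must be >= 1")
  .assert(all(spikes == 0 | spikes == 1), "spike values must be 0 or 1")
  .assert(is.numeric(dt) && dt > 0, "dt must be positive")
  structure(list(spikes = spikes, dt = dt, n_steps = dim(spikes)[2]),
            class = "spike_train_batch")
}

#' @export
print.spike_train_batch <- function(x, ...) {
  d <- dim(x$spikes)
  cat(sprintf("<spike_train_batch> %d samples x %d steps x %d channels, dt=%g ms, rate %.3f\n",
              d[1], d[2], d[3], x$dt, mean(x$spikes)))
  invisible(x)
}

#' Poisson (Bernoulli-per-step) rate encoding of images
#'
#' Every pixel value becomes the probability of its channel spiking in each
#' time step: independent Bernoulli draws with `p = intensity / 255` at every
#' step. Channels are the row-major flattened pixels (row varies slowest),
#' fixed so trained weights are portable across runs. The default 100 steps of
#' 5 ms correspond to 500 ms of simulated stimulus.
#'
#' @param ds an `image_dataset` (intensities on \[0, 255\]).
#' @param n_steps number of time steps (default 100).
#' @param seed integer RNG seed; encoding is bit-identical given the seed.
#' @param dt step size in ms (default 5).
#' @return a [spike_train_batch()] with `n_samples x n_steps x side^2` spikes.
#' @export
poisson_encode <- function(ds, n_steps = 100L, seed = 1L, dt = 5) {
  .assert(inherits(ds, "image_dataset"), "ds must be an image_dataset")
  .assert(n_steps >= 1, "n_steps must be >= 1")
  p <- .flatten_rowmajor(ds$pixels) / 255   # the single /255 in the pipeline
  .assert(all(p >= 0 & p <= 1), "intensities must lie in [0, 255]")
  n <- nrow(p); C <- ncol(p)
  set.seed(as.integer(seed))
  sp <- array(0, dim = c(n, n_steps, C))
  for (t in seq_len(n_steps))                      # one draw block per step
    sp[, t, ] <- (matrix(runif(n * C), n, C) < p) * 1
  spike_train_batch(sp, dt = dt)
}

#' Empirical per-channel firing rate
#'
#' Mean spike probability per sample and channel — the sanity inverse of
#' [poisson_encode()]: for long trains it converges to `intensity / 255`.
#'
#' @param batch a `spike_train_batch`.
#' @return matrix `sample x channel` of rates in \[0, 1\].
#' @export
decode_rate <- function(batch) {
  .assert(inherits(batch, "spike_train_batch"), "batch must be a spike_train_batch")
  d <- dim(batch$spikes)
  # mean over the time dimension: permute time first, then grouped colMeans
  m <- colMeans(aperm(batch$spikes, c(2, 1, 3)), dims = 1)
  matrix(m, d[1], d[3])
}

#' Spike trains as a sparse event list
#'
#' Converts between the dense binary tensor and a tidy event list
#' (`sample`, `step`, `channel`), the plain-text persistence format.
#'
#' @param batch a `spike_train_batch`.
#' @return a data.frame with one row per spike.
#' @export
as_event_list <- function(batch) {
  .assert(inherits(batch, "spike_train_batch"), "batch must be a spike_train_batch")
  idx <- which(batch$spikes == 1, arr.ind = TRUE)
  ev <- data.frame(sample = idx[, 1], step = idx[, 2], channel = idx[, 3])
  ev[order(ev$sample, ev$step, ev$channel), , drop = FALSE]
}

#' @rdname as_event_list
#' @param events data.frame with columns `sample`, `step`, `channel`.
#' @param n_samples,n_steps,n_channels tensor dimensions.
#' @param dt step size in ms.
#' @export
from_event_list <- function(events, n_samples, n_steps, n_channels, dt = 5) {
  sp <- array(0, dim = c(n_samples, n_steps, n_channels))
  if (nrow(events) > 0)
    sp[cbind(events$sample, events$step, events$channel)] <- 1
  spike_train_batch(sp, dt = dt)
}
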