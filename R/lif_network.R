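#' Parameters of a discrete-time LIF layer
#'
#' Houses the quantities of the per-step membrane update
#' \deqn{V_t = \mathrm{ReLU}[\, W^\top x_t + (1 - \Delta t/t_{decay})\, V_{t-1}\,
#'   \Theta_2(V_{thresh} - V_{t-1}) \,], \qquad y_t = \Theta_1(V_t - V_{thresh}).}
#' The per-neuron leak is the inverse decay time (`w_leak = 1 / t_decay`), so
#' the carry factor is `lambda = 1 - dt / t_decay`. Decay times below `dt`
#' would make the carry factor negative (a sampling artifact at this temporal
#' resolution) and are rejected; `t_decay = Inf` (`lambda = 1`, the pure
#' integrator limit) is admitted for limit checks.
#'
#' Heaviside conventions, fixed so that every spike is followed by a reset:
#' `Theta1(0) = 1` (a membrane exactly at threshold spikes) and
#' `Theta2(0) = 0` (a membrane exactly at threshold resets on the next step).
#'
#' @param w_input weight matrix, `channels x neurons`.
#' @param t_decay per-neuron membrane decay time in ms (scalar recycled).
#' @param v_thresh spike threshold (default 1, without loss of generality).
#' @param dt temporal resolution in ms (default 5).
#' @param n_steps number of simulation steps; defaults to
#'   `duration_ms / dt` = 100.
#' @param duration_ms total simulated duration in ms (default 500).
#' @return an object of class `lif_params`.
#' @export
lif_params <- function(w_input, t_decay, v_thresh = 1, dt = 5,
                       n_steps = NULL, duration_ms = 500) {
  .assert(is.matrix(w_input), "w_input must be a channels x neurons matrix")
  n_neurons <- ncol(w_input)
  t_decay <- rep_len(as.numeric(t_decay), n_neurons)
  .assert(all(t_decay >= dt), sprintf(
    "t_decay must be >= dt (%g ms): smaller values are sampling artifacts", dt))
  .assert(v_thresh > 0, "v_thresh must be positive")
  .assert(dt > 0, "dt must be positive")
  if (is.null(n_steps)) n_steps <- as.integer(round(duration_ms / dt))
  .assert(n_steps >= 1, "n_steps must be >= 1")
  structure(list(w_input = w_input, t_decay = t_decay,
                 w_leak = 1 / t_decay, v_thresh = v_thresh,
                 dt = dt, n_steps = as.integer(n_steps),
                 lambda = 1 - dt / t_decay,
                 theta1_at_zero = 1L, theta2_at_zero = 0L),
            class = "lif_params")
}

#' @export
print.lif_params <- function(x, ...) {
  cat(sprintf("<lif_params> %d channels -> %d neurons, dt=%g ms, %d steps, t_decay [%g, %g] ms\n",
              nrow(x$w_input), ncol(x$w_input), x$dt, x$n_steps,
              min(x$t_decay), max(x$t_decay)))
  invisible(x)
}

#' One LIF update step
#'
#' Applies the membrane update to a batch: the weighted input current is added
#' to the leak-decayed previous potential, the carry is suppressed after a
#' spike (`Theta2`), negative inner states are clamped to zero (ReLU), and a
#' spike is emitted where the post-ReLU potential reaches threshold.
#'
#' @param v_prev previous potentials, `samples x neurons` matrix (or a vector
#'   for one sample); must be nonnegative.
#' @param x_t input spikes at this step, `samples x channels`.
#' @param params a [lif_params()].
#' @return list with `V` (post-update potentials, pre-reset at spike entries)
#'   and `y` (binary spikes), both `samples x neurons`.
#' @export
lif_step <- function(v_prev, x_t, params) {
  .assert(inherits(params, "lif_params"), "params must be lif_params")
  if (!is.matrix(x_t)) x_t <- matrix(x_t, nrow = 1)
  if (!is.matrix(v_prev)) v_prev <- matrix(v_prev, nrow = nrow(x_t))
  .assert(ncol(x_t) == nrow(params$w_input), "channel count does not match w_input")
  .assert(ncol(v_prev) == ncol(params$w_input), "neuron count does not match w_input")
  .assert(all(v_prev >= 0), "v_prev must be nonnegative")
  lam <- matrix(params$lambda, nrow(v_prev), ncol(v_prev), byrow = TRUE)
  carry <- v_prev * (v_prev < params$v_thresh)    # Theta2(vth - V_prev), Theta2(0)=0
  V <- x_t %*% params$w_input + lam * carry
  V[V < 0] <- 0                                   # no negative inner states
  y <- (V >= params$v_thresh) * 1                 # Theta1(V - vth), Theta1(0)=1
  list(V = V, y = y)
}

#' Simulate a LIF layer over a spike-train batch
#'
#' Runs [lif_step()] for all time steps from a zero initial state and records
#' the full history needed for spike attribution: membrane potentials (the
#' pre-reset value at spike steps), binary outputs, and zero flags marking
#' steps after which no history is carried forward (reset after a spike, ReLU
#' clamp to zero, or the zero initial state).
#'
#' @param batch input [spike_train_batch()].
#' @param params a [lif_params()]; `params$n_steps` is taken from the batch.
#' @return an object of class `membrane_trace` with arrays `V`, `y`,
#'   `zero_flags` (`samples x steps x neurons`), plus `dt`, `times` and
#'   `params`.
#' @export
simulate_layer <- function(batch, params) {
  .assert(inherits(batch, "spike_train_batch"), "batch must be a spike_train_batch")
  .assert(inherits(params, "lif_params"), "params must be lif_params")
  d <- dim(batch$spikes)
  .assert(d[3] == nrow(params$w_input), "channel count does not match w_input")
  S <- d[1]; Tn <- d[2]; N <- ncol(params$w_input)
  xp <- aperm(batch$spikes, c(1, 3, 2))           # samples x channels x steps
  lamM <- matrix(params$lambda, S, N, byrow = TRUE)
  V <- matrix(0, S, N)
  Varr <- array(0, dim = c(S, Tn, N))
  yarr <- array(0, dim = c(S, Tn, N))
  zarr <- array(0, dim = c(S, Tn, N))
  for (t in seq_len(Tn)) {
    carry <- V * (V < params$v_thresh)
    V <- matrix(xp[, , t], S) %*% params$w_input + lamM * carry
    V[V < 0] <- 0
    y <- (V >= params$v_thresh) * 1
    Varr[, t, ] <- V                              # pre-reset value recorded
    yarr[, t, ] <- y
    zarr[, t, ] <- ((V == 0) | (y == 1)) * 1      # no carry into t+1 from here
  }
  structure(list(V = Varr, y = yarr, zero_flags = zarr,
                 dt = batch$dt, times = seq_len(Tn) * batch$dt,
                 params = params),
            class = "membrane_trace")
}

#' @export
print.membrane_trace <- function(x, ...) {
  d <- dim(x$V)
  cat(sprintf("<membrane_trace> %d samples x %d steps x %d neurons, %d output spikes\n",
              d[1], d[2], d[3], sum(x$y)))
  invisible(x)
}

#' Output spikes of a trace as a spike-train batch
#'
#' @param trace a `membrane_trace`.
#' @return a [spike_train_batch()] of the layer's output spikes.
#' @export
trace_spikes <- function(trace) {
  .assert(inherits(trace, "membrane_trace"), "trace must be a membrane_trace")
  spike_train_batch(trace$y, dt = trace$dt)
}

#' Spike-count readout layer
#'
#' The output layer sums the hidden layer's spikes over time, normalizes by
#' the number of steps (so scores are comparable to one-hot targets under an
#' MSE loss), and maps them linearly to class scores. Predictions are the
#' argmax with ties broken toward the lowest class index.
#'
#' @param hidden a `spike_train_batch` of hidden spikes, or a precomputed
#'   `samples x neurons` spike-count matrix.
#' @param w_out readout matrix `neurons x classes`.
#' @param n_steps number of steps used for normalization (taken from the batch
#'   when `hidden` is one).
#' @return list with `scores` (`samples x classes`) and `predicted`
#'   (0-based class codes).
#' @export
readout <- function(hidden, w_out, n_steps = NULL) {
  if (inherits(hidden, "spike_train_batch")) {
    counts <- apply(hidden$spikes, c(1, 3), sum)
    n_steps <- hidden$n_steps
  } else {
    counts <- hidden
    .assert(!is.null(n_steps), "n_steps required when passing a count matrix")
  }
  .assert(ncol(counts) == nrow(w_out), "neuron count does not match w_out")
  scores <- (counts / n_steps) %*% w_out
  list(scores = scores,
       predicted = max.col(scores, ties.method = "first") - 1L)
}
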