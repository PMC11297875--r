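#' Start of the causally connected window behind an output spike
#'
#' An output spike at step `o` is generated from the input spikes accumulated
#' since the last step at which the neuron carried no history forward — a
#' reset after a previous spike, a ReLU clamp to zero, or the zero initial
#' state. Those events are the trace's `zero_flags`; this function returns the
#' greatest flagged step before `o` (or 0 for the simulation start). Within
#' `(window_start, o)` the potential is strictly positive and no spike occurs,
#' so the membrane update is linear over the window and the potential at `o`
#' decomposes exactly over the window's input spikes.
#'
#' @param trace a `membrane_trace` from [simulate_layer()].
#' @param neuron neuron index (1-based).
#' @param out_step time step of the output spike (1-based).
#' @param sample sample index (default 1).
#' @return the window start step `n0` with `0 <= n0 < out_step`; contributing
#'   input steps are `(n0, out_step]`.
#' @export
find_window_start <- function(trace, neuron, out_step, sample = 1L) {
  .assert(inherits(trace, "membrane_trace"), "trace must be a membrane_trace")
  .assert(trace$y[sample, out_step, neuron] == 1,
          "out_step is not an output spike of this neuron")
  if (out_step == 1L) return(0L)
  flags <- which(trace$zero_flags[sample, seq_len(out_step - 1L), neuron] == 1)
  if (length(flags) == 0) 0L else max(flags)
}

#' Attribute one output spike to its contributing input spikes
#'
#' Backtracks the membrane potential from an output spike to the input spikes
#' that built it, taking weight and membrane-decay effects into account: an
#' input spike on channel `j` at step `m` inside the window contributes
#' `c = w[j, neuron] * lambda^(out_step - m)` to the potential at the output
#' step, with `lambda = 1 - dt / t_decay`. Because the window is anchored at a
#' zero-potential step, the signed contributions of *all* window spikes sum
#' exactly to the recorded pre-reset potential (checked to relative 1e-8).
#'
#' The two operation-mode measures are derived from the attribution:
#' * `n_contributing` — the number of input spikes that actively stimulate the
#'   neuron, i.e. whose positive decayed contribution still accounts for at
#'   least a fraction `eps_frac` of the threshold potential at the output
#'   step (`c > eps_frac * v_thresh`, default 1%). Inhibitory
#'   (negative-weight) spikes enter the conservation sum but are not counted.
#'   The cutoff is what makes "actively contributes" meaningful: a short-decay
#'   neuron retains almost nothing of an input a few steps back, so its
#'   counted spikes and integration interval stay short, while a long-decay
#'   neuron's horizon spans most of the window.
#' * `integration_interval` — `(out_step - earliest counted step) * dt` in ms;
#'   a same-step input gives 0 ms.
#'
#' @param trace a `membrane_trace` of the layer.
#' @param inputs the `spike_train_batch` that was fed to the layer.
#' @param params the layer's [lif_params()].
#' @param neuron,out_step,sample location of the output spike (1-based).
#' @param eps_frac negligibility cutoff as a fraction of `v_thresh`
#'   (default 0.01).
#' @return an object of class `spike_attribution`: list with `neuron`,
#'   `out_step`, `window_start`, `contributions` (data.frame `channel`,
#'   `step`, `contribution`), `n_contributing`, `integration_interval_ms`,
#'   and `conservation_error` (relative).
#' @export
attribute_spike <- function(trace, inputs, params, neuron, out_step, sample = 1L,
                            eps_frac = 0.01) {
  .assert(inherits(inputs, "spike_train_batch"), "inputs must be a spike_train_batch")
  n0 <- find_window_start(trace, neuron, out_step, sample)
  lam <- params$lambda[neuron]
  eps <- eps_frac * params$v_thresh
  steps <- (n0 + 1L):out_step
  contrib <- vector("list", length(steps))
  for (i in seq_along(steps)) {
    m <- steps[i]
    ch <- which(inputs$spikes[sample, m, ] == 1)
    if (length(ch) == 0) next
    d <- out_step - m
    decay <- if (d == 0L) 1 else lam^d
    contrib[[i]] <- data.frame(channel = ch, step = m,
                               contribution = params$w_input[ch, neuron] * decay)
  }
  contrib <- do.call(rbind, contrib)
  if (is.null(contrib))
    contrib <- data.frame(channel = integer(0), step = integer(0),
                          contribution = numeric(0))
  v_pre <- trace$V[sample, out_step, neuron]
  cons_err <- abs(sum(contrib$contribution) - v_pre) / max(abs(v_pre), 1e-300)
  if (cons_err > 1e-8)
    stop(sprintf(
      "attribution inconsistency: window contributions miss the recorded potential by %.3g (relative)",
      cons_err), call. = FALSE)
  counted <- contrib$contribution > eps
  n_contributing <- sum(counted)
  interval <- if (n_contributing == 0) NA_real_
              else (out_step - min(contrib$step[counted])) * trace$dt
  structure(list(neuron = neuron, out_step = out_step, sample = sample,
                 window_start = n0, contributions = contrib,
                 n_contributing = n_contributing,
                 integration_interval_ms = interval,
                 conservation_error = cons_err),
            class = "spike_attribution")
}

#' @export
print.spike_attribution <- function(x, ...) {
  cat(sprintf("<spike_attribution> neuron %d, step %d (window %d..%d): %d contributing spikes over %.0f ms\n",
              x$neuron, x$out_step, x$window_start + 1L, x$out_step,
              x$n_contributing, x$integration_interval_ms))
  invisible(x)
}

# Fast exact aggregation of both measures over every output spike of a
# simulated batch. Counting uses the positive-weight spike-count matrix
# (one matmul per sample); the epsilon cutoff w * lambda^d > eps only bites at
# window depths d >= d_star(neuron) (where even the smallest positive weight
# decays below eps), and those rare deep steps are corrected exactly.
.measure_trace <- function(trace, inputs, params, eps_frac = 0.01) {
  d <- dim(trace$y); S <- d[1]; Tn <- d[2]; N <- d[3]
  W <- params$w_input
  eps <- eps_frac * params$v_thresh
  Wpos <- (W > eps) * 1   # weights at or below eps never count, at any distance
  lam <- params$lambda
  wpmin <- apply(W, 2, function(col) {
    p <- col[col > eps]
    if (length(p) == 0) Inf else min(p)
  })
  d_star <- ifelse(lam <= 0, 1,
            ifelse(lam >= 1 | !is.finite(wpmin), Tn + 1L,
                   pmax(1, ceiling(log(eps / wpmin) / log(pmin(lam, 1 - 1e-16))))))
  tot_n <- numeric(N); tot_iv <- numeric(N); n_spk <- integer(N)
  for (s in seq_len(S)) {
    Xs <- matrix(inputs$spikes[s, , ], Tn)          # T x C
    npos <- Xs %*% Wpos                             # T x N counts of w>0 spikes
    ys <- matrix(trace$y[s, , ], Tn)
    zs <- matrix(trace$zero_flags[s, , ], Tn)
    for (n in seq_len(N)) {
      os <- which(ys[, n] == 1)
      if (length(os) == 0) next
      prev_flag <- cummax(ifelse(zs[, n] == 1, seq_len(Tn), 0L))
      for (o in os) {
        n0 <- if (o == 1L) 0L else prev_flag[o - 1L]
        ms <- (n0 + 1L):o
        cnt <- sum(npos[ms, n])
        deep <- ms[o - ms >= d_star[n]]
        if (length(deep) > 0) {
          for (m in deep[npos[deep, n] > 0]) {
            ch <- which(Xs[m, ] == 1)
            wv <- W[ch, n]
            cnt <- cnt - sum(wv > eps) + sum(wv * lam[n]^(o - m) > eps)
          }
        }
        cand <- ms[npos[ms, n] > 0]
        first <- NA_integer_
        for (m in cand) {                           # earliest counted spike
          if (o - m < d_star[n]) { first <- m; break }
          ch <- which(Xs[m, ] == 1)
          if (any(W[ch, n] * lam[n]^(o - m) > eps)) { first <- m; break }
        }
        if (cnt > 0 && !is.na(first)) {
          tot_n[n] <- tot_n[n] + cnt
          tot_iv[n] <- tot_iv[n] + (o - first) * trace$dt
          n_spk[n] <- n_spk[n] + 1L
        }
      }
    }
  }
  data.frame(neuron = seq_len(N), decay_time_ms = params$t_decay,
             mean_n_contributing = ifelse(n_spk > 0, tot_n / n_spk, NA),
             mean_interval_ms = ifelse(n_spk > 0, tot_iv / n_spk, NA),
             n_spikes = n_spk)[n_spk > 0, , drop = FALSE]
}

#' Compute both operation-mode measures for every hidden neuron
#'
#' Encodes the dataset, simulates the trained network, attributes every output
#' spike of every hidden neuron, and aggregates the two measures (mean number
#' of contributing input spikes, mean effective integration interval) per
#' neuron, tagged with the neuron's decay time. Neurons that never spike yield
#' no row. With `aggregate = "bin"` the per-neuron means are further averaged
#' over neurons sharing a decay time (the binned-uniform granularity).
#'
#' @param model a `trained_model`.
#' @param dataset the evaluation `image_dataset` (typically the held-out
#'   split).
#' @param seed Poisson-encoding seed.
#' @param n_steps simulation steps (default: the model's).
#' @param aggregate `"neuron"` (default) or `"bin"`.
#' @param eps_frac negligibility cutoff for counted contributions, as a
#'   fraction of the threshold potential (default 0.01).
#' @return a data.frame of measure points: `neuron` (absent for bins),
#'   `decay_time_ms`, `mean_n_contributing`, `mean_interval_ms`, `n_spikes`.
#' @export
measure_model <- function(model, dataset, seed = 1L, n_steps = NULL,
                          aggregate = c("neuron", "bin"), eps_frac = 0.01) {
  aggregate <- match.arg(aggregate)
  .assert(inherits(model, "trained_model"), "model must be a trained_model")
  n_steps <- n_steps %||% model$params$n_steps
  batch <- poisson_encode(dataset, n_steps = n_steps, seed = seed,
                          dt = model$params$dt)
  trace <- simulate_layer(batch, model$params)
  mp <- .measure_trace(trace, batch, model$params, eps_frac = eps_frac)
  if (aggregate == "bin") {
    sp <- split(mp, mp$decay_time_ms)
    mp <- do.call(rbind, lapply(sp, function(g) data.frame(
      decay_time_ms = g$decay_time_ms[1],
      mean_n_contributing = mean(g$mean_n_contributing),
      mean_interval_ms = mean(g$mean_interval_ms),
      n_spikes = sum(g$n_spikes), n_neurons = nrow(g))))
    rownames(mp) <- NULL
    mp <- mp[order(mp$decay_time_ms), , drop = FALSE]
  }
  mp
}
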