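#' Decay-time initialization scheme
#'
#' Decay times are a non-trainable hyperparameter, initialized either with one
#' identical value for all hidden neurons (`"constant"`) or as a binned
#' uniform distribution: `n_bins` equidistant values spanning `range`
#' inclusive, each shared by `neurons_per_bin` consecutive neurons. The
#' defaults — 32 bins of 4 neurons spanning \[15, 480\] ms, i.e. 15 ms spacing —
#' cover the 500 ms simulation time while excluding decay times below the 5 ms
#' resolution.
#'
#' @param mode `"binned_uniform"` or `"constant"`.
#' @param constant_value decay time in ms for `mode = "constant"`.
#' @param range inclusive decay-time range in ms for `binned_uniform`.
#' @param n_bins number of equidistant bins.
#' @param neurons_per_bin neurons sharing each bin's decay time.
#' @return an object of class `decay_scheme`.
#' @export
decay_scheme <- function(mode = c("binned_uniform", "constant"),
                         constant_value = 240, range = c(15, 480),
                         n_bins = 32L, neurons_per_bin = 4L) {
  mode <- match.arg(mode)
  .assert(length(range) == 2 && range[1] < range[2], "range must be increasing")
  .assert(n_bins >= 2, "n_bins must be >= 2")
  .assert(neurons_per_bin >= 1, "neurons_per_bin must be >= 1")
  structure(list(mode = mode, constant_value = constant_value, range = range,
                 n_bins = as.integer(n_bins),
                 neurons_per_bin = as.integer(neurons_per_bin)),
            class = "decay_scheme")
}

#' Initialize per-neuron decay times
#'
#' @param scheme a [decay_scheme()].
#' @param hidden_size number of hidden neurons; for `binned_uniform` it must
#'   equal `n_bins * neurons_per_bin`.
#' @return numeric vector of decay times in ms, one per neuron.
#' @export
init_decay <- function(scheme, hidden_size) {
  .assert(inherits(scheme, "decay_scheme"), "scheme must be a decay_scheme")
  if (scheme$mode == "constant") return(rep(scheme$constant_value, hidden_size))
  .assert(scheme$n_bins * scheme$neurons_per_bin == hidden_size,
          sprintf("n_bins (%d) x neurons_per_bin (%d) must equal hidden_size (%d)",
                  scheme$n_bins, scheme$neurons_per_bin, hidden_size))
  vals <- seq(scheme$range[1], scheme$range[2], length.out = scheme$n_bins)
  rep(vals, each = scheme$neurons_per_bin)
}

#' Surrogate derivative of the spike threshold
#'
#' The binary threshold has zero derivative almost everywhere, so the backward
#' pass replaces it with the derivative of a logistic smoothing of the spike
#' function: `beta * s * (1 - s)` with `s = sigmoid(beta * (V - v_thresh))`.
#' It is smooth, nonnegative, and peaks at `beta / 4` when the membrane sits
#' exactly at threshold; `beta` sets the sharpness (default 10).
#'
#' @param V membrane potentials (any shape).
#' @param v_thresh threshold (default 1).
#' @param beta sharpness of the surrogate (default 10).
#' @return pseudo-derivative values, same shape as `V`.
#' @export
surrogate_grad <- function(V, v_thresh = 1, beta = 10) {
  s <- 1 / (1 + exp(-beta * (V - v_thresh)))
  beta * s * (1 - s)
}

#' Training configuration
#'
#' @param hidden_size hidden layer width (default 128).
#' @param n_steps simulation steps (default 100, i.e. 500 ms at 5 ms).
#' @param dt temporal resolution in ms (default 5).
#' @param epochs training epochs (default 10).
#' @param batch_size minibatch size (default 128).
#' @param learning_rate Adam step size (default 1e-3).
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decay rates and epsilon.
#' @param surrogate_beta sharpness of the surrogate gradient (default 10).
#' @param loss `"softmax_mse"` (default: class scores pass through a softmax
#'   before the mean-squared-error loss, so only relative scores matter and
#'   training does not inflate hidden firing rates) or `"mse"` (plain linear
#'   readout scores against one-hot targets).
#' @param init_scale scale of the symmetric-uniform fan-in input-weight
#'   initialization, limit `init_scale / sqrt(n_channels)` (default 0.5,
#'   putting hidden neurons in the sparse fluctuation-driven firing regime).
#' @param seed master seed for weight init, shuffling and encoding.
#' @param k_folds folds for cross-validation (default 5).
#' @return an object of class `train_config`.
#' @export
train_config <- function(hidden_size = 128L, n_steps = 100L, dt = 5,
                         epochs = 10L, batch_size = 128L,
                         learning_rate = 1e-3, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, adam_eps = 1e-8,
                         surrogate_beta = 10, loss = "softmax_mse",
                         init_scale = 0.5, seed = 1L, k_folds = 5L) {
  .assert(loss %in% c("softmax_mse", "mse"), "unknown loss")
  cfg <- list(hidden_size = as.integer(hidden_size), n_steps = as.integer(n_steps),
              dt = dt, epochs = as.integer(epochs),
              batch_size = as.integer(batch_size), learning_rate = learning_rate,
              adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
              adam_eps = adam_eps, surrogate_beta = surrogate_beta,
              loss = loss, init_scale = init_scale,
              seed = as.integer(seed), k_folds = as.integer(k_folds))
  .assert(all(vapply(cfg[c("hidden_size", "n_steps", "dt", "batch_size",
                           "learning_rate", "surrogate_beta", "k_folds")],
                     function(v) v > 0, logical(1))),
          "all train_config sizes and rates must be positive")
  .assert(cfg$epochs >= 0, "epochs must be >= 0")
  structure(cfg, class = "train_config")
}

# ---- forward / backward core -----------------------------------------------

# Forward pass over a batch array (S x T x C). Returns per-step potentials
# (pre-reset) and the spike-count readout features. With smooth = TRUE the
# readout feature uses sigmoid(beta (V - vth)) instead of the hard spike --
# the differentiable model whose exact gradient the BPTT below computes
# (reset and clamp gates frozen), used by the finite-difference check.
.snn_forward <- function(x, w, t_decay, dt = 5, v_thresh = 1, beta = 10,
                         smooth = FALSE, keep_V = TRUE) {
  d <- dim(x); S <- d[1]; Tn <- d[2]
  N <- ncol(w)
  lam <- 1 - dt / t_decay
  lamM <- matrix(lam, S, N, byrow = TRUE)
  xp <- aperm(x, c(1, 3, 2))
  V <- matrix(0, S, N)
  acc <- matrix(0, S, N)
  Varr <- if (keep_V) array(0, dim = c(S, Tn, N)) else NULL
  for (t in seq_len(Tn)) {
    carry <- V * (V < v_thresh)
    V <- matrix(xp[, , t], S) %*% w + lamM * carry
    V[V < 0] <- 0
    if (keep_V) Varr[, t, ] <- V
    acc <- acc + if (smooth) 1 / (1 + exp(-beta * (V - v_thresh)))
                 else (V >= v_thresh) * 1
  }
  list(rate = acc / Tn, V = Varr, xp = xp, lamM = lamM)
}

.softmax <- function(z) {
  e <- exp(z - apply(z, 1, max))
  e / rowSums(e)
}

# Loss and gradients for one batch. BPTT through the unrolled recurrence with
# the threshold's surrogate in the backward pass; the reset gate Theta2 and
# the ReLU mask are treated as constants (no surrogate on the reset path).
# The class mapping ends in a softmax before the MSE loss ("softmax_mse",
# default): only relative scores then matter, so training has no incentive to
# inflate hidden firing rates, which preserves the sparse spiking regime the
# operation-mode measures live in. "mse" is the plain linear-readout loss.
.snn_loss_grad <- function(x, y_onehot, w, w_out, t_decay, dt,
                           v_thresh = 1, beta = 10, smooth = FALSE,
                           loss_fn = c("softmax_mse", "mse")) {
  loss_fn <- match.arg(loss_fn)
  fw <- .snn_forward(x, w, t_decay, dt, v_thresh, beta, smooth = smooth, keep_V = TRUE)
  S <- nrow(fw$rate); K <- ncol(w_out); Tn <- dim(x)[2]
  scores <- fw$rate %*% w_out
  if (loss_fn == "softmax_mse") {
    p <- .softmax(scores)
    loss <- mean((p - y_onehot)^2)
    dp <- 2 * (p - y_onehot) / (S * K)
    ds <- p * (dp - rowSums(dp * p))    # softmax Jacobian applied to dp
  } else {
    err <- scores - y_onehot
    loss <- mean(err^2)
    ds <- 2 * err / (S * K)
  }
  d_wout <- crossprod(fw$rate, ds)
  d_rate <- ds %*% t(w_out)
  d_y <- d_rate / Tn                      # each step's spike enters the mean equally
  lamM <- fw$lamM
  d_w <- matrix(0, nrow(w), ncol(w))
  delta <- d_y * surrogate_grad(fw$V[, Tn, ], v_thresh, beta)
  for (t in seq(Tn, 1)) {
    Vt <- matrix(fw$V[, t, ], S)
    da <- delta * (Vt > 0)                # ReLU mask
    d_w <- d_w + crossprod(matrix(fw$xp[, , t], S), da)
    if (t > 1) {
      Vprev <- matrix(fw$V[, t - 1, ], S)
      delta <- d_y * surrogate_grad(Vprev, v_thresh, beta) +
        da * lamM * (Vprev < v_thresh)    # carry path; reset gate frozen
    }
  }
  if (!is.finite(loss))
    stop("non-finite loss encountered", call. = FALSE)
  list(loss = loss, d_w = d_w, d_wout = d_wout, scores = scores)
}

.adam_init <- function(shape) list(m = array(0, shape), v = array(0, shape), t = 0)

.adam_step <- function(state, grad, lr, b1, b2, eps) {
  state$t <- state$t + 1
  state$m <- b1 * state$m + (1 - b1) * grad
  state$v <- b2 * state$v + (1 - b2) * grad^2
  mhat <- state$m / (1 - b1^state$t)
  vhat <- state$v / (1 - b2^state$t)
  state$step <- lr * mhat / (sqrt(vhat) + eps)
  state
}

.glorot_init <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# Symmetric-uniform fan-in init for the input weights, scaled so hidden
# neurons start in the sparse, fluctuation-driven firing regime (per-step
# input currents well below threshold; spikes from coincidences and slow
# integration rather than constant suprathreshold drive).
.fanin_init <- function(n_in, n_out, scale = 0.5) {
  lim <- scale / sqrt(n_in)
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

.one_hot <- function(labels, n_classes) {
  Y <- matrix(0, length(labels), n_classes)
  Y[cbind(seq_along(labels), labels + 1L)] <- 1
  Y
}

# ---- training ---------------------------------------------------------------

#' Train a feed-forward LIF network
#'
#' Assembles encoder, hidden LIF layer and spike-count readout, and trains the
#' input and readout weights by surrogate-gradient backpropagation through
#' time: the forward pass stays binary; the backward pass replaces the
#' threshold's derivative with [surrogate_grad()] and treats the reset gate as
#' constant. The loss is the mean squared error between the normalized
#' spike-count scores and one-hot labels, minimized with Adam. Decay times
#' come from `scheme` and are never updated. Fully deterministic given
#' `config$seed`.
#'
#' @param dataset an `image_dataset` (the training split).
#' @param config a [train_config()].
#' @param scheme a [decay_scheme()].
#' @return an object of class `trained_model` with `params`
#'   ([lif_params()]), `w_out`, `config`, `scheme`, `history` (per-epoch loss
#'   and training accuracy) and `fold_id` (NA outside cross-validation).
#' @export
train_snn <- function(dataset, config, scheme) {
  .assert(inherits(dataset, "image_dataset"), "dataset must be an image_dataset")
  .assert(inherits(config, "train_config"), "config must be a train_config")
  .assert(inherits(scheme, "decay_scheme"), "scheme must be a decay_scheme")
  t_decay <- init_decay(scheme, config$hidden_size)
  batch <- poisson_encode(dataset, n_steps = config$n_steps,
                          seed = derive_seed(config$seed, "encode"),
                          dt = config$dt)
  C <- dim(batch$spikes)[3]
  K <- max(length(unique(dataset$labels)), max(dataset$labels) + 1L)
  set.seed(derive_seed(config$seed, "weight_init"))
  w <- .fanin_init(C, config$hidden_size, scale = config$init_scale)
  w_out <- .glorot_init(config$hidden_size, K)
  Y <- .one_hot(dataset$labels, K)
  n <- dim(batch$spikes)[1]
  st_w <- .adam_init(dim(w)); st_o <- .adam_init(dim(w_out))
  history <- data.frame(epoch = integer(0), loss = numeric(0), accuracy = numeric(0))
  if (config$epochs > 0) {
    set.seed(derive_seed(config$seed, "shuffle"))
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      ep_loss <- 0; ep_correct <- 0
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + config$batch_size - 1L, n)]
        xb <- batch$spikes[idx, , , drop = FALSE]
        g <- tryCatch(
          .snn_loss_grad(xb, Y[idx, , drop = FALSE], w, w_out, t_decay,
                         dt = config$dt, beta = config$surrogate_beta,
                         loss_fn = config$loss),
          error = function(e) stop(sprintf(
            "training failed at epoch %d, batch starting %d: %s",
            epoch, s0, conditionMessage(e)), call. = FALSE))
        st_w <- .adam_step(st_w, g$d_w, config$learning_rate,
                           config$adam_beta1, config$adam_beta2, config$adam_eps)
        st_o <- .adam_step(st_o, g$d_wout, config$learning_rate,
                           config$adam_beta1, config$adam_beta2, config$adam_eps)
        w <- w - st_w$step
        w_out <- w_out - st_o$step
        ep_loss <- ep_loss + g$loss * length(idx)
        pred <- max.col(g$scores, ties.method = "first") - 1L
        ep_correct <- ep_correct + sum(pred == dataset$labels[idx])
      }
      history <- rbind(history, data.frame(
        epoch = epoch, loss = ep_loss / n, accuracy = ep_correct / n))
    }
  }
  params <- lif_params(w, t_decay, v_thresh = 1, dt = config$dt,
                       n_steps = config$n_steps)
  structure(list(params = params, w_out = w_out, config = config,
                 scheme = scheme, n_classes = K, history = history,
                 fold_id = NA_integer_),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %d channels -> %d LIF neurons -> %d classes (%s decay), %d epochs\n",
              nrow(x$params$w_input), ncol(x$params$w_input), x$n_classes,
              x$scheme$mode, nrow(x$history)))
  if (nrow(x$history) > 0)
    cat(sprintf("  final train loss %.4f, accuracy %.3f\n",
                x$history$loss[nrow(x$history)],
                x$history$accuracy[nrow(x$history)]))
  invisible(x)
}

# ---- metrics ----------------------------------------------------------------

# Rank-based ROC AUC of scores for a binary indicator (Mann-Whitney, ties
# handled by midranks).
.binary_auc <- function(scores, positive) {
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification metrics: accuracy, macro F1, macro one-vs-rest AUC
#'
#' @param scores `samples x classes` score matrix.
#' @param labels true 0-based class codes.
#' @return list with `accuracy`, `macro_f1` and `auc`, each in \[0, 1\].
#'   Per-class F1 is 0 when precision and recall are both undefined or zero;
#'   AUC is macro-averaged over classes present in `labels`.
#' @export
classification_metrics <- function(scores, labels) {
  K <- ncol(scores)
  pred <- max.col(scores, ties.method = "first") - 1L
  acc <- mean(pred == labels)
  f1 <- vapply(seq_len(K) - 1L, function(k) {
    tp <- sum(pred == k & labels == k)
    fp <- sum(pred == k & labels != k)
    fn <- sum(pred != k & labels == k)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  auc <- vapply(seq_len(K) - 1L, function(k)
    .binary_auc(scores[, k + 1L], labels == k), numeric(1))
  list(accuracy = acc, macro_f1 = mean(f1), auc = mean(auc, na.rm = TRUE))
}

#' Evaluate a trained model on a dataset
#'
#' Encodes the dataset with a fresh Poisson seed, forward-simulates the
#' network and computes [classification_metrics()].
#'
#' @param model a `trained_model`.
#' @param dataset an `image_dataset`.
#' @param n_steps simulation steps (default: the model's).
#' @param seed Poisson-encoding seed.
#' @return list of metrics plus the score matrix (attribute `"scores"`).
#' @export
evaluate_model <- function(model, dataset, n_steps = NULL, seed = 1L) {
  .assert(inherits(model, "trained_model"), "model must be a trained_model")
  n_steps <- n_steps %||% model$params$n_steps
  batch <- poisson_encode(dataset, n_steps = n_steps, seed = seed,
                          dt = model$params$dt)
  counts <- .hidden_counts(batch, model$params)
  scores <- readout(counts, model$w_out, n_steps = n_steps)$scores
  m <- classification_metrics(scores, dataset$labels)
  attr(m, "scores") <- scores
  m
}

# hidden spike counts without storing the full trace
.hidden_counts <- function(batch, params) {
  d <- dim(batch$spikes); S <- d[1]; Tn <- d[2]; N <- ncol(params$w_input)
  xp <- aperm(batch$spikes, c(1, 3, 2))
  lamM <- matrix(params$lambda, S, N, byrow = TRUE)
  V <- matrix(0, S, N); counts <- matrix(0, S, N)
  for (t in seq_len(Tn)) {
    carry <- V * (V < params$v_thresh)
    V <- matrix(xp[, , t], S) %*% params$w_input + lamM * carry
    V[V < 0] <- 0
    counts <- counts + (V >= params$v_thresh)
  }
  counts
}

# ---- cross-validation -------------------------------------------------------

#' Seeded stratified k-fold assignment
#'
#' @param labels 0-based class codes.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer fold id (1..k) per sample; per-fold class counts differ
#'   from perfect stratification by at most one sample.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  .assert(k >= 2, "k must be >= 2")
  tab <- table(labels)
  .assert(all(tab >= k),
          sprintf("every class needs at least k=%d members for stratified folds", k))
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (cls in names(tab)) {
    idx <- which(labels == as.integer(cls))
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of the SNN
#'
#' Trains one model per fold on the remaining folds and evaluates it on the
#' held-out fold with a fold-specific encoding seed. The default `k = 5`
#' follows the standard five-fold protocol.
#'
#' @param dataset an `image_dataset`.
#' @param config a [train_config()] (`k_folds` taken from here).
#' @param scheme a [decay_scheme()].
#' @return object of class `cv_result`: list with `folds` (per-fold
#'   `list(model, metrics, test_idx)`) and `summary` (mean and SD of each
#'   metric across folds).
#' @export
crossvalidate_snn <- function(dataset, config, scheme) {
  k <- config$k_folds
  fold <- stratified_folds(dataset$labels, k, seed = derive_seed(config$seed, "folds"))
  res <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- .subset_dataset(dataset, fold != f)
    te <- .subset_dataset(dataset, fold == f)
    cfg_f <- config
    cfg_f$seed <- derive_seed(config$seed, paste0("fold", f))
    model <- train_snn(tr, cfg_f, scheme)
    model$fold_id <- f
    metrics <- evaluate_model(model, te,
                              seed = derive_seed(config$seed, paste0("eval", f)))
    res[[f]] <- list(model = model, metrics = metrics, test_idx = which(fold == f))
  }
  mm <- do.call(rbind, lapply(res, function(r)
    data.frame(accuracy = r$metrics$accuracy, macro_f1 = r$metrics$macro_f1,
               auc = r$metrics$auc)))
  structure(list(folds = res,
                 summary = data.frame(metric = names(mm),
                                      mean = vapply(mm, mean, numeric(1)),
                                      sd = vapply(mm, sd, numeric(1)),
                                      row.names = NULL)),
            class = "cv_result")
}

.subset_dataset <- function(ds, keep) {
  structure(list(pixels = ds$pixels[keep, , , drop = FALSE],
                 labels = ds$labels[keep], meta = ds$meta),
            class = "image_dataset")
}
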