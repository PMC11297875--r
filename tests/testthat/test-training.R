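test_that("init_decay: constant and binned-uniform schemes", {
  expect_equal(init_decay(decay_scheme("constant", constant_value = 240), 128),
               rep(240, 128))
  d <- init_decay(decay_scheme("binned_uniform"), 128)
  u <- sort(unique(d))
  expect_length(u, 32)
  expect_equal(unique(diff(u)), 15)
  expect_equal(range(u), c(15, 480))
  expect_true(all(table(d) == 4))
  expect_error(init_decay(decay_scheme("binned_uniform"), 127), "hidden_size")
})

test_that("surrogate gradient is the logistic-derivative pseudo-spike", {
  beta <- 10
  expect_equal(surrogate_grad(1, beta = beta), beta / 4)
  expect_lt(surrogate_grad(1 + 20 / beta, beta = beta), 1e-6)
  expect_lt(surrogate_grad(1 - 20 / beta, beta = beta), 1e-6)
  # equals the numerical derivative of the smoothed spike sigma(beta(V-1))
  v <- seq(0, 2, by = 0.05)
  h <- 1e-6
  sig <- function(v) 1 / (1 + exp(-beta * (v - 1)))
  num <- (sig(v + h) - sig(v - h)) / (2 * h)
  expect_equal(surrogate_grad(v, beta = beta), num, tolerance = 1e-6)
})

test_that("BPTT gradients match central finite differences on a toy network", {
  # 2 neurons, 3 steps, smooth forward (y = sigmoid), potentials kept away
  # from the threshold so the frozen reset/clamp gates are locally constant
  set.seed(2)
  C <- 3; N <- 2; Tn <- 3; K <- 2
  w <- matrix(runif(C * N, 0.05, 0.25), C, N)
  w_out <- matrix(rnorm(N * K, sd = 0.5), N, K)
  td <- c(30, 200)
  x <- array(0, c(2, Tn, C))
  x[1, 1, 1] <- 1; x[1, 2, 2] <- 1; x[2, 3, 3] <- 1; x[2, 1, 1] <- 1
  Y <- rbind(c(1, 0), c(0, 1))
  for (loss_fn in c("mse", "softmax_mse")) {
    g <- spikemode:::.snn_loss_grad(x, Y, w, w_out, td, dt = 5, beta = 4,
                                    smooth = TRUE, loss_fn = loss_fn)
    lossfun <- function(wv, wo) spikemode:::.snn_loss_grad(
      x, Y, matrix(wv, C, N), matrix(wo, N, K), td, dt = 5, beta = 4,
      smooth = TRUE, loss_fn = loss_fn)$loss
    h <- 1e-6
    num_w <- w
    for (i in seq_along(w)) {
      wp <- as.vector(w); wm <- as.vector(w)
      wp[i] <- wp[i] + h; wm[i] <- wm[i] - h
      num_w[i] <- (lossfun(wp, w_out) - lossfun(wm, w_out)) / (2 * h)
    }
    num_o <- w_out
    for (i in seq_along(w_out)) {
      op <- as.vector(w_out); om <- as.vector(w_out)
      op[i] <- op[i] + h; om[i] <- om[i] - h
      num_o[i] <- (lossfun(as.vector(w), op) - lossfun(as.vector(w), om)) / (2 * h)
    }
    denom <- pmax(abs(num_w), 1e-8)
    expect_lt(max(abs(g$d_w - num_w) / denom), 1e-4)
    expect_lt(max(abs(g$d_wout - num_o) / pmax(abs(num_o), 1e-8)), 1e-4)
  }
})

test_that("training is deterministic, leaves decay times untouched, reduces loss", {
  ds <- make_dataset(dataset_spec(160, image_side = 8, n_classes = 2, seed = 31))
  scheme <- decay_scheme("binned_uniform", n_bins = 8, neurons_per_bin = 2)
  cfg <- train_config(hidden_size = 16, n_steps = 30, epochs = 3,
                      batch_size = 64, seed = 17)
  m1 <- train_snn(ds, cfg, scheme)
  m2 <- train_snn(ds, cfg, scheme)
  expect_identical(m1$params$w_input, m2$params$w_input)
  expect_identical(m1$w_out, m2$w_out)
  expect_identical(m1$params$t_decay, init_decay(scheme, 16))  # bitwise
  expect_lt(m1$history$loss[3], m1$history$loss[1])

  # zero epochs returns the initialization
  m0 <- train_snn(ds, train_config(hidden_size = 16, n_steps = 30, epochs = 0,
                                   batch_size = 64, seed = 17), scheme)
  set.seed(derive_seed(17L, "weight_init"))
  w_init <- spikemode:::.fanin_init(64, 16, scale = cfg$init_scale)
  expect_identical(m0$params$w_input, w_init)
  expect_equal(nrow(m0$history), 0)
})

test_that("smoke test: strong 2-class dataset reaches >0.9 held-out accuracy", {
  ds <- make_dataset(dataset_spec(800, image_side = 12, n_classes = 2, seed = 41))
  fold <- stratified_folds(ds$labels, 5, seed = 1)
  tr <- spikemode:::.subset_dataset(ds, fold != 1L)
  te <- spikemode:::.subset_dataset(ds, fold == 1L)
  cfg <- train_config(hidden_size = 64, epochs = 10, seed = 3)
  scheme <- decay_scheme("binned_uniform", n_bins = 16, neurons_per_bin = 4)
  m <- train_snn(tr, cfg, scheme)
  met <- evaluate_model(m, te, seed = 9)
  expect_gt(met$accuracy, 0.9)
})

test_that("stratified folds partition the data and respect class balance", {
  labels <- rep(0:2, c(30, 21, 13))
  fold <- stratified_folds(labels, 5, seed = 2)
  expect_equal(sort(unique(fold)), 1:5)
  expect_length(fold, length(labels))
  tab <- table(fold, labels)
  for (k in 0:2) expect_lte(diff(range(tab[, k + 1])), 1)
  expect_error(stratified_folds(c(0, 0, 1), 3), "at least k")
})

test_that("classification metrics behave at their reference points", {
  # perfectly separated scores
  lab <- rep(0:1, each = 10)
  sc <- cbind(ifelse(lab == 0, 1, 0), ifelse(lab == 1, 1, 0))
  m <- classification_metrics(sc, lab)
  expect_equal(m$accuracy, 1)
  expect_equal(m$macro_f1, 1)
  expect_equal(m$auc, 1)

  # constant prediction on balanced K-class data -> accuracy 1/K
  labK <- rep(0:3, each = 25)
  scK <- matrix(0, 100, 4); scK[, 1] <- 1
  expect_equal(classification_metrics(scK, labK)$accuracy, 0.25)

  # random scores -> AUC ~ 0.5
  set.seed(7)
  scR <- matrix(rnorm(4000 * 2), 4000, 2)
  labR <- rep(0:1, 2000)
  expect_lt(abs(classification_metrics(scR, labR)$auc - 0.5), 0.05)
})

test_that("cross-validation trains one model per disjoint stratified fold", {
  ds <- make_dataset(dataset_spec(180, image_side = 8, n_classes = 3, seed = 51))
  cfg <- train_config(hidden_size = 16, n_steps = 30, epochs = 2,
                      batch_size = 64, seed = 5, k_folds = 3)
  scheme <- decay_scheme("binned_uniform", n_bins = 8, neurons_per_bin = 2)
  cv <- crossvalidate_snn(ds, cfg, scheme)
  expect_length(cv$folds, 3)
  idx <- sort(unlist(lapply(cv$folds, `[[`, "test_idx")))
  expect_identical(idx, seq_len(180))                     # disjoint cover
  expect_identical(cv$summary$metric, c("accuracy", "macro_f1", "auc"))
  expect_true(all(cv$summary$mean >= 0 & cv$summary$mean <= 1))
  expect_equal(train_config()$k_folds, 5L)                # default protocol
})
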