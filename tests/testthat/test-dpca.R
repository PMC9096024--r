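# Demixed PCA: tensor construction, marginalization identities, PCA limit,
# and cross-validated stimulus decoding with shuffle significance.

# Build a psth_tensor directly from per-trial rate matrices (no spike
# simulation), for precise control of the population signal.
toy_tensor <- function(n_neuron, n_time, n_trials, signal_fun, noise_sd = 1,
                       seed = 1) {
  set.seed(seed)
  conds <- c("pro", "anti")
  trial <- lapply(seq_len(n_neuron), function(i) {
    per <- lapply(conds, function(cond) {
      mu <- signal_fun(i, cond, seq_len(n_time))
      matrix(rep(mu, each = n_trials), n_trials, n_time) +
        matrix(rnorm(n_trials * n_time, 0, noise_sd), n_trials, n_time)
    })
    names(per) <- conds
    per
  })
  names(trial) <- sprintf("n%03d", seq_len(n_neuron))
  avg <- array(NA_real_, dim = c(n_neuron, 2L, n_time),
               dimnames = list(names(trial), conds, NULL))
  for (i in seq_len(n_neuron)) {
    for (j in 1:2) avg[i, j, ] <- colMeans(trial[[i]][[conds[j]]])
  }
  structure(list(avg = avg, trial = trial,
                 time = seq_len(n_time) * 0.1 - 0.65,
                 cell_ids = names(trial), dropped = character(0),
                 bin = 0.1),
            class = "psth_tensor")
}

test_that("tensor construction: bin count, constant cell, trial rule", {
  cfgs <- list(cell_config(baseline_rate_ss = 60, cs_baseline = 0))
  s <- make_spike_session(cfgs, n_blocks = 4, seed = 2)
  tensor <- build_tensor(s$cells, window = c(-1, 1), bin = 0.1)
  expect_equal(dim(tensor$avg), c(1L, 2L, 20L))
  expect_lt(abs(mean(tensor$avg) - 60), 5)

  # a cell lacking trials in one condition is dropped and recorded
  starved <- s$cells[[1]]
  starved$trials$outcome[starved$trials$condition == "anti"] <- "error"
  expect_error(build_tensor(list(starved)), "trial rule")
  both <- build_tensor(list(s$cells[[1]], starved))
  expect_equal(both$dropped, starved$cell_id)

  # rebuilt from the serialized session -> identical
  dir <- withr::local_tempdir()
  write_session(s, dir)
  s2 <- read_session(dir)
  t2 <- build_tensor(s2$cells, window = c(-1, 1), bin = 0.1)
  expect_equal(t2$avg, tensor$avg, tolerance = 1e-12)
})

test_that("stimulus-free populations put all energy in the condition-independent part", {
  # identical signal for pro and anti: stimulus marginalization is exactly 0
  tensor <- toy_tensor(12, 14, 20, function(i, cond, tt) {
    50 + 10 * sin(tt / 3 + i)
  }, noise_sd = 0, seed = 3)
  fit <- fit_dpca(tensor, lambda = 0, n_components = 3)
  expect_lt(fit$marg_var[["stimulus"]], 1e-20)
  expect_equal(fit$marg_var[["condition_independent"]], 1, tolerance = 1e-9)

  # with trial noise, the stimulus share stays small
  tensor_n <- toy_tensor(12, 14, 30, function(i, cond, tt) {
    50 + 10 * sin(tt / 3 + i)
  }, noise_sd = 2, seed = 4)
  fit_n <- fit_dpca(tensor_n, lambda = 0, n_components = 3)
  expect_lt(fit_n$marg_var[["stimulus"]], 0.05)
})

test_that("a pro/anti rate offset loads the leading stimulus component", {
  tensor <- toy_tensor(20, 14, 20, function(i, cond, tt) {
    base <- 50 + 5 * cos(tt / 4 + i / 3)
    if (i <= 10 && cond == "pro") base + 10 else base
  }, noise_sd = 0.5, seed = 5)
  fit <- fit_dpca(tensor, lambda = 0, n_components = 3)
  vc <- fit$marginalizations$stimulus$var_comp
  expect_gt(vc[1] / sum(vc), 0.8)
  expect_gt(fit$marg_var[["stimulus"]], 0.05)
})

test_that("with one marginalization and lambda 0, dPCA reduces to PCA", {
  set.seed(6)
  X <- matrix(rnorm(8 * 30), 8, 30)
  X <- X - rowMeans(X)
  f <- pcsacc:::fit_marginalization(X, X, lambda = 0, q = 3)
  pca <- svd(X)$u[, 1:3]
  # subspace angle between encoder axes and PCA axes
  for (k in 1:3) {
    ang <- acos(min(1, abs(sum(f$encoder[, k] * pca[, k]))))
    expect_lt(ang, 1e-6)
  }
  # explained variance ordered non-increasing
  expect_true(all(diff(f$var_comp) <= 1e-12))
})

test_that("variance fractions are ordered, bounded, and sum below one", {
  tensor <- toy_tensor(15, 14, 15, function(i, cond, tt) {
    50 + 8 * sin(tt / 2 + i) + (cond == "pro") * (i %% 3)
  }, noise_sd = 1, seed = 7)
  fit <- fit_dpca(tensor, lambda = 1, n_components = 4)
  for (m in fit$marginalizations) {
    expect_true(all(m$var_comp >= 0))
    expect_true(all(diff(m$var_comp) <= 1e-12))
  }
  total <- sum(unlist(lapply(fit$marginalizations, `[[`, "var_comp")))
  expect_lte(total, 1 + 1e-6)
})

test_that("decoding is at chance on label-free data and near-perfect on strong signal", {
  # chance: no stimulus signal at all; ridge chosen by cross-validation
  # (an unregularised decoder would overfit the trial noise)
  null_tensor <- toy_tensor(20, 10, 40, function(i, cond, tt) {
    50 + 3 * sin(tt / 2 + i)
  }, noise_sd = 3, seed = 8)
  fit0 <- fit_dpca(null_tensor, lambda = NULL, n_components = 2)
  dec0 <- decode_stimulus(fit0, null_tensor, n_iter = 100, n_shuffles = 20,
                          components = 1, seed = 1)
  # per-bin accuracies wobble around chance (CV iterations reuse the same
  # trials, so their effective sample size is far below n_iter); the mean
  # over bins concentrates at 0.5
  expect_true(all(dec0$accuracy >= 0.30 & dec0$accuracy <= 0.70))
  expect_lt(abs(mean(dec0$accuracy) - 0.5), 0.05)

  # strong stimulus offset from bin 4 onward (instruction onset), 40
  # neurons: accuracy > 0.9 and significance already before bin 7
  # (instruction offset)
  strong <- toy_tensor(40, 14, 30, function(i, cond, tt) {
    base <- 50 + 4 * sin(tt / 3 + i / 2)
    if (cond == "pro") base + 10 * (tt >= 4) else base
  }, noise_sd = 4, seed = 9)
  fit1 <- fit_dpca(strong, lambda = NULL, n_components = 2)
  dec1 <- decode_stimulus(fit1, strong, n_iter = 60, n_shuffles = 40,
                          components = 1, seed = 2)
  expect_true(all(dec1$accuracy[1, 5:14] > 0.9))
  expect_true(any(dec1$significant[1, 5:7]))
  expect_false(any(dec1$significant[1, 1:3]))

  # signal gated on only late (saccade onset ~ bin 10): nothing significant
  # before the gate
  late <- toy_tensor(40, 14, 30, function(i, cond, tt) {
    base <- 50 + 4 * sin(tt / 3 + i / 2)
    if (cond == "pro") base + 10 * (tt >= 10) else base
  }, noise_sd = 4, seed = 10)
  fit2 <- fit_dpca(late, lambda = NULL, n_components = 2)
  dec2 <- decode_stimulus(fit2, late, n_iter = 60, n_shuffles = 40,
                          components = 1, seed = 3)
  expect_false(any(dec2$significant[1, 1:8]))
  expect_true(any(dec2$significant[1, 10:14]))
})

test_that("lambda cross-validation returns a grid value and a usable fit", {
  tensor <- toy_tensor(10, 10, 12, function(i, cond, tt) {
    50 + 5 * sin(tt / 2 + i) + (cond == "pro") * 2
  }, noise_sd = 2, seed = 11)
  lam <- select_lambda(tensor, lambdas = 10^seq(-2, 2), n_folds = 4,
                       n_components = 2)
  expect_true(lam %in% 10^seq(-2, 2))
  fit <- fit_dpca(tensor, lambda = NULL, n_components = 2)
  expect_true(is.finite(fit$lambda))
})
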