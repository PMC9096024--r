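# From-scratch demixed PCA on the population PSTH tensor with
# condition-independent and stimulus marginalizations, variance accounting,
# and component-as-decoder significance testing.

#' Build the population PSTH tensor
#'
#' Bins each neuron's saccade-task SS activity in 100 ms bins aligned to
#' instruction offset (target onset), averaged over correct trials within
#' condition (directions pooled). Neurons lacking `min_trials` correct
#' trials in either condition are dropped (their ids are recorded). A
#' trial-resolved companion tensor is kept for cross-validated decoding.
#'
#' @param cells list of `cell_recording`s with scored trials.
#' @param window `c(a, b)` interval around instruction offset, seconds.
#' @param bin bin width, seconds.
#' @param min_trials per-condition minimum of correct trials.
#' @return object of class `psth_tensor`: list with `avg` (array neuron x
#'   condition x time), `trial` (nested list `[[neuron]][[condition]]` of
#'   trials x time matrices), `time` (bin centres), `cell_ids`, `dropped`.
#' @export
build_tensor <- function(cells, window = c(-0.6, 0.8), bin = 0.100,
                         min_trials = 5) {
  edges <- seq(window[1], window[2], by = bin)
  n_bins <- length(edges) - 1L
  mids <- edges[-1] - bin / 2
  conds <- c("pro", "anti")
  keep <- list(); dropped <- character(0)
  for (cell in cells) {
    tr <- correct_trials(cell)
    n_by_cond <- table(factor(tr$condition, levels = conds))
    if (any(n_by_cond < min_trials)) {
      dropped <- c(dropped, cell$cell_id)
      next
    }
    per_cond <- lapply(conds, function(cond) {
      td <- tr[tr$condition == cond, , drop = FALSE]
      t(vapply(seq_len(nrow(td)), function(k) {
        e <- td$t_target_on[k]
        count_in_window(cell$ss_times, e + edges[-length(edges)],
                        e + edges[-1]) / bin
      }, numeric(n_bins)))
    })
    names(per_cond) <- conds
    keep[[cell$cell_id]] <- per_cond
  }
  if (length(keep) == 0L) stop_invalid("no cells pass the trial rule")
  avg <- array(NA_real_, dim = c(length(keep), 2L, n_bins),
               dimnames = list(names(keep), conds, NULL))
  for (i in seq_along(keep)) {
    for (j in 1:2) avg[i, j, ] <- colMeans(keep[[i]][[j]])
  }
  structure(list(avg = avg, trial = keep, time = mids,
                 cell_ids = names(keep), dropped = dropped, bin = bin),
            class = "psth_tensor")
}

# Unroll an (N, 2, T) array to N x 2T and split into the two
# marginalizations: condition-independent (per-time mean over conditions)
# and stimulus (residual). Rows are mean-centred first.
marginalize <- function(avg) {
  n <- dim(avg)[1]; tt <- dim(avg)[3]
  X <- cbind(avg[, 1, , drop = TRUE], avg[, 2, , drop = TRUE])
  if (n == 1L) X <- matrix(X, nrow = 1L)
  mu <- rowMeans(X)
  X <- X - mu
  ci_half <- (X[, 1:tt, drop = FALSE] + X[, tt + (1:tt), drop = FALSE]) / 2
  X_ci <- cbind(ci_half, ci_half)
  list(X = X, marg = list(condition_independent = X_ci,
                          stimulus = X - X_ci),
       mu = mu, n_time = tt)
}

# svd with a fallback for the occasional dgesdd convergence failure: retry
# on the transpose (uses a different LAPACK path), then with a tiny jitter.
safe_svd <- function(x) {
  tryCatch(svd(x), error = function(e) {
    tryCatch({
      s <- svd(t(x))
      list(d = s$d, u = s$v, v = s$u)
    }, error = function(e2) {
      svd(x * (1 + 1e-12) + max(abs(x)) * 1e-12)
    })
  })
}

# Moore-Penrose pseudo-inverse of a symmetric PSD matrix via its SVD.
psd_pinv <- function(M, tol = 1e-10) {
  s <- safe_svd(M)
  keep <- s$d > max(s$d[1], 0) * tol
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

fit_marginalization <- function(X, X_phi, lambda, q) {
  n <- nrow(X)
  G <- X %*% t(X)
  C <- X_phi %*% t(X) %*% psd_pinv(G + diag(lambda, n))
  P <- C %*% X
  sv <- safe_svd(P)
  r <- sum(sv$d > max(sv$d[1], 1e-12) * 1e-10)
  q <- min(q, r)
  if (q == 0L) {
    return(list(encoder = matrix(0, n, 0), decoder = matrix(0, 0, n),
                var_comp = numeric(0)))
  }
  FF <- sv$u[, seq_len(q), drop = FALSE]       # encoder axes (columns)
  D <- t(FF) %*% C                             # decoder rows
  var_comp <- vapply(seq_len(q), function(i) {
    comp <- FF[, i, drop = FALSE] %*% (D[i, , drop = FALSE] %*% X)
    sum(comp^2)
  }, numeric(1))
  ord <- order(var_comp, decreasing = TRUE)
  list(encoder = FF[, ord, drop = FALSE],
       decoder = D[ord, , drop = FALSE],
       var_comp = var_comp[ord])
}

#' Fit demixed PCA
#'
#' Decomposes the mean-centred population PSTH matrix into
#' condition-independent (average over the two stimulus conditions) and
#' stimulus (residual) marginalizations, then per marginalization solves the
#' ridge-regularised reduced-rank least-squares problem
#' `min ||X_phi - F D X||^2 + lambda ||D||^2` for encoder/decoder axis
#' pairs. Components are ordered by explained variance within
#' marginalization. With a single effective marginalization and
#' `lambda = 0`, the encoder axes coincide with ordinary PCA axes.
#'
#' @param tensor a `psth_tensor` from [build_tensor()].
#' @param lambda ridge regulariser (absolute). `NULL` selects it on a
#'   logarithmic grid by held-out-trial cross-validation
#'   ([select_lambda()]).
#' @param n_components number of components per marginalization.
#' @return object of class `dpca_fit`: per marginalization the `encoder`
#'   (N x q), `decoder` (q x N), `var_comp` (component variance fractions of
#'   total), plus `marg_var` (variance fraction per marginalization),
#'   `total_var`, `time`, `cell_ids`, `lambda`.
#' @export
fit_dpca <- function(tensor, lambda = 0, n_components = 5) {
  avg <- tensor$avg
  if (dim(avg)[1] < 2L || dim(avg)[3] < 2L) {
    stop_invalid("need at least 2 neurons and 2 time bins")
  }
  if (is.null(lambda)) lambda <- select_lambda(tensor,
                                               n_components = n_components)
  mg <- marginalize(avg)
  total <- sum(mg$X^2)
  fits <- lapply(names(mg$marg), function(nm) {
    f <- fit_marginalization(mg$X, mg$marg[[nm]], lambda, n_components)
    f$var_comp <- f$var_comp / total
    f
  })
  names(fits) <- names(mg$marg)
  marg_var <- vapply(mg$marg, function(m) sum(m^2) / total, numeric(1))
  structure(list(marginalizations = fits, marg_var = marg_var,
                 total_var = total, time = tensor$time,
                 cell_ids = tensor$cell_ids, mu = mg$mu,
                 n_time = mg$n_time, lambda = lambda),
            class = "dpca_fit")
}

#' Select the dPCA ridge parameter by cross-validation
#'
#' Splits each neuron's trials into `n_folds` folds; for each candidate
#' lambda, fits dPCA on the training-trial averages and measures the
#' reconstruction error of the held-out-trial averages, summed over
#' marginalizations. Returns the lambda with the smallest mean error.
#'
#' @param tensor a `psth_tensor`.
#' @param lambdas candidate grid.
#' @param n_folds number of folds.
#' @param n_components components per marginalization.
#' @param seed RNG seed for the fold assignment.
#' @return the selected lambda (numeric scalar).
#' @export
select_lambda <- function(tensor, lambdas = 10^seq(-3, 6, by = 1),
                          n_folds = 10, n_components = 5, seed = 1) {
  set.seed(seed)
  conds <- c("pro", "anti")
  n <- length(tensor$trial); tt <- length(tensor$time)
  folds <- lapply(tensor$trial, function(per_cond) {
    lapply(per_cond, function(m) {
      sample(rep_len(seq_len(n_folds), nrow(m)))
    })
  })
  err <- numeric(length(lambdas))
  for (f in seq_len(n_folds)) {
    tr_avg <- array(0, dim = c(n, 2L, tt))
    te_avg <- array(NA_real_, dim = c(n, 2L, tt))
    for (i in seq_len(n)) {
      for (j in 1:2) {
        m <- tensor$trial[[i]][[conds[j]]]
        hold <- folds[[i]][[j]] == f
        if (all(hold) || !any(hold)) {
          hold <- seq_len(nrow(m)) == 1L  # degenerate fold; keep one out
        }
        tr_avg[i, j, ] <- colMeans(m[!hold, , drop = FALSE])
        te_avg[i, j, ] <- colMeans(m[hold, , drop = FALSE])
      }
    }
    mg_tr <- marginalize(tr_avg)
    mg_te <- marginalize(te_avg)
    for (li in seq_along(lambdas)) {
      e <- 0
      for (nm in names(mg_tr$marg)) {
        fit <- fit_marginalization(mg_tr$X, mg_tr$marg[[nm]], lambdas[li],
                                   n_components)
        if (ncol(fit$encoder) == 0L) next
        rec <- fit$encoder %*% (fit$decoder %*% mg_te$X)
        e <- e + sum((mg_te$marg[[nm]] - rec)^2)
      }
      err[li] <- err[li] + e
    }
  }
  lambdas[which.min(err)]
}

#' Decode the stimulus condition from dPCA components
#'
#' Uses each stimulus-marginalization component as a linear decoder of the
#' pro/anti condition, time bin by time bin, with leave-group-out
#' cross-validation: on each iteration one random trial per neuron and
#' condition is held out to form test pseudo-trials, the stimulus decoder
#' axes are refit on the training-trial averages (so held-out trials never
#' influence the axis), class means are computed from the training averages
#' projected on the axis, and the held-out projection is classified to the
#' nearer class mean. Significance uses a shuffle null (condition labels
#' permuted within neuron) with a max-over-time statistic: a bin is
#' significant when its accuracy exceeds the 95th percentile of the
#' shuffles' time-course maxima. Chance level is 0.5.
#'
#' @param fit a `dpca_fit`.
#' @param tensor the `psth_tensor` the fit came from (trial-resolved data).
#' @param n_iter cross-validation iterations.
#' @param n_shuffles label shuffles for the null.
#' @param components which stimulus components to decode (default all
#'   fitted).
#' @param seed RNG seed.
#' @return list with `accuracy` (components x time), `significant`
#'   (logical, same shape), `threshold` (per component), `time`.
#' @export
decode_stimulus <- function(fit, tensor, n_iter = 100, n_shuffles = 100,
                            components = NULL, seed = 1) {
  set.seed(seed)
  n_comp_fit <- nrow(fit$marginalizations$stimulus$decoder)
  if (is.null(components)) components <- seq_len(n_comp_fit)
  conds <- c("pro", "anti")
  n <- length(tensor$trial); tt <- length(tensor$time)
  trial_mats <- lapply(tensor$trial, function(pc) {
    list(pro = pc$pro, anti = pc$anti)
  })
  run_cv <- function(mats, iters) {
    acc <- matrix(0, length(components), tt)
    for (it in seq_len(iters)) {
      test_idx <- lapply(mats, function(pc) {
        c(pro = sample.int(nrow(pc$pro), 1L),
          anti = sample.int(nrow(pc$anti), 1L))
      })
      train_avg <- matrix(0, n, 2L * tt)
      test_mat <- matrix(0, n, 2L * tt)
      for (i in seq_len(n)) {
        for (j in 1:2) {
          m <- mats[[i]][[conds[j]]]
          ti <- test_idx[[i]][j]
          cols <- (j - 1L) * tt + seq_len(tt)
          if (nrow(m) > 1L) {
            train_avg[i, cols] <- colMeans(m[-ti, , drop = FALSE])
          } else {
            # too few trials: resample with replacement
            train_avg[i, cols] <- m[sample.int(nrow(m), 1L), ]
          }
          test_mat[i, cols] <- m[ti, ]
        }
      }
      mu <- rowMeans(train_avg)
      Xtr <- train_avg - mu
      # refit the stimulus decoder on training data only
      ci_half <- (Xtr[, 1:tt, drop = FALSE] +
                    Xtr[, tt + (1:tt), drop = FALSE]) / 2
      X_st <- Xtr - cbind(ci_half, ci_half)
      f <- fit_marginalization(Xtr, X_st, fit$lambda,
                               max(components))
      dec <- f$decoder[components, , drop = FALSE]
      if (nrow(dec) < length(components)) next
      proj_train <- dec %*% Xtr                # q x 2T
      proj_test <- dec %*% (test_mat - mu)
      for (b in seq_len(tt)) {
        m_pro <- proj_train[, b]
        m_anti <- proj_train[, tt + b]
        x_pro <- proj_test[, b]
        x_anti <- proj_test[, tt + b]
        pred_pro <- abs(x_pro - m_pro) < abs(x_pro - m_anti)
        pred_anti <- abs(x_anti - m_anti) < abs(x_anti - m_pro)
        acc[, b] <- acc[, b] + (pred_pro + pred_anti) / 2
      }
    }
    acc / iters
  }
  accuracy <- run_cv(trial_mats, n_iter)
  # shuffle null: permute trial condition labels within neuron
  shuffle_max <- matrix(NA_real_, n_shuffles, length(components))
  n_iter_sh <- max(5L, ceiling(n_iter / 10))
  for (s in seq_len(n_shuffles)) {
    sh <- lapply(trial_mats, function(pc) {
      pool <- rbind(pc$pro, pc$anti)
      idx <- sample.int(nrow(pool))
      n_pro <- nrow(pc$pro)
      list(pro = pool[idx[seq_len(n_pro)], , drop = FALSE],
           anti = pool[idx[-seq_len(n_pro)], , drop = FALSE])
    })
    a <- run_cv(sh, n_iter_sh)
    shuffle_max[s, ] <- apply(a, 1, max)
  }
  threshold <- apply(shuffle_max, 2, quantile, probs = 0.95, names = FALSE)
  significant <- sweep(accuracy, 1, threshold, ">")
  list(accuracy = accuracy, significant = significant,
       threshold = threshold, time = tensor$time)
}
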