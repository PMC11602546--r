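#' Gaussian mean-variance-estimation loss
#'
#' Heteroscedastic negative log-likelihood (constant dropped):
#' `0.5 logvar + 0.5 (y - mu)^2 exp(-logvar)`, summed over its inputs. For
#' fixed `mu` it is minimized at `logvar = ln((y - mu)^2)`; for fixed
#' variance at `mu = y`.
#'
#' @param mu predicted mean(s) on the logit scale.
#' @param logvar predicted log variance(s).
#' @param y_logit observed target(s) on the logit scale.
#' @return scalar loss.
#' @export
mve_loss <- function(mu, logvar, y_logit) {
  sum(0.5 * logvar + 0.5 * (y_logit - mu)^2 * exp(-logvar))
}

# clamp targets away from {0,1} before logit
logit_clamped <- function(x, eps = 1e-3) qlogis(pmin(pmax(x, eps), 1 - eps))

#' Build a per-graph simulated training set
#'
#' Simulates clonal regeneration on one observed graph over a broad sweep
#' of parameters (`f ~ Uniform(0.02, 0.8)`, `p ~ LogUniform(0.01, 1)`),
#' computes the local-assortativity profiles at both damping factors and
#' their summary features for every simulation, and records the true
#' parameters as regression targets. Simulations are sub-seeded by index,
#' so the whole set is deterministic given `seed`. Every fifth simulation
#' (by index) is held out as the validation split.
#'
#' @param graph a connected `cell_graph` (should have passed
#'   [filter_by_size()]).
#' @param n_sim number of simulations (default 2000).
#' @param f_range range of the new-cell fraction sampler.
#' @param p_range range of the (log-uniform) progenitor-fraction sampler.
#' @param dampings the two damping factors for the feature profiles.
#' @param damping_sim damping factor of the simulator gradient/domains.
#' @param seed base RNG seed.
#' @return a `training_set` list: `features` (n_sim x 23 matrix), `targets`
#'   (data.frame with `progenitor_fraction`, `new_fraction`), `is_val`
#'   (logical split), `graph_id`, `seed`, and the precomputed PageRank
#'   matrices in `W` (named by damping, reused at prediction time).
#' @export
build_training_set <- function(graph, n_sim = 2000,
                               f_range = c(0.02, 0.8),
                               p_range = c(0.01, 1),
                               dampings = c(0.1, 0.7),
                               damping_sim = 0.7,
                               seed = 1L) {
  N <- nrow(graph$nodes)
  set.seed(seed)
  f_vec <- runif(n_sim, f_range[1], f_range[2])
  p_vec <- exp(runif(n_sim, log(p_range[1]), log(p_range[2])))
  W <- lapply(unique(c(dampings, damping_sim)), function(d) ppr_matrix(graph, d))
  names(W) <- as.character(unique(c(dampings, damping_sim)))
  Wsim <- W[[as.character(damping_sim)]]
  colors <- matrix(0L, N, n_sim)
  for (i in seq_len(n_sim)) {
    pars <- sim_params(p_vec[i], f_vec[i], seed = seed + i)
    sim <- simulate_regeneration(graph, pars, W = Wsim, damping = damping_sim)
    colors[, i] <- sim$color
  }
  pb1 <- profile_batch(graph, colors, W[[as.character(dampings[1])]])
  pb2 <- profile_batch(graph, colors, W[[as.character(dampings[2])]])
  ok <- pb1$valid & pb2$valid
  if (!all(ok))
    warning(sum(!ok), " simulation(s) produced a monochromatic coloring and were dropped")
  feats <- t(vapply(which(ok), function(i) {
    as.numeric(distribution_features(pb1$r[, i], pb2$r[, i]))
  }, numeric(23)))
  colnames(feats) <- names(distribution_features(pb1$r[, which(ok)[1]],
                                                 pb2$r[, which(ok)[1]]))
  idx <- which(ok)
  structure(list(features = feats,
                 targets = data.frame(progenitor_fraction = p_vec[idx],
                                      new_fraction = f_vec[idx]),
                 is_val = idx %% 5 == 0,
                 sim_index = idx,
                 n_dropped = sum(!ok),
                 graph_id = graph$meta$image_id,
                 dampings = dampings, damping_sim = damping_sim,
                 seed = seed, W = W),
            class = "training_set")
}

# ---- internal MLP machinery (2 hidden layers, tanh, MVE head) ----

mlp_init <- function(d_in, hidden, seed) {
  set.seed(seed)
  sizes <- c(d_in, hidden, 4L)
  pars <- list()
  for (l in seq_len(length(sizes) - 1)) {
    fan_in <- sizes[l]
    pars[[paste0("W", l)]] <- matrix(rnorm(sizes[l] * sizes[l + 1], 0,
                                           sqrt(1 / fan_in)),
                                     sizes[l], sizes[l + 1])
    pars[[paste0("b", l)]] <- rep(0, sizes[l + 1])
  }
  pars
}

mlp_forward <- function(pars, X, lv_clamp) {
  H1 <- tanh(sweep(X %*% pars$W1, 2, pars$b1, "+"))
  H2 <- tanh(sweep(H1 %*% pars$W2, 2, pars$b2, "+"))
  O <- sweep(H2 %*% pars$W3, 2, pars$b3, "+")
  mu <- O[, 1:2, drop = FALSE]
  lv_raw <- O[, 3:4, drop = FALSE]
  lv <- pmin(pmax(lv_raw, lv_clamp[1]), lv_clamp[2])
  list(H1 = H1, H2 = H2, mu = mu, lv = lv, lv_raw = lv_raw)
}

# gradient of mean MVE loss (or warm-up squared error) w.r.t. parameters
mlp_grad <- function(pars, X, Y, fw, lv_clamp, warmup) {
  n <- nrow(X)
  resid <- Y - fw$mu
  if (warmup) {
    dmu <- -resid / n
    dlv <- matrix(0, n, 2)
  } else {
    inv_var <- exp(-fw$lv)
    dmu <- -resid * inv_var / n
    dlv <- (0.5 - 0.5 * resid^2 * inv_var) / n
    dlv[fw$lv_raw < lv_clamp[1] | fw$lv_raw > lv_clamp[2]] <- 0
  }
  dO <- cbind(dmu, dlv)
  gW3 <- crossprod(fw$H2, dO)
  gb3 <- colSums(dO)
  dH2 <- (dO %*% t(pars$W3)) * (1 - fw$H2^2)
  gW2 <- crossprod(fw$H1, dH2)
  gb2 <- colSums(dH2)
  dH1 <- (dH2 %*% t(pars$W2)) * (1 - fw$H1^2)
  gW1 <- crossprod(X, dH1)
  gb1 <- colSums(dH1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

mlp_loss <- function(Y, fw, warmup) {
  if (warmup) {
    mean(rowSums(0.5 * (Y - fw$mu)^2))
  } else {
    mean(rowSums(0.5 * fw$lv + 0.5 * (Y - fw$mu)^2 * exp(-fw$lv)))
  }
}

#' Train the per-graph mean-variance-estimation regressor
#'
#' A feedforward network (default two hidden layers of 32 tanh units) maps
#' the PCA-reduced features of a simulation to per-target Gaussian
#' parameters (mean and log variance) on the logit scale; targets are the
#' old-cell fraction `1 - f` and the progenitor fraction `p`. Training
#' minimizes the Gaussian negative log likelihood ([mve_loss()]) by
#' full-batch Adam, with a warm-up phase that fits the means under frozen
#' unit variance before joint optimization (the standard MVE
#' stabilization), and early stopping on the validation split.
#'
#' @param ts a `training_set` from [build_training_set()].
#' @param projection a [fit_projection()] fitted on the training split of
#'   `ts` (see [fit_inference()] for the assembled pipeline).
#' @param hidden hidden layer widths.
#' @param lv_clamp allowed log-variance range.
#' @param lr Adam step size.
#' @param warmup_epochs,max_epochs training schedule.
#' @param patience early-stopping patience in validation checks (every 10
#'   epochs).
#' @param seed RNG seed for the weight initialization.
#' @return an `mve_model` object.
#' @export
train_model <- function(ts, projection, hidden = c(32, 32),
                        lv_clamp = c(-10, 3), lr = 0.01,
                        warmup_epochs = 500, max_epochs = 5000,
                        patience = 50, seed = 1L) {
  X_all <- apply_projection(projection, ts$features)
  y_old <- logit_clamped(1 - ts$targets$new_fraction)
  y_p <- logit_clamped(ts$targets$progenitor_fraction)
  Y_all <- cbind(y_old, y_p)
  tr <- !ts$is_val
  if (!any(tr)) stop("training split is empty")
  x_mean <- colMeans(X_all[tr, , drop = FALSE])
  x_sd <- pmax(apply(X_all[tr, , drop = FALSE], 2, sd), 1e-12)
  scale_x <- function(X) sweep(sweep(X, 2, x_mean, "-"), 2, x_sd, "/")
  Xtr <- scale_x(X_all[tr, , drop = FALSE]); Ytr <- Y_all[tr, , drop = FALSE]
  Xva <- scale_x(X_all[!tr, , drop = FALSE]); Yva <- Y_all[!tr, , drop = FALSE]
  has_val <- nrow(Xva) > 0

  pars <- mlp_init(ncol(Xtr), hidden, seed)
  m <- lapply(pars, function(p) p * 0)
  v <- lapply(pars, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(loss = Inf, pars = pars, epoch = 0L)
  bad <- 0L
  t_adam <- 0
  for (epoch in seq_len(max_epochs)) {
    warmup <- epoch <= warmup_epochs
    fw <- mlp_forward(pars, Xtr, lv_clamp)
    gr <- mlp_grad(pars, Xtr, Ytr, fw, lv_clamp, warmup)
    t_adam <- t_adam + 1
    for (nm in names(pars)) {
      m[[nm]] <- b1 * m[[nm]] + (1 - b1) * gr[[nm]]
      v[[nm]] <- b2 * v[[nm]] + (1 - b2) * gr[[nm]]^2
      mhat <- m[[nm]] / (1 - b1^t_adam)
      vhat <- v[[nm]] / (1 - b2^t_adam)
      pars[[nm]] <- pars[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    if (epoch > warmup_epochs && epoch %% 10 == 0 && has_val) {
      fv <- mlp_forward(pars, Xva, lv_clamp)
      vloss <- mlp_loss(Yva, fv, warmup = FALSE)
      if (!is.finite(vloss))
        stop("validation loss diverged (NaN); try a smaller step size")
      if (vloss < best$loss - 1e-6) {
        best <- list(loss = vloss, pars = pars, epoch = epoch)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= patience) break
      }
    }
  }
  if (!has_val || !is.finite(best$loss)) best <- list(loss = NA_real_, pars = pars,
                                                      epoch = max_epochs)
  fw_tr <- mlp_forward(best$pars, Xtr, lv_clamp)
  structure(list(pars = best$pars, hidden = hidden, lv_clamp = lv_clamp,
                 x_mean = x_mean, x_sd = x_sd,
                 targets = c("old_fraction", "progenitor_fraction"),
                 graph_id = ts$graph_id, dampings = ts$dampings,
                 seed = seed,
                 train_loss = mlp_loss(Ytr, fw_tr, warmup = FALSE),
                 val_loss = best$loss, stopped_epoch = best$epoch),
            class = "mve_model")
}

# internal: forward pass on raw (projected, unscaled) features
model_forward <- function(model, X_proj) {
  X <- sweep(sweep(X_proj, 2, model$x_mean, "-"), 2, model$x_sd, "/")
  fw <- mlp_forward(model$pars, X, model$lv_clamp)
  list(mu = fw$mu, sigma = sqrt(exp(fw$lv)))
}

#' Fit the full per-graph inference pipeline
#'
#' Convenience wrapper: builds the simulated training set, fits the
#' feature projection on the training split only, and trains the MVE
#' model.
#'
#' @inheritParams build_training_set
#' @param ... passed to [train_model()].
#' @return list with `ts` (training set), `projection` and `model`.
#' @export
fit_inference <- function(graph, n_sim = 2000, seed = 1L, ...) {
  ts <- build_training_set(graph, n_sim = n_sim, seed = seed)
  projection <- fit_projection(ts$features[!ts$is_val, , drop = FALSE])
  model <- train_model(ts, projection, seed = seed, ...)
  list(ts = ts, projection = projection, model = model)
}

#' Predict regeneration parameters for a graph
#'
#' Computes the observed local-assortativity profiles and features,
#' projects them, and returns the logit-normal predictive distribution for
#' each target. The derived `new_fraction` row uses the closure of the
#' logit-normal family under `x -> 1 - x` (`mu -> -mu`, same `sigma`).
#'
#' @param graph the observed `cell_graph` (same topology the model was
#'   trained on).
#' @param model an `mve_model`.
#' @param projection the frozen `feature_projection`.
#' @param W optional named list of precomputed [ppr_matrix()] objects (as
#'   stored in the training set).
#' @return data.frame with one row per target (`old_fraction`,
#'   `progenitor_fraction`, `new_fraction`): logit-scale `mu` and `sigma`,
#'   probability-scale `median` and central 95% interval `lo`/`hi`.
#' @export
predict_graph <- function(graph, model, projection, W = NULL) {
  dampings <- model$dampings
  getW <- function(d) {
    if (!is.null(W) && !is.null(W[[as.character(d)]])) W[[as.character(d)]]
    else ppr_matrix(graph, d)
  }
  p1 <- assortativity_profile(graph, dampings[1], W = getW(dampings[1]))
  if (anyNA(p1)) stop("assortativity undefined for this graph; excluded from prediction")
  p2 <- assortativity_profile(graph, dampings[2], W = getW(dampings[2]))
  feats <- distribution_features(p1, p2)
  fwd <- model_forward(model, apply_projection(projection, as.numeric(feats)))
  mu <- c(fwd$mu[1, ], -fwd$mu[1, 1])
  sigma <- c(fwd$sigma[1, ], fwd$sigma[1, 1])
  data.frame(target = c(model$targets, "new_fraction"),
             mu = mu, sigma = sigma,
             median = plogis(mu),
             lo = plogis(mu - 1.96 * sigma),
             hi = plogis(mu + 1.96 * sigma))
}

#' Daughter cells produced per progenitor
#'
#' On the observed network, `f N` cells are new and `p (1 - f) N` surviving
#' cells founded clones, so each progenitor contributed on average
#' `f / (p (1 - f))` daughters.
#'
#' @param p progenitor fraction (> 0).
#' @param f new-cell fraction in \[0, 1).
#' @return mean number of daughter cells per progenitor.
#' @export
daughters_per_progenitor <- function(p, f) {
  stopifnot(p > 0, f >= 0, f < 1)
  f / (p * (1 - f))
}

#' Aggregate per-graph predictions into a group estimate
#'
#' Inverse-variance weighted mean on the logit scale (optionally further
#' weighted by graph cell counts), with propagated variance
#' `sum(w^2 sigma^2) / (sum w)^2` (which reduces to `1 / sum(1/sigma^2)`
#' for pure inverse-variance weights); the standard error on the
#' probability scale uses the delta method.
#'
#' @param predictions data.frame with columns `mu`, `sigma` (one row per
#'   graph, one common target) and optionally `cells`.
#' @param weights `"ivar"` (inverse variance, default) or `"cells"`
#'   (inverse variance times cell count).
#' @return list: `estimate` (probability scale), `se`, `mu`, `sigma_mu`
#'   (logit scale), `n_graphs`, `n_cells`.
#' @export
aggregate_estimates <- function(predictions, weights = c("ivar", "cells")) {
  weights <- match.arg(weights)
  if (nrow(predictions) == 0) stop("no predictions to aggregate")
  w <- 1 / predictions$sigma^2
  if (weights == "cells") {
    if (is.null(predictions$cells)) stop("cell counts missing for cell weighting")
    w <- w * predictions$cells
  }
  mu <- sum(w * predictions$mu) / sum(w)
  var_mu <- sum(w^2 * predictions$sigma^2) / sum(w)^2
  est <- plogis(mu)
  list(estimate = est,
       se = sqrt(var_mu) * est * (1 - est),
       mu = mu, sigma_mu = sqrt(var_mu),
       n_graphs = nrow(predictions),
       n_cells = if (!is.null(predictions$cells)) sum(predictions$cells) else NA_integer_)
}

#' Save / load an MVE model checkpoint
#'
#' A single self-describing JSON file holding the architecture, weights,
#' input scaling, the frozen feature projection and the training seed.
#'
#' @param model an `mve_model`.
#' @param projection the matching `feature_projection`.
#' @param path output path.
#' @return `save_model`: invisibly, `path`. `load_model`: list with
#'   `model` and `projection`.
#' @export
save_model <- function(model, projection, path) {
  payload <- list(
    class = "clonograph_mve_checkpoint", version = 1L,
    model = list(pars = lapply(model$pars, function(p) unclass(p)),
                 hidden = model$hidden, lv_clamp = model$lv_clamp,
                 x_mean = model$x_mean, x_sd = model$x_sd,
                 targets = model$targets, graph_id = model$graph_id,
                 dampings = model$dampings, seed = model$seed,
                 train_loss = model$train_loss, val_loss = model$val_loss,
                 stopped_epoch = model$stopped_epoch),
    projection = list(mean = projection$mean, sd = projection$sd,
                      keep = projection$keep,
                      rotation = unclass(projection$rotation),
                      rotation_names = colnames(projection$rotation),
                      feature_names = names(projection$mean),
                      n_components = projection$n_components,
                      explained = projection$explained))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$class, "clonograph_mve_checkpoint"))
    stop("not a clonograph model checkpoint: ", path)
  pm <- payload$model
  pars <- pm$pars
  # restore matrix shapes (jsonlite keeps matrices, but be defensive)
  for (nm in names(pars)) if (is.list(pars[[nm]])) pars[[nm]] <- do.call(rbind, pars[[nm]])
  model <- structure(list(pars = pars, hidden = pm$hidden,
                          lv_clamp = pm$lv_clamp, x_mean = pm$x_mean,
                          x_sd = pm$x_sd, targets = pm$targets,
                          graph_id = pm$graph_id, dampings = pm$dampings,
                          seed = pm$seed, train_loss = pm$train_loss,
                          val_loss = pm$val_loss,
                          stopped_epoch = pm$stopped_epoch),
                     class = "mve_model")
  pj <- payload$projection
  rotation <- pj$rotation
  if (is.list(rotation)) rotation <- do.call(rbind, rotation)
  rotation <- as.matrix(rotation)
  colnames(rotation) <- pj$rotation_names
  projection <- structure(list(mean = setNames(pj$mean, pj$feature_names),
                               sd = setNames(pj$sd, pj$feature_names),
                               keep = pj$keep, rotation = rotation,
                               n_components = pj$n_components,
                               explained = pj$explained, fitted = TRUE),
                          class = "feature_projection")
  list(model = model, projection = projection)
}
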