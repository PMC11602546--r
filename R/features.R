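#' Summary features of paired local-assortativity profiles
#'
#' Condenses the per-node local-assortativity distributions of one graph,
#' computed at two damping factors (default 0.1 and 0.7), into a
#' fixed-length vector: per damping the mean, sample variance (1/(N-1)),
#' skewness and excess kurtosis (standardized central moments), and seven
#' quantiles (0.05, 0.1, 0.25, 0.5, 0.75, 0.9, 0.95; linear interpolation);
#' plus the node-paired Pearson correlation between the two profiles.
#'
#' @param profile_a,profile_b numeric profiles over the same nodes in the
#'   same order (conventionally damping 0.1 and 0.7).
#' @param probs quantile probabilities.
#' @return named numeric vector (default length 23). Degenerate constant
#'   profiles get skewness/kurtosis/correlation 0 and attribute
#'   `degenerate = TRUE`.
#' @export
distribution_features <- function(profile_a, profile_b,
                                  probs = c(0.05, 0.1, 0.25, 0.5, 0.75, 0.9, 0.95)) {
  stopifnot(length(profile_a) == length(profile_b))
  N <- length(profile_a)
  if (N < 4) stop("at least 4 nodes are required for moment features")
  degenerate <- FALSE
  one <- function(p, tag) {
    m <- mean(p)
    ctr <- p - m
    m2 <- mean(ctr^2)
    v <- sum(ctr^2) / (N - 1)
    if (m2 < 1e-24) {
      degenerate <<- TRUE
      sk <- 0; ku <- 0
    } else {
      sk <- mean(ctr^3) / m2^1.5
      ku <- mean(ctr^4) / m2^2 - 3
    }
    q <- quantile(p, probs = probs, names = FALSE, type = 7)
    setNames(c(m, v, sk, ku, q),
             paste0(tag, c("_mean", "_var", "_skew", "_kurt",
                           paste0("_q", probs * 100))))
  }
  fa <- one(profile_a, "d1")
  fb <- one(profile_b, "d2")
  cc <- if (sd(profile_a) < 1e-12 || sd(profile_b) < 1e-12) {
    degenerate <- TRUE
    0
  } else cor(profile_a, profile_b)
  out <- c(fa, fb, cor = cc)
  attr(out, "degenerate") <- degenerate
  out
}

#' Fit the z-score + PCA feature projection
#'
#' Standardizes each feature to zero mean and unit variance over the
#' training set (constant features are dropped with a warning) and fits a
#' PCA, keeping the smallest number of components reaching
#' `variance_target` of the total variance, capped at `max_components`.
#' Fitted once on the simulated training set of a graph and then frozen;
#' it is never refit at prediction time.
#'
#' @param features matrix (rows = simulations, columns = features).
#' @param variance_target fraction of variance to retain (default 0.95).
#' @param max_components component cap (default 10).
#' @return a `feature_projection` object.
#' @export
fit_projection <- function(features, variance_target = 0.95,
                           max_components = 10) {
  features <- as.matrix(features)
  if (nrow(features) < 2) stop("at least 2 samples are required to fit a projection")
  mu <- colMeans(features)
  sdv <- apply(features, 2, sd)
  keep <- sdv > 1e-12
  if (!all(keep))
    warning("dropping ", sum(!keep), " constant feature(s): ",
            paste(colnames(features)[!keep], collapse = ", "))
  Z <- sweep(sweep(features[, keep, drop = FALSE], 2, mu[keep], "-"),
             2, sdv[keep], "/")
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  evar <- pc$sdev^2
  frac <- cumsum(evar) / sum(evar)
  ncomp <- min(which(frac >= variance_target)[1], max_components,
               length(evar), na.rm = TRUE)
  structure(list(mean = mu, sd = sdv, keep = keep,
                 rotation = pc$rotation[, seq_len(ncomp), drop = FALSE],
                 n_components = ncomp,
                 explained = frac[ncomp], fitted = TRUE),
            class = "feature_projection")
}

#' Apply a fitted feature projection
#'
#' @param projection a `feature_projection` from [fit_projection()].
#' @param features a feature vector or matrix (rows = samples).
#' @return matrix of reduced component scores (rows = samples).
#' @export
apply_projection <- function(projection, features) {
  stopifnot(inherits(projection, "feature_projection"), isTRUE(projection$fitted))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  features <- as.matrix(features)
  if (ncol(features) != length(projection$mean))
    stop("feature dimension mismatch: got ", ncol(features), ", expected ",
         length(projection$mean))
  Z <- sweep(sweep(features[, projection$keep, drop = FALSE], 2,
                   projection$mean[projection$keep], "-"),
             2, projection$sd[projection$keep], "/")
  Z %*% projection$rotation
}
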