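#' Model parameters
#'
#' One parameter object serves all four learning rules; each rule reads the
#' fields it needs.
#'
#' @param alpha learning rate (associability) in `[0, 1]`; used by
#'   Rescorla-Wagner and TD.  Default 0.3.
#' @param gamma discount factor in `[0, 1]` weighting future against
#'   immediate reward; used by TD and Kalman TD.  Default 0.98.
#' @param sigma_w2 prior variance of the weights (strength of the zero-mean
#'   prior is `1/sigma_w2`).  Default 1.
#' @param sigma_r2 reward (observation) noise variance.  Default 1.
#' @param tau2 diffusion variance of the weight random walk; larger values
#'   model more volatile environments and keep the Kalman gain from
#'   collapsing.  Default 0.01.
#' @param bins_per_stimulus CSC bins per stimulus for real-time models.
#'   Default 4.
#' @param serial_overlap boundary steps shared between successive serial
#'   events in the CSC encoding; see [csc_layout()].  Default 1.
#' @param lr_schedule `"constant"` (default) or `"one_over_n"`; the decaying
#'   schedule `alpha_n = alpha / n` turns the Rescorla-Wagner rule into a
#'   Robbins-Monro stochastic approximation that converges to the maximum
#'   likelihood (least squares) weights.
#' @return a `model_params` list.
#' @export
model_params <- function(alpha = 0.3, gamma = 0.98, sigma_w2 = 1,
                         sigma_r2 = 1, tau2 = 0.01, bins_per_stimulus = 4L,
                         serial_overlap = min(1L, bins_per_stimulus - 1L),
                         lr_schedule = c("constant", "one_over_n")) {
  lr_schedule <- match.arg(lr_schedule)
  chk <- function(v, nm, lo = 0, hi = Inf, open_lo = FALSE) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v < lo || v > hi || (open_lo && v <= lo))
      stop(sprintf("%s must be a finite number in [%s, %s]%s", nm, lo, hi,
                   if (open_lo) " (exclusive below)" else ""), call. = FALSE)
  }
  chk(alpha, "alpha", 0, 1)
  chk(gamma, "gamma", 0, 1)
  chk(sigma_w2, "sigma_w2", 0, Inf, open_lo = TRUE)
  chk(sigma_r2, "sigma_r2", 0, Inf, open_lo = TRUE)
  chk(tau2, "tau2", 0, Inf)
  bins_per_stimulus <- as.integer(bins_per_stimulus)
  serial_overlap <- as.integer(serial_overlap)
  stopifnot(length(bins_per_stimulus) == 1L, bins_per_stimulus >= 1L,
            length(serial_overlap) == 1L, serial_overlap >= 0L,
            serial_overlap < bins_per_stimulus)
  structure(list(alpha = alpha, gamma = gamma, sigma_w2 = sigma_w2,
                 sigma_r2 = sigma_r2, tau2 = tau2,
                 bins_per_stimulus = bins_per_stimulus,
                 serial_overlap = serial_overlap,
                 lr_schedule = lr_schedule),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(paste0("<model_params> alpha=%g gamma=%g sigma_w2=%g ",
                     "sigma_r2=%g tau2=%g bins=%d lr_schedule=%s\n"),
              x$alpha, x$gamma, x$sigma_w2, x$sigma_r2, x$tau2,
              x$bins_per_stimulus, x$lr_schedule))
  invisible(x)
}

#' Initial agent state
#'
#' Point-estimate models (Rescorla-Wagner, TD) carry only the weight vector;
#' Bayesian models (Kalman filter, Kalman TD) additionally carry the posterior
#' covariance, initialised to the prior `sigma_w2 * I` with mean zero.
#'
#' @param n_features weight dimension (or a [csc_layout()]).
#' @param params a [model_params()].
#' @param bayesian carry a posterior covariance matrix?
#' @param feature_names optional names for the weight vector.
#' @return an `agent_state` with `w`, `Sigma` (or NULL) and step counter `n`.
#' @export
agent_state <- function(n_features, params = model_params(), bayesian = TRUE,
                        feature_names = NULL) {
  if (inherits(n_features, "csc_layout")) {
    feature_names <- n_features$feature_names
    n_features <- n_features$n_features
  }
  w <- stats::setNames(numeric(n_features), feature_names)
  Sigma <- if (bayesian) {
    s <- diag(params$sigma_w2, n_features)
    dimnames(s) <- list(feature_names, feature_names)
    s
  }
  structure(list(w = w, Sigma = Sigma, n = 0L), class = "agent_state")
}

#' @export
print.agent_state <- function(x, ...) {
  cat("<agent_state> D=", length(x$w), ", steps=", x$n,
      if (is.null(x$Sigma)) ", point estimate" else ", Bayesian", "\n",
      sep = "")
  print(round(x$w, 4))
  invisible(x)
}

new_update <- function(state, delta, v, gain = NULL) {
  list(state = state, delta = delta, v = v, gain = gain)
}

#' Rescorla-Wagner update
#'
#' The delta rule: `w <- w + alpha_n * x * (r - w'x)`.  The prediction error
#' `delta = r - v` drives learning; with the `one_over_n` schedule
#' (`alpha_n = alpha/n`) the rule is a Robbins-Monro stochastic approximation
#' converging to the maximum-likelihood weights.
#'
#' @param state an [agent_state()] (covariance not required).
#' @param x feature vector.
#' @param r observed reward.
#' @param params a [model_params()].
#' @return list with updated `state`, prediction error `delta`, prediction
#'   `v`, and the effective per-feature `gain` (`alpha_n * x`).
#' @export
rw_update <- function(state, x, r, params = model_params()) {
  stopifnot(length(x) == length(state$w), is.finite(r))
  n <- state$n + 1L
  a <- switch(params$lr_schedule,
              constant = params$alpha,
              one_over_n = params$alpha / n)
  v <- sum(state$w * x)
  delta <- r - v
  state$w <- state$w + a * x * delta
  state$n <- n
  new_update(state, delta, v, gain = a * x)
}

#' Kalman filter update
#'
#' One predict-update cycle of the Kalman filter for the linear-Gaussian
#' dynamical system in which weights diffuse as a random walk with variance
#' `tau2` and reward is `w'x` plus Gaussian noise of variance `sigma_r2`.
#' With `S = Sigma + tau2*I`:
#' \deqn{k = Sx / (x'Sx + \sigma_r^2)}
#' \deqn{w' = w + k (r - w'x), \quad \Sigma' = S - k x' S}
#' The gain `k` is a stimulus-specific, uncertainty-weighted learning rate;
#' the covariance update is re-symmetrised, or computed in Joseph form when
#' `form = "joseph"` (algebraically identical, numerically more robust).
#'
#' @inheritParams rw_update
#' @param form covariance update form, `"standard"` or `"joseph"`.
#' @return list with updated `state`, `delta`, `v` and the Kalman `gain`.
#' @export
kalman_step <- function(state, x, r, params = model_params(),
                        form = c("standard", "joseph")) {
  form <- match.arg(form)
  stopifnot(!is.null(state$Sigma), length(x) == length(state$w))
  if (!all(is.finite(x)) || !is.finite(r))
    stop("non-finite input to kalman_step", call. = FALSE)
  S <- state$Sigma + diag(params$tau2, length(x))
  Sx <- drop(S %*% x)
  denom <- sum(x * Sx) + params$sigma_r2
  k <- Sx / denom
  v <- sum(state$w * x)
  delta <- r - v
  state$w <- state$w + k * delta
  Sigma <- if (form == "standard") {
    S - tcrossprod(k, Sx)
  } else {
    A <- diag(length(x)) - tcrossprod(k, x)
    A %*% S %*% t(A) + tcrossprod(k) * params$sigma_r2
  }
  state$Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(state$Sigma) <- list(names(state$w), names(state$w))
  state$n <- state$n + 1L
  new_update(state, delta, v, gain = stats::setNames(k, names(state$w)))
}

#' Temporal-difference (TD(0)) update
#'
#' Linear value-function TD learning: the prediction error is
#' `delta = r + gamma * w'x_next - w'x`, and `w <- w + alpha * x * delta`.
#' With `gamma = 0` this is exactly the Rescorla-Wagner update.
#'
#' @inheritParams rw_update
#' @param x_next successor feature vector; the zero vector at trial end.
#' @return list with updated `state`, `delta`, `v` (`= w'x`) and `gain`.
#' @export
td_step <- function(state, x, x_next, r, params = model_params()) {
  stopifnot(length(x) == length(state$w), length(x_next) == length(state$w),
            is.finite(r))
  v <- sum(state$w * x)
  v_next <- sum(state$w * x_next)
  delta <- r + params$gamma * v_next - v
  state$w <- state$w + params$alpha * x * delta
  state$n <- state$n + 1L
  new_update(state, delta, v, gain = params$alpha * x)
}

#' Kalman TD update
#'
#' Kalman TD is the Kalman filter applied to the discounted temporal
#' derivative of the stimulus features (see [discounted_derivative()]): the
#' update contract is identical to [kalman_step()] with `x := h_t`.  The
#' resulting weights are long-run value weights and the posterior covariance
#' tracks how value estimates covary across stimuli.
#'
#' @inheritParams kalman_step
#' @param h discounted-derivative feature vector for this time step.
#' @export
kalman_td_step <- function(state, h, r, params = model_params(),
                           form = c("standard", "joseph")) {
  kalman_step(state, h, r, params, form = match.arg(form))
}

#' Diffusion-only predict step
#'
#' Advances the weight random walk without an observation: the posterior mean
#' is unchanged and `n * tau2 * I` is added to the covariance.  Models the
#' growth of uncertainty over an interval (e.g. a delay between sessions),
#' which raises the Kalman gain again after it has decayed — the mechanism by
#' which a retention interval attenuates latent inhibition.
#'
#' @inheritParams kalman_step
#' @param n number of diffusion steps to apply.
#' @return the updated `agent_state`.
#' @export
kalman_predict <- function(state, params = model_params(), n = 1L) {
  stopifnot(!is.null(state$Sigma), n >= 0)
  state$Sigma <- state$Sigma + diag(n * params$tau2, length(state$w))
  state
}

#' Batch conjugate posterior (static-weight oracle)
#'
#' Closed-form Gaussian linear-regression posterior for static weights
#' (`tau2 = 0`): `Sigma = (I/sigma_w2 + X'X/sigma_r2)^-1`,
#' `mu = Sigma X'r / sigma_r2`.  Sequential [kalman_step()] updates with
#' `tau2 = 0` must reproduce this batch posterior exactly, which makes it an
#' independent correctness oracle for the filter.
#'
#' @param X observations-by-features design matrix (0 rows allowed).
#' @param r reward vector, one per row of `X`.
#' @param sigma_w2,sigma_r2 prior weight and reward noise variances.
#' @return list with `mean` and `cov`.
#' @export
batch_posterior_oracle <- function(X, r, sigma_w2 = 1, sigma_r2 = 1) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(r), sigma_w2 > 0, sigma_r2 > 0)
  D <- ncol(X)
  prec <- diag(D) / sigma_w2 + crossprod(X) / sigma_r2
  Sigma <- solve(prec)
  Sigma <- (Sigma + t(Sigma)) / 2
  mu <- drop(Sigma %*% crossprod(X, r)) / sigma_r2
  list(mean = stats::setNames(mu, colnames(X)), cov = Sigma)
}
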