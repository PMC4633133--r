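#' Run a learning model over a full experimental design
#'
#' Expands each phase into an ordered trial sequence, feeds every trial
#' through the chosen learning rule, and reads out a test response for every
#' `?` probe from the final weights (probes never update the state).
#' Trial-level models (`"RW"`, `"KF"`) see one one-hot feature vector per
#' trial and require designs without serial compounds; real-time models
#' (`"TD"`, `"KTD"`) see complete serial compound timelines, with the Kalman
#' TD filter operating on discounted temporal derivatives of the features.
#'
#' Test responses are the conventional anticipatory-response proxy: `w'x` for
#' trial-level models, and the value at stimulus onset (`w'x` at the probe's
#' first CSC step) for real-time models.
#'
#' @param design a [parse_design()] result (or a notation string, parsed with
#'   `n_trials` trials per type).
#' @param model one of `"RW"`, `"KF"`, `"TD"`, `"KTD"`.
#' @param params a [model_params()].
#' @param schedule within-phase trial ordering; see [expand_phase()].
#' @param seed integer seed (only consulted for `schedule = "shuffled"`).
#' @param n_trials trials per type per phase when `design` is a string.
#' @param deriv_sign sign convention for the Kalman TD feature derivative;
#'   see [discounted_derivative()].
#' @param diffusion when to apply the `tau2` predict step in Bayesian
#'   real-time runs: `"per_trial"` (default; the weight random walk is
#'   indexed by trial, so uncertainty grows once per trial regardless of
#'   trial length) or `"per_step"` (once per CSC time step, so forgetting
#'   scales with trial duration).  Trial-level models are unaffected.
#' @return a `model_run`: list with `responses` (named vector, one per
#'   probe), final `state`, `trace` (per-step data.frame plus weight/gain
#'   matrices and, for Bayesian models, a covariance array), `model`,
#'   `params`, `design`.
#' @examples
#' run <- run_model("A->-; A->+; A->?", model = "KF")
#' run$responses
#' @export
run_model <- function(design, model = c("KF", "RW", "TD", "KTD"),
                      params = model_params(),
                      schedule = c("alternating", "shuffled"), seed = 1L,
                      n_trials = 10L, deriv_sign = 1,
                      diffusion = c("per_trial", "per_step")) {
  model <- match.arg(model)
  schedule <- match.arg(schedule)
  diffusion <- match.arg(diffusion)
  if (is.character(design)) design <- parse_design(design, n_trials = n_trials)
  stopifnot(inherits(design, "conditioning_design"))
  trial_level <- model %in% c("RW", "KF")
  bayesian <- model %in% c("KF", "KTD")

  if (trial_level) {
    if (!is_trial_level(design))
      stop(model, " is a trial-level model; design '", format_design(design),
           "' contains serial compounds — use TD or KTD", call. = FALSE)
    feat_names <- design$alphabet
    D <- length(feat_names)
    layout <- NULL
  } else {
    layout <- csc_layout(design$alphabet, params$bins_per_stimulus,
                         params$serial_overlap)
    feat_names <- layout$feature_names
    D <- layout$n_features
  }
  state <- agent_state(D, params, bayesian = bayesian,
                       feature_names = feat_names)
  params_nodiff <- params
  params_nodiff$tau2 <- 0

  rows <- list()
  w_rows <- list(); g_rows <- list(); sig <- list()
  trial_global <- 0L
  for (pi in seq_along(design$phases)) {
    trials <- expand_phase(design$phases[[pi]], schedule = schedule,
                           seed = seed + 101L * pi)
    for (ti in seq_along(trials)) {
      tt <- trials[[ti]]
      trial_global <- trial_global + 1L
      if (trial_level) {
        enc <- encode_trial_level(tt, design$alphabet)
        upd <- if (model == "RW") rw_update(state, enc$x, enc$r, params)
               else kalman_step(state, enc$x, enc$r, params)
        state <- upd$state
        rows[[length(rows) + 1L]] <- data.frame(
          phase = pi, trial = ti, trial_global = trial_global, step = 1L,
          label = tt$label, r = enc$r, v = upd$v, delta = upd$delta)
        w_rows[[length(w_rows) + 1L]] <- state$w
        g_rows[[length(g_rows) + 1L]] <- as.numeric(upd$gain)
        if (bayesian) sig[[length(sig) + 1L]] <- state$Sigma
      } else {
        tl <- encode_csc(tt, layout)
        H <- if (model == "KTD")
          discounted_derivative(tl, params$gamma, sign = deriv_sign)
        for (st in seq_along(tl$r)) {
          if (model == "TD") {
            x_next <- if (st < nrow(tl$x)) tl$x[st + 1L, ] else numeric(D)
            upd <- td_step(state, tl$x[st, ], x_next, tl$r[st], params)
          } else {
            p_st <- if (diffusion == "per_trial" && st > 1L) params_nodiff
                    else params
            upd <- kalman_td_step(state, H$x[st, ], tl$r[st], p_st)
          }
          state <- upd$state
          rows[[length(rows) + 1L]] <- data.frame(
            phase = pi, trial = ti, trial_global = trial_global, step = st,
            label = tt$label, r = tl$r[st], v = upd$v, delta = upd$delta)
          w_rows[[length(w_rows) + 1L]] <- state$w
          g_rows[[length(g_rows) + 1L]] <- as.numeric(upd$gain)
          if (bayesian) sig[[length(sig) + 1L]] <- state$Sigma
        }
      }
    }
  }

  w_mat <- do.call(rbind, c(w_rows, list(NULL)))
  if (is.null(w_mat)) w_mat <- matrix(numeric(0), 0, D)
  colnames(w_mat) <- feat_names
  g_mat <- do.call(rbind, c(g_rows, list(NULL)))
  if (is.null(g_mat)) g_mat <- matrix(numeric(0), 0, D)
  colnames(g_mat) <- feat_names
  Sigma_arr <- if (bayesian && length(sig))
    array(unlist(sig), dim = c(D, D, length(sig)),
          dimnames = list(feat_names, feat_names, NULL))

  responses <- numeric(0)
  for (tt in design$test_trials) {
    x_probe <- if (trial_level) encode_trial_level(tt, design$alphabet)$x
               else encode_csc(tt, layout)$x[1L, ]
    responses[probe_name(tt)] <- sum(state$w * x_probe)
  }

  structure(list(
    model = model, params = params, design = design, schedule = schedule,
    seed = seed, responses = responses, state = state,
    trace = list(steps = if (length(rows)) do.call(rbind, rows) else
                   data.frame(phase = integer(0), trial = integer(0),
                              trial_global = integer(0), step = integer(0),
                              label = character(0), r = numeric(0),
                              v = numeric(0), delta = numeric(0)),
                 w = w_mat, gain = g_mat, Sigma = Sigma_arr),
    layout = layout), class = "model_run")
}

probe_name <- function(tt) paste(vapply(tt$events, paste, character(1),
                                        collapse = ""), collapse = ARROW)

#' @export
print.model_run <- function(x, ...) {
  cat("<model_run> ", x$model, " on '", format_design(x$design), "'\n",
      sep = "")
  if (length(x$responses)) {
    cat("  test responses:\n")
    print(round(x$responses, 4))
  }
  invisible(x)
}

#' Tidy per-step trace table
#'
#' One row per (time step, feature): the weight after the update, the gain
#' applied, the posterior variance (Bayesian models), alongside the step's
#' prediction `v`, prediction error `delta` and reward.
#'
#' @param run a [run_model()] result.
#' @return a data.frame in long format.
#' @export
trace_table <- function(run) {
  stopifnot(inherits(run, "model_run"))
  st <- run$trace$steps
  D <- ncol(run$trace$w)
  if (nrow(st) == 0L)
    return(data.frame(phase = integer(0), trial = integer(0),
                      trial_global = integer(0), step = integer(0),
                      label = character(0), feature = character(0),
                      w = numeric(0), gain = numeric(0),
                      var_w = numeric(0), v = numeric(0),
                      delta = numeric(0), r = numeric(0)))
  idx <- rep(seq_len(nrow(st)), each = D)
  out <- data.frame(
    st[idx, c("phase", "trial", "trial_global", "step", "label")],
    feature = rep(colnames(run$trace$w), nrow(st)),
    w = as.vector(t(run$trace$w)),
    gain = as.vector(t(run$trace$gain)),
    var_w = if (is.null(run$trace$Sigma)) NA_real_ else
      as.vector(apply(run$trace$Sigma, 3, diag)),
    v = st$v[idx], delta = st$delta[idx], r = st$r[idx],
    row.names = NULL)
  out
}

#' Posterior covariance trace for a stimulus pair
#'
#' Extracts the per-step posterior covariance between two features of a
#' Bayesian run — for real-time models, between given CSC bins (default: the
#' onset bins) of two stimuli.
#'
#' @param run a Bayesian [run_model()] result (`"KF"` or `"KTD"`).
#' @param s1,s2 stimulus labels.
#' @param bin1,bin2 CSC bins (ignored for trial-level runs).
#' @return numeric vector, one covariance per model step.
#' @export
covariance_trace <- function(run, s1, s2, bin1 = 1L, bin2 = 1L) {
  stopifnot(inherits(run, "model_run"), !is.null(run$trace$Sigma))
  f1 <- if (is.null(run$layout)) s1 else paste(s1, bin1, sep = ".")
  f2 <- if (is.null(run$layout)) s2 else paste(s2, bin2, sep = ".")
  run$trace$Sigma[f1, f2, ]
}
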