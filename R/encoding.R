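#' Complete serial compound (CSC) feature layout
#'
#' Real-time models represent each stimulus as a sequence of
#' `bins_per_stimulus` non-overlapping time bins; each (stimulus, bin) pair is
#' a distinct feature column.  A stimulus keeps the same columns wherever it
#' appears — across trial types, phases and serial positions — so that what is
#' learned about it transfers.
#'
#' In a serial compound (`Z->X`), the trailing stimulus onsets at the step on
#' which the leading one terminates, so by default the two share one boundary
#' step (the leading stimulus' last bin co-occurs with the trailing one's
#' first bin).  This discretisation of "terminating with the onset of another
#' stimulus" lets successive serial elements compete to predict the outcome —
#' the source of overshadowing between serial elements.  `serial_overlap = 0`
#' gives strict concatenation instead (no shared step).
#'
#' @param alphabet character vector of stimulus labels.
#' @param bins_per_stimulus bins per stimulus (default 4).
#' @param serial_overlap steps shared at each serial transition, in
#'   `[0, bins_per_stimulus - 1]`; default 1 (0 when `bins_per_stimulus` is 1).
#' @return a `csc_layout`: list with `alphabet`, `bins_per_stimulus`,
#'   `serial_overlap`, `n_features` and `feature_names` (`"A.1"`, `"A.2"`, ...).
#' @export
csc_layout <- function(alphabet, bins_per_stimulus = 4L,
                       serial_overlap = min(1L, bins_per_stimulus - 1L)) {
  bins_per_stimulus <- as.integer(bins_per_stimulus)
  serial_overlap <- as.integer(serial_overlap)
  stopifnot(length(bins_per_stimulus) == 1L, bins_per_stimulus >= 1L,
            length(serial_overlap) == 1L, serial_overlap >= 0L,
            serial_overlap < bins_per_stimulus,
            length(alphabet) >= 1L, !anyDuplicated(alphabet))
  alphabet <- sort(alphabet)
  structure(list(
    alphabet = alphabet,
    bins_per_stimulus = bins_per_stimulus,
    serial_overlap = serial_overlap,
    n_features = length(alphabet) * bins_per_stimulus,
    feature_names = as.vector(t(outer(alphabet, seq_len(bins_per_stimulus),
                                      paste, sep = ".")))),
    class = "csc_layout")
}

feature_index <- function(layout, stimulus, bin) {
  i <- match(stimulus, layout$alphabet)
  if (anyNA(i)) stop(sprintf("unknown stimulus label '%s'",
                             paste(stimulus[is.na(i)], collapse = ",")),
                     call. = FALSE)
  (i - 1L) * layout$bins_per_stimulus + bin
}

new_timeline <- function(x, r, trial) {
  structure(list(x = x, r = r, trial = trial), class = "timeline")
}

#' Trial-level one-hot encoding
#'
#' For trial-level models (Rescorla-Wagner, Kalman filter) a trial is a single
#' feature vector with a 1 at each presented cue's index, plus its scalar
#' reward.  Serial compounds have intra-trial temporal structure and must be
#' encoded with [encode_csc()] instead.
#'
#' @param trial a `trial_type` with a single event set.
#' @param alphabet stimulus labels defining the feature order.
#' @return list with `x` (named 0/1 vector) and `r` (reward; 0 for probes).
#' @export
encode_trial_level <- function(trial, alphabet) {
  stopifnot(inherits(trial, "trial_type"))
  if (length(trial$events) != 1L)
    stop("serial-compound trial '", trial$label,
         "' cannot be encoded at trial level; use the CSC encoding",
         call. = FALSE)
  x <- stats::setNames(numeric(length(alphabet)), alphabet)
  idx <- match(trial$events[[1]], alphabet)
  if (anyNA(idx)) stop("unknown stimulus label in '", trial$label, "'",
                       call. = FALSE)
  x[idx] <- 1
  list(x = x, r = if (trial$test) 0 else trial$outcome)
}

#' Encode a trial as a complete serial compound timeline
#'
#' Each event set of the trial occupies `bins_per_stimulus` consecutive time
#' steps; at step `b` of an event, the bin-`b` feature of every stimulus in
#' that event is 1 and all other features are 0.  Successive serial events
#' follow each other in time, sharing `layout$serial_overlap` boundary steps
#' (see [csc_layout()]), and the reward is delivered at the final time step of
#' the trial (stimulus offset), 0 elsewhere.
#'
#' @param trial a `trial_type`.
#' @param layout a [csc_layout()] covering all stimuli in the trial.
#' @return a `timeline`: list with `x` (steps x features matrix), `r` (reward
#'   per step) and `trial` (trial index per step, here all 1).
#' @export
encode_csc <- function(trial, layout) {
  stopifnot(inherits(trial, "trial_type"), inherits(layout, "csc_layout"))
  b <- layout$bins_per_stimulus
  soa <- b - layout$serial_overlap  # onset-to-onset lag between serial events
  n_ev <- length(trial$events)
  n_steps <- b + (n_ev - 1L) * soa
  x <- matrix(0, n_steps, layout$n_features,
              dimnames = list(NULL, layout$feature_names))
  for (e in seq_along(trial$events)) {
    for (bin in seq_len(b)) {
      x[(e - 1L) * soa + bin, feature_index(layout, trial$events[[e]], bin)] <- 1
    }
  }
  r <- numeric(n_steps)
  r[n_steps] <- if (trial$test) 0 else trial$outcome
  new_timeline(x, r, rep(1L, n_steps))
}

#' Concatenate timelines, renumbering trials
#' @param ... `timeline` objects.
#' @return a single `timeline`.
#' @export
bind_timelines <- function(...) {
  tls <- list(...)
  stopifnot(all(vapply(tls, inherits, logical(1), "timeline")))
  trial <- integer(0); off <- 0L
  for (tl in tls) {
    trial <- c(trial, tl$trial + off)
    off <- max(trial)
  }
  new_timeline(do.call(rbind, lapply(tls, `[[`, "x")),
               unlist(lapply(tls, `[[`, "r"), use.names = FALSE), trial)
}

#' Discounted temporal derivative of a timeline's features
#'
#' Kalman TD filters the discounted time derivative of the stimulus features,
#' `h_t = x_t - gamma * x_{t+1}`, rather than the raw features: if values are
#' linear in `x`, the immediate reward is linear in `h`, so the same
#' linear-Gaussian machinery used for immediate-reward prediction estimates
#' long-run value weights.  At the last step of each trial the successor is
#' taken to be the zero vector, so `h_T = x_T`; derivatives never leak across
#' trial boundaries.  Rewards pass through unchanged.
#'
#' With this sign convention reward-predicting cues acquire positive weights
#' and `r_t = w'h_t` matches the TD fixed point
#' `r_t + gamma*V(x_{t+1}) - V(x_t) = 0`.  `sign = -1` selects the opposite
#' convention (`h_t = gamma*x_{t+1} - x_t`), which negates the posterior mean
#' and leaves all covariances unchanged.
#'
#' @param timeline a `timeline` from [encode_csc()] or [bind_timelines()].
#' @param gamma discount factor in `[0, 1]`.
#' @param sign `+1` (default) or `-1`; see Details.
#' @return a `timeline` whose `x` holds `h_t`.
#' @export
discounted_derivative <- function(timeline, gamma, sign = 1) {
  stopifnot(inherits(timeline, "timeline"), sign %in% c(-1, 1))
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0 || gamma > 1)
    stop("gamma must be in [0, 1]", call. = FALSE)
  x <- timeline$x
  n <- nrow(x)
  nxt <- rbind(x[-1, , drop = FALSE], 0)
  # zero the successor at each trial's last step
  last <- timeline$trial != c(timeline$trial[-1], -1L)
  nxt[last, ] <- 0
  h <- sign * (x - gamma * nxt)
  new_timeline(h, timeline$r, timeline$trial)
}

#' Tabulate a timeline
#' @param x a `timeline`.
#' @param ... unused.
#' @return data.frame with one row per time step: trial, step, features, reward.
#' @export
as.data.frame.timeline <- function(x, ...) {
  step <- stats::ave(seq_along(x$trial), x$trial, FUN = seq_along)
  data.frame(trial = x$trial, step = step, x$x, reward = x$r,
             check.names = FALSE)
}

#' @export
print.csc_layout <- function(x, ...) {
  cat("<csc_layout> ", length(x$alphabet), " stimuli x ",
      x$bins_per_stimulus, " bins = ", x$n_features, " features\n", sep = "")
  invisible(x)
}
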