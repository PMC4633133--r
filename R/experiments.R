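#' Construct an experiment specification
#'
#' An experiment is a named set of conditions (designs in the compact
#' notation), the models to run, and the expected partial order over
#' `(condition, probe)` test responses per model — the directional
#' predictions that the corresponding conditioning experiments established.
#'
#' @param name identifier.
#' @param conditions named character vector of design notation strings; every
#'   design must parse and contain at least one `?` probe.
#' @param models models to run, subset of `c("RW","KF","TD","KTD")`.
#' @param ordering list of constraints, each created by [ordering_constraint()].
#' @param n_trials trials per trial type per phase (default 10).
#' @return an `experiment_spec`.
#' @export
experiment_spec <- function(name, conditions, models, ordering,
                            n_trials = 10L) {
  stopifnot(is.character(conditions), length(conditions) >= 1L,
            !is.null(names(conditions)), all(nzchar(names(conditions))))
  designs <- lapply(conditions, parse_design, n_trials = n_trials)
  for (nm in names(designs))
    if (length(designs[[nm]]$test_trials) == 0L)
      stop(sprintf("condition '%s' of experiment '%s' has no test probe",
                   nm, name), call. = FALSE)
  structure(list(name = name, conditions = conditions, models = models,
                 ordering = ordering, n_trials = as.integer(n_trials)),
            class = "experiment_spec")
}

#' Expected-ordering constraint
#'
#' @param model model the prediction applies to.
#' @param cond1,probe1 condition and probe stimulus of the left-hand response.
#' @param cond2,probe2 condition and probe of the right-hand response.
#' @param relation `"gt"` (left strictly exceeds right) or `"eq"` (equal
#'   within `tol`).
#' @param tol equality tolerance.
#' @return a `list` describing the constraint.
#' @export
ordering_constraint <- function(model, cond1, probe1, cond2, probe2,
                                relation = c("gt", "eq"), tol = 1e-9) {
  list(model = model, cond1 = cond1, probe1 = probe1, cond2 = cond2,
       probe2 = probe2, relation = match.arg(relation), tol = tol)
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat("<experiment_spec> ", x$name, "\n", sep = "")
  for (nm in names(x$conditions))
    cat(sprintf("  %-16s %s\n", nm, x$conditions[[nm]]))
  cat("  models: ", paste(x$models, collapse = ", "),
      "; constraints: ", length(x$ordering), "\n", sep = "")
  invisible(x)
}

gt <- function(model, c1, p1, c2, p2)
  ordering_constraint(model, c1, p1, c2, p2, "gt")
eq <- function(model, c1, p1, c2, p2)
  ordering_constraint(model, c1, p1, c2, p2, "eq")

#' Catalog of classic conditioning paradigms
#'
#' The bundled simulation catalog.  Five trial-level paradigms run under the
#' Kalman filter: latent inhibition, and the four post-training recovery
#' designs (unovershadowing, unblocking, recovery from overexpectation,
#' uninhibition) in which extinguishing a former compound partner changes
#' responding to an absent stimulus via the negative weight covariance
#' acquired during compound training.  Five real-time paradigms contrast
#' Kalman TD with TD: second-order conditioning after overshadowing,
#' second-order extinction, serial-compound extinction, serial latent
#' inhibition, and recovery from overshadowing by extinction of the
#' second-order stimulus.  All phases use 10 trials per trial type.
#'
#' @return named list of [experiment_spec()] objects.
#' @examples
#' names(experiment_catalog())
#' experiment_catalog()[["forward_blocking"]]
#' @export
experiment_catalog <- function() {
  specs <- list(
    experiment_spec(
      "latent_inhibition",
      c(pre = "A->-; A->+; A->?", no_pre = "A->+; A->?"),
      "KF",
      list(gt("KF", "no_pre", "A", "pre", "A"))),
    experiment_spec(
      "overshadowing",
      c(overshadowing = "AB->+; B->?",
        unovershadowing = "AB->+; A->-; B->?"),
      "KF",
      list(gt("KF", "unovershadowing", "B", "overshadowing", "B"))),
    experiment_spec(
      "forward_blocking",
      c(blocking = "A->+; AB->+; B->?",
        unblocking = "A->+; AB->+; A->-; B->?"),
      "KF",
      list(gt("KF", "unblocking", "B", "blocking", "B"))),
    experiment_spec(
      "overexpectation",
      c(overexpectation = "A->+ / B->+; AB->+; B->?",
        unoverexpectation = "A->+ / B->+; AB->+; A->-; B->?"),
      "KF",
      list(gt("KF", "unoverexpectation", "B", "overexpectation", "B"))),
    experiment_spec(
      "conditioned_inhibition",
      c(inhibition = "A->+ / AB->-; B->?",
        uninhibition = "A->+ / AB->-; A->-; B->?"),
      "KF",
      list(gt("KF", "uninhibition", "B", "inhibition", "B"))),
    experiment_spec(
      "overshadowing_second_order",
      c(ov_a = "AX->+ / BY->+; A->-; Z->X; Z->?",
        ov_b = "AX->+ / BY->+; B->-; Z->X; Z->?"),
      c("KTD", "TD"),
      list(gt("KTD", "ov_a", "Z", "ov_b", "Z"),
           eq("TD", "ov_a", "Z", "ov_b", "Z"))),
    experiment_spec(
      "second_order_extinction",
      c(extinction = "A->+; Z->A; A->-; Z->?",
        control = "A->+; Z->A; Z->?"),
      c("KTD", "TD"),
      list(gt("KTD", "control", "Z", "extinction", "Z"),
           eq("TD", "control", "Z", "extinction", "Z"))),
    experiment_spec(
      "serial_compound_extinction",
      c(extinction = "Z->X->+; X->-; Z->?",
        control = "Z->X->+; Z->?"),
      c("KTD", "TD"),
      list(gt("KTD", "control", "Z", "extinction", "Z"),
           eq("TD", "control", "Z", "extinction", "Z"))),
    experiment_spec(
      "serial_latent_inhibition",
      c(pre = "X->-; Z->X->+; Z->?",
        no_pre = "Z->X->+; Z->?"),
      c("KTD", "TD"),
      list(gt("KTD", "no_pre", "Z", "pre", "Z"),
           eq("TD", "no_pre", "Z", "pre", "Z"))),
    experiment_spec(
      "serial_recovery_from_overshadowing",
      c(extinction = "Z->X->+ / W->Y->+; Z->-; X->? / Y->?"),
      c("KTD", "TD"),
      list(gt("KTD", "extinction", "X", "extinction", "Y"),
           eq("TD", "extinction", "X", "extinction", "Y"))))
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

#' Run every (condition, model) cell of an experiment
#'
#' @param spec an [experiment_spec()] (or a catalog name).
#' @param params a [model_params()].
#' @param schedule,seed,diffusion passed to [run_model()].
#' @param keep_traces retain the full per-step traces of each run (default
#'   TRUE; set FALSE to save memory in sweeps).
#' @return an `experiment_result`: list with `responses` (data.frame with
#'   columns condition, model, probe, value), `runs` (nested list of
#'   [run_model()] results, unless `keep_traces = FALSE`), and `spec`.
#' @examples
#' res <- run_experiment("latent_inhibition")
#' res$responses
#' ordering_report(res)
#' @export
run_experiment <- function(spec, params = model_params(),
                           schedule = c("alternating", "shuffled"), seed = 1L,
                           diffusion = c("per_trial", "per_step"),
                           keep_traces = TRUE) {
  if (is.character(spec)) {
    cat_ <- experiment_catalog()
    if (!spec %in% names(cat_))
      stop("unknown experiment '", spec, "'; see experiment_catalog()",
           call. = FALSE)
    spec <- cat_[[spec]]
  }
  stopifnot(inherits(spec, "experiment_spec"))
  schedule <- match.arg(schedule)
  diffusion <- match.arg(diffusion)
  rows <- list()
  runs <- list()
  for (cond in names(spec$conditions)) {
    design <- parse_design(spec$conditions[[cond]], n_trials = spec$n_trials)
    runs[[cond]] <- list()
    for (model in spec$models) {
      run <- run_model(design, model = model, params = params,
                       schedule = schedule, seed = seed,
                       diffusion = diffusion)
      if (keep_traces) runs[[cond]][[model]] <- run
      if (length(run$responses))
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cond, model = model,
          probe = names(run$responses), value = unname(run$responses))
    }
  }
  responses <- do.call(rbind, rows)
  if (any(!is.finite(responses$value)))
    stop("non-finite test response in experiment '", spec$name, "'",
         call. = FALSE)
  structure(list(spec = spec, responses = responses,
                 runs = if (keep_traces) runs,
                 params = params, schedule = schedule, seed = seed),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result> ", x$spec$name, "\n", sep = "")
  print(x$responses, row.names = FALSE)
  rep_ <- ordering_report(x)
  cat(sum(rep_$pass), "/", nrow(rep_), " expected orderings satisfied\n",
      sep = "")
  invisible(x)
}

response_value <- function(result, condition, model, probe) {
  r <- result$responses
  hit <- r$condition == condition & r$model == model & r$probe == probe
  if (sum(hit) != 1L)
    stop(sprintf("no unique response for (%s, %s, %s)", condition, model,
                 probe), call. = FALSE)
  r$value[hit]
}

#' Check an experiment's expected response orderings
#'
#' One row per constraint: the two responses, the margin `lhs - rhs`, and
#' whether the constraint holds (strict inequality, or equality within the
#' constraint's tolerance).
#'
#' @param result an [run_experiment()] result.
#' @return data.frame with columns model, description, lhs, rhs, margin, pass.
#' @export
ordering_report <- function(result) {
  stopifnot(inherits(result, "experiment_result"))
  rows <- lapply(result$spec$ordering, function(cn) {
    lhs <- response_value(result, cn$cond1, cn$model, cn$probe1)
    rhs <- response_value(result, cn$cond2, cn$model, cn$probe2)
    op <- if (cn$relation == "gt") ">" else "=="
    data.frame(
      model = cn$model,
      description = sprintf("%s[%s] %s %s[%s]", cn$cond1, cn$probe1, op,
                            cn$cond2, cn$probe2),
      lhs = lhs, rhs = rhs, margin = lhs - rhs,
      pass = if (cn$relation == "gt") lhs > rhs else
        abs(lhs - rhs) <= cn$tol)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
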