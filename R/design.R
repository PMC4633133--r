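ARROW <- "→"

OUTCOME_TOKENS <- c("+", "-", "?")

#' Parse a conditioning-design notation string
#'
#' Experimental paradigms are written in a compact textual notation: uppercase
#' letters denote conditioned stimuli (`A`, `B`, ...), letter runs denote
#' simultaneous compounds (`AB`), and arrows denote temporal succession.
#' `A->+` (or `A`→`+`) is a trial in which stimulus A terminates in reward,
#' `A->-` one terminating in no reward, and `A->B` one in which A terminates
#' with the onset of B (a serial compound).  `A->?` marks a test probe:
#' conditioned responding to A is the dependent measure.  Trial types
#' interleaved within a phase are separated by `/`, and successive phases by
#' `;`.  An optional numeric outcome (`A->0.5`) sets the reward magnitude.
#'
#' @param text notation string, e.g. `"A->+ / AB->-; A->-"`.  Both the UTF-8
#'   arrow and ASCII `"->"` are accepted.
#' @param n_trials number of trials per trial type within each phase
#'   (recycled across phases).  Default 10, the convention used throughout the
#'   bundled experiment catalog.
#' @return an object of class `conditioning_design`: a list with elements
#'   `phases` (each a `design_phase` holding `trial_types` and `n_trials`),
#'   `alphabet` (sorted stimulus labels) and `test_trials` (the `?`-marked
#'   probe trial types).
#' @examples
#' d <- parse_design("A->+ / AB->-; A->-; B->?")
#' d
#' format_design(d)
#' @seealso [format_design()], [expand_phase()]
#' @export
parse_design <- function(text, n_trials = 10L) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("design text must be a single nonempty string", call. = FALSE)
  txt <- gsub("->", ARROW, text, fixed = TRUE)
  bad <- gsub(sprintf("[A-Z0-9+?./;%s[:space:]-]", ARROW), "", txt)
  if (nzchar(bad))
    stop(sprintf("unknown character(s) '%s' in design '%s'", bad, text),
         call. = FALSE)
  phase_txt <- strsplit(txt, ";", fixed = TRUE)[[1]]
  if (length(phase_txt) == 0L || any(!nzchar(trimws(phase_txt))) ||
      grepl(";\\s*$", txt))
    stop(sprintf("empty phase in design '%s'", text), call. = FALSE)
  n_trials <- as.integer(n_trials)
  if (any(is.na(n_trials)) || any(n_trials < 1L))
    stop("n_trials must be a positive integer", call. = FALSE)
  n_trials <- rep_len(n_trials, length(phase_txt))
  phases <- vector("list", length(phase_txt))
  for (i in seq_along(phase_txt)) {
    tt_txt <- strsplit(phase_txt[i], "/", fixed = TRUE)[[1]]
    if (any(!nzchar(trimws(tt_txt))) || grepl("/\\s*$", phase_txt[i]))
      stop(sprintf("empty trial type in phase '%s'", trimws(phase_txt[i])),
           call. = FALSE)
    tts <- lapply(tt_txt, parse_trial_type)
    phases[[i]] <- structure(list(trial_types = tts, n_trials = n_trials[i]),
                             class = "design_phase")
  }
  new_design(phases)
}

parse_trial_type <- function(tt_text) {
  raw <- trimws(tt_text)
  tokens <- strsplit(raw, ARROW, fixed = TRUE)[[1]]
  tokens <- trimws(tokens)
  if (length(tokens) == 0L || any(!nzchar(tokens)) ||
      grepl(paste0(ARROW, "\\s*$"), raw))
    stop(sprintf("dangling arrow in trial type '%s'", raw), call. = FALSE)
  last <- tokens[length(tokens)]
  is_num <- grepl("^[0-9]*\\.?[0-9]+$", last)
  if (last %in% OUTCOME_TOKENS || is_num) {
    ev_tokens <- tokens[-length(tokens)]
    if (length(ev_tokens) == 0L)
      stop(sprintf("trial type '%s' has an outcome but no stimulus", raw),
           call. = FALSE)
    test <- identical(last, "?")
    outcome <- if (test) NA_real_
               else if (identical(last, "+")) 1
               else if (identical(last, "-")) 0
               else as.numeric(last)
  } else {
    # implicit no-reward serial trial such as "Z->X"
    ev_tokens <- tokens
    test <- FALSE
    outcome <- 0
  }
  events <- lapply(ev_tokens, function(tok) {
    if (!grepl("^[A-Z]+$", tok))
      stop(sprintf("malformed stimulus token '%s' in trial type '%s'",
                   tok, raw), call. = FALSE)
    labs <- sort(strsplit(tok, "", fixed = TRUE)[[1]])
    if (anyDuplicated(labs))
      stop(sprintf("duplicated stimulus in compound '%s'", tok), call. = FALSE)
    labs
  })
  new_trial_type(events, outcome, test)
}

new_trial_type <- function(events, outcome, test) {
  tt <- structure(list(events = events, outcome = outcome, test = test,
                       label = NA_character_), class = "trial_type")
  tt$label <- format_trial_type(tt)
  tt
}

new_design <- function(phases) {
  labels <- unlist(lapply(phases, function(ph)
    unlist(lapply(ph$trial_types, function(tt) unlist(tt$events)))))
  tts <- unlist(lapply(phases, `[[`, "trial_types"), recursive = FALSE)
  structure(list(phases = phases,
                 alphabet = sort(unique(labels)),
                 test_trials = Filter(function(tt) tt$test, tts)),
            class = "conditioning_design")
}

#' Render a design back to canonical notation
#'
#' The canonical form uses the UTF-8 arrow, single spaces around `/`, `"; "`
#' between phases, and always prints an explicit outcome token, so that
#' `parse_design(format_design(d))` is structurally identical to `d`.
#'
#' @param design a `conditioning_design`.
#' @return a single notation string.
#' @export
format_design <- function(design) {
  stopifnot(inherits(design, "conditioning_design"))
  paste(vapply(design$phases, function(ph)
    paste(vapply(ph$trial_types, format_trial_type, character(1)),
          collapse = " / "),
    character(1)), collapse = "; ")
}

format_trial_type <- function(tt) {
  ev <- vapply(tt$events, paste, character(1), collapse = "")
  out <- if (tt$test) "?"
         else if (isTRUE(all.equal(tt$outcome, 1))) "+"
         else if (isTRUE(all.equal(tt$outcome, 0))) "-"
         else format(tt$outcome)
  paste(c(ev, out), collapse = ARROW)
}

#' Expand a phase into an ordered trial sequence
#'
#' Trial types interleaved within a phase are laid out either in strict
#' round-robin alternation (the default, which makes every simulation
#' bit-reproducible) or in a seeded random permutation with equal counts.
#' Test probes (`?` trial types) are never included: they are read out from
#' the final weights, not trained on.
#'
#' @param phase a `design_phase` (element of `conditioning_design$phases`).
#' @param schedule `"alternating"` (round-robin) or `"shuffled"`.
#' @param seed integer seed used only for `"shuffled"`.
#' @return list of `trial_type` objects of length
#'   `n_trials * number of non-test trial types`.
#' @export
expand_phase <- function(phase, schedule = c("alternating", "shuffled"),
                         seed = 1L) {
  stopifnot(inherits(phase, "design_phase"))
  schedule <- match.arg(schedule)
  tts <- Filter(function(tt) !tt$test, phase$trial_types)
  if (length(tts) == 0L) return(list())
  out <- rep(tts, times = phase$n_trials)  # round-robin: T1,T2,...,T1,T2,...
  if (schedule == "shuffled") {
    perm <- with_local_seed(seed, sample.int(length(out)))
    out <- out[perm]
  }
  out
}

# run `expr` under a temporary RNG seed without disturbing the caller's stream
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' @export
print.conditioning_design <- function(x, ...) {
  cat("<conditioning_design> ", format_design(x), "\n", sep = "")
  cat("  stimuli: ", paste(x$alphabet, collapse = ", "),
      "; phases: ", length(x$phases),
      "; trials/type: ",
      paste(vapply(x$phases, `[[`, integer(1), "n_trials"), collapse = ","),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.trial_type <- function(x, ...) {
  cat("<trial_type> ", x$label, "\n", sep = "")
  invisible(x)
}

# TRUE when a design has no serial compounds (needed by trial-level models)
is_trial_level <- function(design) {
  all(vapply(unlist(lapply(design$phases, `[[`, "trial_types"),
                    recursive = FALSE),
             function(tt) length(tt$events) == 1L, logical(1)))
}
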