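# shared fixtures built in code

default_params <- function(...) model_params(...)

# random regression problem with 0/1 cue features, for oracle property tests
rand_problem <- function(seed, max_features = 20L, max_obs = 200L) {
  set.seed(seed)
  D <- sample(2:max_features, 1L)
  n <- sample(5:max_obs, 1L)
  X <- matrix(rbinom(n * D, 1L, 0.4), n, D)
  X[rowSums(X) == 0, 1L] <- 1  # every trial presents at least one cue
  w_true <- rnorm(D)
  r <- drop(X %*% w_true) + rnorm(n, sd = 0.5)
  list(X = X, r = r)
}

# sequential Kalman filtering of a raw (X, r) sequence
kalman_run_sequence <- function(X, r, params) {
  st <- agent_state(ncol(X), params, bayesian = TRUE)
  for (i in seq_len(nrow(X))) st <- kalman_step(st, X[i, ], r[i], params)$state
  st
}

min_eigen <- function(S) min(eigen(S, symmetric = TRUE,
                                   only.values = TRUE)$values)
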