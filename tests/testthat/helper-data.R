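# Small cohort generators used across tests.

# two-source cohort whose covariates carry no membership signal
null_cohort <- function(n_trial = 200, n_external = 200, k = 2, seed = 1,
                        p = 0.5) {
  set.seed(seed)
  n <- n_trial + n_external
  x <- matrix(rnorm(n * k), n, k)
  colnames(x) <- paste0("x", seq_len(k))
  as_subject_table(
    tibble::tibble(z = c(rep(1L, n_trial), rep(0L, n_external)),
                   y = rbinom(n, 1, p), !!!as.data.frame(x)),
    covariates = colnames(x))
}

# cohort whose external covariate means are shifted by `shift` SDs
shifted_cohort <- function(n_trial = 300, n_external = 300, k = 2,
                           shift = 1, seed = 1) {
  set.seed(seed)
  xt <- matrix(rnorm(n_trial * k), n_trial, k)
  xe <- matrix(rnorm(n_external * k, mean = shift), n_external, k)
  x <- rbind(xt, xe)
  colnames(x) <- paste0("x", seq_len(k))
  as_subject_table(
    tibble::tibble(z = c(rep(1L, n_trial), rep(0L, n_external)),
                   y = rbinom(n_trial + n_external, 1, 0.5),
                   !!!as.data.frame(x)),
    covariates = colnames(x))
}

# a fixed-lambda propensity_fit stub for weight-scheme unit tests
lambda_fit <- function(lambda, n_trial) {
  structure(list(lambda = lambda, converged = TRUE,
                 separation_flags = rep(FALSE, length(lambda)),
                 n_trial = n_trial, n = length(lambda)),
            class = "propensity_fit")
}
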