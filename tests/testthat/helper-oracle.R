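# Independent numerical oracles for the beta-binomial power-prior posterior.
# These integrate the joint density on a grid and never call the package's
# closed-form Beta-function expressions.

# log C(delta) by adaptive quadrature over theta; the integrand is rescaled
# by its mode so the integral stays well inside double range
oracle_log_scaling <- function(delta, a_e, b_e) {
  a <- delta * a_e
  b <- delta * b_e
  m <- if (a + b > 0) a * log(a / (a + b)) + b * log(b / (a + b)) else 0
  f <- function(t) exp(a * log(t) + b * log1p(-t) - m)
  log(stats::integrate(f, 0, 1, rel.tol = 1e-12, abs.tol = 0)$value) + m
}

# moments of the joint posterior by 2-D trapezoid quadrature
oracle_joint <- function(a_e, b_e, a0, b0, alpha = 1, beta = 1,
                         n_theta = 2001, n_delta = 401) {
  th <- seq(0, 1, length.out = n_theta)[-c(1, n_theta)]
  dl <- seq(0, 1, length.out = n_delta)
  trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  marg <- numeric(n_delta)
  mth <- numeric(n_delta)
  for (i in seq_along(dl)) {
    d <- dl[i]
    cd <- trapz(th, exp(d * a_e * log(th) + d * b_e * log1p(-th)))
    num <- exp((d * a_e + a0) * log(th) + (d * b_e + b0) * log1p(-th))
    marg[i] <- trapz(th, num) / cd * stats::dbeta(d, alpha, beta)
    mth[i] <- trapz(th, th * num) / trapz(th, num)
  }
  norm <- trapz(dl, marg)
  m1 <- trapz(dl, dl * marg) / norm
  m2 <- trapz(dl, dl^2 * marg) / norm
  list(delta_mean = m1, delta_var = m2 - m1^2,
       theta_mean = trapz(dl, mth * marg) / norm,
       log_density = function(d_eval) {
         # unnormalised log marginal of delta at arbitrary points
         vapply(d_eval, function(d) {
           cd <- trapz(th, exp(d * a_e * log(th) + d * b_e * log1p(-th)))
           num <- trapz(th, exp((d * a_e + a0) * log(th) +
                                  (d * b_e + b0) * log1p(-th)))
           log(num / cd) + stats::dbeta(d, alpha, beta, log = TRUE)
         }, numeric(1))
       })
}
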