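# Independent oracles, kept deliberately dumb: brute-force grids and
# hand-rolled linear algebra, never the package's own code paths.

# perpendicular dipolar frequency from first principles (CODATA 2018)
oracle_nu_perp <- function(r_nm, g1 = 2.0023, g2 = 2.0023) {
  mu0_4pi <- 1e-7
  muB <- 9.2740100783e-24
  h <- 6.62607015e-34
  (mu0_4pi * g1 * g2 * muB^2 / (h * (r_nm * 1e-9)^3)) / 1e6
}

# powder average by plain Riemann sum on a dense theta grid
oracle_kernel <- function(r_nm, t_ns, tau_ns, n_grid = 2e5) {
  theta <- (seq_len(n_grid) - 0.5) * (pi / 2) / n_grid
  nu <- oracle_nu_perp(r_nm) * (1 - 3 * cos(theta)^2)
  mean_w <- sum(sin(theta)) * (pi / 2) / n_grid
  sum(cos(2 * pi * nu * (t_ns - tau_ns) * 1e-3) * sin(theta)) *
    (pi / 2) / n_grid / mean_w
}

# polynomial least squares by explicit normal equations
oracle_polyfit <- function(t, v, order) {
  X <- outer(t, 0:order, `^`)
  beta <- solve(crossprod(X), crossprod(X, v))
  as.vector(X %*% beta)
}

# direct-summation cosine transform at one frequency (MHz), loop form
oracle_cosine_amp <- function(v, t_ns, tau_ns, nu_MHz) {
  acc <- 0
  for (k in seq_along(v))
    acc <- acc + v[k] * cos(2 * pi * nu_MHz * (t_ns[k] - tau_ns) * 1e-3)
  acc
}

# one-bin distance uncertainty of the zero-filled spectrum at distance r_A
bin_distance_error <- function(r_A, n_zf = 1024, dt_ns = 8) {
  res <- 1e3 / (n_zf * dt_ns)
  nu <- oracle_nu_perp(r_A / 10)
  r_A / (3 * nu) * res
}
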