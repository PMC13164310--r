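# Shared fixtures: small panels and hand-built Gaussian summaries.

tiny_config <- function(topology = "random", mu_B = 0, seed = 42L,
                        n = 36L, n_A = 12L, n_B = 12L, p = 20L,
                        n_subnetworks = 2L) {
  sim_config(n = n, n_A = n_A, n_B = n_B, p = p,
             n_subnetworks = n_subnetworks, topology = topology,
             mu_B = mu_B, seed = seed)
}

scalar_summary <- function(mu, var = 1) {
  gaussian_summary(mu, matrix(var, 1, 1))
}

random_pd <- function(p, seed) {
  set.seed(seed)
  a <- matrix(rnorm(p * p), p, p)
  crossprod(a) + diag(p) * 0.5
}

# closed-form KL between two univariate normals
kl_1d <- function(mu_a, var_a, mu_b, var_b) {
  0.5 * (log(var_b / var_a) - 1 + var_a / var_b + (mu_a - mu_b)^2 / var_b)
}
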