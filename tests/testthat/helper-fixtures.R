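# Shared fixtures, memoized so expensive objects are built once per run.
.fixture_env <- new.env()

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE))
    assign(name, expr, envir = .fixture_env)
  get(name, envir = .fixture_env, inherits = FALSE)
}

# small climate record / bank with a reduced SPEI grid, for model-level tests
small_climate <- function() memo("small_climate",
  simulate_climate(n_sites = 2, years = c(1930, 2011), seed = 5))

small_bank <- function() memo("small_bank",
  suppressWarnings(build_index_bank(small_climate(), spei_scales = 1:24,
                                    spi_scales = 1:3)))

# truth with timescales inside the reduced grid
small_truth <- function() ts_truth(t_hist = 20, t_cont = 10, t_spi = 2)

small_sim <- function() memo("small_sim",
  simulate_observations(small_truth(), small_bank(), n_wetlands = 12,
                        years_per_era = 5, seed = 8))

# a cheap fitted model shared by posterior-side tests
small_fit <- function() memo("small_fit", {
  ctrl <- ts_control(chains = 2, burnin = 300, iter = 600, thin = 3,
                     adapt = TRUE, window_spei = 4)
  timescale_betareg(small_sim()$data, control = ctrl, seed = 99)
})

# an update-flag list with everything off except the named blocks
only_updates <- function(...) {
  on <- c(...)
  all_blocks <- c("latent_mu", "latent_phi", "beta_mu", "gamma", "beta_phi",
                  "eps", "precisions", "timescales", "interweave")
  as.list(stats::setNames(all_blocks %in% on, all_blocks))
}

# Kolmogorov-Smirnov distance between a sample and a CDF given on a grid
ks_distance <- function(draws, grid, cdf) {
  ecdf_at <- stats::ecdf(draws)(grid)
  max(abs(ecdf_at - cdf))
}

expect_no_na <- function(x) expect_false(anyNA(x))

# a random valid model state for joint-density tests
random_state <- function(data, seed = 1) {
  set.seed(seed)
  I <- length(data$wetland_id)
  N <- length(data$y)
  list(beta = rnorm(7, 0, 0.5), bphi = rnorm(1, 2, 0.5),
       gamma = rnorm(I, 0, 0.3), eps = rnorm(I, 0, 0.3),
       l = rnorm(N, 0, 1), m = rnorm(N, 2, 0.5),
       tau_gamma = runif(1, 0.5, 30), tau_delta = runif(1, 0.2, 3),
       tau_eps = runif(1, 0.5, 30), tau_zeta = runif(1, 0.2, 3),
       t_hist = sample(ncol(data$spei), 1), t_cont = sample(ncol(data$spei), 1),
       t_spi = sample(ncol(data$spi), 1))
}

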