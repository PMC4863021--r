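test_that("chains are deterministic given a seed and allow empty runs", {
  data <- small_sim()$data
  ctrl <- ts_control(chains = 1, burnin = 50, iter = 100, thin = 2,
                     window_spei = 4)
  a <- run_chain(data, control = ctrl, seed = 42)
  b <- run_chain(data, control = ctrl, seed = 42)
  expect_identical(a, b)
  c <- run_chain(data, control = ctrl, seed = 43)
  expect_false(identical(a$draws, c$draws))

  empty <- run_chain(data, control = ts_control(chains = 1, burnin = 10,
                                                iter = 0, thin = 1),
                     seed = 1)
  expect_equal(nrow(empty$draws), 0)
})

test_that("random-walk step size drives latent acceptance to its limits", {
  data <- small_sim()$data
  base <- list(control = NULL)
  tiny <- suppressWarnings(run_chain(data, control = ts_control(
    chains = 1, burnin = 0, iter = 200, thin = 10, step_mu = 1e-4,
    step_phi = 1e-4, updates = only_updates("latent_mu", "latent_phi")),
    seed = 7))
  expect_gt(tiny$acceptance$latent_mu, 0.98)
  expect_gt(tiny$acceptance$latent_phi, 0.98)
  huge <- suppressWarnings(run_chain(data, control = ts_control(
    chains = 1, burnin = 0, iter = 200, thin = 10, step_mu = 50,
    step_phi = 50, updates = only_updates("latent_mu", "latent_phi")),
    seed = 7))
  expect_lt(huge$acceptance$latent_mu, 0.2)
  expect_lt(huge$acceptance$latent_phi, 0.2)
})

test_that("precision Gibbs block draws from its closed-form conditional", {
  data <- small_sim()$data
  I <- length(data$wetland_id)
  init <- droughtscale:::default_init(data)
  ctrl <- ts_control(chains = 1, burnin = 0, iter = 8000, thin = 1,
                     updates = only_updates("precisions"))
  res <- run_chain(data, control = ctrl, seed = 5, init = init)
  # everything else held fixed: the tau_gamma conditional is
  # Gamma(a + I/2, b + sum(gamma^2)/2) at the initial gamma
  shape <- 0.001 + I / 2
  rate <- 0.001 + sum(init$gamma^2) / 2
  draws <- res$draws[, "tau_gamma"]
  expect_lt(abs(mean(draws) - shape / rate),
            3 * sqrt(shape / rate^2 / length(draws)))
  grid <- seq(min(draws), max(draws), length.out = 400)
  expect_lt(ks_distance(draws, grid, pgamma(grid, shape, rate)), 0.05)
  # and with gamma frozen at zero the shape collapses to a + I/2, rate b
  init0 <- init
  init0$gamma <- rep(0, I)
  res0 <- run_chain(data, control = ts_control(chains = 1, burnin = 0,
                                               iter = 4000, thin = 1,
                                               updates = only_updates("precisions")),
                    seed = 6, init = init0)
  d0 <- res0$draws[, "tau_gamma"]
  expect_lt(abs(mean(d0) - (0.001 + I / 2) / 0.001),
            3 * sd(d0) / sqrt(length(d0)))
})

test_that("timescale posterior is uniform when all bank columns are identical", {
  sim <- small_sim()
  data <- sim$data
  # flatten the bank: every SPEI column identical -> likelihood flat in t
  K <- 5
  data$spei <- matrix(rep(data$spei[, 1], K), ncol = K)
  data$spei_scales <- 1:K
  ctrl <- ts_control(chains = 1, burnin = 200, iter = 6000, thin = 1,
                     window_spei = 2,
                     updates = only_updates("timescales"))
  init <- droughtscale:::default_init(data)
  res <- run_chain(data, control = ctrl, seed = 2, init = init)
  expect_equal(res$acceptance$t_hist, 1)
  expect_equal(res$acceptance$t_cont, 1)
  f <- tabulate(res$draws[, "t_spei_hist"], nbins = K) / nrow(res$draws)
  expect_true(all(abs(f - 1 / K) < 0.06))
})

test_that("M-H acceptance uses exactly the local log-joint difference", {
  # moving one latent l_i changes the full log joint by the beta-likelihood
  # difference plus the delta-normal difference -- the quantity the sampler's
  # acceptance rule computes
  data <- small_sim()$data
  pr <- ts_priors()
  st <- random_state(data, 9)
  X <- build_design_matrix(data, st$t_hist, st$t_cont, st$t_spi)
  eta <- drop(X %*% st$beta) + st$gamma[data$wetland]
  i <- 4
  st2 <- st
  st2$l <- replace(st$l, i, st$l[i] + 0.37)
  local <- beta_logpdf(data$y[i], plogis(st2$l[i]), exp(st$m[i])) -
    beta_logpdf(data$y[i], plogis(st$l[i]), exp(st$m[i])) +
    dnorm(st2$l[i], eta[i], 1 / sqrt(st$tau_delta), log = TRUE) -
    dnorm(st$l[i], eta[i], 1 / sqrt(st$tau_delta), log = TRUE)
  expect_equal(log_joint(st2, data, pr) - log_joint(st, data, pr), local,
               tolerance = 1e-8)

  # switching one timescale changes the joint only through the delta-normal
  # terms of the affected era's observations
  st3 <- st
  st3$t_hist <- st$t_hist %% ncol(data$spei) + 1
  X3 <- build_design_matrix(data, st3$t_hist, st3$t_cont, st3$t_spi)
  eta3 <- drop(X3 %*% st$beta) + st$gamma[data$wetland]
  h <- data$era == 0
  local3 <- sum(dnorm(st$l[h], eta3[h], 1 / sqrt(st$tau_delta), log = TRUE)) -
    sum(dnorm(st$l[h], eta[h], 1 / sqrt(st$tau_delta), log = TRUE))
  expect_equal(log_joint(st3, data, pr) - log_joint(st, data, pr), local3,
               tolerance = 1e-8)
})

test_that("Gelman-Rubin diagnostic behaves on designed chain sets", {
  set.seed(31)
  one <- matrix(rnorm(500), ncol = 1, dimnames = list(NULL, "x"))
  expect_lte(gelman_rubin(list(one, one, one))[["x"]], 1)
  iid <- lapply(1:3, function(i)
    matrix(rnorm(1000), ncol = 1, dimnames = list(NULL, "x")))
  expect_lt(gelman_rubin(iid)[["x"]], 1.05)
  div <- iid
  div[[3]] <- div[[3]] + 10
  expect_gt(gelman_rubin(div)[["x"]], 1.2)
  expect_error(gelman_rubin(list(one)), "at least 2 chains")
  expect_error(gelman_rubin(list(one[1:5, , drop = FALSE],
                                 one[1:5, , drop = FALSE])), "at least 10")
})

test_that("latent-block acceptance rates sit inside the working band", {
  fit <- small_fit()
  for (a in fit$acceptance) {
    expect_gt(a$latent_mu, 0.05); expect_lt(a$latent_mu, 0.95)
    expect_gt(a$latent_phi, 0.05); expect_lt(a$latent_phi, 0.95)
  }
})

test_that("every stored draw satisfies the state invariants", {
  fit <- small_fit()
  taus <- fit$draws[, c("tau_gamma", "tau_delta", "tau_eps", "tau_zeta")]
  expect_true(all(taus > 0))
  K <- length(fit$data$spei_scales)
  expect_true(all(fit$draws[, "t_spei_hist"] %in% seq_len(K)))
  expect_true(all(fit$draws[, "t_spei_cont"] %in% seq_len(K)))
  expect_true(all(fit$draws[, "t_spi"] %in%
                    seq_along(fit$data$spi_scales)))
  expect_no_na(fit$draws)
})
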