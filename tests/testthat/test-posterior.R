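make_fake_fit <- function(draws, data, gamma = NULL, eps = NULL, chains = 1) {
  n <- nrow(draws)
  I <- length(data$wetland_id)
  structure(list(
    draws = draws,
    chain = rep(seq_len(chains), each = n / chains),
    iteration = rep(seq_len(n / chains), chains),
    gamma = if (is.null(gamma)) matrix(0, n, I) else gamma,
    eps = if (is.null(eps)) matrix(0, n, I) else eps,
    data = data, priors = ts_priors(),
    control = ts_control(chains = chains, burnin = 0, iter = n, thin = 1)
  ), class = "ts_betareg")
}

test_that("posterior summaries report mean, SE and quantiles correctly", {
  const <- matrix(2.5, 100, 1, dimnames = list(NULL, "x"))
  s <- droughtscale:::summarize_draws(const)
  expect_equal(s$mean, 2.5)
  expect_equal(s$se, 0)
  expect_equal(s$q2.5, 2.5)
  expect_equal(s$q97.5, 2.5)

  set.seed(14)
  z <- matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "z"))
  s2 <- droughtscale:::summarize_draws(z)
  expect_lt(abs(s2$mean), 0.05)
  expect_lt(abs(s2$q2.5 + 1.96), 0.1)
  expect_lt(abs(s2$q97.5 - 1.96), 0.1)

  t84 <- matrix(84, 50, 1, dimnames = list(NULL, "t_spei_hist"))
  s3 <- droughtscale:::summarize_draws(t84)
  expect_equal(unlist(s3[, c("mean", "se", "q2.5", "q97.5")], use.names = FALSE),
               c(84, 0, 84, 84))
  expect_error(droughtscale:::summarize_draws(z[0, , drop = FALSE]), "empty")
})

test_that("summary method attaches convergence diagnostics", {
  s <- summary(small_fit())
  expect_s3_class(s, "summary.ts_betareg")
  expect_true(all(c("parameter", "mean", "se", "q2.5", "q97.5", "rhat")
                  %in% names(s)))
  expect_true(all(s$q2.5 <= s$q97.5))
  expect_output(print(s), "Posterior summary")
})

test_that("weighted index reduces correctly and matches a brute-force loop", {
  bank <- small_bank()
  K <- ncol(bank$spei)
  # point mass: the weighted series is exactly that column
  w1 <- weighted_index(bank, rep(7L, 50))
  expect_equal(w1$index, unname(bank$spei[, 7]))
  expect_equal(sum(attr(w1, "weights")), 1)
  # two equal weights: arithmetic mean of the two columns
  w2 <- weighted_index(bank, rep(c(3L, 9L), 25))
  expect_equal(w2$index, unname((bank$spei[, 3] + bank$spei[, 9]) / 2))
  # arbitrary draws against an explicit per-month loop
  set.seed(6)
  t_draws <- sample(1:K, 400, replace = TRUE, prob = stats::dpois(0:(K - 1), 6))
  w3 <- weighted_index(bank, t_draws)
  wts <- tabulate(t_draws, nbins = K) / 400
  for (m in c(30, 200, 900)) {
    expect_equal(w3$index[m], sum(wts * bank$spei[m, ]))
  }
  # order invariance
  w4 <- weighted_index(bank, rev(t_draws))
  expect_equal(w3$index, w4$index)
  # months where a weighted column is undefined are flagged missing
  expect_true(is.na(w3$index[1]))
  expect_error(weighted_index(bank, c(1L, 200L)), "outside")
})

test_that("era-by-region index comparison equals group averages", {
  bank <- small_bank()
  w <- weighted_index(bank, rep(5L, 10))
  regions <- c(S1 = "west", S2 = "east")
  cmp <- compare_index_by_group(w, regions)
  expect_equal(nrow(cmp), 4)
  for (i in seq_len(nrow(cmp))) {
    in_era <- if (cmp$era[i] == 0) w$year <= 1969 else w$year >= 2003
    sel <- in_era & regions[as.character(w$site_id)] == cmp$region[i] &
      !is.na(w$index)
    expect_equal(cmp$mean[i], mean(w$index[sel]))
    expect_equal(cmp$n[i], sum(sel))
    expect_true(cmp$lower[i] <= cmp$mean[i] && cmp$mean[i] <= cmp$upper[i])
  }
  # constructed shift: moving contemporary months up by 1 moves cell means
  w_shift <- w
  w_shift$index[w_shift$year >= 2003] <- w_shift$index[w_shift$year >= 2003] + 1
  cmp2 <- compare_index_by_group(w_shift, regions)
  d <- cmp2$mean[cmp2$era == 1] - cmp$mean[cmp$era == 1]
  expect_equal(d, rep(1, 2))
  expect_error(compare_index_by_group(w, c(S1 = "west")), "unlabeled")
  expect_error(compare_index_by_group(w, regions, era_cutoffs = c(1800, 1801)),
               "empty cell")
})

test_that("population-level predictions follow the logistic link", {
  data <- small_sim()$data
  bank <- small_bank()
  w <- weighted_index(bank, rep(5L, 10))
  w <- w[w$site_id == "S1", ]
  # all-zero coefficients: mu = 0.5 with a zero-width band
  d0 <- matrix(0, 40, 15, dimnames = list(NULL, droughtscale:::SCALAR_PARAMS))
  d0[, c("tau_gamma", "tau_delta", "tau_eps", "tau_zeta")] <- 1
  d0[, c("t_spei_hist", "t_spei_cont", "t_spi")] <- 1
  f0 <- make_fake_fit(d0, data)
  p0 <- predict(f0, w, era = 0)
  expect_true(all(p0$mean == 0.5 & p0$lower == 0.5 & p0$upper == 0.5))
  # intercept -0.62 alone puts the mean proportion at plogis(-0.62) ~ 0.35
  # when the index covariate is zero
  d1 <- d0
  d1[, "beta0"] <- -0.62
  f1 <- make_fake_fit(d1, data)
  w0 <- w
  w0$index <- 0
  p1 <- predict(f1, w0, era = 1)
  expect_equal(unique(p1$mean), plogis(-0.62))
  expect_equal(round(unique(p1$mean), 2), 0.35)
  # positive SPEI coefficient: mu nondecreasing in the weighted index
  d2 <- d0
  d2[, "beta_spei"] <- runif(40, 0.2, 1)
  f2 <- make_fake_fit(d2, data)
  p2 <- predict(f2, w, era = 0)
  o <- order(w$index[w$month == data$month & !is.na(w$index)])
  expect_true(all(diff(p2$mean[o]) >= 0))
  expect_error(predict(f2, w, era = 3), "era must be")
})

test_that("predictive R-squared spans its limits", {
  fit <- small_fit()
  r2c <- predictive_r2(fit, "conditional", ndraw = 40, seed = 2)
  r2m <- predictive_r2(fit, "marginal", ndraw = 40, seed = 2)
  expect_true(r2c >= 0 && r2c <= 1)
  expect_true(r2m >= 0 && r2m <= 1)
  # independence limit: against a shuffled response the R2 collapses
  fit_ind <- fit
  set.seed(9)
  fit_ind$data$y <- sample(fit$data$y)
  r2_ind <- predictive_r2(fit_ind, "conditional", ndraw = 40, seed = 2)
  expect_lt(r2_ind, 0.08)
  expect_error(predictive_r2(fit, "sideways"), "arg")
})

test_that("simulate and residuals methods return well-formed values", {
  fit <- small_fit()
  sims <- simulate(fit, nsim = 10, seed = 1, mode = "marginal")
  expect_equal(dim(sims), c(10, length(fit$data$y)))
  expect_true(all(sims >= 0 & sims <= 1))
  r <- residuals(fit)
  expect_equal(length(r), length(fit$data$y))
  expect_no_na(r)
  expect_gt(sd(r), 0)
  # residuals co-move with the response around its fitted mean
  expect_gt(cor(r, fit$data$y), 0)
  expect_error(simulate(fit, mode = "bogus"), "mode")
})

test_that("plot methods run without error", {
  fit <- small_fit()
  pdf(NULL)
  on.exit(dev.off())
  expect_no_error(plot(fit, which = "timescale"))
  expect_no_error(plot(fit, which = "trace"))
  expect_output(print(fit), "Hierarchical beta regression")
})
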