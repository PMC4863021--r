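#' Summarize posterior draws
#'
#' Pools chains and reports, per scalar parameter, the posterior mean,
#' standard error (posterior SD) and empirical 2.5\%/97.5\% quantiles, in the
#' conventional parameter-table layout. Attaches Gelman-Rubin \eqn{\hat R}
#' when more than one chain is present.
#'
#' @param object A \code{ts_betareg} fit.
#' @param ... Unused.
#' @return Object of class \code{summary.ts_betareg}: a data frame with
#'   columns \code{parameter, mean, se, q2.5, q97.5} (and \code{rhat} when
#'   available).
#' @export
summary.ts_betareg <- function(object, ...) {
  out <- summarize_draws(object$draws)
  if (object$control$chains >= 2 && min(table(object$chain)) >= 10)
    out$rhat <- unname(gelman_rubin(object))
  class(out) <- c("summary.ts_betareg", "data.frame")
  attr(out, "acceptance") <- object$acceptance
  out
}

summarize_draws <- function(draws) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  if (nrow(draws) == 0) stop("summarize: empty posterior sample")
  q <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(parameter = colnames(draws),
             mean = colMeans(draws),
             se = apply(draws, 2, stats::sd),
             q2.5 = q[1, ], q97.5 = q[2, ],
             row.names = NULL)
}

#' @export
print.summary.ts_betareg <- function(x, digits = 3, ...) {
  cat("Posterior summary (chains pooled)\n")
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], round, digits)
  print(df, row.names = FALSE)
  if (!is.null(x$rhat) && any(x$rhat > 1.1, na.rm = TRUE))
    cat("Warning: R-hat > 1.1 for",
        paste(x$parameter[x$rhat > 1.1], collapse = ", "),
        "- chains may not have converged\n")
  invisible(x)
}

#' Posterior-predictive simulation
#'
#' Simulates replicate response vectors from the beta likelihood, one per
#' posterior draw. \code{mode = "marginal"} draws fresh wetland effects and
#' residuals from their precision-implied normal distributions ("fixed
#' effects" prediction); \code{mode = "conditional"} keeps the stored wetland
#' effects and redraws only the residuals.
#'
#' @param object A \code{ts_betareg} fit.
#' @param nsim Number of replicate datasets (posterior draws are subsampled
#'   evenly; default all).
#' @param seed Optional seed.
#' @param mode \code{"marginal"} or \code{"conditional"}.
#' @param ... Unused.
#' @return Matrix nsim x N of simulated responses.
#' @export
simulate.ts_betareg <- function(object, nsim = nrow(object$draws),
                                seed = NULL, mode = "conditional", ...) {
  if (!mode %in% c("marginal", "conditional"))
    stop("mode must be 'marginal' or 'conditional'")
  if (!is.null(seed)) set.seed(seed)
  data <- object$data
  N <- length(data$y)
  idx <- unique(round(seq(1, nrow(object$draws), length.out = nsim)))
  out <- matrix(NA_real_, length(idx), N)
  for (r in seq_along(idx)) {
    d <- object$draws[idx[r], ]
    X <- build_design_matrix(data, d["t_spei_hist"], d["t_spei_cont"],
                             d["t_spi"])
    if (mode == "marginal") {
      gam <- stats::rnorm(length(data$wetland_id), 0, 1 / sqrt(d["tau_gamma"]))
      ep <- stats::rnorm(length(data$wetland_id), 0, 1 / sqrt(d["tau_eps"]))
    } else {
      gam <- object$gamma[idx[r], ]
      ep <- object$eps[idx[r], ]
    }
    delta <- stats::rnorm(N, 0, 1 / sqrt(d["tau_delta"]))
    zeta <- stats::rnorm(N, 0, 1 / sqrt(d["tau_zeta"]))
    mu <- inv_logit(drop(X %*% d[1:7]) + gam[data$wetland] + delta)
    phi <- exp(d["log_phi"] + ep[data$wetland] + zeta)
    out[r, ] <- stats::rbeta(N, mu * phi, (1 - mu) * phi)
  }
  out
}

#' Posterior-predictive R-squared
#'
#' Model-fit diagnostic: for each posterior draw, simulates data from the
#' fitted beta likelihood and computes the coefficient of determination of
#' the regression of simulated on observed responses (the squared Pearson
#' correlation), averaged over draws. \code{"marginal"} uses fixed effects
#' only (fresh random effects); \code{"conditional"} re-uses the estimated
#' wetland effects.
#'
#' @param fit A \code{ts_betareg} fit.
#' @param mode \code{"marginal"} or \code{"conditional"}.
#' @param ndraw Number of posterior draws to use (default 100).
#' @param seed Optional seed for the simulation.
#' @return Mean R-squared across draws.
#' @export
predictive_r2 <- function(fit, mode = c("marginal", "conditional"),
                          ndraw = 100, seed = NULL) {
  mode <- match.arg(mode)
  sims <- simulate(fit, nsim = ndraw, seed = seed, mode = mode)
  y <- fit$data$y
  r2 <- apply(sims, 1, function(ys) {
    if (stats::sd(ys) == 0) return(0)
    stats::cor(ys, y)^2
  })
  mean(r2)
}

#' Posterior-weighted climate index
#'
#' Collapses the bank of candidate SPEI columns into a single series per
#' site-month: the sum of each candidate index weighted by the posterior
#' relative frequency of its timescale in the draws (the estimated timescale
#' distribution for one era).
#'
#' @param bank An \code{index_bank}.
#' @param t_draws Integer draws of the timescale (positions in the bank's
#'   SPEI grid), e.g. \code{fit$draws[, "t_spei_hist"]}.
#' @return Object of class \code{weighted_index}: data frame with
#'   \code{site_id, year, month, index}, plus attribute \code{"weights"}
#'   (named vector over timescales, summing to 1). Months where any
#'   positively-weighted column is undefined are \code{NA}.
#' @export
weighted_index <- function(bank, t_draws) {
  K <- ncol(bank$spei)
  t_draws <- as.integer(round(t_draws))
  if (any(t_draws < 1 | t_draws > K))
    stop("weighted_index: timescale draws outside the bank grid 1..", K)
  w <- tabulate(t_draws, nbins = K) / length(t_draws)
  used <- which(w > 0)
  idx <- drop(bank$spei[, used, drop = FALSE] %*% w[used])
  undef <- rowSums(is.na(bank$spei[, used, drop = FALSE])) > 0
  idx[undef] <- NA_real_
  out <- data.frame(site_id = bank$site_id, year = bank$year,
                    month = bank$month, index = idx)
  attr(out, "weights") <- stats::setNames(w, colnames(bank$spei))
  class(out) <- c("weighted_index", "data.frame")
  out
}

#' Era-by-region means of a weighted index
#'
#' Post hoc comparison of mean climate between eras and regions: the mean of
#' the weighted index over the site-months in each era x region cell with a
#' normal-approximation 95\% interval from the cell standard error.
#'
#' @param weighted A \code{\link{weighted_index}} object.
#' @param regions Named character vector mapping site_id to region label.
#' @param era_cutoffs Length-2 numeric: historical era is \code{year <=
#'   era_cutoffs[1]}, contemporary is \code{year >= era_cutoffs[2]} (default
#'   \code{c(1969, 2003)}); years between belong to neither.
#' @return Data frame with \code{era, region, mean, lower, upper, n}.
#' @export
compare_index_by_group <- function(weighted, regions,
                                   era_cutoffs = c(1969, 2003)) {
  if (is.null(names(regions)))
    stop("regions must be a named vector (names = site ids)")
  reg <- regions[as.character(weighted$site_id)]
  if (anyNA(reg))
    stop("unlabeled site(s): ",
         paste(unique(weighted$site_id[is.na(reg)]), collapse = ", "))
  era <- ifelse(weighted$year <= era_cutoffs[1], 0L,
                ifelse(weighted$year >= era_cutoffs[2], 1L, NA_integer_))
  keep <- !is.na(era) & !is.na(weighted$index)
  cells <- expand.grid(era = 0:1, region = unique(unname(reg)),
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- keep & era == cells$era[i] & reg == cells$region[i]
    n <- sum(sel)
    if (n == 0)
      stop("empty cell: era ", cells$era[i], ", region ", cells$region[i])
    v <- weighted$index[sel]
    se <- if (n > 1) stats::sd(v) / sqrt(n) else 0
    data.frame(era = cells$era[i], region = cells$region[i],
               mean = mean(v), lower = mean(v) - 1.96 * se,
               upper = mean(v) + 1.96 * se, n = n)
  })
  do.call(rbind, res)
}

#' Predicted proportion filled over time
#'
#' Population-level prediction of the proportion of a basin covered with
#' water: for each year (at the dataset's evaluation month) and each
#' posterior draw, the inverse-logit of the mean linear predictor built from
#' the posterior-weighted SPEI index, with the SPI covariate held at its mean
#' and random effects at zero (optionally integrated by sampling them from
#' their precisions).
#'
#' @param object A \code{ts_betareg} fit.
#' @param weighted A \code{\link{weighted_index}} for the era of interest
#'   (typically built from that era's timescale draws), covering one site.
#' @param era 0 (historical) or 1 (contemporary).
#' @param integrate_effects Sample wetland effect and residual from their
#'   precision draws instead of setting them to zero (default \code{FALSE}).
#' @param ... Unused.
#' @return Data frame with \code{year, mean, lower, upper} (posterior mean
#'   and 2.5\%/97.5\% quantiles of \eqn{\mu}).
#' @export
predict.ts_betareg <- function(object, weighted, era,
                               integrate_effects = FALSE, ...) {
  if (!era %in% c(0, 1)) stop("era must be 0 or 1")
  sel <- weighted$month == object$data$month & !is.na(weighted$index)
  w <- weighted[sel, ]
  spi_bar <- mean(object$data$spi[, 1])
  draws <- object$draws
  R <- nrow(draws)
  mu <- matrix(NA_real_, R, nrow(w))
  for (r in seq_len(R)) {
    b <- draws[r, 1:7]
    s <- w$index
    eta <- b[1] + b[2] * era + s * (b[3] + b[5] * era) + b[4] * spi_bar +
      s * spi_bar * (b[6] + b[7] * era)
    if (integrate_effects) {
      eta <- eta + stats::rnorm(1, 0, 1 / sqrt(draws[r, "tau_gamma"])) +
        stats::rnorm(length(eta), 0, 1 / sqrt(draws[r, "tau_delta"]))
    }
    mu[r, ] <- inv_logit(eta)
  }
  q <- apply(mu, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(year = w$year, mean = colMeans(mu), lower = q[1, ], upper = q[2, ])
}

#' Posterior-mean Pearson residuals
#'
#' @param object A \code{ts_betareg} fit.
#' @param ... Unused.
#' @return Vector of residuals \eqn{(y - \hat\mu)/\widehat{SD}(y)} with
#'   \eqn{\hat\mu} and the beta SD averaged over draws (conditional on the
#'   stored wetland effects, residuals at zero).
#' @export
residuals.ts_betareg <- function(object, ...) {
  data <- object$data
  draws <- object$draws
  R <- nrow(draws)
  mu_acc <- sd_acc <- 0
  for (r in seq_len(R)) {
    d <- draws[r, ]
    X <- build_design_matrix(data, d["t_spei_hist"], d["t_spei_cont"],
                             d["t_spi"])
    mu <- inv_logit(drop(X %*% d[1:7]) + object$gamma[r, data$wetland])
    phi <- exp(d["log_phi"] + object$eps[r, data$wetland])
    mu_acc <- mu_acc + mu
    sd_acc <- sd_acc + sqrt(mu * (1 - mu) / (1 + phi))
  }
  (data$y - mu_acc / R) / (sd_acc / R)
}

#' Plot a fitted timescale beta regression
#'
#' \code{which = "timescale"} draws the posterior distributions of the SPEI
#' timescale for both eras against the uniform prior; \code{which = "trace"}
#' draws per-chain trace plots of the main coefficients.
#'
#' @param x A \code{ts_betareg} fit.
#' @param which \code{"timescale"} or \code{"trace"}.
#' @param ... Passed to the underlying plotting calls.
#' @export
plot.ts_betareg <- function(x, which = c("timescale", "trace"), ...) {
  which <- match.arg(which)
  if (which == "timescale") {
    K <- length(x$data$spei_scales)
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    for (par_name in c("t_spei_hist", "t_spei_cont")) {
      f <- tabulate(x$draws[, par_name], nbins = K) / nrow(x$draws)
      graphics::barplot(f, names.arg = x$data$spei_scales,
                        main = par_name, xlab = "timescale (months)",
                        ylab = "posterior frequency", border = NA, ...)
      graphics::abline(h = 1 / K, col = "red")
    }
  } else {
    op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    for (par_name in c("beta0", "beta_era", "beta_spei", "t_spei_hist")) {
      graphics::plot(x$iteration, x$draws[, par_name], type = "n",
                     xlab = "kept iteration", ylab = par_name,
                     main = par_name)
      for (ch in unique(x$chain)) {
        sel <- x$chain == ch
        graphics::lines(x$iteration[sel], x$draws[sel, par_name], col = ch)
      }
    }
  }
  invisible(x)
}
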