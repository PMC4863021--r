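#' Sampler configuration
#'
#' Controls for the Gibbs-within-Metropolis sampler: chain count, burn-in,
#' post-burn-in iterations, thinning, random-walk step sizes for the latent
#' blocks (logit and log scales), and the half-widths of the symmetric,
#' edge-reflected integer windows used to propose new timescales.
#'
#' @param chains Number of chains (default 3).
#' @param burnin Burn-in sweeps per chain (default 10000).
#' @param iter Post-burn-in sweeps per chain (default 100000).
#' @param thin Keep every \code{thin}-th post-burn-in sweep (default 100);
#'   any remainder is dropped.
#' @param step_mu,step_phi M-H step SD for the latent logit-mean and
#'   log-dispersion blocks (default 0.3 each).
#' @param window_spei,window_spi Timescale proposal half-widths in grid steps
#'   (defaults 12 and 1).
#' @param adapt Adapt step sizes toward 0.44 acceptance during burn-in only
#'   (default \code{FALSE}; steps are frozen after burn-in either way).
#' @param store_latents Keep thinned draws of the per-observation latents
#'   (memory-heavy; default \code{FALSE}).
#' @param updates Named list of logical flags enabling individual update
#'   blocks; used to isolate blocks for validation. Defaults to all on.
#' @return Object of class \code{ts_control}.
#' @export
ts_control <- function(chains = 3, burnin = 10000, iter = 100000, thin = 100,
                       step_mu = 0.3, step_phi = 0.3,
                       window_spei = 12, window_spi = 1,
                       adapt = FALSE, store_latents = FALSE,
                       updates = list()) {
  if (chains < 1 || burnin < 0 || iter < 0 || thin < 1)
    stop("ts_control: counts must be positive (burnin/iter may be 0)")
  upd <- list(latent_mu = TRUE, latent_phi = TRUE, beta_mu = TRUE,
              gamma = TRUE, beta_phi = TRUE, eps = TRUE,
              precisions = TRUE, timescales = TRUE, interweave = TRUE)
  bad <- setdiff(names(updates), names(upd))
  if (length(bad)) stop("unknown update block(s): ", paste(bad, collapse = ", "))
  upd[names(updates)] <- updates
  structure(list(chains = as.integer(chains), burnin = as.integer(burnin),
                 iter = as.integer(iter), thin = as.integer(thin),
                 step_mu = step_mu, step_phi = step_phi,
                 window_spei = as.integer(window_spei),
                 window_spi = as.integer(window_spi),
                 adapt = adapt, store_latents = store_latents,
                 updates = upd),
            class = "ts_control")
}

SCALAR_PARAMS <- c("beta0", "beta_era", "beta_spei", "beta_spi",
                   "beta_spei_era", "beta_spei_spi", "beta_spei_spi_era",
                   "log_phi", "tau_gamma", "tau_delta", "tau_eps", "tau_zeta",
                   "t_spei_hist", "t_spei_cont", "t_spi")

# Default initial state: coefficients from OLS of logit(y) on the design at
# grid-midpoint timescales; wetland effects at 0; precisions at 1; latent
# logit-means at logit(y) (bounded away from 0/1) and latent log-dispersions
# jittered about the intercept, so the first precision updates see residual
# spreads of realistic magnitude rather than a degenerate zero.
default_init <- function(data, jitter_sd = 0) {
  Ks <- ncol(data$spei); Kp <- ncol(data$spi)
  t0 <- max(1L, Ks %/% 2L); p0 <- max(1L, Kp %/% 2L)
  yb <- pmin(pmax(data$y, 1e-5), 1 - 1e-5)
  X <- build_design_matrix(data, t0, t0, p0)
  beta <- tryCatch(stats::lm.fit(X, logit(yb))$coefficients,
                   error = function(e) rep(0, 7))
  beta[!is.finite(beta)] <- 0
  if (jitter_sd > 0) beta <- beta + stats::rnorm(7, 0, jitter_sd)
  bphi <- log(10) + if (jitter_sd > 0) stats::rnorm(1, 0, jitter_sd) else 0
  I <- length(data$wetland_id)
  N <- length(data$y)
  m <- rep(bphi, N)
  if (jitter_sd > 0) m <- m + stats::rnorm(N, 0, 1)
  l <- logit(yb)
  # ANOVA-style moment starts for the mean-model variance components, so no
  # chain starts deep in the precision/effect funnel
  r <- l - drop(X %*% beta)
  rbar <- tapply(r, data$wetland, mean)
  gamma <- as.numeric(rbar[as.character(seq_len(I))])
  gamma[is.na(gamma)] <- 0
  within <- stats::var(r - gamma[data$wetland])
  if (!is.finite(within)) within <- 1
  nbar <- N / I
  vg <- max(stats::var(gamma) - within / nbar, 0.01)
  if (!is.finite(vg)) vg <- 1
  list(beta = as.numeric(beta), bphi = bphi,
       gamma = gamma, eps = rep(0, I),
       l = l, m = m,
       tau_gamma = 1 / vg, tau_delta = 1 / max(within, 0.01),
       tau_eps = 1, tau_zeta = 1,
       t_hist = t0, t_cont = t0, t_spi = p0)
}

#' Run a single MCMC chain
#'
#' Low-level entry point used by \code{\link{timescale_betareg}}; runs one
#' chain of the hybrid sampler and returns its thinned draws.
#'
#' @param data A \code{\link{wetland_data}} object.
#' @param priors A \code{\link{ts_priors}} object.
#' @param control A \code{\link{ts_control}} object (\code{chains} ignored).
#' @param seed Integer seed; the chain is deterministic given it.
#' @param init Optional initial state (as \code{default_init}); when
#'   \code{NULL} a seed-jittered default is used.
#' @return List with matrix \code{draws} (kept sweeps x scalar parameters),
#'   matrices \code{gamma} and \code{eps} of wetland-effect draws, acceptance
#'   rates per block, and final step sizes.
#' @export
run_chain <- function(data, priors = ts_priors(), control = ts_control(),
                      seed = 1, init = NULL) {
  set.seed(seed)
  if (is.null(init)) init <- default_init(data, jitter_sd = 0.5)
  res <- run_chain_cpp(data$y, data$wetland - 1L, data$era,
                       data$spei, data$spi, init,
                       unclass(priors), unclass(control))
  colnames(res$draws) <- SCALAR_PARAMS
  colnames(res$gamma) <- data$wetland_id
  colnames(res$eps) <- data$wetland_id
  res
}

#' Fit the hierarchical beta regression with estimated timescales
#'
#' Fits the Bayesian beta regression for proportion responses in which the
#' SPEI timescale (one per era) and the SPI timescale are discrete unknowns,
#' by Gibbs-within-Metropolis MCMC over multiple chains.
#'
#' The mean model is \eqn{logit(\mu_{ij}) = X_{ij}\beta + \gamma_i +
#' \delta_{ij}} and the dispersion model \eqn{\log(\phi_{ij}) = \beta_\phi +
#' \epsilon_i + \zeta_{ij}}, with \eqn{y_{ij} \sim Beta(\mu\phi, (1-\mu)\phi)}
#' and normal random effects parameterized by precisions with gamma priors.
#'
#' @param data A \code{\link{wetland_data}} object.
#' @param priors A \code{\link{ts_priors}} object.
#' @param control A \code{\link{ts_control}} object.
#' @param seed Integer seed; chain c uses \code{seed + c - 1}.
#' @return Object of class \code{ts_betareg} with elements \code{draws}
#'   (combined matrix with \code{chain} and \code{iteration} columns),
#'   \code{gamma}, \code{eps} (wetland-effect draws), \code{acceptance},
#'   \code{data}, \code{priors}, \code{control}, \code{seed}.
#' @seealso \code{\link{summary.ts_betareg}}, \code{\link{predict.ts_betareg}},
#'   \code{\link{predictive_r2}}, \code{\link{weighted_index}}
#' @export
timescale_betareg <- function(data, priors = ts_priors(),
                              control = ts_control(), seed = 1) {
  stopifnot(inherits(data, "wetland_data"))
  chains <- lapply(seq_len(control$chains), function(c)
    run_chain(data, priors, control, seed = seed + c - 1))
  n_keep <- nrow(chains[[1]]$draws)
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  fit <- structure(list(
    draws = draws,
    chain = rep(seq_len(control$chains), each = n_keep),
    iteration = rep(seq_len(n_keep), control$chains),
    gamma = do.call(rbind, lapply(chains, `[[`, "gamma")),
    eps = do.call(rbind, lapply(chains, `[[`, "eps")),
    acceptance = lapply(chains, `[[`, "acceptance"),
    data = data, priors = priors, control = control, seed = seed,
    call = match.call()
  ), class = "ts_betareg")
  fit
}

#' @export
print.ts_betareg <- function(x, ...) {
  cat("Hierarchical beta regression with estimated drought-index timescales\n")
  cat("  observations:", length(x$data$y), " wetlands:",
      length(x$data$wetland_id), "\n")
  cat("  chains:", x$control$chains, " kept draws:", nrow(x$draws), "\n")
  mu <- colMeans(x$draws)
  cat("  posterior means:\n")
  print(round(mu, 3))
  invisible(x)
}

#' @export
coef.ts_betareg <- function(object, ...) {
  colMeans(object$draws[, 1:8])
}

# per-chain list of draw matrices for a fit
chain_split <- function(fit, what = "draws") {
  lapply(split(seq_len(nrow(fit[[what]])), fit$chain),
         function(i) fit[[what]][i, , drop = FALSE])
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic multi-chain convergence diagnostic: for each parameter, compares
#' the between-chain and within-chain variances,
#' \eqn{\hat R = \sqrt{((n-1)/n \, W + B/n) / W}}. Timescale parameters are
#' treated through their numeric values.
#'
#' @param x A \code{ts_betareg} fit, or a list of per-chain draw matrices
#'   with identical dimensions.
#' @return Named vector of \eqn{\hat R} values.
#' @export
gelman_rubin <- function(x) {
  if (inherits(x, "ts_betareg")) x <- chain_split(x)
  if (!is.list(x) || length(x) < 2)
    stop("gelman_rubin: at least 2 chains required")
  n <- nrow(x[[1]])
  if (n < 10) stop("gelman_rubin: at least 10 draws per chain required")
  sapply(seq_len(ncol(x[[1]])), function(j) {
    mns <- sapply(x, function(ch) mean(ch[, j]))
    vars <- sapply(x, function(ch) stats::var(ch[, j]))
    W <- mean(vars)
    B <- n * stats::var(mns)
    if (W == 0) return(if (B == 0) 1 else Inf)
    sqrt(((n - 1) / n * W + B / n) / W)
  }) |> stats::setNames(colnames(x[[1]]))
}
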