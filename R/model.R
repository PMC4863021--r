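#' Clamp an area ratio into the open unit interval
#'
#' The beta likelihood is undefined at 0 and 1; digitization error can push
#' observed water surface areas past the basin area. Ratios at or above 1 are
#' recoded to 0.99999 and ratios at or below 0 to 0.00001.
#'
#' @param area_ha Observed water surface area, ha (\code{>= 0}).
#' @param basin_ha Basin area, ha (\code{> 0}).
#' @return Numeric vector of proportions strictly inside (0, 1); the number
#'   of clamped records is attached as attribute \code{"n_clamped"}.
#' @export
clamp_proportion <- function(area_ha, basin_ha) {
  if (any(basin_ha <= 0)) stop("clamp_proportion: basin_ha must be > 0")
  r <- area_ha / basin_ha
  # the recode values act as floor and ceiling: ratios beyond them (including
  # ratios so close to 0 or 1 that the beta log-density underflows) are snapped
  hi <- r >= 0.99999
  lo <- r <= 1 - 0.99999
  r[hi] <- 0.99999
  r[lo] <- 1 - 0.99999
  structure(r, n_clamped = sum(hi | lo))
}

#' Beta log-density in mean/dispersion parameterization
#'
#' Log-density of \eqn{y \sim Beta(\mu\phi, (1-\mu)\phi)}, the likelihood of
#' the hierarchical beta regression.
#'
#' @param y Response in the open interval (0, 1).
#' @param mu Mean parameter in (0, 1).
#' @param phi Dispersion (precision) parameter, \code{> 0}.
#' @return Log-density (vectorised).
#' @export
beta_logpdf <- function(y, mu, phi) {
  if (any(y <= 0 | y >= 1))
    stop("beta_logpdf: y must be strictly inside (0, 1); clamp first")
  if (any(mu <= 0 | mu >= 1) || any(phi <= 0))
    stop("beta_logpdf: mu must be in (0, 1) and phi > 0")
  stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE)
}

logit <- function(p) log(p) - log1p(-p)
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Assemble a model-ready wetland dataset
#'
#' Joins each wetland-year observation to the drought-index bank at its site
#' and a fixed evaluation month, clamps the proportion response, and stores
#' per-observation index values at every candidate timescale so the sampler
#' can switch timescale without touching the bank again.
#'
#' @param obs Data frame with columns \code{wetland_id, site_id, year, era,
#'   area_ha, basin_ha} (\code{era} is 0 = historical, 1 = contemporary).
#' @param bank An \code{\link{build_index_bank}} object covering every
#'   observation's site and year.
#' @param month Calendar month at which the index is evaluated for each
#'   observation year (default 8, August).
#' @return An object of class \code{wetland_data}: list with the response
#'   \code{y}, integer wetland index \code{wetland} (1..I), \code{era},
#'   matrices \code{spei} (N x length of SPEI grid) and \code{spi}, the scale
#'   grids, and bookkeeping columns.
#' @export
wetland_data <- function(obs, bank, month = 8) {
  need <- c("wetland_id", "site_id", "year", "era", "area_ha", "basin_ha")
  miss <- setdiff(need, names(obs))
  if (length(miss))
    stop("observation table is missing column(s): ",
         paste(miss, collapse = ", "))
  if (!all(obs$era %in% c(0, 1))) stop("era must be 0 or 1")
  rows <- bank_rows(bank, obs$site_id, obs$year, month)
  if (anyNA(rows)) {
    bad <- which(is.na(rows))[1]
    stop("no bank entry for observation ", bad, " (wetland ",
         obs$wetland_id[bad], ", site ", obs$site_id[bad], ", year ",
         obs$year[bad], ", month ", month, ")")
  }
  spei <- bank$spei[rows, , drop = FALSE]
  spi <- bank$spi[rows, , drop = FALSE]
  if (anyNA(spei) || anyNA(spi)) {
    bad <- which(rowSums(is.na(spei)) + rowSums(is.na(spi)) > 0)[1]
    stop("undefined index value for observation ", bad, " (wetland ",
         obs$wetland_id[bad], ", year ", obs$year[bad],
         "): series too short at the largest timescale")
  }
  y <- clamp_proportion(obs$area_ha, obs$basin_ha)
  wid <- match(obs$wetland_id, unique(obs$wetland_id))
  structure(list(
    y = as.numeric(y),
    wetland = wid,
    wetland_id = unique(obs$wetland_id),
    era = as.integer(obs$era),
    year = obs$year,
    site_id = obs$site_id,
    spei = spei,
    spi = spi,
    spei_scales = bank$spei_scales,
    spi_scales = bank$spi_scales,
    month = month,
    n_clamped = attr(y, "n_clamped")
  ), class = "wetland_data")
}

#' @export
print.wetland_data <- function(x, ...) {
  cat("Wetland proportion dataset\n")
  cat("  observations:", length(x$y), " wetlands:", length(x$wetland_id), "\n")
  cat("  eras: historical", sum(x$era == 0), "/ contemporary",
      sum(x$era == 1), "\n")
  cat("  clamped records:", x$n_clamped, "\n")
  cat("  index grids: SPEI", length(x$spei_scales), "| SPI",
      length(x$spi_scales), " (evaluation month ", x$month, ")\n", sep = " ")
  invisible(x)
}

# column order of the mean-model design matrix
DESIGN_COLS <- c("intercept", "era", "spei", "spi", "spei_era", "spei_spi",
                 "spei_spi_era")

#' Mean-model design matrix at given timescales
#'
#' Builds the 7-column design matrix (intercept, era, SPEI, SPI, SPEI x era,
#' SPEI x SPI, SPEI x SPI x era). The SPEI column of an observation uses the
#' historical timescale when era = 0 and the contemporary timescale when
#' era = 1; SPI uses a single timescale shared between eras. Timescales are
#' positions in the dataset's scale grids.
#'
#' @param data A \code{\link{wetland_data}} object.
#' @param t_hist,t_cont Index (1-based) into the SPEI scale grid for the
#'   historical and contemporary eras.
#' @param t_spi Index into the SPI scale grid.
#' @return Numeric matrix N x 7 with column names \code{DESIGN_COLS}.
#' @export
build_design_matrix <- function(data, t_hist, t_cont, t_spi) {
  Ks <- ncol(data$spei); Kp <- ncol(data$spi)
  if (t_hist < 1 || t_hist > Ks || t_cont < 1 || t_cont > Ks)
    stop("SPEI timescale index out of 1..", Ks)
  if (t_spi < 1 || t_spi > Kp) stop("SPI timescale index out of 1..", Kp)
  s <- ifelse(data$era == 0, data$spei[, t_hist], data$spei[, t_cont])
  p <- data$spi[, t_spi]
  e <- data$era
  X <- cbind(1, e, s, p, s * e, s * p, s * p * e)
  colnames(X) <- DESIGN_COLS
  X
}

#' Prior specification for the hierarchical beta regression
#'
#' @param beta_mean,beta_precision Normal prior mean and precision for each
#'   of the 7 mean-model coefficients (recycled).
#' @param bphi_mean,bphi_precision Normal prior for the dispersion intercept
#'   (log scale).
#' @param tau_shape,tau_rate Gamma hyperparameters shared by all four
#'   precision terms.
#' @return Object of class \code{ts_priors}.
#' @export
ts_priors <- function(beta_mean = 0, beta_precision = 1e-6,
                      bphi_mean = 0, bphi_precision = 1e-6,
                      tau_shape = 0.001, tau_rate = 0.001) {
  if (any(beta_precision <= 0) || bphi_precision <= 0 ||
      tau_shape <= 0 || tau_rate <= 0)
    stop("precisions and gamma hyperparameters must be > 0")
  structure(list(
    beta_mean = rep_len(beta_mean, 7),
    beta_precision = rep_len(beta_precision, 7),
    bphi_mean = bphi_mean, bphi_precision = bphi_precision,
    tau_shape = tau_shape, tau_rate = tau_rate
  ), class = "ts_priors")
}

#' Unnormalized log posterior density of a full model state
#'
#' Sum of the beta log-likelihood, the normal densities of all random-effect
#' and residual terms at their precisions, the normal priors on the regression
#' coefficients, the gamma priors on the precisions, and the (uniform)
#' categorical prior mass of the three timescales.
#'
#' @param state Named list with elements \code{beta} (7-vector), \code{bphi},
#'   \code{gamma}, \code{eps} (per wetland), \code{l}, \code{m} (per
#'   observation, logit-mean and log-dispersion latents), \code{tau_gamma,
#'   tau_delta, tau_eps, tau_zeta}, and timescale indices \code{t_hist,
#'   t_cont, t_spi}.
#' @param data A \code{\link{wetland_data}} object.
#' @param priors A \code{\link{ts_priors}} object.
#' @return Scalar log density (unnormalized).
#' @export
log_joint <- function(state, data, priors = ts_priors()) {
  with(state, {
    if (any(c(tau_gamma, tau_delta, tau_eps, tau_zeta) <= 0))
      stop("log_joint: precisions must be > 0")
    X <- build_design_matrix(data, t_hist, t_cont, t_spi)
    eta_mu <- drop(X %*% beta) + gamma[data$wetland]
    eta_phi <- bphi + eps[data$wetland]
    mu <- inv_logit(l)
    phi <- exp(m)
    ll <- sum(beta_logpdf(data$y, mu, phi))
    ld <- sum(stats::dnorm(l, eta_mu, 1 / sqrt(tau_delta), log = TRUE))
    lz <- sum(stats::dnorm(m, eta_phi, 1 / sqrt(tau_zeta), log = TRUE))
    lg <- sum(stats::dnorm(gamma, 0, 1 / sqrt(tau_gamma), log = TRUE))
    le <- sum(stats::dnorm(eps, 0, 1 / sqrt(tau_eps), log = TRUE))
    pb <- sum(stats::dnorm(beta, priors$beta_mean,
                           1 / sqrt(priors$beta_precision), log = TRUE))
    pp <- stats::dnorm(bphi, priors$bphi_mean,
                       1 / sqrt(priors$bphi_precision), log = TRUE)
    pt <- sum(stats::dgamma(c(tau_gamma, tau_delta, tau_eps, tau_zeta),
                            shape = priors$tau_shape, rate = priors$tau_rate,
                            log = TRUE))
    ptime <- -log(ncol(data$spei)) * 2 - log(ncol(data$spi))
    ll + ld + lz + lg + le + pb + pp + pt + ptime
  })
}
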