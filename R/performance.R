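# Analytic performance model and nonlinear regression with AICc model
# selection over the compass-specific parameters (g, b0, s, rho).

#' Expected number of flight-steps under heading error
#'
#' Expected southward progress per step scales with the mean resultant
#' length, so the expected step count inflates by its inverse:
#' \eqn{\hat N = N_0\, I_0(\kappa)/I_1(\kappa)}.
#'
#' @param N0 error-free (minimum) number of steps (>= 1).
#' @param kappa_step per-flight-step von Mises concentration (> 0).
#' @return expected number of steps; diverges (with a warning) as
#'   \eqn{\kappa \to 0}.
#' @export
expected_steps <- function(N0, kappa_step) {
  if (any(N0 < 1)) stop("`N0` must be >= 1")
  if (any(kappa_step <= 0)) stop("`kappa_step` must be > 0")
  r <- circular_length(kappa_step)
  if (any(r < 1e-3)) warning("kappa_step near 0: expected step count diverges")
  N0 / r
}

# error function via the normal cdf
.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Planar-normal arrival probability
#'
#' First approximation of arrival probability on a plane: the route-mean
#' heading of \eqn{\hat N} steps with per-step deviation
#' \eqn{\sigma_{step}} falls within the goal breadth \eqn{\beta}:
#' \deqn{p \approx \mathrm{erf}\!\left(\frac{\beta}
#'   {\sqrt{2}\,\sigma_{step}/\sqrt{\hat N}}\right).}
#'
#' @param beta goal breadth in radians.
#' @param sigma_step_deg per-step deviation in degrees.
#' @param n_hat expected number of steps.
#' @return probability in (0, 1]; 1 in the deterministic limit.
#' @export
performance_normal <- function(beta, sigma_step_deg, n_hat) {
  if (any(beta <= 0) || any(n_hat < 1)) stop("need beta > 0 and n_hat >= 1")
  if (any(sigma_step_deg < 0)) stop("sigma must be >= 0")
  ifelse(sigma_step_deg == 0, 1,
         .erf(beta / (sqrt(2) * .rad(sigma_step_deg) / sqrt(n_hat))))
}

#' Generalized many-wrongs exponent
#'
#' Generalizes the normal \eqn{1/\hat N^{0.5}} convergence of route-mean
#' headings to
#' \deqn{\eta(\sigma_{step} \mid s, b) = (0.5 + b)\,e^{-s\sigma_{step}^2},}
#' with \eqn{b = b_0 R'^{\rho}_{step}} (flight-step distance scaled by its
#' median among species; \eqn{\rho} applies to TCSC courses only).
#' Positive \eqn{b} reflects self-correction, negative \eqn{b} iterative
#' error augmentation, and \eqn{s} damps convergence as precision degrades
#' (consistent with the circular-uniform limit where no timely convergence
#' occurs).
#'
#' @param sigma_step_deg per-step deviation (degrees).
#' @param s damping exponent (>= 0); sigma enters in radians.
#' @param b0 baseline offset to the 0.5 exponent.
#' @param r_step_scaled flight-step distance scaled by the species-set
#'   median (dimensionless, default 1).
#' @param rho flight-step-distance modulation (TCSC only; default 0).
#' @return the exponent \eqn{\eta}.
#' @export
eta_exponent <- function(sigma_step_deg, s = 0, b0 = 0,
                         r_step_scaled = 1, rho = 0) {
  (0.5 + b0 * r_step_scaled^rho) * exp(-s * .rad(sigma_step_deg)^2)
}

#' Probability of timely arrival at the goal latitude
#'
#' Central-limit bound on reaching the goal latitude within the seasonal
#' step budget: total southward progress of \eqn{N_{max}} steps (mean
#' per-step projection \eqn{\cos\bar\alpha\, I_1/I_0}, per-step dispersion
#' [cosine_dispersion()]) must reach the error-free requirement:
#' \deqn{p \approx \tfrac12\left[1 - \mathrm{erf}\!\left(
#'   \left(\frac{N_0}{N_{max}} - \frac{I_1(\kappa)}{I_0(\kappa)}\right)
#'   \frac{\cos\bar\alpha\,\sqrt{N_{max}}}{\sigma_C\sqrt{2}}\right)\right].}
#'
#' @param N0,N_max error-free and maximum step counts (`N_max >= N0`).
#' @param kappa_step per-step concentration.
#' @param mean_heading_deg route-mean heading (degrees from South).
#' @return probability in (0, 1).
#' @export
timely_arrival <- function(N0, N_max, kappa_step, mean_heading_deg = 0) {
  if (any(N_max < N0)) stop("`N_max` must be >= `N0`")
  if (any(is.infinite(kappa_step))) {
    return(rep_len(1, max(length(N0), length(kappa_step))))
  }
  r1 <- circular_length(kappa_step)
  sC <- cosine_dispersion(kappa_step)
  z <- (N0 / N_max - r1) * cos(.rad(mean_heading_deg)) * sqrt(N_max) /
    (sC * sqrt(2))
  0.5 * (1 - .erf(z))
}

#' Performance parameters of the generalized model
#'
#' @param g spherical-geometry exponent (null 1).
#' @param b0 many-wrongs baseline offset (null 0).
#' @param s damping exponent (null 0).
#' @param rho flight-step-distance modulation, TCSC only (null 0).
#' @return list of class `performance_params`.
#' @export
performance_params <- function(g = 1, b0 = 0, s = 0, rho = 0) {
  structure(list(g = g, b0 = b0, s = s, rho = rho),
            class = "performance_params")
}

#' Full analytic migratory performance
#'
#' The product of the precision term -- the generalized spherical-geometry
#' arrival probability
#' \deqn{\mathrm{erf}\!\left(\frac{\beta_A}
#'  {G^g\sqrt{2\left(\sigma_{ind}^2 + (\sigma_{step}/\hat N^{\eta})^2\right)}}
#'  \right)}
#' -- and the timely-arrival probability ([timely_arrival()]). With null
#' parameters, a North-South route (G = 1), and no individual variability
#' this reduces to the planar-normal approximation.
#'
#' @param beta_A arrival-adjusted goal breadth (radians), see
#'   [goal_breadths()].
#' @param G spherical-geometry factor.
#' @param N0,N_max step counts.
#' @param sigma_step_deg per-step deviation (deg).
#' @param sigma_ind_deg between-individual deviation (deg).
#' @param mean_heading_deg route-mean heading (deg from South).
#' @param params a [performance_params()].
#' @param r_step_scaled scaled flight-step distance (for rho).
#' @return arrival probability in [0, 1].
#' @export
performance_full <- function(beta_A, G, N0, N_max, sigma_step_deg,
                             sigma_ind_deg = 0, mean_heading_deg = 0,
                             params = performance_params(),
                             r_step_scaled = 1) {
  zero <- sigma_step_deg <= 0
  sigma_step_deg <- ifelse(zero, 1e-6, sigma_step_deg)
  kappa <- 1 / .rad(sigma_step_deg)^2
  n_hat <- expected_steps(N0, kappa)
  eta <- eta_exponent(sigma_step_deg, params$s, params$b0, r_step_scaled,
                      params$rho)
  s_eff <- sqrt(.rad(sigma_ind_deg)^2 + (.rad(sigma_step_deg) / n_hat^eta)^2)
  p_prec <- .erf(beta_A / (G^params$g * sqrt(2) * s_eff))
  p_time <- timely_arrival(N0, N_max, kappa, mean_heading_deg)
  p <- pmin(1, pmax(0, p_prec * p_time))
  p[zero] <- 1
  p
}

# ---- regression with AICc model selection ----------------------------------

# prediction over an observation table for a parameter vector
.predict_perf <- function(obs, g, b0, s, rho) {
  pp <- performance_params(g, b0, s, rho)
  performance_full(obs$beta_A, obs$G, obs$N0, obs$N_max, obs$sigma_step_deg,
                   obs$sigma_ind_deg, obs$mean_heading_deg, pp,
                   obs$r_step_scaled)
}

.aicc <- function(rss, n, k) {
  # Gaussian RSS likelihood; k fitted coefficients + 1 variance parameter
  kk <- k + 1
  n * log(rss / n) + 2 * kk + 2 * kk * (kk + 1) / (n - kk - 1)
}

#' Fit the performance model with AICc model selection
#'
#' Nonlinear least squares (Levenberg-Marquardt via \pkg{minpack.lm}) of
#' the full analytic performance model to observed (typically simulated)
#' arrival fractions across species and error scenarios, for every subset
#' of the parameters \{g, b0, s\} (plus rho for TCSC courses); parameters
#' outside a subset are pinned at their null values (g = 1, b0 = s = rho =
#' 0). The most parsimonious subset minimizes the small-sample-corrected
#' Akaike information criterion (AICc).
#'
#' @param obs data frame with columns `species`, `sigma_step_deg`,
#'   `performance`, `beta_A`, `G`, `N0`, `N_max`, and optionally
#'   `sigma_ind_deg` (default 0), `mean_heading_deg` (default 0),
#'   `r_step_scaled` (default 1). Needs at least 2 species x 3 scenarios.
#' @param course_type the fitted course; `rho` is only considered for
#'   `"tcsc"`.
#' @return object of class `performance_fit`: `params` (selected
#'   [performance_params()]), `estimates` (with standard errors),
#'   `selected` (names of the free parameters), `aicc_table`, `adj_r2`.
#' @export
fit_performance <- function(obs, course_type = "geographic_lox") {
  req <- c("sigma_step_deg", "performance", "beta_A", "G", "N0", "N_max")
  miss <- setdiff(req, names(obs))
  if (length(miss)) stop("`obs` lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(obs$sigma_ind_deg)) obs$sigma_ind_deg <- 0
  if (is.null(obs$mean_heading_deg)) obs$mean_heading_deg <- 0
  if (is.null(obs$r_step_scaled)) obs$r_step_scaled <- 1
  if (!is.null(obs$species) &&
      (length(unique(obs$species)) < 2 ||
       length(unique(obs$sigma_step_deg)) < 3)) {
    stop("need at least 2 species and 3 error scenarios")
  }
  cand <- c("g", "b0", "s", if (course_type == "tcsc") "rho")
  null_vals <- c(g = 1, b0 = 0, s = 0, rho = 0)
  start_vals <- c(g = 1.2, b0 = 0.1, s = 1, rho = 0.5)
  lower <- c(g = 0, b0 = -0.49, s = 0, rho = -5)
  upper <- c(g = 10, b0 = 5, s = 50, rho = 5)
  nobs <- nrow(obs)

  subsets <- unlist(lapply(0:length(cand), function(k) {
    utils::combn(cand, k, simplify = FALSE)
  }), recursive = FALSE)

  rows <- list(); fits <- list()
  for (ss in subsets) {
    label <- if (length(ss)) paste(ss, collapse = "+") else "(null)"
    par <- null_vals
    resid_fun <- function(theta) {
      par[ss] <- theta
      obs$performance - .predict_perf(obs, par["g"], par["b0"], par["s"], par["rho"])
    }
    if (length(ss)) {
      fit <- tryCatch(
        minpack.lm::nls.lm(start_vals[ss], lower = lower[ss], upper = upper[ss],
                           fn = resid_fun,
                           control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL
      )
      if (is.null(fit) || !fit$info %in% 1:4) {
        warning("subset ", label, " did not converge; excluded from selection")
        rows[[label]] <- data.frame(subset = label, k = length(ss),
                                    rss = NA, aicc = NA)
        next
      }
      par[ss] <- fit$par
      rss <- sum(fit$fvec^2)
      se <- tryCatch(sqrt(diag(solve(fit$hessian)) * rss / (nobs - length(ss))),
                     error = function(e) rep(NA_real_, length(ss)))
    } else {
      rss <- sum(resid_fun(numeric(0))^2)
      se <- numeric(0); fit <- NULL
    }
    rows[[label]] <- data.frame(subset = label, k = length(ss), rss = rss,
                                aicc = .aicc(rss, nobs, length(ss)))
    fits[[label]] <- list(par = par, se = stats::setNames(se, ss), subset = ss,
                          rss = rss)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$aicc), ]
  best <- fits[[tab$subset[1]]]
  p <- length(best$subset)
  tss <- sum((obs$performance - mean(obs$performance))^2)
  adj_r2 <- 1 - (best$rss / (nobs - p - 1)) / (tss / (nobs - 1))
  structure(list(
    params = performance_params(best$par[["g"]], best$par[["b0"]],
                                best$par[["s"]], best$par[["rho"]]),
    estimates = data.frame(parameter = names(best$par),
                           estimate = unname(best$par),
                           se = unname(best$se[names(best$par)]),
                           free = names(best$par) %in% best$subset),
    selected = best$subset,
    aicc_table = tab, adj_r2 = adj_r2, n = nobs, course_type = course_type
  ), class = "performance_fit")
}

#' @export
print.performance_fit <- function(x, ...) {
  cat(sprintf("<performance_fit> %s: selected {%s}, adj R^2 = %.3f (n = %d)\n",
              x$course_type,
              if (length(x$selected)) paste(x$selected, collapse = ", ") else "null",
              x$adj_r2, x$n))
  print(x$estimates, row.names = FALSE)
  invisible(x)
}

#' Generate observations from the analytic performance model
#'
#' Builds a (species x error-scenario) observation table by evaluating the
#' full analytic model at known parameters, optionally adding Gaussian
#' noise -- the parameter-recovery harness for [fit_performance()].
#'
#' @param routes data frame with columns `species`, `beta_A`, `G`, `N0`,
#'   `N_max` and optionally `mean_heading_deg`, `r_step_scaled`.
#' @param sigmas_deg error scenarios (per-step deviations, degrees).
#' @param params generating [performance_params()].
#' @param noise_sd Gaussian noise standard deviation on the probabilities.
#' @return observation data frame suitable for [fit_performance()].
#' @export
synthetic_performance_obs <- function(routes, sigmas_deg,
                                      params = performance_params(),
                                      noise_sd = 0) {
  obs <- merge(routes, data.frame(sigma_step_deg = sigmas_deg))
  if (is.null(obs$mean_heading_deg)) obs$mean_heading_deg <- 0
  if (is.null(obs$r_step_scaled)) obs$r_step_scaled <- 1
  obs$sigma_ind_deg <- 0
  obs$performance <- .predict_perf(obs, params$g, params$b0, params$s,
                                   params$rho)
  if (noise_sd > 0) {
    obs$performance <- pmin(1, pmax(0, obs$performance +
                                      stats::rnorm(nrow(obs), 0, noise_sd)))
  }
  obs
}
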