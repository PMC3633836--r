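#' Gompertz growth law
#'
#' \eqn{V(t) = V(0)\exp(\alpha/\beta\,(1 - e^{-\beta t}))}: saturating tumor
#' growth with initial specific growth rate \eqn{\alpha} (per day), decay of
#' that rate \eqn{\beta} (per day), and plateau \eqn{V(0)e^{\alpha/\beta}}.
#' The \eqn{\beta = 0} degenerate case is handled as its limit, exponent
#' \eqn{\alpha t} (pure exponential growth).
#'
#' @param t time (days), vectorized, `t >= 0`.
#' @param v0 initial volume V(0).
#' @param alpha,beta Gompertz rate constants (per day).
#' @return volume(s) at `t`.
#' @export
gompertz_volume <- function(t, v0, alpha, beta) {
  stopifnot(all(t >= 0), v0 > 0)
  expo <- if (beta == 0) alpha * t else (alpha / beta) * (1 - exp(-beta * t))
  v0 * exp(expo)
}

#' Fit the Gompertz growth law to a volume time series
#'
#' Nonlinear least squares of the Gompertz law. By default the fit is on
#' log-volumes (Gaussian errors on log V, i.e. multiplicative lognormal
#' noise on V) because spheroid volumes span orders of magnitude and
#' measurement error scales with size; `log_scale = FALSE` fits raw volumes.
#' Replicate observations may simply be pooled (repeated `times` entries).
#'
#' Initialization: `V0` from the earliest observations, `beta` as the
#' reciprocal time range, `alpha` from the overall log-fold change; all
#' parameters bounded below at 1e-12. Levenberg–Marquardt, parameter
#' tolerance 1e-10, up to 10000 evaluations.
#'
#' The plateau \eqn{V(0)e^{\alpha/\beta}} is reported with a delta-method
#' standard error from the fit's covariance.
#'
#' @param times observation days (>= 4 distinct values).
#' @param volumes observed volumes, positive, same length.
#' @param log_scale fit on log(V) (default) or raw V.
#' @return `gompertz_fit`: list with `params` (named `v0`, `alpha`, `beta`),
#'   `plateau`, `plateau_se`, `residuals` (on the fitted scale), `rss`,
#'   `converged`, and `fitted`, a function of t.
#' @export
fit_gompertz <- function(times, volumes, log_scale = TRUE) {
  stopifnot(length(times) == length(volumes))
  if (length(unique(times)) < 4L) {
    stop("need at least 4 distinct timepoints", call. = FALSE)
  }
  if (any(!is.finite(volumes)) || any(volumes <= 0)) {
    stop("volumes must be positive and finite", call. = FALSE)
  }
  t0 <- min(times)
  v_first <- mean(volumes[times == t0])
  v_last <- mean(volumes[times == max(times)])
  beta0 <- 1 / max(diff(range(times)), 1e-6)
  alpha0 <- max(beta0 * (log(v_last) - log(v_first)), 1e-6)
  start <- c(lv0 = log(v_first), alpha = alpha0, beta = beta0)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 10000,
                                     ptol = 1e-10, ftol = 1e-14)
  lv <- log(volumes)
  resid_fn <- function(p) {
    pred <- p[1] + (p[2] / p[3]) * (1 - exp(-p[3] * times))
    if (log_scale) lv - pred else volumes - exp(pred)
  }
  fit <- minpack.lm::nls.lm(
    par = start, fn = resid_fn,
    lower = c(lv0 = -Inf, alpha = 1e-12, beta = 1e-12),
    control = ctrl)
  if (!(fit$info %in% 1:4)) {
    stop(sprintf(
      "Gompertz fit did not converge (start lv0=%.4g alpha=%.4g beta=%.4g; %d iterations): %s",
      start[1], start[2], start[3], fit$niter, fit$message), call. = FALSE)
  }
  cf <- fit$par
  v0 <- exp(cf[["lv0"]]); alpha <- cf[["alpha"]]; beta <- cf[["beta"]]
  plateau <- v0 * exp(alpha / beta)
  # delta method on (lv0, alpha, beta): log plateau = lv0 + alpha/beta
  grad <- plateau * c(1, 1 / beta, -alpha / beta^2)
  dof <- length(times) - 3L
  sigma2 <- if (dof > 0) fit$deviance / dof else NA_real_
  vc <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  plateau_se <- if (is.null(vc) || any(!is.finite(vc))) NA_real_ else {
    se2 <- drop(t(grad) %*% vc %*% grad)
    if (se2 >= 0) sqrt(se2) else NA_real_
  }
  structure(list(params = c(v0 = v0, alpha = alpha, beta = beta),
                 plateau = plateau,
                 plateau_se = plateau_se,
                 residuals = as.numeric(fit$fvec),
                 rss = fit$deviance,
                 converged = TRUE,
                 log_scale = log_scale,
                 fitted = function(t) gompertz_volume(t, v0, alpha, beta)),
            class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("<gompertz_fit> V0 = %.4g, alpha = %.4g/day, beta = %.4g/day; plateau = %.4g (SE %.3g); RSS %.3g (%s scale)\n",
              p["v0"], p["alpha"], p["beta"], x$plateau, x$plateau_se,
              x$rss, if (x$log_scale) "log" else "raw"))
  invisible(x)
}

#' Per-timepoint replicate summary of growth series
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' replicate volumes at each shared timepoint — the "mean volume of n
#' spheroids +/- SD" summary. A timepoint with a single replicate gets
#' `sd_volume = NA`.
#'
#' @param growth data.frame with columns `replicate`, `day`, `volume_um3`
#'   (extra columns such as `arm` are allowed and ignored); replicates must
#'   share a common time grid.
#' @return data.frame with columns `day`, `mean_volume`, `sd_volume`, `n`.
#' @export
summarize_growth <- function(growth) {
  need <- c("replicate", "day", "volume_um3")
  miss <- setdiff(need, names(growth))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  grids <- split(growth$day, growth$replicate)
  common <- sort(unique(growth$day))
  same <- all(vapply(grids, function(g) identical(sort(unique(g)), common),
                     logical(1)))
  if (!same) stop("replicates do not share a common time grid", call. = FALSE)
  out <- do.call(rbind, lapply(common, function(d) {
    v <- growth$volume_um3[growth$day == d]
    data.frame(day = d, mean_volume = mean(v),
               sd_volume = if (length(v) > 1) sd(v) else NA_real_,
               n = length(v))
  }))
  rownames(out) <- NULL
  out
}

#' Compare two treatment arms at a timepoint
#'
#' Two-sided Welch's t-test on the replicate volumes of two arms at one
#' timepoint (unequal variances assumed; no multiplicity correction by
#' default). Arms may be given as bare numeric vectors of volumes, or as
#' growth data.frames together with `timepoint`. Degenerate zero-variance
#' data (all volumes identical within each arm) is handled directly:
#' equal means give statistic 0 and p = 1, unequal means give p = 0.
#'
#' @param arm_a,arm_b numeric volumes, or data.frames with `day` and
#'   `volume_um3` columns.
#' @param timepoint day at which to compare (required for data.frame input).
#' @return list with `statistic` (Welch t), `p_value`, `df`, `n_a`, `n_b`.
#' @export
compare_arms <- function(arm_a, arm_b, timepoint = NULL) {
  pick <- function(x) {
    if (is.data.frame(x)) {
      if (is.null(timepoint)) stop("`timepoint` required for data.frame arms",
                                   call. = FALSE)
      x$volume_um3[x$day == timepoint]
    } else as.numeric(x)
  }
  a <- pick(arm_a); b <- pick(arm_b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least 2 replicates per arm", call. = FALSE)
  }
  if (sd(a) == 0 && sd(b) == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(statistic = if (equal) 0 else Inf * sign(mean(a) - mean(b)),
                p_value = if (equal) 1 else 0,
                df = NA_real_, n_a = length(a), n_b = length(b)))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), n_a = length(a), n_b = length(b))
}
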