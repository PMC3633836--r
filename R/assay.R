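#' Normalize viability from APH plate absorbances
#'
#' The acid-phosphatase assay normalization
#' \deqn{\%\,viability = 100\,\frac{A_{treatment} - A_{media}}{A_{control} - A_{media}}}
#' where each A is a mean absorbance at 405 nm. Values outside \[0, 100\]
#' are returned as-is (they carry information about outliers or stimulated
#' wells); callers may flag them downstream.
#'
#' @param a_treatment treated-well absorbance (vectorized).
#' @param a_control untreated control absorbance.
#' @param a_media cell-free media blank absorbance.
#' @return percent viability (same length as `a_treatment`).
#' @export
normalize_viability <- function(a_treatment, a_control, a_media) {
  if (any(a_control <= a_media)) {
    stop("invalid plate: A_control must exceed A_media", call. = FALSE)
  }
  100 * (a_treatment - a_media) / (a_control - a_media)
}

#' Hill viability curve
#'
#' Four-parameter logistic with the top plateau fixed at 100% (data are
#' normalized to untreated controls):
#' \deqn{v(C) = bottom + \frac{100 - bottom}{1 + (C/x_{50})^{h}}}
#' `x50` is the curve midpoint; the absolute IC50 (v = 50) is
#' \eqn{x_{50}\,(50/(50 - bottom))^{1/h}} and exists only when
#' `bottom < 50`.
#'
#' @param concentration drug concentration (ng/mL), vectorized; 0 allowed
#'   (gives the top plateau).
#' @param x50 midpoint concentration (> 0).
#' @param hill_slope Hill coefficient h (> 0).
#' @param bottom lower plateau, percent, in \[0, 100).
#' @return percent viability.
#' @export
hill_viability <- function(concentration, x50, hill_slope = 1, bottom = 0) {
  stopifnot(x50 > 0, hill_slope > 0, bottom >= 0, bottom < 100)
  bottom + (100 - bottom) / (1 + (concentration / x50)^hill_slope)
}

#' Fit the Hill equation to dose-response viability data
#'
#' Least-squares fit of [hill_viability()] on log10 concentration with the
#' top fixed at 100%, `bottom` free in \[0, 100) and `hill_slope` free > 0.
#' Individual wells should be passed directly (not per-concentration means).
#'
#' The reported `ic50` is the absolute IC50 — the concentration where the
#' fitted curve crosses 50% viability — not the curve midpoint. When the
#' fitted curve never reaches 50% within the tested concentration range
#' (e.g. resistant spheroids whose viability plateaus above 50%),
#' `ic50_reached` is `FALSE` and `ic50` is `NA` with the maximum tested
#' concentration recorded, to be reported as "> max tested".
#'
#' @param concentrations positive drug concentrations (ng/mL), >= 4
#'   distinct values.
#' @param viabilities percent viabilities, same length.
#' @return `hill_fit`: list with `ic50`, `ic50_reached`, `x50` (midpoint),
#'   `hill_slope`, `bottom`, `top` (100), `max_tested`, `rss`, `vcov`
#'   (parameter covariance for `log10_x50`, `hill_slope`, `bottom`), and
#'   `fitted`, a function of concentration.
#' @export
fit_hill <- function(concentrations, viabilities) {
  stopifnot(length(concentrations) == length(viabilities))
  if (any(concentrations <= 0)) {
    stop("concentrations must be positive (baseline wells enter via normalization, not the fit)",
         call. = FALSE)
  }
  if (length(unique(concentrations)) < 4L) {
    stop("need at least 4 distinct concentrations", call. = FALSE)
  }
  if (any(!is.finite(viabilities))) stop("viabilities must be finite",
                                         call. = FALSE)
  if (diff(range(viabilities)) < sqrt(.Machine$double.eps)) {
    stop("no response: all viabilities identical", call. = FALSE)
  }
  df <- data.frame(lc = log10(concentrations), v = viabilities)
  # start near the concentration whose mean viability is closest to midway
  agg <- vapply(split(df$v, df$lc), mean, numeric(1))
  bottom0 <- min(max(min(agg), 0), 99)
  mid <- bottom0 + (100 - bottom0) / 2
  l50_0 <- as.numeric(names(agg))[which.min(abs(agg - mid))]
  ctrl <- minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 10000,
                                     ptol = 1e-10, ftol = 1e-14)
  resid_fn <- function(p) {
    df$v - (p[3] + (100 - p[3]) / (1 + 10^(p[2] * (df$lc - p[1]))))
  }
  fit <- minpack.lm::nls.lm(
    par = c(l50 = l50_0, h = 1, bottom = bottom0),
    fn = resid_fn,
    lower = c(l50 = -30, h = 1e-6, bottom = 0),
    upper = c(l50 = 30, h = 50, bottom = 99.999),
    control = ctrl)
  if (!(fit$info %in% 1:4)) {
    stop("Hill fit did not converge: ", fit$message, call. = FALSE)
  }
  cf <- fit$par
  x50 <- 10^cf[["l50"]]; h <- cf[["h"]]; bottom <- cf[["bottom"]]
  max_tested <- max(concentrations)
  ic50 <- if (bottom < 50) x50 * (50 / (50 - bottom))^(1 / h) else NA_real_
  reached <- is.finite(ic50) && ic50 <= max_tested
  dof <- nrow(df) - 3L
  sigma2 <- if (dof > 0) fit$deviance / dof else NA_real_
  vc <- tryCatch(sigma2 * solve(fit$hessian),
                 error = function(e) matrix(NA_real_, 3, 3))
  dimnames(vc) <- list(c("log10_x50", "hill_slope", "bottom"),
                       c("log10_x50", "hill_slope", "bottom"))
  structure(list(ic50 = if (reached) ic50 else NA_real_,
                 ic50_reached = reached,
                 ic50_crossing = ic50,  # may exceed max_tested
                 x50 = x50, hill_slope = h, bottom = bottom, top = 100,
                 max_tested = max_tested,
                 rss = fit$deviance,
                 vcov = vc,
                 fitted = function(concentration)
                   hill_viability(concentration, x50, h, bottom)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  ic <- if (x$ic50_reached) sprintf("%.4g ng/mL", x$ic50)
        else sprintf("> %g ng/mL (not reached)", x$max_tested)
  cat(sprintf("<hill_fit> IC50 = %s; midpoint %.4g, slope %.3g, bottom %.1f%%\n",
              ic, x$x50, x$hill_slope, x$bottom))
  invisible(x)
}

#' Plating efficiency of an untreated clonogenic control
#'
#' Colonies formed divided by cells plated for untreated controls. Zero
#' colonies gives 0 with a warning, since the downstream surviving fraction
#' is then undefined.
#'
#' @param colonies colony count (colonies of at least 50 cells).
#' @param cells_plated cells plated (> 0).
#' @return plating efficiency, a fraction.
#' @export
plating_efficiency <- function(colonies, cells_plated) {
  stopifnot(cells_plated > 0, colonies >= 0, colonies <= cells_plated)
  if (colonies == 0) {
    warning("plating efficiency is 0; surviving fractions will be undefined")
  }
  colonies / cells_plated
}

#' Surviving fraction after treatment
#'
#' Colonies divided by the product of cells plated and the plating
#' efficiency of the untreated control.
#'
#' @param colonies treated-condition colony count.
#' @param cells_plated cells plated in the treated condition.
#' @param pe plating efficiency from [plating_efficiency()] (> 0).
#' @return surviving fraction.
#' @export
surviving_fraction <- function(colonies, cells_plated, pe) {
  stopifnot(cells_plated > 0, colonies >= 0)
  if (pe <= 0) stop("surviving fraction undefined: plating efficiency is 0",
                    call. = FALSE)
  colonies / (cells_plated * pe)
}

#' APH assay linearity validation
#'
#' Ordinary least squares of absorbance on cell number; the assay is valid
#' when absorbance grows linearly with viable cell number (R-squared at or
#' above the cutoff). Saturating readouts fail this check.
#'
#' @param cell_numbers cell counts (n >= 3).
#' @param absorbances matching absorbances at 405 nm.
#' @param r2_cutoff minimum R-squared to pass (default 0.95).
#' @return list with `slope`, `intercept`, `r_squared`, `passed`.
#' @export
aph_linearity <- function(cell_numbers, absorbances, r2_cutoff = 0.95) {
  stopifnot(length(cell_numbers) == length(absorbances))
  if (length(cell_numbers) < 3L) stop("need at least 3 points", call. = FALSE)
  fit <- lm(absorbances ~ cell_numbers)
  r2 <- summary(fit)$r.squared
  list(slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r_squared = r2,
       passed = r2 >= r2_cutoff)
}

#' Cumulative release fraction at a time
#'
#' Linear interpolation of a cumulative release profile at time `t` — the
#' "fraction released by t hours" summary of a dialysis release experiment.
#' Extrapolation outside the sampled range is refused.
#'
#' @param profile data.frame with columns `time_h` (increasing) and
#'   `cumulative_fraction` in \[0, 1\].
#' @param t time in hours, within the sampled range.
#' @return interpolated cumulative fraction released at `t`.
#' @export
release_fraction_at <- function(profile, t) {
  need <- c("time_h", "cumulative_fraction")
  miss <- setdiff(need, names(profile))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (any(t < min(profile$time_h)) || any(t > max(profile$time_h))) {
    stop(sprintf("t outside sampled range [%g, %g] h: refusing to extrapolate",
                 min(profile$time_h), max(profile$time_h)), call. = FALSE)
  }
  approx(profile$time_h, profile$cumulative_fraction, xout = t,
         ties = "ordered")$y
}
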