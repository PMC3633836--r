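#' @name synthetic-data
#' @title Seeded synthetic-data generators
#' @description
#' Each `gen_*()` generator emits one kind of input the analysis pipeline
#' consumes — brightfield micrographs, stained sections, growth series,
#' viability plates, clonogenic counts, release profiles — together with a
#' [synthetic_truth()] record of the exact ground-truth parameters used.
#' Every generator takes an integer `seed` and is deterministic given
#' (parameters, seed); the caller's global random state is left untouched.
NULL

#' Ground-truth record attached to generated data
#'
#' @param kind one of `"brightfield"`, `"section"`, `"growth"`,
#'   `"dose_response"`, `"clonogenic"`, `"release"`.
#' @param params named list of the exact ground-truth parameters used.
#' @param seed integer seed the generator ran with.
#' @return a `synthetic_truth` object.
#' @export
synthetic_truth <- function(kind, params, seed) {
  kind <- match.arg(kind, c("brightfield", "section", "growth",
                            "dose_response", "clonogenic", "release"))
  structure(list(kind = kind, params = params, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> kind = %s, seed = %d\n", x$kind, x$seed))
  scalar <- vapply(x$params, function(p) is.numeric(p) && length(p) == 1L,
                   logical(1))
  if (any(scalar)) {
    p <- unlist(x$params[scalar])
    cat(paste0("  ", names(p), " = ", signif(p, 6), collapse = "\n"), "\n")
  }
  invisible(x)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Generate a synthetic brightfield spheroid micrograph
#'
#' A dark, filled, quasi-circular disc of known diameter on a bright
#' background, matching the appearance of a tumor spheroid under a
#' brightfield microscope: the disc centre is jittered by up to 2 px, the
#' edge rolls off smoothly over `edge_softness_px` (logistic profile in the
#' radial distance), and i.i.d. Gaussian noise is added before clipping to
#' the 8-bit range.
#'
#' @param diameter_um true spheroid diameter in micrometres.
#' @param um_per_px calibration (micrometres per pixel).
#' @param image_size_px side of the square frame in pixels.
#' @param edge_softness_px scale of the edge roll-off in pixels (0 = hard
#'   edge).
#' @param noise_sd additive Gaussian noise SD on the 8-bit scale.
#' @param foreground,background disc and background intensity levels.
#' @param seed integer seed.
#' @return list with `image` (a calibrated [pixel_image()]) and `truth`
#'   (diameter, radius in px, analytic area and sphere volume).
#' @export
gen_brightfield_spheroid <- function(diameter_um, um_per_px,
                                     image_size_px = 512L,
                                     edge_softness_px = 2,
                                     noise_sd = 0,
                                     foreground = 30, background = 220,
                                     seed = 1L) {
  stopifnot(diameter_um > 0, um_per_px > 0, noise_sd >= 0,
            edge_softness_px >= 0)
  diameter_px <- diameter_um / um_per_px
  offset_max <- 2
  if (diameter_px + 2 * offset_max + 4 * edge_softness_px >= image_size_px) {
    stop(sprintf(
      "disc of %.0f px (plus offset/edge margin) exceeds the %d px frame",
      diameter_px, image_size_px), call. = FALSE)
  }
  radius_px <- diameter_px / 2
  withr::with_seed(seed, {
    centre <- (image_size_px + 1) / 2 + stats::runif(2, -offset_max, offset_max)
    rr <- matrix(seq_len(image_size_px), image_size_px, image_size_px)
    cc <- t(rr)
    r <- sqrt((rr - centre[1])^2 + (cc - centre[2])^2)
    profile <- if (edge_softness_px == 0) (r > radius_px) + 0 else {
      stats::plogis((r - radius_px) / edge_softness_px)
    }
    m <- foreground + (background - foreground) * profile
    if (noise_sd > 0) m <- m + rnorm(length(m), sd = noise_sd)
    img <- pixel_image(clip255(m), um_per_px = um_per_px)
  })
  truth <- synthetic_truth("brightfield", list(
    diameter_um = diameter_um,
    radius_px = radius_px,
    centre_px = centre,
    area_px = pi * radius_px^2,
    area_um2 = pi * (diameter_um / 2)^2,
    volume_um3 = sphere_volume(diameter_um),
    um_per_px = um_per_px,
    edge_softness_px = edge_softness_px,
    noise_sd = noise_sd), seed)
  list(image = img, truth = truth)
}

#' Generate a synthetic stained spheroid cross-section
#'
#' A circular section mask in which each pixel is stain-positive with a
#' probability given by `depth_profile(depth / R)`, where depth is the
#' pixel's Euclidean distance to the section boundary and R the maximum
#' depth. This emulates radially structured markers: a proliferation rim is
#' a profile high near depth 0, a hypoxic core a profile high near depth 1.
#' Positive and negative pixels draw intensities from two Gaussian
#' distributions (clipped to the 8-bit range).
#'
#' The truth record contains the exact per-region positive-intensity sums of
#' the emitted image (computed from the generated positive pixels and
#' [assign_regions()] of the emitted mask), so downstream quantification can
#' be checked pixel-for-pixel.
#'
#' @param radius_px section radius in pixels (>= 10).
#' @param depth_profile function mapping depth fraction in \[0,1\] to a
#'   positivity probability in \[0,1\].
#' @param pos_intensity,neg_intensity length-2 numeric `c(mean, sd)` of the
#'   positive / negative intensity distributions.
#' @param frame_px side of the square frame (default fits the section with
#'   a 10 px margin).
#' @param seed integer seed.
#' @return list with `image` ([pixel_image()]), `mask` ([spheroid_mask()]),
#'   and `truth` carrying `region_pos_sums`, `total_pos_sum`,
#'   `region_pos_counts` and the separating `threshold` midway between the
#'   two intensity means.
#' @export
gen_stained_section <- function(radius_px,
                                depth_profile = function(f) rep(1, length(f)),
                                pos_intensity = c(180, 10),
                                neg_intensity = c(40, 10),
                                frame_px = NULL,
                                seed = 1L) {
  stopifnot(radius_px >= 10)
  if (is.null(frame_px)) frame_px <- 2L * ceiling(radius_px) + 21L
  centre <- (frame_px + 1) / 2
  rr <- matrix(seq_len(frame_px), frame_px, frame_px)
  cc <- t(rr)
  mask <- sqrt((rr - centre)^2 + (cc - centre)^2) <= radius_px
  regions <- assign_regions(mask)
  fdepth <- regions$depth_map / regions$max_depth_px
  p <- numeric(length(mask))
  p[mask] <- depth_profile(fdepth[mask])
  if (any(p < 0 | p > 1) || any(!is.finite(p[mask]))) {
    stop("depth_profile must map [0,1] to probabilities in [0,1]",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    positive <- matrix(FALSE, frame_px, frame_px)
    positive[mask] <- stats::runif(sum(mask)) < p[mask]
    m <- matrix(0, frame_px, frame_px)
    npos <- sum(positive); nneg <- sum(mask & !positive)
    if (npos) m[positive] <- clip255(rnorm(npos, pos_intensity[1],
                                           pos_intensity[2]))
    if (nneg) m[mask & !positive] <- clip255(rnorm(nneg, neg_intensity[1],
                                                   neg_intensity[2]))
  })
  sums <- vapply(1:3, function(k) sum(m[positive & regions$labels == k]),
                 numeric(1))
  counts <- vapply(1:3, function(k) sum(positive & regions$labels == k),
                   numeric(1))
  truth <- synthetic_truth("section", list(
    radius_px = radius_px,
    region_pos_sums = setNames(sums, region_names),
    region_pos_counts = setNames(counts, region_names),
    total_pos_sum = sum(sums),
    n_positive = npos,
    threshold = (pos_intensity[1] + neg_intensity[1]) / 2,
    pos_intensity = pos_intensity,
    neg_intensity = neg_intensity), seed)
  list(image = pixel_image(m),
       mask = spheroid_mask(mask),
       truth = truth)
}

#' Generate replicated Gompertz growth series
#'
#' Observations \eqn{V_{obs}(t) = V(t)\,\epsilon} with V(t) the Gompertz
#' curve and \eqn{\epsilon} a median-1 lognormal multiplier whose
#' coefficient of variation is `cv` (multiplicative noise: volume errors
#' scale with size and volumes stay positive).
#'
#' @param v0,alpha,beta Gompertz parameters (see [gompertz_volume()]).
#' @param days observation days.
#' @param n_replicates number of replicate spheroids.
#' @param cv coefficient of variation of the noise multiplier (>= 0).
#' @param arm optional arm label attached to the data.
#' @param seed integer seed.
#' @return list with `data` (data.frame `arm`, `replicate`, `day`,
#'   `volume_um3`) and `truth` (parameters incl. the plateau
#'   \eqn{V_0 e^{\alpha/\beta}}).
#' @export
gen_growth_series <- function(v0, alpha, beta, days, n_replicates = 6L,
                              cv = 0.05, arm = "control", seed = 1L) {
  stopifnot(v0 > 0, alpha >= 0, beta > 0, cv >= 0, n_replicates >= 1)
  mu <- gompertz_volume(days, v0, alpha, beta)
  sdlog <- sqrt(log(1 + cv^2))
  df <- expand.grid(replicate = seq_len(n_replicates), day = days,
                    KEEP.OUT.ATTRS = FALSE)
  withr::with_seed(seed, {
    mult <- if (cv == 0) rep(1, nrow(df)) else rlnorm(nrow(df), 0, sdlog)
  })
  df$volume_um3 <- mu[match(df$day, days)] * mult
  df <- data.frame(arm = arm, df[order(df$replicate, df$day), ],
                   row.names = NULL)
  truth <- synthetic_truth("growth", list(
    v0 = v0, alpha = alpha, beta = beta,
    plateau = v0 * exp(alpha / beta),
    cv = cv, n_replicates = n_replicates, days = days), seed)
  list(data = df, truth = truth)
}

#' Generate a synthetic APH dose-response plate
#'
#' Treatment-well absorbances follow
#' \eqn{A = A_{media} + (A_{control} - A_{media})\,v(C)/100 + \epsilon}
#' with v(C) the Hill viability ([hill_viability()]) and Gaussian read noise
#' \eqn{\epsilon}; untreated control wells and cell-free media blanks are
#' included with the same noise, so the plate can be normalized exactly as a
#' real one.
#'
#' @param ic50 midpoint concentration `x50` of the generating Hill curve
#'   (equals the absolute IC50 when `bottom = 0`).
#' @param hill_slope Hill coefficient (> 0).
#' @param bottom lower viability plateau, percent, in \[0, 100).
#' @param a_media,a_control media-blank and untreated mean absorbances
#'   (`a_control > a_media`).
#' @param concentrations positive test concentrations (ng/mL).
#' @param n_replicates wells per concentration (and per control/media role).
#' @param noise_sd Gaussian absorbance noise SD.
#' @param seed integer seed.
#' @return list with `data` (data.frame `well`, `role`
#'   (treatment/control/media), `concentration_ng_ml`, `absorbance`) and
#'   `truth`.
#' @export
gen_dose_response <- function(ic50, hill_slope = 1, bottom = 0,
                              a_media = 0.1, a_control = 0.9,
                              concentrations, n_replicates = 3L,
                              noise_sd = 0.02, seed = 1L) {
  stopifnot(a_control > a_media, bottom >= 0, bottom < 100, noise_sd >= 0,
            all(concentrations > 0))
  v <- hill_viability(concentrations, ic50, hill_slope, bottom)
  mu_treat <- a_media + (a_control - a_media) * v / 100
  df <- rbind(
    expand.grid(rep = seq_len(n_replicates),
                concentration_ng_ml = concentrations,
                KEEP.OUT.ATTRS = FALSE),
    data.frame(rep = seq_len(n_replicates), concentration_ng_ml = NA_real_),
    data.frame(rep = seq_len(n_replicates), concentration_ng_ml = NA_real_))
  n_t <- n_replicates * length(concentrations)
  df$role <- c(rep("treatment", n_t), rep("control", n_replicates),
               rep("media", n_replicates))
  mu <- c(mu_treat[match(df$concentration_ng_ml[seq_len(n_t)],
                         concentrations)],
          rep(a_control, n_replicates), rep(a_media, n_replicates))
  withr::with_seed(seed, {
    df$absorbance <- mu + if (noise_sd > 0) rnorm(nrow(df), sd = noise_sd)
                          else 0
  })
  df$well <- sprintf("W%03d", seq_len(nrow(df)))
  df <- df[, c("well", "role", "concentration_ng_ml", "absorbance")]
  truth <- synthetic_truth("dose_response", list(
    ic50 = ic50, hill_slope = hill_slope, bottom = bottom,
    a_media = a_media, a_control = a_control,
    concentrations = concentrations, n_replicates = n_replicates,
    noise_sd = noise_sd), seed)
  list(data = df, truth = truth)
}

#' Generate a synthetic clonogenic record
#'
#' Colonies are drawn as Binomial(cells plated, plating efficiency x true
#' surviving fraction): each plated cell independently forms a countable
#' colony with that probability.
#'
#' @param n_plated cells plated.
#' @param plating_efficiency colony-forming fraction of untreated cells.
#' @param sf_true true surviving fraction of the treatment (1 for the
#'   untreated control).
#' @param condition label for the record.
#' @param seed integer seed.
#' @return list with `record` (data.frame `condition`, `cells_plated`,
#'   `colonies`) and `truth`.
#' @export
gen_clonogenic <- function(n_plated, plating_efficiency, sf_true = 1,
                           condition = "control", seed = 1L) {
  p <- plating_efficiency * sf_true
  stopifnot(n_plated >= 1, p >= 0, p <= 1)
  withr::with_seed(seed, {
    colonies <- rbinom(1, n_plated, p)
  })
  truth <- synthetic_truth("clonogenic", list(
    n_plated = n_plated, plating_efficiency = plating_efficiency,
    sf_true = sf_true), seed)
  list(record = data.frame(condition = condition, cells_plated = n_plated,
                           colonies = colonies),
       truth = truth)
}

#' Generate a synthetic cumulative drug-release profile
#'
#' First-order release from a dialysis bag:
#' \eqn{F(t) = f_\infty (1 - e^{-kt})} plus Gaussian noise, clipped to
#' \[0, 1\]; `monotone = TRUE` additionally enforces a nondecreasing
#' cumulative profile (running maximum).
#'
#' @param k first-order release rate (per hour, > 0).
#' @param f_inf fraction released at infinite time, in (0, 1].
#' @param times sampling times in hours.
#' @param noise_sd Gaussian noise SD on the fraction scale.
#' @param monotone enforce a nondecreasing profile.
#' @param seed integer seed.
#' @return list with `data` (data.frame `time_h`, `cumulative_fraction`)
#'   and `truth`.
#' @export
gen_release <- function(k, f_inf = 1, times, noise_sd = 0,
                        monotone = FALSE, seed = 1L) {
  stopifnot(k > 0, f_inf > 0, f_inf <= 1, noise_sd >= 0)
  times <- sort(times)
  f <- f_inf * (1 - exp(-k * times))
  withr::with_seed(seed, {
    if (noise_sd > 0) f <- f + rnorm(length(f), sd = noise_sd)
  })
  f <- pmin(pmax(f, 0), 1)
  if (monotone) f <- cummax(f)
  truth <- synthetic_truth("release", list(
    k = k, f_inf = f_inf, half_life_h = log(2) / k, noise_sd = noise_sd),
    seed)
  list(data = data.frame(time_h = times, cumulative_fraction = f),
       truth = truth)
}
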