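# Pressure-volume curve analysis.
#
# A bench-dried leaf traverses two regimes: while turgid, water potential is
# the sum of a (near-linear in RWC) turgor pressure and an osmotic term;
# after turgor loss only the osmotic term remains, so -1/psi is linear in
# RWC.  Segmenting the -1/psi vs RWC plot at the turgor loss point and
# fitting the post-TLP ("osmotic") line yields the classical PV parameters.

#' Configuration for pressure-volume curve fitting
#'
#' @param min_points_linear minimum number of points in the linear
#'   (osmotic) region, and on each side of an interior breakpoint for the
#'   exhaustive method (default 4).
#' @param breakpoint_method `"dry_growth"` (default): grow the osmotic line
#'   from the driest points towards full turgor, stopping when the next
#'   point deviates upward by more than `growth_k` times the residual scale
#'   (one-sided, because turgid points always lie above the osmotic line in
#'   -1/psi space); exact on noise-free curves.  `"piecewise_rss"`:
#'   two-segment least squares on -1/psi vs RWC over all admissible
#'   breakpoints, minimising total RSS.  `"incremental_r2"`: grow the
#'   linear region from the driest point while its r^2 stays at or above
#'   `r2_min`.  The latter two are retained for sensitivity checks.
#' @param initial_slope_points number of initial (wettest) drydown points
#'   used for the capacitance slope dRWC/dpsi; `NULL` (default) uses the
#'   initial turgor-loss region (turgid points carrying at least
#'   `turgor_frac` of the maximum turgor), matching the region used for the
#'   elastic modulus.
#' @param turgor_frac turgid points with turgor below this fraction of the
#'   maximum turgor are excluded from the initial turgor-loss line
#'   (default 0.25); near-zero-turgor points around the breakpoint carry no
#'   slope information and are sensitive to breakpoint placement.
#' @param psi_floor water potentials below this protocol floor (MPa) are
#'   excluded before fitting (default -3.0, the bench-drying endpoint).
#' @param growth_k one-sided tolerance multiplier for `"dry_growth"`
#'   (default 3).
#' @param rel_floor relative tolerance floor for `"dry_growth"` (default
#'   0.01 of the mean transformed response), guarding against a
#'   zero-residual early fit.
#' @param r2_min r^2 threshold for `"incremental_r2"` (default 0.99).
#' @param epsilon_eval RWC at which the elastic-modulus slope is evaluated:
#'   `"mean_turgid"` (default, mean RWC of the points on the initial
#'   turgor-loss line) or `"full_turgor"` (RWC = 1).
#' @param estimator `"model"` (default): refine the graphical estimates by
#'   weighted nonlinear least squares of the linear-turgor PV model in
#'   psi space, where measurement noise is homoscedastic (weights
#'   `1/(psi_precision^2 + (dpsi/dRWC * rwc_precision)^2)` absorb the mass
#'   noise propagated through the curve gradient).  `"graphical"`: report
#'   the classical inverse-plot estimates directly.
#' @param psi_precision pressure-chamber precision (MPa, default 0.03);
#'   used only to weight the model refinement.
#' @param mass_precision balance precision (g, default 5e-4); converted to
#'   RWC units through the observation's SW - DW.
#' @param water_molar_mass molar mass of water, g mol^-1 (18.015).
#' @return A list of class `"pv_fit_config"`.
#' @export
pv_fit_config <- function(min_points_linear = 4,
                          breakpoint_method = c("dry_growth",
                                                "piecewise_rss",
                                                "incremental_r2"),
                          estimator = c("model", "graphical"),
                          initial_slope_points = NULL,
                          turgor_frac = 0.25,
                          psi_floor = -3.0,
                          growth_k = 3,
                          rel_floor = 0.01,
                          r2_min = 0.99,
                          epsilon_eval = c("mean_turgid", "full_turgor"),
                          psi_precision = 0.03,
                          mass_precision = 5e-4,
                          water_molar_mass = 18.015) {
  breakpoint_method <- match.arg(breakpoint_method)
  estimator <- match.arg(estimator)
  epsilon_eval <- match.arg(epsilon_eval)
  if (min_points_linear < 3) stop("min_points_linear must be >= 3")
  if (!is.null(initial_slope_points) && initial_slope_points < 3)
    stop("initial_slope_points must be >= 3")
  if (turgor_frac < 0 || turgor_frac >= 1)
    stop("turgor_frac must lie in [0, 1)")
  structure(list(min_points_linear = min_points_linear,
                 breakpoint_method = breakpoint_method,
                 estimator = estimator,
                 initial_slope_points = initial_slope_points,
                 turgor_frac = turgor_frac,
                 psi_floor = psi_floor, growth_k = growth_k,
                 rel_floor = rel_floor, r2_min = r2_min,
                 epsilon_eval = epsilon_eval,
                 psi_precision = psi_precision,
                 mass_precision = mass_precision,
                 water_molar_mass = water_molar_mass),
            class = "pv_fit_config")
}

#' Linear-turgor pressure-volume model
#'
#' The standard construction behind PV analysis: osmotic potential dilutes
#' with symplastic water content R_s = (RWC - AWF)/(1 - AWF) following
#' van't Hoff (psi_pi = psi_ft / R_s), turgor declines linearly
#' (psi_p = max(0, -psi_ft - epsilon (1 - R_s))), and the measured water
#' potential is their sum.  `pv_model_rwc` inverts the curve for water
#' potential targets (hyperbolic branch past turgor loss, quadratic root
#' while turgid).
#'
#' @param rwc relative water content (fraction).
#' @param psi water potential targets (MPa, <= 0).
#' @param psi_ft osmotic potential at full turgor (MPa, < 0).
#' @param epsilon symplastic-basis elastic modulus (MPa, > -psi_ft).
#' @param awf apoplastic water fraction.
#' @return Water potential (MPa) or RWC (fraction) vectors.
#' @export
pv_model_psi <- function(rwc, psi_ft, epsilon, awf) {
  rs <- (rwc - awf) / (1 - awf)
  pmax(0, -psi_ft - epsilon * (1 - rs)) + psi_ft / rs
}

#' @rdname pv_model_psi
#' @export
pv_model_rwc <- function(psi, psi_ft, epsilon, awf) {
  psi_tlp <- psi_ft * epsilon / (epsilon + psi_ft)
  bq <- psi_ft + epsilon + psi
  rs_turgid <- (bq + sqrt(pmax(bq^2 - 4 * epsilon * psi_ft, 0))) /
    (2 * epsilon)
  rs <- ifelse(psi <= psi_tlp, psi_ft / psi, rs_turgid)
  awf + rs * (1 - awf)
}

# weighted nonlinear least squares of the PV model in psi space
pv_model_fit <- function(rwc, psi, psi_ft0, epsilon0, awf0,
                         s_psi = 0.03, s_rwc = 0.006) {
  obj <- function(p) {
    ft <- -exp(p[1])
    eps <- -ft + exp(p[2])        # epsilon > -psi_ft by construction
    awf <- stats::plogis(p[3])
    mu <- pv_model_psi(rwc, ft, eps, awf)
    g <- (pv_model_psi(rwc + 1e-6, ft, eps, awf) - mu) / 1e-6
    w <- 1 / (s_psi^2 + (g * s_rwc)^2 + 1e-12)
    sum(w * (psi - mu)^2)
  }
  p0 <- c(log(-psi_ft0),
          log(max(epsilon0 + psi_ft0, 0.1 * -psi_ft0)),
          stats::qlogis(min(max(awf0, 0.01), 0.9)))
  o <- stats::optim(p0, obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-12, maxit = 1500))
  o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-12, maxit = 1500))
  list(psi_ft = -exp(o$par[1]),
       epsilon = exp(o$par[1]) + exp(o$par[2]),
       awf = stats::plogis(o$par[3]),
       value = o$value, converged = o$convergence == 0, par = o$par)
}

#' Relative water content of a drydown series
#'
#' RWC = (FW - DW) / (SW - DW) for every fresh mass in the observation.
#'
#' @param observation a [pv_curve_observation()].
#' @return Numeric vector of RWC fractions, same length and order as the
#'   mass series.
#' @export
compute_rwc <- function(observation) {
  sw <- observation$saturated_mass; dw <- observation$dry_mass
  if (!is.finite(sw - dw) || sw - dw <= 0)
    stop("invalid observation: saturated mass must exceed dry mass")
  rwc <- (observation$fresh_mass - dw) / (sw - dw)
  if (any(rwc < -1e-9 | rwc > 1.02 + 1e-9))
    warning("RWC outside [0, 1.02] for leaf '", observation$leaf_id, "'",
            call. = FALSE)
  rwc
}

# simple OLS on (x, y): list(intercept, slope, rss, r2)
ols_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) return(list(intercept = my, slope = 0, rss = sum((y - my)^2),
                            r2 = NA_real_))
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  fit <- intercept + slope * x
  rss <- sum((y - fit)^2)
  tss <- sum((y - my)^2)
  list(intercept = intercept, slope = slope, rss = rss,
       r2 = if (tss > 0) 1 - rss / tss else NA_real_)
}

#' Segment a pressure-volume curve into turgid and osmotic regions
#'
#' Works on the transformed curve y = -1/psi vs RWC.  Points past the
#' turgor loss point fall on a straight line (the osmotic line); the turgid
#' region curves above it.  The breakpoint index is the first point
#' assigned to the linear (osmotic) region, counted along the drydown.
#' Saturation points (psi ~ 0, where -1/psi diverges) are excluded from the
#' transformed-space fits but retained in the series.
#'
#' @param rwc numeric RWC series in drydown order (decreasing).
#' @param psi numeric psi series (MPa, <= 0), same length.
#' @param config a [pv_fit_config()].
#' @return A list of class `"pv_segmentation"`: `breakpoint` (index of the
#'   first osmotic point), `intercept`, `slope`, `r2` of the osmotic line
#'   (y = intercept + slope * RWC), `rss_total`, `used` (logical, points
#'   entering transformed-space fits), and `flags`.
#' @export
segment_pv_curve <- function(rwc, psi, config = pv_fit_config()) {
  n <- length(rwc)
  if (n != length(psi)) stop("rwc and psi must have the same length")
  if (length(unique(psi)) == 1) stop("all psi values are equal; cannot segment")
  finite <- psi < -1e-9            # -1/psi defined
  y <- ifelse(finite, -1 / psi, NA_real_)
  m <- config$min_points_linear
  flags <- character()

  candidates <- integer()
  # interior breakpoints: >= m points on each side
  lo <- m + 1; hi <- n - m + 1
  if (lo <= hi) candidates <- lo:hi
  # degenerate all-linear candidate (no turgid region)
  candidates <- c(1L, candidates)

  eval_candidate <- function(b) {
    lin <- b:n
    lin_ok <- lin[finite[lin]]
    if (length(lin_ok) < min(m, length(lin))) return(NULL)
    fl <- ols_line(rwc[lin_ok], y[lin_ok])
    rss <- fl$rss
    if (b > 1) {
      tur <- which(finite[seq_len(b - 1)])
      if (length(tur) >= 2) rss <- rss + ols_line(rwc[tur], y[tur])$rss
    }
    list(b = b, line = fl, rss = rss)
  }

  if (config$breakpoint_method == "dry_growth") {
    # start from the m driest points (post-TLP by protocol design) and
    # extend towards full turgor; turgid points deviate upward from the
    # osmotic line, so the stop test is one-sided
    if (n - m + 1 < 1 || sum(finite[(n - m + 1):n]) < m)
      stop("too few usable points to segment curve")
    b <- n - m + 1L
    fl <- NULL
    repeat {
      lin <- (b:n)[finite[b:n]]
      fl <- ols_line(rwc[lin], y[lin])
      if (b <= 1) break
      cand <- b - 1L
      if (!finite[cand]) { b <- cand; next }  # saturation point: raw-space only
      s <- sqrt(fl$rss / max(1, length(lin) - 2))
      tol <- max(config$growth_k * s,
                 config$rel_floor * abs(mean(y[lin])))
      pred <- fl$intercept + fl$slope * rwc[cand]
      if (y[cand] - pred < tol) b <- cand else break
    }
    lin <- (b:n)[finite[b:n]]
    fl <- ols_line(rwc[lin], y[lin])
    best <- list(b = b, line = fl, rss = fl$rss)
  } else if (config$breakpoint_method == "piecewise_rss") {
    fits <- Filter(Negate(is.null), lapply(candidates, eval_candidate))
    if (!length(fits)) stop("too few usable points to segment curve")
    rsses <- vapply(fits, `[[`, numeric(1), "rss")
    best <- fits[[which.min(rsses)]]
  } else {
    # grow linear region from the driest point while r^2 stays high
    best <- NULL
    for (b in rev(candidates)) {
      cand <- eval_candidate(b)
      if (is.null(cand)) next
      if (is.na(cand$line$r2) || cand$line$r2 >= config$r2_min) best <- cand
      else break
    }
    if (is.null(best)) stop("no linear region satisfies the r^2 threshold")
  }

  if (best$b == 1)
    flags <- c(flags, "no turgid region: breakpoint at series start")
  if (!is.na(best$line$slope) && best$line$slope <= 0)
    stop("osmotic line has non-positive slope (unphysical fit)")
  structure(list(breakpoint = best$b,
                 intercept = best$line$intercept,
                 slope = best$line$slope,
                 r2 = best$line$r2,
                 rss_total = best$rss,
                 used = finite,
                 flags = flags),
            class = "pv_segmentation")
}

#' Derive the six pressure-volume parameters from a drydown
#'
#' From the fitted osmotic line y = a + b RWC (y = -1/psi):
#' * `psi_ft` (osmotic potential at full turgor) = -1/(a + b);
#' * `awf` (apoplastic water fraction) = -a/b, the RWC where the line
#'   predicts infinite osmotic potential (all symplastic water gone);
#' * turgor pressure over the turgid region is psi - psi_pi with
#'   psi_pi(RWC) = -1/(a + b RWC); `rwc_tlp` is the zero-turgor intercept
#'   of the turgor vs RWC regression and `psi_tlp` = -1/(a + b rwc_tlp);
#' * `epsilon` = (d turgor / d RWC) x RWC, the slope of the turgor line
#'   times the evaluation RWC (mean turgid RWC by default);
#' * `c_bulk` = (dRWC/dpsi over the first `initial_slope_points` points)
#'   x (DW/LA) x (SW/DW) x (1/M), in mol m^-2 MPa^-1.
#'
#' @param observation a [pv_curve_observation()].
#' @param config a [pv_fit_config()].
#' @return A list of class `"pv_parameters"` with fields `psi_tlp`,
#'   `psi_ft`, `rwc_tlp`, `awf`, `epsilon`, `c_bulk`, `breakpoint`,
#'   `r2_osmotic` and `flags`.
#' @export
derive_pv_parameters <- function(observation, config = pv_fit_config()) {
  rwc_all <- compute_rwc(observation)
  keep <- observation$psi >= config$psi_floor
  if (sum(keep) < 2 * config$min_points_linear)
    stop("fewer than ", 2 * config$min_points_linear,
         " points within the protocol range")
  rwc <- rwc_all[keep]; psi <- observation$psi[keep]
  seg <- segment_pv_curve(rwc, psi, config)
  a <- seg$intercept; b <- seg$slope
  flags <- seg$flags

  psi_ft <- -1 / (a + b)
  awf <- -a / b
  lin_idx <- seg$breakpoint:length(rwc)
  if (awf >= min(rwc[lin_idx]))
    flags <- c(flags, "AWF >= smallest linear-region RWC: unreliable")

  # turgor pressure over the turgid region (includes saturation points,
  # which are finite in raw psi space); the elastic modulus and RWC_TLP
  # come from the *initial* turgor-loss line: points still carrying at
  # least turgor_frac of the maximum turgor, since near-zero-turgor points
  # around the breakpoint carry no slope information
  tur_idx <- seq_len(seg$breakpoint - 1)
  rwc_tlp <- NA_real_; epsilon <- NA_real_
  init_idx <- tur_idx
  if (length(tur_idx) >= 2) {
    psi_pi <- -1 / (a + b * rwc[tur_idx])
    turgor <- psi[tur_idx] - psi_pi
    keep_t <- turgor >= config$turgor_frac * max(turgor)
    if (sum(keep_t) < min(3, length(tur_idx))) {
      keep_t <- rank(-turgor, ties.method = "first") <=
        min(3, length(tur_idx))
    }
    init_idx <- tur_idx[keep_t]
    tl <- ols_line(rwc[init_idx], turgor[keep_t])
    if (is.finite(tl$slope) && tl$slope > 0) {
      rwc_tlp <- -tl$intercept / tl$slope
      eval_rwc <- switch(config$epsilon_eval,
                         mean_turgid = mean(rwc[init_idx]),
                         full_turgor = 1)
      epsilon <- tl$slope * eval_rwc
    }
  }
  # fallback: first point assigned to the linear region
  if (!is.finite(rwc_tlp) || rwc_tlp <= awf || rwc_tlp >= 1) {
    rwc_tlp <- rwc[seg$breakpoint]
    flags <- c(flags, "turgor regression degenerate: RWC_TLP from breakpoint")
  }
  psi_tlp <- -1 / (a + b * rwc_tlp)
  eval_rwc <- if (length(init_idx) >= 2) mean(rwc[init_idx]) else 1
  model_converged <- NA
  eps_sym <- NA_real_

  # optional refinement: weighted least squares of the linear-turgor model
  # in psi space (homoscedastic psi noise; the graphical estimates seed it)
  if (config$estimator == "model" && is.finite(epsilon) && psi_ft < 0) {
    eps_sym0 <- epsilon * (1 - awf) /
      switch(config$epsilon_eval, mean_turgid = eval_rwc, full_turgor = 1)
    s_rwc <- config$mass_precision /
      (observation$saturated_mass - observation$dry_mass)
    fit <- pv_model_fit(rwc, psi, psi_ft, eps_sym0,
                        min(max(awf, 0.01), 0.9),
                        s_psi = config$psi_precision, s_rwc = s_rwc)
    model_converged <- fit$converged
    if (!fit$converged)
      flags <- c(flags, "model refinement did not converge")
    psi_ft <- fit$psi_ft; awf <- fit$awf; eps_sym <- fit$epsilon
    psi_tlp <- psi_ft * fit$epsilon / (fit$epsilon + psi_ft)
    rwc_tlp <- awf + (fit$epsilon + psi_ft) / fit$epsilon * (1 - awf)
    turgor_m <- pmax(0, -psi_ft - fit$epsilon *
                       (1 - (rwc - awf) / (1 - awf)))
    init_idx <- which(turgor_m >= config$turgor_frac * max(turgor_m))
    if (length(init_idx) < 3) init_idx <- order(-turgor_m)[1:3]
    eval_rwc <- switch(config$epsilon_eval,
                       mean_turgid = mean(rwc[init_idx]), full_turgor = 1)
    epsilon <- fit$epsilon / (1 - awf) * eval_rwc
  }

  # capacitance from the initial slope of RWC vs psi, over the same
  # initial turgor-loss region (or a fixed point count when configured)
  cap_idx <- if (is.null(config$initial_slope_points)) {
    if (length(init_idx) >= 3) init_idx
    else seq_len(min(4, length(rwc)))
  } else seq_len(min(config$initial_slope_points, length(rwc)))
  if (config$estimator == "model" && isTRUE(model_converged) &&
      is.null(config$initial_slope_points)) {
    # evaluate the secant on the fitted curve at the observed psi levels
    rwc_m <- pv_model_rwc(pmin(psi[cap_idx], 0), psi_ft, eps_sym, awf)
    cs <- ols_line(psi[cap_idx], rwc_m)
  } else {
    cs <- ols_line(psi[cap_idx], rwc[cap_idx])
  }
  dw <- observation$dry_mass; sw <- observation$saturated_mass
  la <- observation$leaf_area
  c_bulk <- cs$slope * (dw / la) * (sw / dw) / config$water_molar_mass
  if (!is.finite(c_bulk) || c_bulk <= 0)
    flags <- c(flags, "non-positive capacitance slope")

  structure(list(leaf_id = observation$leaf_id,
                 psi_tlp = psi_tlp, psi_ft = psi_ft, rwc_tlp = rwc_tlp,
                 awf = awf, epsilon = epsilon, c_bulk = c_bulk,
                 breakpoint = seg$breakpoint, r2_osmotic = seg$r2,
                 estimator = config$estimator,
                 model_converged = model_converged,
                 flags = flags),
            class = "pv_parameters")
}

#' @export
print.pv_parameters <- function(x, ...) {
  cat("PV parameters", if (!is.na(x$leaf_id)) paste0(" (leaf '", x$leaf_id, "')"),
      ":\n", sep = "")
  cat(sprintf("  psi_TLP = %.3f MPa   psi_FT = %.3f MPa\n", x$psi_tlp, x$psi_ft))
  cat(sprintf("  RWC_TLP = %.3f       AWF    = %.3f\n", x$rwc_tlp, x$awf))
  cat(sprintf("  epsilon = %.2f MPa   C_bulk = %.4f mol m^-2 MPa^-1\n",
              x$epsilon, x$c_bulk))
  cat(sprintf("  osmotic line r^2 = %.4f (breakpoint index %d)\n",
              x$r2_osmotic, x$breakpoint))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Tabulate PV parameters for a list of observations
#'
#' @param observations list of [pv_curve_observation()] objects.
#' @param config a [pv_fit_config()].
#' @return Data frame with one row per leaf (failed fits carry `NA`s and
#'   the error message in the `flags` column).
#' @export
pv_parameter_table <- function(observations, config = pv_fit_config()) {
  rows <- lapply(observations, function(obs) {
    res <- tryCatch(derive_pv_parameters(obs, config), error = function(e) e)
    if (inherits(res, "error"))
      data.frame(leaf_id = obs$leaf_id, psi_tlp = NA_real_, psi_ft = NA_real_,
                 rwc_tlp = NA_real_, awf = NA_real_, epsilon = NA_real_,
                 c_bulk = NA_real_, r2_osmotic = NA_real_,
                 flags = conditionMessage(res))
    else
      data.frame(leaf_id = res$leaf_id, psi_tlp = res$psi_tlp,
                 psi_ft = res$psi_ft, rwc_tlp = res$rwc_tlp, awf = res$awf,
                 epsilon = res$epsilon, c_bulk = res$c_bulk,
                 r2_osmotic = res$r2_osmotic,
                 flags = paste(res$flags, collapse = "; "))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
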