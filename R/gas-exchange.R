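# Light-response fitting (nonrectangular hyperbola) and leaf hydraulic
# conductance by the evaporative flux method.

#' Evaluate the nonrectangular hyperbola light-response model
#'
#' The saturating core is the lower root of
#' theta A^2 - (phi Q + sat) A + phi Q sat = 0.  For assimilation the
#' offset (dark respiration R_d) is subtracted, so the response at Q = 0 is
#' exactly -R_d; for conductance the offset (g_0) is added, so the response
#' at Q = 0 is exactly g_0.
#'
#' @param ppfd PPFD (umol m^-2 s^-1).
#' @param phi apparent quantum yield (initial slope).
#' @param sat light-saturated response (A_sat or g_sat).
#' @param theta curvature parameter in (0, 1].
#' @param offset R_d (assimilation) or g_0 (conductance).
#' @param kind `"assimilation"` or `"conductance"`.
#' @return Numeric vector of model responses.
#' @export
nrh_response <- function(ppfd, phi, sat, theta, offset,
                         kind = c("assimilation", "conductance")) {
  kind <- match.arg(kind)
  s <- phi * ppfd + sat
  disc <- pmax(s^2 - 4 * theta * phi * ppfd * sat, 0)
  core <- if (theta > 1e-9) (s - sqrt(disc)) / (2 * theta)
          else phi * ppfd * sat / s   # theta -> 0 rectangular limit
  if (kind == "assimilation") core - offset else core + offset
}

#' Fit a nonrectangular hyperbola to a light-response series
#'
#' Least-squares fit of (phi, sat, theta, offset) with theta constrained to
#' (0, 1] via a logistic transform and phi, sat kept positive via log
#' transforms.  Eight deterministic starting points are derived from data
#' heuristics (initial slope over the lowest nonzero PPFD levels for phi,
#' the maximum response for sat, theta in {0.5, 0.9}), each refined with
#' BFGS followed by a Nelder-Mead polish; the best final objective wins, so
#' the refined objective never exceeds the best start.
#'
#' @param series a [light_response_series()].
#' @return A list of class `"light_response_fit"`: `phi`, `sat`, `theta`,
#'   `offset`, `kind`, `rmse`, `converged`, `theta_at_bound`, `sse`,
#'   `n_starts`.
#' @export
fit_nonrectangular_hyperbola <- function(series) {
  stopifnot(inherits(series, "light_response_series"))
  q <- series$ppfd; y <- series$response; kind <- series$kind
  if (length(unique(q)) < 5)
    stop("need at least 5 distinct PPFD levels")
  if (max(q) < 1200 || min(q) > 50)
    warning("PPFD design lacks a level <= 50 or >= 1200; ",
            "parameters may be poorly identified", call. = FALSE)

  # normalise the response scale so assimilation (tens) and conductance
  # (tenths) fits are numerically identical
  y_scale <- max(abs(y), 1e-12)
  y <- y / y_scale

  sgn <- if (kind == "assimilation") -1 else 1
  # heuristics
  off0 <- if (any(q == 0)) sgn * mean(y[q == 0]) else
    if (kind == "assimilation") max(0.5, -min(y)) else max(min(y), 1e-3)
  nz <- sort(unique(q[q > 0]))[1:2]
  idx <- q %in% nz
  sl <- ols_line(q[idx], y[idx] + if (kind == "assimilation") off0 else -off0)
  phi0 <- max(sl$slope, 1e-4)
  sat0 <- max(max(y) + (if (kind == "assimilation") off0 else -off0), 1e-3)

  to_par <- function(phi, sat, theta, offset)
    c(log(phi), log(sat), stats::qlogis(min(max(theta, 1e-6), 1 - 1e-9)), offset)
  from_par <- function(p)
    list(phi = exp(p[1]), sat = exp(p[2]), theta = stats::plogis(p[3]),
         offset = p[4])
  sse <- function(p) {
    th <- from_par(p)
    r <- y - nrh_response(q, th$phi, th$sat, th$theta, th$offset, kind)
    sum(r * r)
  }

  starts <- list()
  for (th in c(0.5, 0.9)) for (fp in c(1, 2)) for (fs in c(1, 1.3))
    starts[[length(starts) + 1]] <- to_par(phi0 * fp, sat0 * fs, th, off0)

  # stage 1: a short Nelder-Mead run from every start; stage 2: tight
  # polish of the best (the refined objective never exceeds the best start)
  best <- NULL
  for (st in starts) {
    f1 <- stats::optim(st, sse, method = "Nelder-Mead",
                       control = list(reltol = 1e-8, maxit = 400))
    if (is.null(best) || f1$value < best$value) best <- f1
  }
  for (k in 1:2) {
    fk <- stats::optim(best$par, sse, method = "Nelder-Mead",
                       control = list(reltol = 1e-12, maxit = 4000))
    if (fk$value <= best$value) best <- fk
  }
  th <- from_par(best$par)
  structure(list(phi = th$phi * y_scale, sat = th$sat * y_scale,
                 theta = th$theta,
                 offset = th$offset * y_scale, kind = kind,
                 rmse = y_scale * sqrt(best$value / length(y)),
                 sse = best$value * y_scale^2,
                 converged = best$convergence == 0,
                 theta_at_bound = th$theta > 1 - 1e-6 || th$theta < 1e-6,
                 n_starts = length(starts), id = series$id),
            class = "light_response_fit")
}

#' @export
print.light_response_fit <- function(x, ...) {
  lab <- if (x$kind == "assimilation") c("A_sat", "R_d") else c("g_sat", "g_0")
  cat("Nonrectangular hyperbola fit (", x$kind, "):\n", sep = "")
  cat(sprintf("  phi = %.5f  %s = %.4f  theta = %.4f  %s = %.4f\n",
              x$phi, lab[1], x$sat, x$theta, lab[2], x$offset))
  cat(sprintf("  rmse = %.4g  converged = %s%s\n", x$rmse, x$converged,
              if (x$theta_at_bound) "  [theta pinned at bound]" else ""))
  invisible(x)
}

#' Residual-bootstrap confidence intervals for a light-response fit
#'
#' Resamples centred residuals, refits, and returns percentile intervals.
#'
#' @param series a [light_response_series()].
#' @param fit the corresponding [fit_nonrectangular_hyperbola()] result.
#' @param n_boot number of bootstrap replicates.
#' @param level confidence level.
#' @param seed optional integer seed.
#' @return Matrix with rows phi, sat, theta, offset and columns lower/upper.
#' @export
nrh_bootstrap_ci <- function(series, fit, n_boot = 199, level = 0.95,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- series$ppfd
  mu <- nrh_response(q, fit$phi, fit$sat, fit$theta, fit$offset, fit$kind)
  res <- series$response - mu
  res <- res - mean(res)
  draws <- matrix(NA_real_, n_boot, 4)
  for (b in seq_len(n_boot)) {
    yb <- mu + sample(res, length(res), replace = TRUE)
    fb <- tryCatch(
      fit_nonrectangular_hyperbola(
        light_response_series(q, yb, fit$kind, id = series$id)),
      error = function(e) NULL)
    if (!is.null(fb)) draws[b, ] <- c(fb$phi, fb$sat, fb$theta, fb$offset)
  }
  a <- (1 - level) / 2
  ci <- t(apply(draws, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE))
  dimnames(ci) <- list(c("phi", "sat", "theta", "offset"),
                       c("lower", "upper"))
  ci
}

#' Leaf hydraulic conductance by the evaporative flux method
#'
#' K_leaf = E / (psi_stem - psi_leaf).  The stem water potential comes from
#' an adjacent covered (non-transpiring) leaf; the driving gradient must be
#' positive, otherwise the leaf pair is equilibrated or mismeasured.
#'
#' @param spot a [spot_hydraulics()] object, or the transpiration rate E
#'   (mmol m^-2 s^-1) when `psi_stem`/`psi_leaf` are given directly.
#' @param psi_stem,psi_leaf water potentials (MPa) when `spot` is numeric.
#' @return K_leaf in mmol m^-2 s^-1 MPa^-1 (vectorised).
#' @export
compute_kleaf <- function(spot, psi_stem = NULL, psi_leaf = NULL) {
  if (inherits(spot, "spot_hydraulics")) {
    E <- spot$E; ps <- spot$psi_stem; pl <- spot$psi_leaf
  } else {
    E <- spot; ps <- psi_stem; pl <- psi_leaf
  }
  if (any(E < 0)) stop("transpiration must be non-negative")
  grad <- ps - pl
  if (any(grad <= 0))
    stop("undefined gradient: psi_stem must exceed psi_leaf ",
         "(equilibrated or mismeasured leaf pair)")
  E / grad
}
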