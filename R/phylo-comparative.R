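# Phylogenetic comparative methods implemented from the Brownian-motion
# likelihood: Pagel's-lambda covariance, PGLS with profile-ML lambda, and
# maximum-likelihood ancestral state reconstruction with variances.

#' Phylogenetic covariance matrix under Pagel's lambda
#'
#' Shared root-to-tip path lengths with off-diagonal entries multiplied by
#' lambda.  The diagonal (tip depths) is untouched, so lambda = 0 yields a
#' diagonal matrix (no phylogenetic signal) and lambda = 1 the Brownian
#' expectation.
#'
#' @param tree an [ape::phylo] tree (should be ultrametric).
#' @param lambda signal strength in `[0, 1]`.
#' @return Symmetric positive-definite matrix, rows/cols named by tips.
#' @export
phylo_covariance <- function(tree, lambda = 1) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  C <- ape::vcv(tree)
  if (any(diag(C) <= 0))
    stop("zero-depth tips make the covariance singular")
  off <- C * lambda
  diag(off) <- diag(C)
  # duplicated tips (zero-length terminal branches) are singular at lambda=1
  if (lambda == 1 && any(duplicated(round(off, 12)) &
                         duplicated(round(off, 12), fromLast = FALSE))) {
    ev <- eigen(off, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-12 * max(ev))
      stop("zero-length terminal branches cause a singular covariance; ",
           "resolve the tree rather than jittering")
  }
  off
}

# profile log-likelihood machinery shared by pgls_fit
gls_profile <- function(y, X, C_off, C_diag, lambda) {
  V <- C_off * lambda
  diag(V) <- C_diag
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  logdet <- 2 * sum(log(diag(R)))
  # rotate: solve(t(R)) %*% .
  yr <- backsolve(R, y, transpose = TRUE)
  Xr <- backsolve(R, X, transpose = TRUE)
  qr_ <- qr(Xr)
  beta <- qr.coef(qr_, yr)
  r <- yr - Xr %*% beta
  rss <- sum(r * r)
  n <- length(y)
  s2_ml <- rss / n
  ll <- -0.5 * (n * log(2 * pi * s2_ml) + n + logdet)
  list(beta = beta, rss = rss, s2_ml = s2_ml, loglik = ll,
       Xr = Xr, yr = yr, qr = qr_, logdet = logdet)
}

#' Phylogenetic generalised least squares with Pagel's lambda
#'
#' Fits y = X beta + e with e ~ N(0, sigma^2 V(lambda)), where V(lambda)
#' scales the off-diagonal shared path lengths by lambda.  With
#' `lambda = "ml"` the profile log-likelihood (sigma^2 profiled out as
#' RSS/n) is maximised over `[0, 1]` by Brent search plus explicit endpoint
#' evaluation, ties broken toward the interior.  Coefficient t-tests use
#' n - k degrees of freedom (k = columns of the design); r^2 is defined
#' against the GLS intercept-only model at the fitted lambda and
#' adjusted r^2 = 1 - (1 - r^2)(n - 1)/(n - p - 1) with p the number of
#' non-intercept predictors.
#'
#' @param formula model formula, variables found in `data`.
#' @param data data frame with row names matching tree tip labels.
#' @param tree an [ape::phylo] ultrametric tree.
#' @param lambda `"ml"` (default) or a fixed value in `[0, 1]`.
#' @return Object of class `"pgls_fit"`: `coefficients` (estimate, se, t,
#'   p), `lambda`, `lambda_mode`, `sigma2` (ML), `loglik`, `r2`, `adj_r2`,
#'   `n`, `k`, `residuals` (GLS-rotated), plus the profile at the
#'   endpoints for boundary diagnostics.
#' @export
pgls_fit <- function(formula, data, tree, lambda = "ml") {
  mt <- match_tree_table(tree, data)
  tree <- mt$tree; data <- mt$table
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  if (nrow(mf) < nrow(data)) {
    keep <- rownames(mf)
    mt <- match_tree_table(tree, data[keep, , drop = FALSE])
    tree <- mt$tree
    mf <- stats::model.frame(formula, mt$table, na.action = stats::na.fail)
  }
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  ord <- match(tree$tip.label, rownames(mf))
  y <- y[ord]; X <- X[ord, , drop = FALSE]
  n <- length(y); k <- ncol(X)
  if (n < k + 3) stop("need at least k + 3 tips for a k-column design")
  if (qr(X)$rank < k) stop("singular design matrix")

  C <- phylo_covariance(tree, 1)
  C_diag <- diag(C)
  C_off <- C; diag(C_off) <- 0

  prof <- function(lam) {
    g <- gls_profile(y, X, C_off, C_diag, lam)
    if (is.null(g)) -Inf else g$loglik
  }

  boundary <- c(`0` = prof(0), `1` = prof(1))
  if (identical(lambda, "ml")) {
    opt <- stats::optimize(prof, interval = c(0, 1), maximum = TRUE,
                           tol = 1e-6)
    cands <- c(opt$maximum, 0, 1)
    vals <- c(opt$objective, boundary)
    lam_hat <- cands[which.max(vals)]   # ties resolve to the interior first
    mode <- "ml"
  } else {
    lam_hat <- as.numeric(lambda)
    if (is.na(lam_hat) || lam_hat < 0 || lam_hat > 1)
      stop("lambda must be 'ml' or a number in [0, 1]")
    mode <- "fixed"
  }

  g <- gls_profile(y, X, C_off, C_diag, lam_hat)
  if (is.null(g)) stop("covariance not positive definite at fitted lambda")
  s2_df <- g$rss / (n - k)
  XtX_inv <- chol2inv(qr.R(g$qr))
  se <- sqrt(s2_df * diag(XtX_inv))
  tval <- as.vector(g$beta) / se
  pval <- 2 * stats::pt(-abs(tval), df = n - k)

  # intercept-only GLS model at the same lambda for r^2
  g0 <- gls_profile(y, matrix(1, n, 1), C_off, C_diag, lam_hat)
  r2 <- if (g0$rss > 0) 1 - g$rss / g0$rss else NA_real_
  p_pred <- k - as.integer("(Intercept)" %in% colnames(X))
  adj_r2 <- if (n - p_pred - 1 > 0) 1 - (1 - r2) * (n - 1) / (n - p_pred - 1)
            else NA_real_

  coef_tab <- data.frame(estimate = as.vector(g$beta), se = se,
                         t = tval, p = pval,
                         row.names = colnames(X))
  structure(list(coefficients = coef_tab, lambda = lam_hat,
                 lambda_mode = mode, sigma2 = g$s2_ml, loglik = g$loglik,
                 loglik_boundary = boundary,
                 r2 = r2, adj_r2 = adj_r2, n = n, k = k,
                 residuals = as.vector(g$yr - g$Xr %*% g$beta),
                 formula = formula, tip_order = tree$tip.label),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit:", deparse(x$formula), "\n")
  cat(sprintf("  lambda = %.4f (%s)  sigma2 = %.4g  logLik = %.3f\n",
              x$lambda, x$lambda_mode, x$sigma2, x$loglik))
  cat(sprintf("  n = %d  r2 = %.4f  adjusted r2 = %.4f\n",
              x$n, x$r2, x$adj_r2))
  stats::printCoefmat(as.matrix(x$coefficients), P.values = TRUE,
                      has.Pvalue = TRUE)
  invisible(x)
}

#' Maximum-likelihood Brownian-motion ancestral state reconstruction
#'
#' Internal-node states maximise the joint BM likelihood with tip states
#' fixed, i.e. they solve the sparse linear system given by the
#' branch-length-weighted graph Laplacian (weights 1/branch length).  The
#' reported variance of each node state is the conditional variance of
#' that node given the tips, sigma^2 times the corresponding diagonal of
#' the inverse internal-node precision matrix; the 95% CI is the state
#' +/- 1.96 sqrt(variance).  sigma^2 is estimated from the tip likelihood
#' (ML, divisor n, or an n-1 REML-style divisor).
#'
#' @param tree an [ape::phylo] rooted tree.
#' @param x named numeric trait vector covering every tip.
#' @param sigma2_method `"ml"` (divisor n, default) or `"unbiased"`
#'   (divisor n - 1).
#' @return Object of class `"asr_result"`: data frame `states` (node id,
#'   state, var, lower95, upper95), `sigma2`, `root_state`, and a
#'   `degenerate` flag for zero-variance traits.
#' @export
ancestral_states_bm <- function(tree, x, sigma2_method = c("ml", "unbiased")) {
  sigma2_method <- match.arg(sigma2_method)
  ntip <- ape::Ntip(tree); nnode <- tree$Nnode
  if (is.null(names(x))) {
    if (length(x) != ntip) stop("trait vector must cover every tip")
    names(x) <- tree$tip.label
  }
  if (!all(tree$tip.label %in% names(x)))
    stop("trait vector must be named by (all) tip labels")
  x <- x[tree$tip.label]
  if (any(is.na(x))) stop("trait vector must be complete over tips")

  el <- tree$edge.length
  internal_child <- tree$edge[, 2] > ntip
  if (any(el <= 0 & internal_child))
    stop("zero-length internal branches: collapse to a polytomy first")
  if (any(el <= 0))
    stop("zero-length terminal branches make the reconstruction singular")

  ntot <- ntip + nnode
  w <- 1 / el
  L <- matrix(0, ntot, ntot)
  for (e in seq_len(nrow(tree$edge))) {
    i <- tree$edge[e, 1]; j <- tree$edge[e, 2]
    L[i, i] <- L[i, i] + w[e]; L[j, j] <- L[j, j] + w[e]
    L[i, j] <- L[i, j] - w[e]; L[j, i] <- L[j, i] - w[e]
  }
  int <- (ntip + 1):ntot
  L_II <- L[int, int, drop = FALSE]
  L_IT <- L[int, seq_len(ntip), drop = FALSE]
  Sinv <- solve(L_II)
  states <- as.vector(-Sinv %*% (L_IT %*% x))

  # sigma^2 from the tip likelihood (GLS mean at the root)
  C <- ape::vcv(tree)
  Ci <- chol2inv(chol(C))
  ones <- rep(1, ntip)
  mu <- sum(Ci %*% x) / sum(Ci)
  r <- x - mu
  q <- as.numeric(t(r) %*% Ci %*% r)
  s2 <- q / if (sigma2_method == "ml") ntip else ntip - 1
  degenerate <- s2 <= .Machine$double.eps * max(1, mean(x)^2)

  vars <- s2 * diag(Sinv)
  half <- 1.96 * sqrt(pmax(vars, 0))
  out <- data.frame(node = int, state = states, var = vars,
                    lower95 = states - half, upper95 = states + half)
  structure(list(states = out, sigma2 = s2, root_state = states[1],
                 degenerate = degenerate, sigma2_method = sigma2_method,
                 n_tips = ntip),
            class = "asr_result")
}

#' @export
print.asr_result <- function(x, ...) {
  cat("Brownian-motion ancestral states (", nrow(x$states), " nodes, ",
      x$n_tips, " tips)\n", sep = "")
  cat(sprintf("  sigma2 (%s) = %.5g; root = %.4f [%.4f, %.4f]\n",
              x$sigma2_method, x$sigma2, x$root_state,
              x$states$lower95[1], x$states$upper95[1]))
  if (x$degenerate)
    cat("  trait variance ~ 0: confidence intervals are degenerate\n")
  invisible(x)
}
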