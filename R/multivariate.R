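# Group comparisons (tie-corrected Kruskal-Wallis, Dunn post hoc, compact
# letter display) and standardised PCA of climate variables.

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic on midranks with a chi-squared reference
#' distribution on k - 1 degrees of freedom.  When every pooled
#' observation is identical the tie correction degenerates; H is then
#' defined as 0 with p = 1.
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups), or a
#'   numeric vector when `g` supplies group labels.
#' @param g optional factor of group labels.
#' @return List of class `"kw_test"` with `H`, `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(groups, g = NULL) {
  if (!is.null(g)) groups <- split(as.numeric(groups), g)
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stop("need at least 2 non-empty groups")
  x <- unlist(groups, use.names = FALSE)
  lab <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(x) < 5)
    warning("fewer than 5 observations: chi-squared approximation is poor",
            call. = FALSE)
  if (length(unique(x)) == 1) {
    res <- list(H = 0, df = length(groups) - 1, p_value = 1, n = length(x))
  } else {
    kt <- stats::kruskal.test(x, lab)
    res <- list(H = unname(kt$statistic), df = unname(kt$parameter),
                p_value = kt$p.value, n = length(x))
  }
  structure(res, class = "kw_test")
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g (n = %d)\n",
              x$H, x$df, x$p_value, x$n))
  invisible(x)
}

#' Dunn's post hoc rank comparisons
#'
#' Pairwise z-tests on pooled midranks with the tie-corrected Dunn
#' standard error, two-sided p-values adjusted by Holm's method (or
#' pairwise Mann-Whitney tests as an alternative).
#'
#' @param groups list of numeric vectors, or a numeric vector with `g`.
#' @param g optional factor of group labels.
#' @param method `"dunn"` (default) or `"mann_whitney"`.
#' @param p_adjust multiplicity adjustment passed to [stats::p.adjust()].
#' @return Data frame with columns `group1`, `group2`, `statistic`, `p`,
#'   `p_adj`.
#' @export
dunn_posthoc <- function(groups, g = NULL,
                         method = c("dunn", "mann_whitney"),
                         p_adjust = "holm") {
  method <- match.arg(method)
  if (!is.null(g)) groups <- split(as.numeric(groups), g)
  groups <- groups[lengths(groups) > 0]
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  nm <- names(groups)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  lab <- rep(seq_len(k), lengths(groups))
  N <- length(x)
  pairs <- utils::combn(k, 2)
  if (method == "dunn") {
    rk <- rank(x)
    rbar <- tapply(rk, lab, mean)
    ties <- table(x)
    tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
    s2 <- N * (N + 1) / 12 - tie_term
    stat <- p <- numeric(ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      se <- sqrt(s2 * (1 / sum(lab == i1) + 1 / sum(lab == i2)))
      z <- (rbar[i1] - rbar[i2]) / se
      stat[j] <- z
      p[j] <- 2 * stats::pnorm(-abs(z))
    }
  } else {
    stat <- p <- numeric(ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      wt <- suppressWarnings(
        stats::wilcox.test(groups[[pairs[1, j]]], groups[[pairs[2, j]]],
                           exact = FALSE, correct = TRUE))
      stat[j] <- unname(wt$statistic); p[j] <- wt$p.value
    }
  }
  data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
             statistic = stat, p = p,
             p_adj = stats::p.adjust(p, method = p_adjust),
             row.names = NULL)
}

#' Compact letter display from pairwise significance
#'
#' Insert-and-absorb algorithm: groups that share a letter are pairwise
#' non-significant, and the letter set is minimal for the significance
#' graph.  Letters are assigned in group order, so relabelling groups
#' permutes the display consistently.
#'
#' @param groups list of numeric vectors (named), or a numeric vector with
#'   `g`.
#' @param g optional factor of group labels.
#' @param alpha significance level for the adjusted pairwise p-values.
#' @param method,p_adjust passed to [dunn_posthoc()].
#' @return Named character vector of letter strings, one per group.
#' @export
compact_letter_display <- function(groups, g = NULL, alpha = 0.05,
                                   method = "dunn", p_adjust = "holm") {
  if (!is.null(g)) groups <- split(as.numeric(groups), g)
  groups <- groups[lengths(groups) > 0]
  k <- length(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  if (k == 1) return(stats::setNames("a", nm))
  ph <- dunn_posthoc(groups, method = method, p_adjust = p_adjust)
  sig <- ph[ph$p_adj < alpha, , drop = FALSE]
  idx <- function(s) match(s, nm)
  # insert-and-absorb on columns (sets of groups allowed to share a letter)
  cols <- list(seq_len(k))
  for (r in seq_len(nrow(sig))) {
    i <- idx(sig$group1[r]); j <- idx(sig$group2[r])
    for (ci in rev(seq_along(cols))) {
      cc <- cols[[ci]]
      if (i %in% cc && j %in% cc) {
        cols[[ci]] <- setdiff(cc, i)
        cols[[length(cols) + 1]] <- setdiff(cc, j)
      }
    }
    # absorb columns contained in another
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols))
      if (a != b && keep[a] && keep[b] &&
          all(cols[[a]] %in% cols[[b]])) keep[a] <- FALSE
    cols <- cols[keep]
  }
  # deterministic order: by smallest member
  cols <- cols[order(vapply(cols, min, numeric(1)))]
  letters_out <- rep("", k)
  for (ci in seq_along(cols))
    for (gidx in cols[[ci]])
      letters_out[gidx] <- paste0(letters_out[gidx], letters[ci])
  stats::setNames(letters_out, nm)
}

#' Standardised principal component analysis of climate variables
#'
#' Columns are centred and scaled to unit variance (zero-variance columns
#' dropped with a warning) and decomposed by singular values.  Each
#' component's sign is fixed so its largest-magnitude loading is positive,
#' making the orientation reproducible; flip PC1 afterwards if a specific
#' climatic orientation is preferred.
#'
#' @param x numeric matrix or data frame, sites x variables.
#' @return Object of class `"climate_pca"`: `scores` (sites x components),
#'   `loadings` (variables x components), `prop_var` (proportion of total
#'   variance per component), `sdev`, `dropped` (zero-variance columns).
#' @export
climate_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 sites")
  v <- apply(x, 2, stats::var)
  dropped <- colnames(x)[v == 0 | is.na(v)]
  if (length(dropped)) {
    warning("dropping zero-variance column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    x <- x[, !(colnames(x) %in% dropped), drop = FALSE]
  }
  if (ncol(x) < 1) stop("no variable with positive variance")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  rot <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  prop <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = rot, prop_var = prop,
                 sdev = pc$sdev, dropped = dropped),
            class = "climate_pca")
}

#' @export
print.climate_pca <- function(x, ...) {
  cat("Climate PCA:", nrow(x$scores), "sites x", nrow(x$loadings),
      "variables\n")
  np <- min(4, length(x$prop_var))
  cat("  variance shares:",
      paste(sprintf("PC%d %.1f%%", seq_len(np), 100 * x$prop_var[seq_len(np)]),
            collapse = ", "), "\n")
  invisible(x)
}
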