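# Independent oracles used across the suite.

# Brute-force ML ancestral states: numerically maximise the joint BM
# likelihood over internal-node states with tip states fixed (the
# objective is the negative joint log-likelihood kernel, a quadratic in
# the internal states), independently of the linear-system implementation.
asr_brute_force <- function(tree, x) {
  ntip <- ape::Ntip(tree)
  x <- x[tree$tip.label]
  nll <- function(a) {
    states <- c(x, a)
    d <- states[tree$edge[, 2]] - states[tree$edge[, 1]]
    sum(d^2 / tree$edge.length)
  }
  grad <- function(a) {
    states <- c(x, a)
    d <- (states[tree$edge[, 2]] - states[tree$edge[, 1]]) / tree$edge.length
    g <- numeric(length(a))
    for (e in seq_len(nrow(tree$edge))) {
      pa <- tree$edge[e, 1] - ntip
      ch <- tree$edge[e, 2] - ntip
      if (pa >= 1) g[pa] <- g[pa] - 2 * d[e]
      if (ch >= 1) g[ch] <- g[ch] + 2 * d[e]
    }
    g
  }
  a <- rep(mean(x), tree$Nnode)
  for (r in 1:50) {
    o <- stats::optim(a, nll, gr = grad, method = "BFGS",
                      control = list(reltol = 1e-16, maxit = 10000))
    a <- o$par
    if (max(abs(grad(a))) < 1e-12) break
  }
  a
}

# Regression-through-origin slope of phylogenetically independent
# contrasts (Felsenstein), as the lambda = 1 PGLS slope oracle.
pic_slope <- function(tree, y, x) {
  cy <- ape::pic(y[tree$tip.label], tree)
  cx <- ape::pic(x[tree$tip.label], tree)
  sum(cx * cy) / sum(cx * cx)
}

# Write a PV drydown list to a temporary CSV in the reader's layout.
write_pv_csv <- function(obs_list, path = tempfile(fileext = ".csv")) {
  rows <- do.call(rbind, lapply(obs_list, function(o)
    data.frame(leaf_id = o$leaf_id, fresh_mass = o$fresh_mass, psi = o$psi,
               saturated_mass = o$saturated_mass, dry_mass = o$dry_mass,
               leaf_area = o$leaf_area)))
  utils::write.csv(rows, path, row.names = FALSE)
  path
}
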