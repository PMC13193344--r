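# Seeded forward generators for every input the pipeline consumes, with
# known ground truth.  The PV generator uses the standard linear-turgor /
# van't Hoff construction: osmotic potential dilutes with symplastic water,
# turgor declines linearly with symplastic water content, and the two sum
# to the measured water potential.

# derive a deterministic substream seed so adding generators never perturbs
# existing fixtures
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) * 1009L + as.integer(h %% 100003L)) %% 2147483647L
}

#' Ground truth for a simulated pressure-volume drydown
#'
#' @param psi_ft osmotic potential at full turgor (MPa, < 0).
#' @param epsilon bulk modulus of elasticity on the symplastic-water basis
#'   (MPa, must exceed -psi_ft so the turgor loss point exists).
#' @param awf apoplastic water fraction in `[0, 1)`.
#' @param sw,dw,la saturated mass (g), dry mass (g), leaf area (m^2).
#' @param noise_sd_psi,noise_sd_mass Gaussian measurement noise SDs for
#'   water potential (MPa) and mass (g); defaults 0.03 MPa and 0.0005 g,
#'   typical pressure-chamber and 4-point-balance precision.
#' @param psi_step target drydown interval (MPa, default 0.25, matching the
#'   bench protocol's 0.2-0.3 MPa spacing).
#' @param psi_floor protocol drydown endpoint (MPa, default -3.0).  When
#'   the implied turgor loss point approaches the floor, the drydown is
#'   extended to `psi_tlp - n_min_osmotic * psi_step` so the post-TLP
#'   linear region is always sampled (a drydown that stops at turgor loss
#'   cannot yield PV parameters).
#' @param n_min_osmotic minimum number of sampled post-TLP intervals.
#' @param seed optional integer seed.
#' @return List of class `"pv_ground_truth"`, including the implied
#'   `psi_tlp`, `rwc_tlp`, and the effective drydown floor.
#' @export
pv_ground_truth <- function(psi_ft = -1.2, epsilon = 10, awf = 0.25,
                            sw = 0.12, dw = 0.04, la = 0.001,
                            noise_sd_psi = 0.03, noise_sd_mass = 5e-4,
                            psi_step = 0.25, psi_floor = -3.0,
                            n_min_osmotic = 4, seed = NULL) {
  if (psi_ft >= 0) stop("psi_ft must be negative")
  if (epsilon <= -psi_ft)
    stop("epsilon must exceed -psi_ft (turgor loss point must exist)")
  if (awf < 0 || awf >= 1) stop("awf must lie in [0, 1)")
  if (dw >= sw) stop("dry mass must be smaller than saturated mass")
  psi_tlp <- psi_ft * epsilon / (epsilon + psi_ft)
  rs_tlp <- (epsilon + psi_ft) / epsilon
  rwc_tlp <- awf + rs_tlp * (1 - awf)
  if (!is.finite(psi_tlp) || psi_tlp >= psi_ft)
    stop("implied turgor loss point is not below psi_ft")
  floor_eff <- min(psi_floor, psi_tlp - n_min_osmotic * psi_step)
  structure(list(psi_ft = psi_ft, epsilon = epsilon, awf = awf,
                 sw = sw, dw = dw, la = la,
                 noise_sd_psi = noise_sd_psi, noise_sd_mass = noise_sd_mass,
                 psi_step = psi_step, psi_floor = psi_floor,
                 floor_eff = floor_eff, n_min_osmotic = n_min_osmotic,
                 psi_tlp = psi_tlp, rwc_tlp = rwc_tlp, seed = seed),
            class = "pv_ground_truth")
}

# forward model evaluation/inversion for a ground-truth object
pv_forward_psi <- function(rwc, truth)
  pv_model_psi(rwc, truth$psi_ft, truth$epsilon, truth$awf)

pv_forward_rwc <- function(psi, truth)
  pv_model_rwc(psi, truth$psi_ft, truth$epsilon, truth$awf)

#' Simulate a pressure-volume drydown
#'
#' Evaluates the forward PV model on an RWC grid chosen so successive
#' water-potential steps match the bench protocol (`psi_step`, default
#' 0.25 MPa) from full turgor down to the protocol floor, back-computes
#' fresh masses from RWC, and adds Gaussian measurement noise to psi and
#' mass.  Noisy psi values are clamped to be non-positive.
#'
#' @param truth a [pv_ground_truth()].
#' @return A [pv_curve_observation()] with attributes `"truth"` and
#'   `"psi_floor"` (the effective protocol floor used).
#' @export
simulate_pv_curve <- function(truth) {
  stopifnot(inherits(truth, "pv_ground_truth"))
  if (truth$rwc_tlp <= truth$awf)
    stop("degenerate parameters: RWC_TLP does not exceed AWF")
  if (!is.null(truth$seed)) set.seed(substream_seed(truth$seed, "pv"))
  n_steps <- ceiling(-truth$floor_eff / truth$psi_step)
  targets <- -(0:n_steps) * truth$psi_step
  rwc <- pv_forward_rwc(targets, truth)
  rwc[1] <- 1  # psi = 0 at full turgor exactly
  psi <- pv_forward_psi(rwc, truth)
  psi[1] <- 0
  fw <- truth$dw + rwc * (truth$sw - truth$dw)
  if (truth$noise_sd_psi > 0)
    psi <- pmin(psi + stats::rnorm(length(psi), 0, truth$noise_sd_psi), 0)
  if (truth$noise_sd_mass > 0)
    fw <- pmax(fw + stats::rnorm(length(fw), 0, truth$noise_sd_mass),
               truth$dw)
  obs <- suppressWarnings(
    pv_curve_observation("synthetic", fw, psi, truth$sw, truth$dw, truth$la))
  attr(obs, "truth") <- truth
  attr(obs, "psi_floor") <- min(targets)
  obs
}

#' Parameter values the PV estimators target, from the noiseless model
#'
#' Applies the printed estimator definitions analytically to the noiseless
#' forward model (independently of the curve-fitting code): psi_ft, awf and
#' the turgor-loss quantities are closed-form; the elastic modulus is the
#' symplastic turgor slope epsilon/(1 - AWF) times the mean RWC of the
#' initial turgor-loss grid points (turgor at least `turgor_frac` of its
#' maximum); the capacitance slope is the least-squares secant of RWC vs
#' psi over those same noiseless grid points (or the first
#' `initial_slope_points` when given).
#'
#' @param truth a [pv_ground_truth()].
#' @param turgor_frac initial turgor-loss region threshold (default 0.25,
#'   matching [pv_fit_config()]).
#' @param initial_slope_points optional fixed point count for the
#'   capacitance secant.
#' @param water_molar_mass g mol^-1.
#' @return Named numeric vector `psi_tlp`, `psi_ft`, `rwc_tlp`, `awf`,
#'   `epsilon`, `c_bulk`.
#' @export
pv_true_parameters <- function(truth, turgor_frac = 0.25,
                               initial_slope_points = NULL,
                               water_molar_mass = 18.015) {
  n_steps <- ceiling(-truth$floor_eff / truth$psi_step)
  targets <- -(0:n_steps) * truth$psi_step
  rwc <- pv_forward_rwc(targets, truth)
  rwc[1] <- 1
  psi <- pv_forward_psi(rwc, truth)
  psi[1] <- 0
  rs <- (rwc - truth$awf) / (1 - truth$awf)
  turgor <- pmax(0, -truth$psi_ft - truth$epsilon * (1 - rs))
  init <- which(turgor >= turgor_frac * max(turgor))
  if (length(init) < 3) init <- order(-turgor)[1:3]
  eps_est <- truth$epsilon / (1 - truth$awf) * mean(rwc[init])
  cap_idx <- if (is.null(initial_slope_points)) init
             else seq_len(min(initial_slope_points, length(rwc)))
  cs <- ols_line(psi[cap_idx], rwc[cap_idx])
  c_bulk <- cs$slope * (truth$dw / truth$la) * (truth$sw / truth$dw) /
    water_molar_mass
  c(psi_tlp = truth$psi_tlp, psi_ft = truth$psi_ft,
    rwc_tlp = truth$rwc_tlp, awf = truth$awf,
    epsilon = eps_est, c_bulk = c_bulk)
}

#' Simulate a light-response series from the nonrectangular hyperbola
#'
#' @param phi,sat,theta,offset model parameters (see [nrh_response()]).
#' @param kind `"assimilation"` or `"conductance"`.
#' @param noise_sd Gaussian noise SD in response units (default 0.5 for
#'   assimilation-scale data; pass e.g. 0.01 for conductance).
#' @param ppfd PPFD design; default is the standard 9-level sequence
#'   2000, 1600, 1200, 800, 400, 200, 100, 50, 0 umol m^-2 s^-1.
#' @param seed optional integer seed.
#' @return A [light_response_series()] with attribute `"truth"`.
#' @export
simulate_light_curve <- function(phi, sat, theta, offset,
                                 kind = c("assimilation", "conductance"),
                                 noise_sd = 0.5,
                                 ppfd = c(2000, 1600, 1200, 800, 400, 200,
                                          100, 50, 0),
                                 seed = NULL) {
  kind <- match.arg(kind)
  if (theta <= 0 || theta > 1) stop("theta must lie in (0, 1]")
  if (!is.null(seed)) set.seed(substream_seed(seed, "light"))
  y <- nrh_response(ppfd, phi, sat, theta, offset, kind)
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  out <- light_response_series(ppfd, y, kind)
  attr(out, "truth") <- c(phi = phi, sat = sat, theta = theta,
                          offset = offset)
  out
}

#' Simulate a pure-birth ultrametric tree scaled to unit depth
#'
#' @param n_taxa number of tips (>= 3).
#' @param seed optional integer seed.
#' @return An [ape::phylo] tree with depth 1, tips `t1..tn`.
#' @export
simulate_tree <- function(n_taxa, seed = NULL) {
  if (n_taxa < 3) stop("need at least 3 taxa")
  if (!is.null(seed)) set.seed(substream_seed(seed, "tree"))
  tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
  depth <- max(tip_depths(tr))
  tr$edge.length <- tr$edge.length / depth
  annotate_ultrametric(tr)
}

#' Simulate tip traits under lambda-transformed Brownian motion
#'
#' Draws a multivariate normal vector with mean `root_state` and covariance
#' `sigma2 * phylo_covariance(tree, lambda)`.
#'
#' @param tree an [ape::phylo] tree.
#' @param sigma2 Brownian rate.
#' @param lambda phylogenetic signal in `[0, 1]`.
#' @param root_state ancestral mean.
#' @param seed optional integer seed.
#' @return Named numeric vector over the tips.
#' @export
simulate_bm_traits <- function(tree, sigma2 = 1, lambda = 1,
                               root_state = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(substream_seed(seed, "bm"))
  C <- phylo_covariance(tree, lambda)
  R <- chol(sigma2 * C)
  z <- stats::rnorm(nrow(C))
  stats::setNames(root_state + as.vector(t(R) %*% z), rownames(C))
}

#' Simulate a climate matrix with a planted dominant component
#'
#' One-factor model x_ij = l_j f_i + e_ij over 19 variables emulating the
#' standard bioclimatic set: temperature/precipitation means load
#' positively on the factor, seasonality variables negatively.
#'
#' @param n_sites number of sites.
#' @param loadings length-19 loading vector; the default mixes positive
#'   (means) and negative (seasonality/range) loadings.
#' @param factor_sd SD of the latent site factor.
#' @param noise_sd SD of the idiosyncratic noise.
#' @param seed optional integer seed.
#' @return Numeric matrix sites x 19 (`bio1..bio19`) with attribute
#'   `"loadings"`.
#' @export
simulate_climate <- function(n_sites,
                             loadings = NULL,
                             factor_sd = 1, noise_sd = 0.3, seed = NULL) {
  if (is.null(loadings))
    loadings <- c(1, -0.6, 0.4, -0.8, 0.7, 0.5, 0.6, 0.9, 0.3, 0.8,
                  0.4, 1, 0.7, -0.7, 0.8, 0.6, 0.9, -0.5, 0.5)
  if (length(loadings) != 19)
    stop("loading vector must have length 19")
  if (!is.null(seed)) set.seed(substream_seed(seed, "climate"))
  f <- stats::rnorm(n_sites, 0, factor_sd)
  eps <- matrix(stats::rnorm(n_sites * 19, 0, noise_sd), n_sites, 19)
  x <- outer(f, loadings) + eps
  dimnames(x) <- list(paste0("site", seq_len(n_sites)),
                      paste0("bio", 1:19))
  attr(x, "loadings") <- loadings
  x
}

#' Simulate a complete comparative study
#'
#' Emulates the structure of a multi-population grass water-relations
#' study: 13 populations in five photosynthetic-type x ploidy groups
#' (3 x C3-2x, 3 x C3-C4-2x, 3 x C4-2x, 3 x C4-6x, 1 x C4-12x), each with
#' `n_replicates` leaves, on a pure-birth phylogeny whose topology groups
#' conspecific types together.  C4 populations get higher minor vein
#' density, bundle-sheath area, apoplastic fraction, capacitance and
#' hydraulic conductance, and a less negative d13C; polyploids get thicker
#' leaves.  A 19-variable climate matrix with a planted dominant component
#' is attached.  All numbers are seed-deterministic.
#'
#' @param seed integer seed.
#' @param n_replicates leaves per population (default 3).
#' @return List with `tree`, `populations` (id, group, d13c), `truths`
#'   (per-population PV ground truths), `pv_curves` (population x replicate
#'   list), `light_assim`, `light_cond` (per population x replicate),
#'   `spots` (data frame of evaporative-flux measurements), `anatomy`
#'   (list of [anatomy_record()]), `climate` (matrix).
#' @export
simulate_study <- function(seed = 1, n_replicates = 3) {
  groups <- c(rep("C3-2x", 3), rep("C3-C4-2x", 3), rep("C4-2x", 3),
              rep("C4-6x", 3), "C4-12x")
  n_pop <- length(groups)
  ids <- sprintf("pop%02d", seq_len(n_pop))
  # ladderise so neighbouring tips get consecutive ids: groups then sit
  # together on the tree, giving the traits mild phylogenetic structure
  tree <- ape::ladderize(simulate_tree(n_pop, seed = seed))
  tree$tip.label <- ids
  set.seed(substream_seed(seed, "study"))

  is_c4 <- grepl("^C4", groups)
  ploidy <- ifelse(grepl("12x$", groups), 12, ifelse(grepl("6x$", groups), 6, 2))

  d13c <- ifelse(is_c4, stats::rnorm(n_pop, -12.5, 0.8),
                 ifelse(groups == "C3-C4-2x", stats::rnorm(n_pop, -25, 0.8),
                        stats::rnorm(n_pop, -27, 0.8)))

  # per-population PV ground truths: C4 higher AWF and capacitance-relevant
  # mass ratios; small among-population scatter
  truths <- vector("list", n_pop)
  for (i in seq_len(n_pop)) {
    awf_i <- (if (is_c4[i]) 0.30 else if (groups[i] == "C3-C4-2x") 0.22
              else 0.15) + stats::rnorm(1, 0, 0.02)
    eps_i <- max(6, 10 + stats::rnorm(1, 0, 1.5))
    ft_i <- -1.2 + stats::rnorm(1, 0, 0.1)
    sw_i <- if (is_c4[i]) 0.14 else 0.11
    truths[[i]] <- pv_ground_truth(
      psi_ft = ft_i, epsilon = eps_i, awf = min(max(awf_i, 0.05), 0.45),
      sw = sw_i, dw = 0.04, la = 0.001,
      seed = substream_seed(seed, paste0("pvtruth", i)))
  }

  pv_curves <- list()
  for (i in seq_len(n_pop)) for (r in seq_len(n_replicates)) {
    tr <- truths[[i]]
    tr$seed <- substream_seed(seed, paste0("pv", i, "_", r))
    obs <- simulate_pv_curve(tr)
    obs$leaf_id <- sprintf("%s_leaf%d", ids[i], r)
    pv_curves[[obs$leaf_id]] <- obs
  }

  light_assim <- list(); light_cond <- list()
  for (i in seq_len(n_pop)) for (r in seq_len(n_replicates)) {
    key <- sprintf("%s_leaf%d", ids[i], r)
    asat <- (if (is_c4[i]) 30 else 20) + stats::rnorm(1, 0, 1.5)
    gsat <- (if (is_c4[i]) 0.25 else 0.35) + stats::rnorm(1, 0, 0.02)
    light_assim[[key]] <- simulate_light_curve(
      phi = 0.06, sat = asat, theta = 0.7, offset = 1.5,
      kind = "assimilation", noise_sd = 0.5,
      seed = substream_seed(seed, paste0("la", i, "_", r)))
    light_assim[[key]]$id <- key
    light_cond[[key]] <- simulate_light_curve(
      phi = 0.0008, sat = gsat, theta = 0.7, offset = 0.02,
      kind = "conductance", noise_sd = 0.005,
      seed = substream_seed(seed, paste0("lc", i, "_", r)))
    light_cond[[key]]$id <- key
  }

  # evaporative-flux spot measurements: C4 higher K_leaf
  spots <- do.call(rbind, lapply(seq_len(n_pop), function(i) {
    k_true <- (if (is_c4[i]) 6 else 4) + stats::rnorm(n_replicates, 0, 0.4)
    E <- pmax(stats::rnorm(n_replicates, 2, 0.2), 0.5)
    psi_stem <- stats::rnorm(n_replicates, -0.3, 0.03)
    psi_leaf <- psi_stem - E / k_true
    data.frame(id = sprintf("%s_leaf%d", ids[i], seq_len(n_replicates)),
               population = ids[i], E = E, psi_stem = psi_stem,
               psi_leaf = psi_leaf)
  }))

  anatomy <- lapply(seq_len(n_pop), function(i) {
    width <- 4 + stats::rnorm(1, 0, 0.3)
    minor <- round((if (is_c4[i]) 7 else 3) * width + stats::rnorm(1, 0, 1.5))
    major <- round(1.5 * width + stats::rnorm(1, 0, 0.8))
    lt <- c(`2` = 150, `6` = 210, `12` = 260)[as.character(ploidy[i])] +
      stats::rnorm(1, 0, 10)
    bsa_scale <- if (is_c4[i]) 60 else 25  # um^2 per um width
    ibsa <- bsa_scale * width * 1000 * stats::runif(1, 0.9, 1.1)
    pbsa <- 0.8 * bsa_scale * width * 1000 * stats::runif(1, 0.9, 1.1)
    anatomy_record(major_vein_count = max(major, 1),
                   minor_vein_count = max(minor, 0),
                   leaf_width = width, leaf_thickness = lt,
                   total_ibsa = ibsa, total_pbsa = pbsa,
                   d13c = d13c[i], id = ids[i])
  })
  names(anatomy) <- ids

  climate <- simulate_climate(n_pop, seed = substream_seed(seed, "clim"))
  rownames(climate) <- ids

  list(tree = tree,
       populations = data.frame(id = ids, group = groups, ploidy = ploidy,
                                d13c = d13c, row.names = ids),
       truths = stats::setNames(truths, ids),
       pv_curves = pv_curves,
       light_assim = light_assim, light_cond = light_cond,
       spots = spots, anatomy = anatomy, climate = climate,
       seed = seed, n_replicates = n_replicates)
}
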