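#' leafhydro: leaf hydraulics, pressure-volume analysis and phylogenetic
#' comparative methods
#'
#' Tools for analysing leaf water relations in grasses: pressure-volume (PV)
#' curve parameter extraction, light-response curve fitting, leaf hydraulic
#' conductance, anatomical trait derivation, and a phylogenetic comparative
#' layer (PGLS with Pagel's lambda, Brownian-motion ancestral states,
#' Kruskal-Wallis group comparisons, climate PCA).  Every input can be
#' simulated with a known ground truth (see [simulate_pv_curve()],
#' [simulate_light_curve()], [simulate_tree()], [simulate_climate()],
#' [simulate_study()]), so the full pipeline ([run_pipeline()]) runs without
#' field data.
#'
#' @keywords internal
#' @aliases leafhydro-package
"_PACKAGE"

# ---------------------------------------------------------------------------
# Domain types.  Plain lists with S3 classes, in the style of ape/phytools:
# constructors validate, validators return a character vector of problems so
# that readers can report per-record issues with row context.
# ---------------------------------------------------------------------------

#' Construct a single-leaf pressure-volume drydown observation
#'
#' Holds one leaf's bench-drying series: paired fresh mass and leaf water
#' potential measurements in drying order, plus the saturated mass, dry mass
#' and leaf area needed to convert mass to relative water content and to
#' express capacitance per unit area.
#'
#' @param leaf_id character scalar identifying the leaf.
#' @param fresh_mass numeric vector of fresh masses (g), in measurement order.
#' @param psi numeric vector of leaf water potentials (MPa, <= 0), same
#'   length as `fresh_mass`.
#' @param saturated_mass saturated (fully rehydrated) mass SW (g).
#' @param dry_mass oven-dry mass DW (g).
#' @param leaf_area one-sided leaf area (m^2).
#' @param psi_increase_tol tolerated transient increase in psi between
#'   successive measurements (MPa) before the overall drying trend is
#'   flagged; default 0.05 MPa, about instrument precision.
#'
#' @return An object of class `"pv_curve_observation"`.  Validation problems
#'   (if any) are stored in `attr(x, "flags")` and raised as a warning.
#' @seealso [compute_rwc()], [derive_pv_parameters()], [read_pv_curves()]
#' @export
pv_curve_observation <- function(leaf_id, fresh_mass, psi, saturated_mass,
                                 dry_mass, leaf_area,
                                 psi_increase_tol = 0.05) {
  obj <- structure(
    list(leaf_id = as.character(leaf_id)[1],
         fresh_mass = as.numeric(fresh_mass),
         psi = as.numeric(psi),
         saturated_mass = as.numeric(saturated_mass)[1],
         dry_mass = as.numeric(dry_mass)[1],
         leaf_area = as.numeric(leaf_area)[1]),
    class = "pv_curve_observation")
  flags <- validate_pv_curve_observation(obj, psi_increase_tol)
  attr(obj, "flags") <- flags
  if (length(flags))
    warning("pv_curve_observation '", obj$leaf_id, "': ",
            paste(flags, collapse = "; "), call. = FALSE)
  obj
}

#' Validate a pressure-volume observation
#'
#' @param x a `"pv_curve_observation"`.
#' @param psi_increase_tol tolerated transient psi increase (MPa).
#' @return Character vector of problems (empty if the object is valid).
#' @export
validate_pv_curve_observation <- function(x, psi_increase_tol = 0.05) {
  p <- character()
  n <- length(x$fresh_mass)
  if (n != length(x$psi))
    p <- c(p, "fresh_mass and psi differ in length")
  if (n < 6)
    p <- c(p, sprintf("only %d points (need >= 6)", n))
  if (!is.finite(x$dry_mass) || !is.finite(x$saturated_mass) ||
      x$dry_mass >= x$saturated_mass)
    p <- c(p, "dry mass must be smaller than saturated mass")
  if (!is.finite(x$leaf_area) || x$leaf_area <= 0)
    p <- c(p, "leaf area must be positive")
  if (any(!is.finite(x$fresh_mass)) || any(!is.finite(x$psi)))
    p <- c(p, "non-finite mass or psi values")
  else {
    if (any(x$fresh_mass < x$dry_mass - 1e-12) ||
        any(x$fresh_mass > 1.02 * x$saturated_mass))
      p <- c(p, "fresh mass outside [DW, 1.02*SW]")
    if (any(x$psi > 0))
      p <- c(p, "positive leaf water potential")
    if (n == length(x$psi) && n > 1 &&
        any(diff(x$psi) > psi_increase_tol))
      p <- c(p, "psi series not non-increasing beyond tolerance")
  }
  p
}

#' @export
print.pv_curve_observation <- function(x, ...) {
  cat("PV drydown for leaf '", x$leaf_id, "': ", length(x$psi), " points, ",
      "psi in [", round(min(x$psi), 3), ", ", round(max(x$psi), 3),
      "] MPa\n  SW = ", x$saturated_mass, " g, DW = ", x$dry_mass,
      " g, LA = ", x$leaf_area, " m^2\n", sep = "")
  fl <- attr(x, "flags")
  if (length(fl)) cat("  flags:", paste(fl, collapse = "; "), "\n")
  invisible(x)
}

#' Construct a light-response series
#'
#' A set of paired photosynthetic photon flux density (PPFD) levels and
#' responses, either net CO2 assimilation or stomatal conductance, to be
#' fitted with a nonrectangular hyperbola.
#'
#' @param ppfd PPFD levels (umol m^-2 s^-1, >= 0).
#' @param response response values: net assimilation A_n
#'   (umol m^-2 s^-1) or stomatal conductance g_s (mol m^-2 s^-1).
#' @param kind `"assimilation"` or `"conductance"`.
#' @param id optional curve identifier.
#' @return An object of class `"light_response_series"`.
#' @seealso [fit_nonrectangular_hyperbola()], [simulate_light_curve()]
#' @export
light_response_series <- function(ppfd, response,
                                  kind = c("assimilation", "conductance"),
                                  id = NA_character_) {
  kind <- match.arg(kind)
  ppfd <- as.numeric(ppfd); response <- as.numeric(response)
  if (length(ppfd) != length(response))
    stop("ppfd and response must have the same length")
  if (any(ppfd < 0)) stop("PPFD must be non-negative")
  if (length(unique(ppfd)) < 5)
    stop("need at least 5 distinct PPFD levels")
  structure(list(ppfd = ppfd, response = response, kind = kind,
                 id = as.character(id)[1]),
            class = "light_response_series")
}

#' Construct a spot hydraulics measurement
#'
#' One evaporative-flux measurement: transpiration of a freely transpiring
#' leaf together with the water potentials of that leaf and of an adjacent
#' bagged (non-transpiring) leaf used as a stem water potential assay.
#'
#' @param E transpiration rate (mmol m^-2 s^-1, >= 0).
#' @param psi_stem stem water potential (MPa), from the covered leaf.
#' @param psi_leaf leaf water potential of the transpiring leaf (MPa).
#' @param id optional identifier.
#' @return An object of class `"spot_hydraulics"`.
#' @seealso [compute_kleaf()]
#' @export
spot_hydraulics <- function(E, psi_stem, psi_leaf, id = NA_character_) {
  if (any(E < 0)) stop("transpiration must be non-negative")
  structure(list(E = as.numeric(E), psi_stem = as.numeric(psi_stem),
                 psi_leaf = as.numeric(psi_leaf), id = as.character(id)[1]),
            class = "spot_hydraulics")
}

#' Construct an anatomy record
#'
#' Cross-section measurements for one leaf: vein counts, bundle-sheath areas
#' (inner and parenchymatous), leaf width and thickness, and the leaf
#' carbon-isotope composition used to classify the photosynthetic type.
#'
#' @param major_vein_count,minor_vein_count integer counts per cross-section
#'   (major = 2 degree veins; minor = 3-5 degree veins).
#' @param leaf_width leaf (section) width in mm.
#' @param leaf_thickness leaf thickness in um.
#' @param total_ibsa,total_pbsa total inner / parenchymatous bundle-sheath
#'   cross-sectional areas per section (um^2).
#' @param d13c carbon isotope composition (per mil); may be `NA`.
#' @param id optional identifier.
#' @return An object of class `"anatomy_record"`.
#' @seealso [vein_densities()], [bsa_per_leaf_width()],
#'   [classify_photosynthetic_type()]
#' @export
anatomy_record <- function(major_vein_count, minor_vein_count, leaf_width,
                           leaf_thickness, total_ibsa, total_pbsa,
                           d13c = NA_real_, id = NA_character_) {
  if (any(c(major_vein_count, minor_vein_count) < 0))
    stop("vein counts must be non-negative")
  if (leaf_width <= 0) stop("leaf width must be positive")
  if (any(c(total_ibsa, total_pbsa) < 0))
    stop("bundle-sheath areas must be non-negative")
  structure(list(major_vein_count = major_vein_count,
                 minor_vein_count = minor_vein_count,
                 leaf_width = leaf_width, leaf_thickness = leaf_thickness,
                 total_ibsa = total_ibsa, total_pbsa = total_pbsa,
                 d13c = d13c, id = as.character(id)[1]),
            class = "anatomy_record")
}

# ---------------------------------------------------------------------------
# Newick trees (ape backend) with an ultrametricity flag
# ---------------------------------------------------------------------------

#' Read a rooted tree from a Newick file and verify ultrametricity
#'
#' Parses a Newick file (branch lengths required), checks that tip labels
#' are unique, and flags whether the tree is ultrametric within a relative
#' tolerance of the mean root-to-tip depth.  Non-ultrametric trees are
#' accepted with a warning so they can still be inspected; comparative
#' operations check the flag.
#'
#' @param path path to a Newick file, or a Newick string when `text = TRUE`.
#' @param text logical; interpret `path` as Newick text.
#' @param tol relative ultrametricity tolerance (default 1e-6).
#' @return An [ape::phylo] object with attributes `"ultrametric"` (logical)
#'   and `"depth"` (mean root-to-tip depth).
#' @export
read_newick <- function(path, text = FALSE, tol = 1e-6) {
  tree <- if (text) ape::read.tree(text = path) else ape::read.tree(path)
  if (is.null(tree)) stop("failed to parse Newick input")
  if (is.null(tree$edge.length))
    stop("Newick input has no branch lengths")
  if (anyDuplicated(tree$tip.label))
    stop("duplicated tip labels in tree")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths in tree")
  annotate_ultrametric(tree, tol)
}

annotate_ultrametric <- function(tree, tol = 1e-6) {
  depths <- tip_depths(tree)
  mu <- mean(depths)
  ultra <- mu > 0 && max(abs(depths - mu)) / mu < tol
  if (!ultra)
    warning("tree is not ultrametric within tolerance ", tol, call. = FALSE)
  attr(tree, "ultrametric") <- ultra
  attr(tree, "depth") <- mu
  tree
}

# root-to-tip path lengths, in tip order
tip_depths <- function(tree) {
  nd <- ape::node.depth.edgelength(tree)
  nd[seq_len(ape::Ntip(tree))]
}

#' Write a tree to a Newick file
#'
#' @param tree an [ape::phylo] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Reconcile a phylogeny with a trait table
#'
#' Drops tree tips absent from the table and table rows absent from the
#' tree, with a warning listing what was pruned, so that comparative
#' operations always see matching label sets (mirroring the usual trimming
#' of a larger species tree to the studied accessions).
#'
#' @param tree an [ape::phylo] object.
#' @param table a data frame whose row names are tip labels.
#' @return A list with elements `tree` and `table`, rows of `table` ordered
#'   as `tree$tip.label`.
#' @export
match_tree_table <- function(tree, table) {
  tips <- tree$tip.label
  rows <- rownames(table)
  if (is.null(rows)) stop("trait table must have row names (tip labels)")
  common <- intersect(tips, rows)
  if (length(common) < 3)
    stop("fewer than 3 labels shared between tree and table")
  drop_tips <- setdiff(tips, common)
  drop_rows <- setdiff(rows, common)
  if (length(drop_tips))
    warning("pruning ", length(drop_tips), " tree tip(s) absent from table: ",
            paste(drop_tips, collapse = ", "), call. = FALSE)
  if (length(drop_rows))
    warning("dropping ", length(drop_rows), " table row(s) absent from tree: ",
            paste(drop_rows, collapse = ", "), call. = FALSE)
  if (length(drop_tips)) tree <- ape::drop.tip(tree, drop_tips)
  table <- table[tree$tip.label, , drop = FALSE]
  list(tree = tree, table = table)
}

# ---------------------------------------------------------------------------
# CSV readers.  Comma-separated, header required, '.' decimal separator,
# "" or "NA" as missing; columns located by an explicit mapping so field
# layouts can vary.
# ---------------------------------------------------------------------------

read_study_csv <- function(path) {
  df <- utils::read.csv(path, header = TRUE, na.strings = c("", "NA"),
                        stringsAsFactors = FALSE)
  df
}

require_columns <- function(df, mapping, path) {
  missing <- setdiff(unname(mapping), names(df))
  if (length(missing))
    stop("file '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

as_numeric_col <- function(df, col, path) {
  x <- df[[col]]
  if (is.numeric(x)) return(x)
  y <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(y))
  if (length(bad))
    stop("non-numeric values in column '", col, "' of '", path,
         "' at row(s) ", paste(bad, collapse = ", "))
  y
}

#' Read pressure-volume drydown curves from a CSV file
#'
#' Expects one row per measurement, with a leaf identifier column grouping
#' rows into curves; the saturated mass, dry mass and leaf area must be
#' constant within a leaf.  Column names are located through `mapping` so
#' arbitrary field layouts can be ingested.
#'
#' @param path CSV path.
#' @param mapping named character vector mapping the canonical field names
#'   `leaf_id`, `fresh_mass`, `psi`, `saturated_mass`, `dry_mass`,
#'   `leaf_area` to the file's column names.
#' @return A list of [pv_curve_observation()] objects.  Records that fail
#'   validation carry their problems in `attr(x, "flags")` (a warning is
#'   emitted with row context).  An empty file yields an empty list with a
#'   warning.
#' @export
read_pv_curves <- function(path,
                           mapping = c(leaf_id = "leaf_id",
                                       fresh_mass = "fresh_mass",
                                       psi = "psi",
                                       saturated_mass = "saturated_mass",
                                       dry_mass = "dry_mass",
                                       leaf_area = "leaf_area")) {
  df <- read_study_csv(path)
  if (nrow(df) == 0) {
    warning("'", path, "' contains no data rows", call. = FALSE)
    return(list())
  }
  require_columns(df, mapping, path)
  for (f in c("fresh_mass", "psi", "saturated_mass", "dry_mass", "leaf_area"))
    df[[mapping[[f]]]] <- as_numeric_col(df, mapping[[f]], path)
  ids <- as.character(df[[mapping[["leaf_id"]]]])
  out <- lapply(unique(ids), function(id) {
    rows <- which(ids == id)
    sub <- df[rows, ]
    obs <- withCallingHandlers(
      pv_curve_observation(
        leaf_id = id,
        fresh_mass = sub[[mapping[["fresh_mass"]]]],
        psi = sub[[mapping[["psi"]]]],
        saturated_mass = sub[[mapping[["saturated_mass"]]]][1],
        dry_mass = sub[[mapping[["dry_mass"]]]][1],
        leaf_area = sub[[mapping[["leaf_area"]]]][1]),
      warning = function(w) {
        warning("rows ", rows[1], "-", rows[length(rows)], ": ",
                conditionMessage(w), call. = FALSE)
        invokeRestart("muffleWarning")
      })
    obs
  })
  names(out) <- unique(ids)
  out
}

#' Read light-response curves from a CSV file
#'
#' @param path CSV path.
#' @param kind `"assimilation"` or `"conductance"`.
#' @param mapping named character vector mapping `curve_id`, `ppfd` and
#'   `response` to the file's column names.
#' @return A list of [light_response_series()] objects.
#' @export
read_light_curves <- function(path,
                              kind = c("assimilation", "conductance"),
                              mapping = c(curve_id = "curve_id",
                                          ppfd = "ppfd",
                                          response = "response")) {
  kind <- match.arg(kind)
  df <- read_study_csv(path)
  if (nrow(df) == 0) {
    warning("'", path, "' contains no data rows", call. = FALSE)
    return(list())
  }
  require_columns(df, mapping, path)
  for (f in c("ppfd", "response"))
    df[[mapping[[f]]]] <- as_numeric_col(df, mapping[[f]], path)
  ids <- as.character(df[[mapping[["curve_id"]]]])
  out <- lapply(unique(ids), function(id) {
    sub <- df[ids == id, ]
    light_response_series(sub[[mapping[["ppfd"]]]],
                          sub[[mapping[["response"]]]],
                          kind = kind, id = id)
  })
  names(out) <- unique(ids)
  out
}

#' Read a population-level trait table
#'
#' Rows are populations/accessions (row identifiers must match tree tip
#' labels when the table is used in comparative operations); columns are
#' named numeric traits plus optional label columns (e.g. a photosynthetic
#' type x ploidy group).  Missing values stay `NA`.
#'
#' @param path CSV path.
#' @param id_column name of the column holding row identifiers.
#' @return A data frame with row names set from `id_column`.
#' @export
read_trait_table <- function(path, id_column = "population") {
  df <- read_study_csv(path)
  if (!id_column %in% names(df))
    stop("file '", path, "' lacks identifier column '", id_column, "'")
  if (anyDuplicated(df[[id_column]]))
    stop("duplicated identifiers in '", path, "'")
  rownames(df) <- as.character(df[[id_column]])
  df[[id_column]] <- NULL
  df
}

#' Write a tidy trait table with a JSON run-metadata sidecar
#'
#' @param table data frame (one row per leaf/population).
#' @param path output CSV path; the sidecar is written to `<path>.meta.json`.
#' @param metadata named list of run metadata (seed, config, etc.).  The
#'   package version and timestamp-free provenance fields are added.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path, metadata = list()) {
  df <- cbind(id = rownames(table), table)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- c(list(package = "leafhydro",
                 version = as.character(utils::packageVersion("leafhydro"))),
            metadata)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
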