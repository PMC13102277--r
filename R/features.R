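# Per-cell feature extraction: 11 base quantities spanning cluster-level
# properties, localization densities, qPAINT binding kinetics, and spatial
# neighbourhood organization, each summarized per cell by mean, SD, min and
# max -> 44 features.

feature_bases <- c(
  n_locs            = "localizations per cluster",
  radius_gyr_nm     = "cluster radius of gyration (nm)",
  hull_area_nm2     = "cluster convex-hull area (nm^2)",
  cluster_loc_dens  = "localization density inside cluster (per nm^2)",
  cell_loc_dens     = "cell-level localization density (per um^2)",
  tau_d_s           = "cluster mean dark time (s)",
  tau_b_s           = "cluster mean bright time (s)",
  inv_tau_d         = "cluster 1/tau_d (1/s)",
  self_nn_nm        = "nearest-neighbour distance between cluster centers (nm)",
  cross_nn_nm       = "distance from cluster center to nearest partner localization (nm)",
  cross_count_150   = "partner localizations within 150 nm of cluster center")

feature_stats <- c("mean", "sd", "min", "max")

#' Feature registry
#'
#' Names and definitions of all 44 per-cell features: 11 base quantities
#' x 4 summary statistics (mean, SD, min, max). Single-valued cell-level
#' quantities degenerate to SD = 0 and min = max = mean.
#'
#' @return Tibble `name`, `base`, `stat`, `description`.
#' @export
feature_registry <- function() {
  tidyr::expand_grid(base = names(feature_bases), stat = feature_stats) |>
    dplyr::mutate(name = paste(.data$base, .data$stat, sep = "_"),
                  description = paste(unname(feature_bases[.data$base]),
                                      "-", .data$stat)) |>
    dplyr::select("name", "base", "stat", "description")
}

summarise4 <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) == 0) return(c(mean = NA_real_, sd = NA_real_,
                               min = NA_real_, max = NA_real_))
  c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
    min = min(v), max = max(v))
}

#' Extract the 44-feature vector of one cell
#'
#' @param clusters Filtered cluster tibble for the cell's target.
#' @param kinetics [extract_kinetics()] output for those clusters.
#' @param density One-row [densities()] output for the cell.
#' @param partner_locs Optional partner-target [loc_table()] (for the
#'   cross-target features; absent partner leaves them `NA`).
#' @param r_nm Cross-count radius (nm).
#' @return Named numeric vector of length 44 (registry order). Cells with
#'   zero clusters yield all-`NA` features with attribute `flagged = TRUE`.
#' @export
extract_features <- function(clusters, kinetics, density, partner_locs = NULL,
                             r_nm = 150) {
  reg <- feature_registry()
  if (nrow(clusters) == 0) {
    out <- stats::setNames(rep(NA_real_, nrow(reg)), reg$name)
    attr(out, "flagged") <- TRUE
    return(out)
  }
  unflagged <- kinetics[!kinetics$flagged, ]
  base_vals <- list(
    n_locs = as.numeric(clusters$n_locs),
    radius_gyr_nm = clusters$radius_of_gyration_nm,
    hull_area_nm2 = clusters$convex_hull_area_nm2,
    cluster_loc_dens = ifelse(clusters$convex_hull_area_nm2 > 0,
                              clusters$n_locs / clusters$convex_hull_area_nm2,
                              NA_real_),
    cell_loc_dens = density$locs_per_um2,
    tau_d_s = unflagged$tau_d_s,
    tau_b_s = kinetics$tau_b_s,
    inv_tau_d = unflagged$inv_tau_d_per_s,
    self_nn_nm = if (nrow(clusters) >= 2)
      nn_distances(clusters, mode = "self") else NA_real_,
    cross_nn_nm = if (!is.null(partner_locs) && nrow(partner_locs) > 0)
      nn_distances(clusters, partner_locs, mode = "cross") else NA_real_,
    cross_count_150 = if (!is.null(partner_locs) && nrow(partner_locs) > 0) {
      cw <- cpp_count_within(clusters$center_x, clusters$center_y,
                             partner_locs$x, partner_locs$y, r_nm)
      as.numeric(cw[, 1])
    } else NA_real_)
  out <- unlist(lapply(base_vals, summarise4))
  names(out) <- paste(rep(names(base_vals), each = 4), feature_stats, sep = "_")
  out <- out[reg$name]
  attr(out, "flagged") <- FALSE
  out
}

#' Assemble a feature matrix over cells
#'
#' @param feature_list Named list of [extract_features()] vectors
#'   (names = cell ids).
#' @param conditions Character vector of condition labels, parallel to
#'   `feature_list`.
#' @param target Target label.
#' @return Tibble: `cell_id`, `condition`, `target`, then the 44 feature
#'   columns. Flagged (zero-cluster) cells are dropped with a message.
#' @export
build_feature_matrix <- function(feature_list, conditions, target = NA_character_) {
  flagged <- vapply(feature_list, function(f) isTRUE(attr(f, "flagged")), logical(1))
  if (any(flagged))
    message("dropping ", sum(flagged), " cell(s) with zero clusters: ",
            paste(names(feature_list)[flagged], collapse = ", "))
  fl <- feature_list[!flagged]
  conds <- conditions[!flagged]
  mat <- do.call(rbind, fl)
  dplyr::bind_cols(
    tibble(cell_id = names(fl) %||% as.character(seq_along(fl)),
           condition = conds, target = target),
    as_tibble(mat))
}

#' Impute missing feature values
#'
#' Per-condition median imputation (falling back to the global median);
#' imputed cells/columns are recorded in attribute `imputed`.
#'
#' @param fm A [build_feature_matrix()] tibble.
#' @return The imputed tibble.
#' @export
impute_features <- function(fm) {
  feat_cols <- feature_registry()$name
  imputed <- list()
  for (cc in feat_cols) {
    miss <- !is.finite(fm[[cc]])
    if (!any(miss)) next
    med_by_cond <- tapply(fm[[cc]][!miss], fm$condition[!miss], stats::median)
    fill <- med_by_cond[fm$condition[miss]]
    fill[is.na(fill)] <- stats::median(fm[[cc]][!miss])
    fm[[cc]][miss] <- fill
    imputed[[cc]] <- fm$cell_id[miss]
  }
  attr(fm, "imputed") <- imputed
  fm
}
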