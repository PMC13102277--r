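# Spatial statistics: densities per masked area, self/cross
# nearest-neighbour distances, cumulative cross-target proximity profiles
# with AUC comparison, and between-condition density testing.

#' Cluster and localization densities per masked cell area
#'
#' Clusters whose centers fall outside the mask are excluded (and reported
#' in attribute `excluded`); localizations outside the mask are likewise
#' excluded from the localization density.
#'
#' @param clusters Cluster tibble ([dbscan_clusters()] output).
#' @param table The corresponding [loc_table()].
#' @param mask A [cell_mask()].
#' @return One-row tibble: `cell_id`, `condition`, `target`, `n_clusters`,
#'   `clusters_per_um2`, `n_locs`, `locs_per_um2`, `mask_area_um2`.
#' @export
densities <- function(clusters, table, mask) {
  if (mask$area_um2 <= 0) stop("mask area must be positive", call. = FALSE)
  inside_c <- if (nrow(clusters)) in_mask(clusters$center_x, clusters$center_y, mask)
              else logical(0)
  inside_l <- if (nrow(table)) in_mask(table$x, table$y, mask) else logical(0)
  out <- tibble(
    cell_id = table$cell_id[1] %||% NA_character_,
    condition = table$condition[1] %||% NA_character_,
    target = table$target[1] %||% NA_character_,
    n_clusters = sum(inside_c),
    clusters_per_um2 = sum(inside_c) / mask$area_um2,
    n_locs = sum(inside_l),
    locs_per_um2 = sum(inside_l) / mask$area_um2,
    mask_area_um2 = mask$area_um2)
  attr(out, "excluded") <- clusters[!inside_c, , drop = FALSE]
  out
}

as_xy <- function(p) {
  if (is.matrix(p)) return(cbind(x = p[, 1], y = p[, 2]))
  if (all(c("center_x", "center_y") %in% names(p)))
    return(cbind(x = p$center_x, y = p$center_y))
  cbind(x = p$x, y = p$y)
}

#' Nearest-neighbour distances
#'
#' Per point of `a`, the Euclidean distance to the nearest point of `b`.
#' In `"self"` mode (`b` defaults to `a`) the point's own zero distance is
#' excluded.
#'
#' @param a,b Point sets: two-column matrices, or data frames with
#'   `x`/`y` or `center_x`/`center_y` columns.
#' @param mode `"self"` or `"cross"`.
#' @return Numeric vector of distances (nm), one per point of `a`.
#' @export
nn_distances <- function(a, b = NULL, mode = c("self", "cross")) {
  mode <- match.arg(mode)
  pa <- as_xy(a)
  pb <- if (mode == "self") pa else as_xy(b)
  if (nrow(pb) == 0) stop("empty reference point set", call. = FALSE)
  if (mode == "self" && nrow(pa) < 2)
    stop("self mode needs at least 2 points", call. = FALSE)
  cpp_nn_dist(pa[, 1], pa[, 2], pb[, 1], pb[, 2], mode == "self")
}

#' Cumulative cross-target proximity profile
#'
#' For each A-cluster center, counts B-localizations within distance
#' `r` for r on the edges `0, bin_nm, ..., r_max_nm`, then averages over
#' centers: the mean number of B-localizations within r of an A cluster.
#' The AUC is the trapezoidal area under the mean cumulative curve.
#'
#' @param centers_a Cluster centers (matrix or tibble with
#'   `center_x`/`center_y`); at least one.
#' @param locs_b Partner-target localizations (tibble with `x`/`y`).
#' @param r_max_nm,bin_nm Profile range and bin size in nm.
#' @return Object of class `cumulative_profile`: tibble `edge_nm`,
#'   `mean_count`; attributes `auc`, `n_centers`, `per_center` (raw count
#'   matrix).
#' @export
cumulative_profile <- function(centers_a, locs_b, r_max_nm = 150, bin_nm = 10) {
  ca <- as_xy(centers_a)
  if (nrow(ca) < 1) stop("need at least one cluster center", call. = FALSE)
  cb <- as_xy(locs_b)
  edges <- seq(0, r_max_nm, by = bin_nm)
  counts <- if (nrow(cb) > 0)
    cpp_count_within(ca[, 1], ca[, 2], cb[, 1], cb[, 2], edges)
  else matrix(0, nrow(ca), length(edges))
  mean_count <- colMeans(counts)
  out <- tibble(edge_nm = edges, mean_count = mean_count)
  class(out) <- c("cumulative_profile", class(out))
  attr(out, "auc") <- profile_auc(edges, mean_count)
  attr(out, "n_centers") <- nrow(ca)
  attr(out, "per_center") <- counts
  out
}

profile_auc <- function(edges, counts) {
  sum(diff(edges) * (utils::head(counts, -1) + utils::tail(counts, -1)) / 2)
}

#' Aggregate per-cell profiles
#'
#' Cell-level mean and SD of the cumulative curves per bin, plus per-cell
#' AUCs, ready for plotting and testing.
#'
#' @param profiles Named list of [cumulative_profile()]s (names = cell ids)
#'   or a list of lists per condition.
#' @param conditions Optional character vector parallel to `profiles`.
#' @return List with `curve` (tibble `condition`, `edge_nm`, `mean`, `sd`)
#'   and `auc` (tibble `cell_id`, `condition`, `auc`).
#' @export
aggregate_profiles <- function(profiles, conditions = NULL) {
  if (is.null(conditions)) conditions <- rep(NA_character_, length(profiles))
  cells <- names(profiles) %||% as.character(seq_along(profiles))
  auc <- tibble(cell_id = cells, condition = conditions,
                auc = vapply(profiles, function(p) attr(p, "auc"), numeric(1)))
  curves <- purrr::map2_dfr(profiles, conditions, function(p, cond)
    tibble(condition = cond, edge_nm = p$edge_nm, count = p$mean_count))
  curve <- curves |>
    dplyr::group_by(.data$condition, .data$edge_nm) |>
    dplyr::summarise(mean = mean(.data$count),
                     sd = stats::sd(.data$count), .groups = "drop")
  list(curve = curve, auc = auc)
}

#' Compare proximity AUCs between conditions
#'
#' Per-cell AUCs of each condition are compared against the reference
#' condition with a two-sided Mann-Whitney U test.
#'
#' @param auc_table Tibble `cell_id`, `condition`, `auc`.
#' @param reference Reference condition (default `"resting"`, else the
#'   first condition present).
#' @return Tibble `condition`, `n_cells`, `median_auc`, `auc_ratio`
#'   (vs. reference median), `p_value`, `note`.
#' @export
compare_auc <- function(auc_table, reference = "resting") {
  conds <- unique(auc_table$condition)
  if (!reference %in% conds) reference <- conds[1]
  ref <- auc_table$auc[auc_table$condition == reference]
  purrr::map_dfr(conds, function(cond) {
    v <- auc_table$auc[auc_table$condition == cond]
    if (cond == reference)
      return(tibble(condition = cond, n_cells = length(v),
                    median_auc = stats::median(v), auc_ratio = 1,
                    p_value = NA_real_, note = "reference"))
    if (length(v) < 2 || length(ref) < 2)
      return(tibble(condition = cond, n_cells = length(v),
                    median_auc = stats::median(v),
                    auc_ratio = stats::median(v) / stats::median(ref),
                    p_value = NA_real_, note = "skipped: < 2 cells"))
    p <- mann_whitney_p(v, ref)
    tibble(condition = cond, n_cells = length(v),
           median_auc = stats::median(v),
           auc_ratio = stats::median(v) / stats::median(ref),
           p_value = p, note = "")
  })
}

# two-sided Mann-Whitney U; exact when possible, tie-corrected normal
# approximation otherwise
mann_whitney_p <- function(x, y) {
  has_ties <- anyDuplicated(c(x, y)) > 0
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = !has_ties, correct = TRUE)$p.value)
}

#' Significance labels
#' @param p Numeric p-values.
#' @return `"***"` (p <= 0.001), `"**"` (p <= 0.01), `"*"` (p <= 0.05),
#'   else `"n.s."`.
#' @export
signif_label <- function(p) {
  dplyr::case_when(is.na(p) ~ NA_character_,
                   p <= 0.001 ~ "***",
                   p <= 0.01 ~ "**",
                   p <= 0.05 ~ "*",
                   TRUE ~ "n.s.")
}

#' Pairwise density tests between conditions
#'
#' Two-sided Mann-Whitney U test for every pair of conditions, with
#' significance labels at 0.05 / 0.01 / 0.001.
#'
#' @param density_table Tibble with `condition` and a value column.
#' @param value Name of the value column (default `"clusters_per_um2"`).
#' @return Tibble `condition_a`, `condition_b`, `n_a`, `n_b`, `p_value`,
#'   `label`.
#' @export
density_test <- function(density_table, value = "clusters_per_um2") {
  conds <- unique(density_table$condition)
  if (length(conds) < 2) stop("need >= 2 conditions", call. = FALSE)
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    a <- density_table[[value]][density_table$condition == pr[1]]
    b <- density_table[[value]][density_table$condition == pr[2]]
    p <- if (length(a) < 2 || length(b) < 2) NA_real_ else mann_whitney_p(a, b)
    tibble(condition_a = pr[1], condition_b = pr[2],
           n_a = length(a), n_b = length(b),
           p_value = p, label = signif_label(p))
  })
}
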