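# Per-cell embedding: z-scored 44-feature vectors -> 2-D UMAP -> k-means
# with k = number of experimental conditions.

zscore_cols <- function(mat) {
  mu <- colMeans(mat)
  sd <- apply(mat, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1  # constant columns map to 0
  sweep(sweep(mat, 2, mu), 2, sd, "/")
}

#' Embed cells and partition into condition-level groups
#'
#' Standardizes the feature columns (z-score per column), projects cells
#' into 2-D with UMAP (Euclidean metric, `n_neighbors = 15`,
#' `min_dist = 0.1` by default, single-threaded for exact seed
#' reproducibility), and partitions the embedding with k-means. `k`
#' defaults to the number of distinct conditions. Cluster labels are
#' renumbered by descending cluster size so runs are comparable.
#'
#' @param fm Feature matrix from [build_feature_matrix()] (after
#'   [impute_features()] if needed).
#' @param k Number of k-means clusters; default = number of conditions.
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @param seed Integer seed controlling UMAP and k-means.
#' @return Object of class `paint_embedding`: tibble `cell_id`,
#'   `condition`, `target`, `umap1`, `umap2`, `cluster`; attributes `k`,
#'   `seed`, `kmeans`.
#' @export
embed_and_partition <- function(fm, k = NULL, n_neighbors = 15, min_dist = 0.1,
                                seed = 42L) {
  feat_cols <- intersect(feature_registry()$name, names(fm))
  mat <- as.matrix(fm[, feat_cols])
  if (any(!is.finite(mat)))
    stop("feature matrix contains missing values; run impute_features() first",
         call. = FALSE)
  if (is.null(k)) k <- length(unique(fm$condition))
  if (nrow(mat) < k)
    stop("fewer cells (", nrow(mat), ") than clusters k = ", k, call. = FALSE)
  z <- zscore_cols(mat)
  nn <- min(n_neighbors, nrow(z) - 1)
  set.seed(seed)
  emb <- uwot::umap(z, n_neighbors = nn, min_dist = min_dist,
                    metric = "euclidean", init = "pca",
                    n_threads = 1, n_sgd_threads = 1)
  set.seed(seed)
  km <- stats::kmeans(emb, centers = min(k, nrow(unique(emb))), nstart = 25,
                      iter.max = 100)
  # canonical labels: descending cluster size, ties by first appearance
  sizes <- table(km$cluster)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  labels <- unname(relabel[as.character(km$cluster)])
  out <- tibble(cell_id = fm$cell_id, condition = fm$condition,
                target = fm$target %||% NA_character_,
                umap1 = emb[, 1], umap2 = emb[, 2],
                cluster = as.integer(labels))
  class(out) <- c("paint_embedding", class(out))
  attr(out, "k") <- k
  attr(out, "seed") <- seed
  attr(out, "kmeans") <- km
  out
}

#' Condition composition of embedding clusters
#'
#' @param embedding A `paint_embedding`.
#' @return Tibble `cluster`, `condition`, `n`, `fraction`; fractions sum to
#'   1 within each cluster.
#' @export
composition_table <- function(embedding) {
  as_tibble(embedding) |>
    dplyr::count(.data$cluster, .data$condition, name = "n") |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
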