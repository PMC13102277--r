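# Batch orchestration: conditions x cells x targets through the full chain
# (postprocess -> qPAINT -> spatial -> features/embedding), with a
# structured log and deterministic, seed-reproducible outputs.

#' Pipeline parameters
#'
#' @param pixel_size_nm Camera pixel size for file reading.
#' @param exposure_s Frame time (s).
#' @param link_max_dark Maximum dark gap (frames) for event linking.
#' @param min_locs DBSCAN minimum localizations per cluster.
#' @param eps_factor DBSCAN radius as a multiple of the NeNA precision.
#' @param link_factor Linking radius as a multiple of the NeNA precision.
#' @param kinetic_mode Mean-frame filter mode (`"auto"`, `"paper"`,
#'   `"explicit"`).
#' @param kinetic_range Kept range for `"explicit"` mode.
#' @param xi An [influx_rate()], or `"calibrate"` is not supported at the
#'   pipeline level (calibrate separately with [calibrate_influx()]).
#' @param primary_target Target whose cluster centers anchor the
#'   cross-target profile (default: first target in the manifest).
#' @param reference_condition Reference for all comparisons.
#' @param r_max_nm,bin_nm Proximity-profile range and bin size.
#' @param k Number of k-means clusters (default: number of conditions).
#' @param drift_correct Apply fiducial drift correction when fiducial
#'   tracks can be identified (simulator `kind` column).
#' @param seed Root seed for the stochastic stages (UMAP, k-means).
#' @return List of class `pipeline_params`.
#' @export
pipeline_params <- function(pixel_size_nm = 158, exposure_s = 0.1,
                            link_max_dark = 1L, min_locs = 7L,
                            eps_factor = 1, link_factor = 4,
                            kinetic_mode = "auto", kinetic_range = NULL,
                            xi = influx_rate(), primary_target = NULL,
                            reference_condition = "resting",
                            r_max_nm = 150, bin_nm = 10, k = NULL,
                            drift_correct = FALSE, seed = 42L) {
  structure(as.list(environment()), class = "pipeline_params")
}

#' Validate a run manifest
#'
#' A manifest has one row per (condition, cell, target) with file paths:
#' columns `condition`, `cell_id`, `target`, `locs`, `mask`.
#'
#' @param manifest Manifest tibble.
#' @return The manifest (sorted deterministically), or an error.
#' @export
validate_manifest <- function(manifest) {
  need <- c("condition", "cell_id", "target", "locs", "mask")
  miss <- setdiff(need, names(manifest))
  if (length(miss) > 0)
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(manifest) == 0) stop("manifest is empty", call. = FALSE)
  for (f in unique(c(manifest$locs, manifest$mask)))
    if (!file.exists(f)) stop("manifest file not found: ", f, call. = FALSE)
  dplyr::arrange(as_tibble(manifest), .data$condition, .data$cell_id, .data$target)
}

process_cell_target <- function(locs_path, mask, params) {
  raw <- read_locs(locs_path, pixel_size_nm = params$pixel_size_nm)
  log <- list(n_locs_raw = nrow(raw))
  if (params$drift_correct && "kind" %in% names(raw) &&
      any(startsWith(raw$kind, "fiducial"))) {
    raw <- correct_drift(raw, fiducial_tracks_from_kind(raw))
    log$fiducial_rms_nm <- attr(raw, "fiducial_rms_nm")
  }
  if ("kind" %in% names(raw))
    raw <- raw[!startsWith(raw$kind, "fiducial"), ]
  nena <- nena_precision(raw)
  linked <- link_localizations(raw, nena$sigma_nena_nm,
                               max_dark_frames = params$link_max_dark)
  log$n_locs_linked <- nrow(linked)
  clusters <- dbscan_clusters(linked, params$eps_factor * nena$sigma_nena_nm,
                              min_locs = params$min_locs)
  log$n_noise_locs <- sum(attr(clusters, "labels") == 0)
  log$n_clusters_dbscan <- nrow(clusters)
  kept <- kinetic_filter(clusters, mode = params$kinetic_mode,
                         range_frames = params$kinetic_range)
  log$n_clusters_kept <- nrow(kept)
  log$n_clusters_rejected <- nrow(attr(kept, "rejected"))
  kin <- extract_kinetics(kept, linked, params$exposure_s)
  dens <- densities(kept, linked, mask)
  list(raw = raw, nena = nena, linked = linked, clusters = kept,
       kinetics = kin, density = dens, log = log)
}

#' Run the full analysis pipeline
#'
#' Executes, per cell and target: precision estimation, optional drift
#' correction, event linking, DBSCAN isolation, kinetic filtering, qPAINT
#' kinetics and densities; then per cell: the cross-target proximity
#' profile; then per condition: oligomer mixture fits (monomer position
#' fixed from the reference condition) with jackknife uncertainties and
#' z-score comparisons, AUC and density tests; and finally the per-target
#' 44-feature embedding with k-means partitioning. A failure in one cell
#' is recorded and the run continues.
#'
#' @param manifest See [validate_manifest()].
#' @param params A [pipeline_params()].
#' @return List of class `paint_report` with elements `nena`, `densities`,
#'   `density_tests`, `profile_curves`, `auc`, `auc_tests`, `mixtures`,
#'   `oligomer_tests`, `features`, `embedding`, `log`, `errors`, `params`.
#' @export
run_pipeline <- function(manifest, params = pipeline_params()) {
  manifest <- validate_manifest(manifest)
  targets <- unique(manifest$target)
  primary <- params$primary_target %||% targets[1]
  cells <- dplyr::distinct(manifest, .data$condition, .data$cell_id)

  per_ct <- list(); logs <- list(); errors <- list()
  for (i in seq_len(nrow(cells))) {
    cond <- cells$condition[i]; cid <- cells$cell_id[i]
    rows <- manifest[manifest$condition == cond & manifest$cell_id == cid, ]
    mask <- load_mask(rows$mask[1])
    for (j in seq_len(nrow(rows))) {
      key <- paste(cond, cid, rows$target[j], sep = "|")
      res <- tryCatch(process_cell_target(rows$locs[j], mask, params),
                      error = function(e) e)
      if (inherits(res, "error")) {
        errors[[key]] <- conditionMessage(res)
      } else {
        per_ct[[key]] <- c(res, list(condition = cond, cell_id = cid,
                                     target = rows$target[j], mask = mask))
        logs[[key]] <- tibble(condition = cond, cell_id = cid,
                              target = rows$target[j],
                              !!!res$log[lengths(res$log) == 1])
      }
    }
  }

  ok <- function(tg) Filter(function(r) r$target == tg, per_ct)
  nena_tbl <- purrr::map_dfr(per_ct, function(r)
    tibble(condition = r$condition, cell_id = r$cell_id, target = r$target,
           sigma_nena_nm = r$nena$sigma_nena_nm, n_pairs = r$nena$n_pairs))
  dens_tbl <- purrr::map_dfr(per_ct, "density")
  dens_tests <- purrr::map_dfr(targets, function(tg) {
    sub <- dens_tbl[dens_tbl$target == tg, ]
    if (length(unique(sub$condition)) < 2) return(tibble())
    dplyr::mutate(density_test(sub), target = tg, .before = 1)
  })

  # cross-target proximity: primary-target cluster centers vs partner events
  partner <- setdiff(targets, primary)[1]
  profiles <- list(); prof_conds <- character(0)
  if (!is.na(partner)) {
    for (i in seq_len(nrow(cells))) {
      kp <- paste(cells$condition[i], cells$cell_id[i], primary, sep = "|")
      kq <- paste(cells$condition[i], cells$cell_id[i], partner, sep = "|")
      if (is.null(per_ct[[kp]]) || is.null(per_ct[[kq]])) next
      if (nrow(per_ct[[kp]]$clusters) == 0) next
      profiles[[cells$cell_id[i]]] <-
        cumulative_profile(per_ct[[kp]]$clusters, per_ct[[kq]]$linked,
                           r_max_nm = params$r_max_nm, bin_nm = params$bin_nm)
      prof_conds <- c(prof_conds, cells$condition[i])
    }
  }
  prof <- if (length(profiles) > 0) aggregate_profiles(profiles, prof_conds)
          else list(curve = tibble(), auc = tibble())
  auc_tests <- if (nrow(prof$auc) > 0 &&
                   length(unique(prof$auc$condition)) > 1)
    compare_auc(prof$auc, reference = params$reference_condition)
  else tibble()

  # qPAINT mixtures per target, mu1 fixed from the reference condition
  mixtures <- list(); olig_tests <- list()
  for (tg in targets) {
    rs <- ok(tg)
    conds <- unique(vapply(rs, `[[`, character(1), "condition"))
    vals_by_cond <- lapply(stats::setNames(conds, conds), function(cn) {
      rr <- Filter(function(r) r$condition == cn, rs)
      stats::setNames(lapply(rr, function(r)
        r$kinetics$inv_tau_d_per_s[!r$kinetics$flagged]),
        vapply(rr, `[[`, character(1), "cell_id"))
    })
    ref <- params$reference_condition
    if (!ref %in% conds) ref <- conds[1]
    ref_vals <- unlist(vals_by_cond[[ref]], use.names = FALSE)
    if (length(ref_vals) < 50) next
    mu1 <- fit_oligomer_mixture(ref_vals)$mu1
    for (cn in conds) {
      v <- vals_by_cond[[cn]]
      if (length(unlist(v)) < 50) next
      jk <- tryCatch(mixture_jackknife(v, mu1 = mu1), error = function(e) NULL)
      if (is.null(jk)) next
      mixtures[[paste(tg, cn, sep = "|")]] <-
        dplyr::mutate(jk, target = tg, condition = cn, .before = 1)
    }
    for (cn in setdiff(conds, ref)) {
      a <- mixtures[[paste(tg, ref, sep = "|")]]
      b <- mixtures[[paste(tg, cn, sep = "|")]]
      if (is.null(a) || is.null(b)) next
      olig_tests[[paste(tg, cn, sep = "|")]] <-
        dplyr::mutate(compare_oligomer_areas(a, b),
                      target = tg, condition = cn, .before = 1)
    }
  }

  # features + embedding per target
  feats <- list(); embeddings <- list()
  for (tg in targets) {
    rs <- ok(tg)
    if (length(rs) == 0) next
    fl <- lapply(rs, function(r) {
      pk <- paste(r$condition, r$cell_id,
                  if (tg == primary) partner else primary, sep = "|")
      plocs <- if (!is.na(partner) && !is.null(per_ct[[pk]]))
        per_ct[[pk]]$linked else NULL
      extract_features(r$clusters, r$kinetics, r$density, plocs,
                       r_nm = params$r_max_nm)
    })
    names(fl) <- vapply(rs, `[[`, character(1), "cell_id")
    fm <- build_feature_matrix(fl, vapply(rs, `[[`, character(1), "condition"),
                               target = tg)
    fm <- impute_features(fm)
    feats[[tg]] <- fm
    k <- params$k %||% length(unique(fm$condition))
    if (nrow(fm) >= k && nrow(fm) >= 3)
      embeddings[[tg]] <- embed_and_partition(fm, k = k, seed = params$seed)
  }

  structure(list(
    nena = nena_tbl, densities = dens_tbl, density_tests = dens_tests,
    profile_curves = prof$curve, auc = prof$auc, auc_tests = auc_tests,
    mixtures = dplyr::bind_rows(mixtures),
    oligomer_tests = dplyr::bind_rows(olig_tests),
    features = feats, embedding = embeddings,
    log = dplyr::bind_rows(logs),
    errors = errors, params = params,
    n_failed = length(errors)), class = "paint_report")
}

#' @exportS3Method base::print
print.paint_report <- function(x, ...) {
  cat("<paint_report>\n")
  cat("  cells x targets processed:", nrow(x$log), "; failed:", x$n_failed, "\n")
  cat("  conditions:", paste(unique(x$densities$condition), collapse = ", "), "\n")
  cat("  sections: nena, densities, density_tests, profile_curves, auc,",
      "auc_tests,\n    mixtures, oligomer_tests, features, embedding, log\n")
  invisible(x)
}

#' Write a machine-readable report
#'
#' Writes each tabular section as CSV plus a combined JSON report.
#'
#' @param report A `paint_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("nena", "densities", "density_tests", "profile_curves", "auc",
            "auc_tests", "mixtures", "oligomer_tests", "log")
  js <- list()
  for (tb in tabs) {
    t <- report[[tb]]
    if (is.null(t) || nrow(t) == 0) next
    readr::write_csv(t, file.path(dir, paste0(tb, ".csv")), progress = FALSE)
    js[[tb]] <- t
  }
  for (tg in names(report$features))
    readr::write_csv(report$features[[tg]],
                     file.path(dir, paste0("features_", tg, ".csv")),
                     progress = FALSE)
  for (tg in names(report$embedding)) {
    readr::write_csv(as_tibble(report$embedding[[tg]]),
                     file.path(dir, paste0("embedding_", tg, ".csv")),
                     progress = FALSE)
    js[[paste0("composition_", tg)]] <- composition_table(report$embedding[[tg]])
  }
  js$errors <- report$errors
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Simulate a complete multitarget study on disk
#'
#' Generates, for each condition and cell, a two-target (EGFR + Grb2)
#' Exchange-PAINT dataset with the paper-style presets, writes the
#' localization containers and mask files, and returns a run manifest.
#'
#' @param out_dir Output directory.
#' @param conditions Condition names (must be valid [sim_preset()] names).
#' @param n_cells Cells per condition (recycled).
#' @param seed Root seed; per-cell seeds are derived deterministically.
#' @param mask_side_um Side of the square cell mask.
#' @param ... Overrides passed to [sim_preset()].
#' @return Manifest tibble (`condition`, `cell_id`, `target`, `locs`,
#'   `mask`); ground truths in attribute `ground_truth`.
#' @export
simulate_study <- function(out_dir, conditions = c("resting", "EGF_1min"),
                           n_cells = 2, seed = 1L, mask_side_um = 10, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_cells <- rep_len(n_cells, length(conditions))
  rows <- list(); gts <- list()
  counter <- 0L
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    for (cell in seq_len(n_cells[ci])) {
      counter <- counter + 1L
      cid <- sprintf("%s_cell%02d", cond, cell)
      mask <- square_mask(mask_side_um)
      mask_path <- file.path(out_dir, paste0(cid, "_mask.json"))
      save_mask(mask, mask_path)
      for (tg in c("EGFR", "Grb2")) {
        cfg <- sim_preset(condition = cond, target = tg, mask = mask,
                          cell_id = cid,
                          seed = (seed * 10007L + counter * 211L +
                                    ifelse(tg == "EGFR", 0L, 101L)) %% 2147483647L,
                          ...)
        sim <- simulate_cell(cfg)
        locs_path <- file.path(out_dir, paste0(cid, "_", tg, ".hdf5"))
        write_locs(sim$locs, locs_path)
        rows[[paste(cid, tg)]] <- tibble(condition = cond, cell_id = cid,
                                         target = tg, locs = locs_path,
                                         mask = mask_path)
        gts[[paste(cid, tg)]] <- sim$ground_truth
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)
  attr(manifest, "ground_truth") <- gts
  manifest
}
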