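## End-to-end feature extraction: cloud -> per-tree table.

#' Extract per-tree features from a point cloud
#'
#' Runs the full chain: progressive TIN ground filtering, DEM and CHM
#' construction, high-vegetation detection, watershed crown
#' segmentation, and per-tree height / crown radius; in TLS mode a
#' breast-height circle fit adds DBH per detected tree.
#'
#' @param cloud a [point_cloud].
#' @param mode `"ALS"` or `"TLS"` (selects the published parameter sets).
#' @param cell_size CHM/DEM cell size in m (default 0.25 ALS, 0.10 TLS).
#' @param ground_params a [ground_filter_params].
#' @param veg_params a [vegetation_params]; default by mode.
#' @param seg_params a [segmentation_params]; default by mode.
#' @param dbh_args list of extra arguments to [estimate_dbh()] (TLS).
#' @return list with `trees` (a `tree_records` data frame: `x`, `y` =
#'   apex or fitted stem centre, `H_m`, `R_m`, and `DBH_cm` for TLS),
#'   `segments`, `dem`, `chm`, and the classified `cloud`.
#' @export
extract_tree_features <- function(cloud, mode = c("ALS", "TLS"),
                                  cell_size = NULL,
                                  ground_params = ground_filter_params(),
                                  veg_params = NULL,
                                  seg_params = NULL,
                                  dbh_args = list()) {
  mode <- match.arg(mode)
  cell_size <- cell_size %||% if (mode == "ALS") 0.25 else 0.10
  veg_params <- veg_params %||%
    if (mode == "ALS") vegetation_params() else vegetation_params_tls()
  seg_params <- seg_params %||%
    if (mode == "ALS") segmentation_params(chm_cell_size = cell_size)
    else segmentation_params_tls()
  seg_params$chm_cell_size <- cell_size
  seg_params$min_height <- veg_params$lower_height
  cls <- filter_ground(cloud, ground_params)
  dem <- build_dem(cls, cell_size)
  chm <- build_chm(cls, dem, cell_size)
  norm <- normalize_heights(cls, dem)
  veg_mask <- detect_high_vegetation(norm, veg_params)
  veg_cloud <- subset_cloud(norm, veg_mask)
  segs <- segment_crowns(chm, seg_params, cloud = veg_cloud)
  H <- if (nrow(segs)) extract_tree_height(segs, chm) else numeric(0)
  trees <- data.frame(tree_id = segs$segment_id, plot_id = NA_integer_,
                      species = NA_character_,
                      x = segs$apex_x, y = segs$apex_y,
                      H_m = H, DBH_cm = NA_real_, R_m = segs$R_m,
                      W_ref_kg = NA_real_, source = mode)
  if (mode == "TLS" && nrow(trees)) {
    for (i in seq_len(nrow(trees))) {
      fit <- do.call(estimate_dbh,
                     c(list(cloud = norm,
                            seed_xy = c(trees$x[i], trees$y[i])), dbh_args))
      if (fit$ok) {
        trees$DBH_cm[i] <- fit$dbh_cm
        trees$x[i] <- fit$center[1]
        trees$y[i] <- fit$center[2]
      }
    }
  }
  trees <- if (nrow(trees)) as_tree_records(trees) else trees
  list(trees = trees, segments = segs, dem = dem, chm = chm, cloud = cls)
}
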