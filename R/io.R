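## CSV/YAML/JSON plumbing: segment tables, run configuration, result export.
## CSV dialect: UTF-8, comma-separated, '.' decimal, mandatory header; dose
## factor columns always on the 1e-11 Gy s^-1 per Bq g^-1 scale.

#' Read or write a segment table
#'
#' One row per segment; `dims` and `coverage` are `;`-delimited lists. The
#' write/read round trip is the identity on the data model.
#'
#' @param path CSV file path.
#' @return `readSegmentTable`: data.frame.
#' @export
readSegmentTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "segment_id", "shape", "dims", "ct_th", "coverage",
            "tb_th", "tb_sp", "bvtv", "bvtv_min", "bvtv_max", "marrow_mass")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("segment table ", path, " lacks columns: ",
         paste(miss, collapse = ", "))
  for (i in seq_len(nrow(tab))) {
    nd <- SHAPE_NDIMS[tab$shape[i]]
    if (is.na(nd))
      stop("row ", i, ": unknown shape '", tab$shape[i], "'")
    if (length(parseDims(tab$dims[i])) != nd)
      stop("row ", i, " column 'dims': expected ", nd, " values")
  }
  tab
}

#' @rdname readSegmentTable
#' @param tab segment data.frame (the layout of [readSegmentTable()]).
#' @export
writeSegmentTable <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize SegmentSpec objects to a segment table
#'
#' @param segments list of [SegmentSpec-class] objects.
#' @return data.frame in the segment-table layout.
#' @export
segmentsToTable <- function(segments) {
  do.call(rbind, lapply(segments, function(s) {
    v <- s@variability
    data.frame(
      site = s@site_id, segment_id = s@segment_id, shape = s@shape@kind,
      dims = paste(s@shape@dims, collapse = ";"),
      ct_th = s@ct_th,
      coverage = paste(as.integer(s@cortical_coverage), collapse = ";"),
      tb_th = s@micro@tb_th, tb_sp = s@micro@tb_sp, bvtv = s@micro@bvtv,
      bvtv_min = s@micro@bvtv_range[1], bvtv_max = s@micro@bvtv_range[2],
      marrow_mass = s@marrow_mass,
      macro_cv = v@macro_cv[1], ct_th_cv = v@ct_th_cv,
      tb_th_cv = v@tb_th_cv, tb_sp_cv = v@tb_sp_cv,
      stringsAsFactors = FALSE)
  }))
}

#' Read and validate a run configuration (YAML or JSON)
#'
#' Recognized fields: `nuclide`, `seed`, `resolution` (absolute cm) or
#' `resolution_tbth` (multiple of Tb.Th), `rho`, `n_realizations`,
#' `n_outer`, `n_inner`, `budget_overrides`, `paths`. Unknown nuclides and
#' nonpositive sizes fail validation.
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return validated named list with defaults filled in.
#' @export
readRunConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- list(nuclide = "Sr90", seed = 1L, rho = 0.5,
                   n_realizations = 12L, n_outer = 400L, n_inner = 250L,
                   resolution_tbth = 0.75)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  checkNuclide(cfg$nuclide)
  if (cfg$rho < 0 || cfg$rho >= 1) stop("config: rho must be in [0, 1)")
  for (k in c("n_realizations", "n_outer", "n_inner"))
    if (cfg[[k]] < 1) stop("config: ", k, " must be >= 1")
  if (!is.null(cfg$resolution) && cfg$resolution <= 0)
    stop("config: resolution must be positive")
  cfg
}

#' Write skeletal dose-factor results
#'
#' @param results list of [SkeletalDF-class] objects.
#' @param path_csv,path_json output paths (either may be `NULL`).
#' @return invisibly, the result data.frame.
#' @export
writeResults <- function(results, path_csv = NULL, path_json = NULL) {
  tab <- do.call(rbind, lapply(results, function(r) data.frame(
    nuclide = r@nuclide, source = r@source, mean = r@mean,
    ci_low = r@ci90[1], ci_high = r@ci90[2],
    delta_shared = r@delta_shared, delta_unshared = r@delta_unshared,
    delta_overall = r@delta_overall, stringsAsFactors = FALSE)))
  if (!is.null(path_csv))
    utils::write.csv(tab, path_csv, row.names = FALSE, quote = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(tab, path_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(tab)
}
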