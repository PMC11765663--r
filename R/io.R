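#' Read and write point clouds
#'
#' Plain-text point cloud I/O. `read_point_cloud()` dispatches on
#' `format` (or the file extension): whitespace-separated XYZ text with
#' an optional fourth scanner-id column, or ASCII PLY with `x`, `y`, `z`
#' vertex properties and an optional `scanner` property. Coordinates are
#' meters. Missing scanner ids default to 0.
#'
#' @param path file path.
#' @param format `"xyz"` or `"ply"`; guessed from the extension when
#'   missing.
#' @return data.frame with `x`, `y`, `z`, `scanner_id`.
#' @export
read_point_cloud <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("xyz", "ply")) format <- "xyz"
  }
  switch(match.arg(format, c("xyz", "ply")),
         xyz = read_xyz(path),
         ply = read_ply(path))
}

#' @rdname read_point_cloud
#' @param points data.frame with `x`, `y`, `z` and optionally
#'   `scanner_id`, or an n-by-3 matrix.
#' @export
write_point_cloud <- function(points, path, format = NULL) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("xyz", "ply")) format <- "xyz"
  }
  switch(match.arg(format, c("xyz", "ply")),
         xyz = write_xyz(points, path),
         ply = write_ply(points, path))
}

#' @rdname read_point_cloud
#' @export
read_xyz <- function(path) {
  df <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = "numeric"),
    error = function(e) stop("parse error in XYZ file '", path, "': ",
                             conditionMessage(e)))
  if (ncol(df) < 3) stop("parse error in XYZ file '", path, "': fewer than 3 columns")
  out <- data.frame(x = df[[1]], y = df[[2]], z = df[[3]])
  out$scanner_id <- if (ncol(df) >= 4) as.integer(df[[4]]) else 0L
  out
}

#' @rdname read_point_cloud
#' @export
write_xyz <- function(points, path) {
  pts <- as_point_df(points)
  utils::write.table(
    format(pts[, c("x", "y", "z", "scanner_id")], digits = 17, trim = TRUE,
           scientific = FALSE),
    path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_point_cloud
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || trimws(lines[1]) != "ply") {
    stop("parse error in PLY file '", path, "': missing 'ply' magic (line 1)")
  }
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end)) stop("parse error in PLY file '", path, "': no end_header")
  hdr <- trimws(lines[seq_len(hdr_end)])
  if (!any(grepl("^format\\s+ascii", hdr))) {
    stop("parse error in PLY file '", path, "': only ASCII PLY is supported")
  }
  vline <- grep("^element\\s+vertex\\s+", hdr, value = TRUE)
  if (length(vline) != 1) stop("parse error in PLY file '", path,
                               "': expected one vertex element")
  nv <- as.integer(sub("^element\\s+vertex\\s+", "", vline))
  vpos <- grep("^element\\s+vertex\\s+", hdr)
  later_elem <- grep("^element\\s+", hdr)
  next_elem <- later_elem[later_elem > vpos]
  pend <- if (length(next_elem)) next_elem[1] else hdr_end
  props <- sub("^property\\s+\\S+\\s+", "",
               grep("^property\\s+", hdr[(vpos + 1):(pend - 1)], value = TRUE))
  need <- match(c("x", "y", "z"), props)
  if (anyNA(need)) stop("parse error in PLY file '", path,
                        "': vertex element lacks x/y/z properties")
  body <- lines[(hdr_end + 1):(hdr_end + nv)]
  vals <- tryCatch(
    matrix(scan(text = body, quiet = TRUE), nrow = nv, byrow = TRUE),
    error = function(e) stop("parse error in PLY file '", path,
                             "' vertex records: ", conditionMessage(e)))
  if (ncol(vals) != length(props)) {
    stop("parse error in PLY file '", path, "': record width ", ncol(vals),
         " does not match ", length(props), " declared properties")
  }
  out <- data.frame(x = vals[, need[1]], y = vals[, need[2]], z = vals[, need[3]])
  sidx <- match("scanner", props)
  out$scanner_id <- if (!is.na(sidx)) as.integer(vals[, sidx]) else 0L
  out
}

#' @rdname read_point_cloud
#' @export
write_ply <- function(points, path) {
  pts <- as_point_df(points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(pts)),
               "property double x", "property double y", "property double z",
               "property int scanner", "end_header"), con)
  writeLines(paste(format(pts$x, digits = 17, scientific = FALSE, trim = TRUE),
                   format(pts$y, digits = 17, scientific = FALSE, trim = TRUE),
                   format(pts$z, digits = 17, scientific = FALSE, trim = TRUE),
                   pts$scanner_id), con)
  invisible(path)
}

#' Serialize a fuzzy point cloud as CSV
#'
#' One row per Gaussian point: mean coordinates (`x`, `y`, `z`, meters),
#' the six unique covariance entries (`cov_xx`, `cov_xy`, `cov_xz`,
#' `cov_yy`, `cov_yz`, `cov_zz`, square meters) and the `scanner_id`.
#' Reading reconstructs the cloud; the geometry the covariances were
#' built from is not stored, so `geometry_used` is `NULL` after a
#' round-trip.
#'
#' @param fc a [make_fuzzy_cloud()] result.
#' @param path CSV file path.
#' @return `write_fuzzy_cloud()`: `path` invisibly;
#'   `read_fuzzy_cloud()`: a `"fuzzy_point_cloud"`.
#' @export
write_fuzzy_cloud <- function(fc, path) {
  stopifnot(inherits(fc, "fuzzy_point_cloud"))
  df <- data.frame(x = fc$mean[, 1], y = fc$mean[, 2], z = fc$mean[, 3],
                   cov_xx = fc$cov[, 1], cov_xy = fc$cov[, 2],
                   cov_xz = fc$cov[, 3], cov_yy = fc$cov[, 4],
                   cov_yz = fc$cov[, 5], cov_zz = fc$cov[, 6],
                   scanner_id = fc$scanner_id)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fuzzy_cloud
#' @export
read_fuzzy_cloud <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x", "y", "z", "cov_xx", "cov_xy", "cov_xz", "cov_yy",
            "cov_yz", "cov_zz")
  if (!all(need %in% names(df))) {
    stop("parse error in fuzzy cloud CSV '", path, "': missing columns")
  }
  structure(
    list(mean = as.matrix(df[, c("x", "y", "z")]),
         cov = as.matrix(df[, need[4:9]]),
         scanner_id = if (is.null(df$scanner_id)) rep(0L, nrow(df)) else
           as.integer(df$scanner_id),
         geometry_used = NULL),
    class = "fuzzy_point_cloud")
}

#' Read a run configuration file
#'
#' YAML configuration: a `scanners` list (keys `position`,
#' `exit_diameter_m`, `divergence_half_angle_rad`, `base_range_sigma_m`,
#' `angular_step_deg`), an optional `truth` cylinder (`radius_m`,
#' `azimuth_deg`, `elevation_deg`, `center`, `length_m`), method
#' settings (`tangent_lines`, `max_updates`, `ransac_subsets`) and a
#' `seed`. Angles carry explicit `_deg`/`_rad` suffixes and degrees are
#' converted on load; lengths are meters.
#'
#' @param path YAML file path.
#' @return list with `scanners` (list of [scanner_spec()]), `truth`
#'   (NULL or [cylinder_geometry()]), `tangent_lines`, `max_updates`,
#'   `ransac_subsets`, `seed`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  scanners <- lapply(seq_along(cfg$scanners), function(i) {
    s <- cfg$scanners[[i]]
    scanner_spec(
      position = as.numeric(s$position),
      exit_diameter = s$exit_diameter_m %||% 2.12e-3,
      divergence_half_angle = s$divergence_half_angle_rad %||% 0.15e-3,
      base_range_sigma = s$base_range_sigma_m %||% 1.0e-3,
      angular_step = (s$angular_step_deg %||% 0.018) * pi / 180,
      id = s$id %||% (i - 1L))
  })
  truth <- NULL
  if (!is.null(cfg$truth)) {
    tr <- cfg$truth
    truth <- cylinder_geometry(
      radius = tr$radius_m %||% 0.05,
      azimuth = (tr$azimuth_deg %||% 0) * pi / 180,
      elevation = (tr$elevation_deg %||% 90) * pi / 180,
      center = as.numeric(tr$center %||% c(0, 0, 0)),
      length = tr$length_m %||% 0.25)
  }
  list(scanners = scanners, truth = truth,
       tangent_lines = cfg$tangent_lines %||% 1000L,
       max_updates = cfg$max_updates %||% 10L,
       ransac_subsets = cfg$ransac_subsets %||% 100L,
       seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize fits and experiment reports
#'
#' `write_report()` writes a schema-versioned JSON payload for a
#' `"cylinder_fit"` or `"cylinder_experiment"`; for experiments an
#' optional CSV table (one row per method, nu/sigma column pairs per
#' parameter) is written alongside. No timestamps are included, so equal
#' inputs produce byte-identical files. `report_json()` returns the JSON
#' string; `read_report()` reads a JSON report back as a list.
#'
#' @param x a `"cylinder_fit"` or `"cylinder_experiment"`.
#' @param path output JSON path.
#' @param csv_path optional CSV path (experiments only).
#' @return `write_report()`: `path`, invisibly.
#' @export
write_report <- function(x, path, csv_path = NULL) {
  writeLines(report_json(x), path)
  if (!is.null(csv_path)) {
    if (!inherits(x, "cylinder_experiment")) {
      stop("csv_path is only supported for cylinder_experiment reports")
    }
    tab <- experiment_table(x)
    utils::write.csv(data.frame(method = rownames(tab), tab,
                                check.names = FALSE),
                     csv_path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
report_json <- function(x) {
  payload <- if (inherits(x, "cylinder_fit")) {
    g <- x$geometry
    list(schema_version = 1L, type = "cylinder_fit", method = x$method,
         geometry = list(radius = g$radius, azimuth = g$azimuth,
                         elevation = g$elevation, center = g$center,
                         axis = g$axis),
         objective = x$objective, converged = x$converged,
         iterations = x$iterations, outer_iterations = x$outer_iterations)
  } else if (inherits(x, "cylinder_experiment")) {
    list(schema_version = 1L, type = "cylinder_experiment",
         scenario = x$scenario, n_replicates = x$n_replicates,
         seed = x$seed, tangent_lines = x$t, n_points = x$n_points,
         nu = lapply(x$nu, as.list), sigma = lapply(x$sigma, as.list),
         p_values = lapply(x$p_values, as.list),
         failures = as.list(x$failures),
         errors = lapply(x$errors, function(E) unname(as.data.frame(E))))
  } else {
    stop("write_report expects a cylinder_fit or cylinder_experiment")
  }
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null",
                   na = "null", pretty = TRUE)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
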