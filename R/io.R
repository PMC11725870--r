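#' Read and write point tables
#'
#' Point tables are CSV files with header `x_nm,y_nm[,channel][,precision_nm]`
#' (comma-separated, '.' decimal, UTF-8). The membrane region comes from a
#' polygon sidecar ([read_region()]) or, for rectangular sheets, an
#' `area_um2` argument placing the points in a square of that area anchored
#' at the origin.
#'
#' @param path CSV file path.
#' @param region Polygon vertex matrix in nm (see [read_region()]).
#' @param area_um2 Alternative to `region`: area of a square region (um^2).
#' @return `read_point_table` returns a [point_pattern()];
#'   `write_point_table` returns `path` invisibly (the region goes to a
#'   `<path>.region.wkt` sidecar).
#' @export
read_point_table <- function(path, region = NULL, area_um2 = NULL) {
  if (is.null(region) && is.null(area_um2)) {
    sidecar <- paste0(path, ".region.wkt")
    if (file.exists(sidecar)) {
      region <- read_region(sidecar)
    } else {
      stop("supply `region`, `area_um2`, or a ", sidecar, " sidecar",
           call. = FALSE)
    }
  }
  if (is.null(region)) region <- rect_region(sqrt(area_um2))
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!all(c("x_nm", "y_nm") %in% names(df))) {
    stop("point table needs columns x_nm, y_nm", call. = FALSE)
  }
  bad <- which(!is.finite(df$x_nm) | !is.finite(df$y_nm))
  if (length(bad)) {
    stop("malformed coordinate in data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  point_pattern(df$x_nm, df$y_nm, region,
                channel = if ("channel" %in% names(df)) df$channel,
                precision = if ("precision_nm" %in% names(df)) df$precision_nm)
}

#' @rdname read_point_table
#' @param pattern A [point_pattern()] to write.
#' @export
write_point_table <- function(pattern, path) {
  stopifnot(inherits(pattern, "point_pattern"))
  df <- as.data.frame(pattern)
  names(df)[names(df) == "x"] <- "x_nm"
  names(df)[names(df) == "y"] <- "y_nm"
  names(df)[names(df) == "precision"] <- "precision_nm"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  write_region(attr(pattern, "region"), paste0(path, ".region.wkt"))
  invisible(path)
}

#' Read and write region polygons as WKT
#'
#' Regions are stored as a single WKT `POLYGON ((x y, x y, ...))` ring in nm
#' coordinates (no holes).
#'
#' @param path File path.
#' @return `read_region` returns a vertex matrix (nm); `write_region`
#'   returns `path` invisibly.
#' @export
read_region <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = " ")
  m <- regmatches(txt, regexec("POLYGON\\s*\\(\\(([^)]*)\\)\\)", txt))[[1]]
  if (length(m) != 2L) stop("no WKT POLYGON found in ", path, call. = FALSE)
  pairs <- strsplit(trimws(strsplit(m[2], ",")[[1]]), "\\s+")
  coords <- t(vapply(pairs, function(p) as.numeric(p[1:2]), numeric(2)))
  if (any(!is.finite(coords))) stop("malformed WKT coordinates", call. = FALSE)
  as_region(coords)
}

#' @rdname read_region
#' @param region Polygon vertex matrix (nm) to write.
#' @export
write_region <- function(region, path) {
  region <- as_region(region)
  ring <- rbind(region, region[1, , drop = FALSE])
  writeLines(sprintf("POLYGON ((%s))",
                     paste(sprintf("%.9g %.9g", ring[, 1], ring[, 2]),
                           collapse = ", ")), path)
  invisible(path)
}

#' Read and write aggregation parameters as JSON
#'
#' Schema: `{"dG_bulk_RT": ..., "A0_um2": ..., "alpha": ...}`.
#'
#' @param path File path.
#' @return `read_params` returns an [aggregation_params()]; `write_params`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("dG_bulk_RT", "A0_um2") %in% names(js))) {
    stop("params JSON needs keys dG_bulk_RT and A0_um2", call. = FALSE)
  }
  aggregation_params(js$dG_bulk_RT, js$A0_um2,
                     boundary_exponent = if (!is.null(js$alpha)) js$alpha else 0.5)
}

#' @rdname read_params
#' @param params An [aggregation_params()] to write.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "aggregation_params"))
  jsonlite::write_json(list(dG_bulk_RT = params$dG_bulk, A0_um2 = params$A0,
                            alpha = params$boundary_exponent),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a fit result as JSON
#'
#' Writes the global cohesion energy, per-dataset configurational areas and
#' implied monomer densities, objective, convergence flag and the fitting
#' configuration.
#'
#' @param fit A `hots_fit` from [fit_single()] or [fit_global()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "hots_fit"))
  out <- list(
    dG_bulk_RT = fit$dG_bulk,
    A0_um2 = fit$A0,
    cmon_um2 = fit$cmon,
    ctot_um2 = fit$ctot,
    nmax = fit$nmax,
    objective = fit$objective,
    converged = fit$converged,
    config = fit$config[c("loss", "weights", "log_floor", "dG_bounds",
                          "A0_bounds", "nmax_policy")]
  )
  if (!is.null(fit$boot)) out$dG_ci95 <- fit$boot$ci
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
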