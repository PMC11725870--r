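#' Cluster size distribution
#'
#' A per-size table of cluster densities over a membrane area: for each
#' cluster size `n`, the density (um^-2) of clusters comprising exactly `n`
#' labeled proteins. This is the common currency of the package -- the model,
#' the lattice simulation, the point-pattern pipeline and the fitter all
#' produce or consume it.
#'
#' @param n Cluster sizes, positive integers (need not be contiguous; gaps
#'   are treated as zero-density sizes by consumers).
#' @param density Cluster density per size, um^-2, non-negative.
#' @param counts Optional raw cluster counts per size. When both `counts` and
#'   `area` are given, `density` must equal `counts / area`.
#' @param se Optional per-size standard error of `density`, um^-2.
#' @param area Optional membrane area in um^2.
#' @param ctot Optional declared total protein density (um^-2). Must agree
#'   with `sum(n * density)` to a relative tolerance of 1e-9; computed from
#'   the table when omitted.
#' @return A data frame of class `size_distribution` with columns `n`,
#'   `density` and optionally `counts`, `se`; attributes `area` and `ctot`.
#' @examples
#' d <- size_distribution(n = 1:3, density = c(1, 0.5, 0.2))
#' total_concentration(d) # 1 + 1 + 0.6
#' @export
size_distribution <- function(n, density, counts = NULL, se = NULL,
                              area = NULL, ctot = NULL) {
  n <- check_cluster_sizes(n)
  stopifnot(is.numeric(density), length(density) == length(n))
  if (anyDuplicated(n)) stop("duplicated cluster sizes `n`", call. = FALSE)
  if (any(!is.finite(density)) || any(density < 0)) {
    stop("densities must be finite and >= 0", call. = FALSE)
  }
  df <- data.frame(n = n, density = as.numeric(density))
  if (!is.null(counts)) {
    stopifnot(is.numeric(counts), length(counts) == length(n))
    if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
    df$counts <- as.numeric(counts)
  }
  if (!is.null(se)) {
    stopifnot(is.numeric(se), length(se) == length(n))
    df$se <- as.numeric(se)
  }
  if (!is.null(area)) {
    stopifnot(is.numeric(area), length(area) == 1L, area > 0)
    if (!is.null(counts) &&
        any(abs(density - counts / area) > 1e-9 * pmax(density, 1e-300))) {
      stop("`density` must equal `counts / area`", call. = FALSE)
    }
  }
  implied <- sum(df$n * df$density)
  if (!is.null(ctot)) {
    stopifnot(is.numeric(ctot), length(ctot) == 1L, ctot >= 0)
    if (implied > 0 && abs(ctot - implied) > 1e-9 * ctot) {
      stop(sprintf(
        "declared ctot (%.8g) disagrees with sum(n * density) = %.8g",
        ctot, implied), call. = FALSE)
    }
  } else {
    ctot <- implied
  }
  df <- df[order(df$n), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, area = if (is.null(area)) NA_real_ else as.numeric(area),
            ctot = as.numeric(ctot),
            class = c("size_distribution", "data.frame"))
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("Cluster size distribution: %d size bins, n in [%d, %d]\n",
              nrow(x), min(x$n), max(x$n)))
  cat(sprintf("  total protein density: %.4g um^-2", attr(x, "ctot")))
  if (!is.na(attr(x, "area"))) cat(sprintf("  (area %.4g um^2)", attr(x, "area")))
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Total protein density of a size distribution
#'
#' The mass balance `sum(n * density)`: proteins per um^2 held across all
#' tabulated cluster sizes.
#'
#' @param dist A [size_distribution].
#' @return Density in um^-2.
#' @export
total_concentration <- function(dist) {
  stopifnot(inherits(dist, "size_distribution"))
  sum(dist$n * dist$density)
}

#' Membrane area of a size distribution
#' @param dist A [size_distribution].
#' @return Area in um^2 (NA when not recorded).
#' @export
dist_area <- function(dist) {
  stopifnot(inherits(dist, "size_distribution"))
  attr(dist, "area")
}

#' Density at given sizes, with absent sizes read as zero
#' @param dist A [size_distribution].
#' @param n Sizes to look up.
#' @return Densities (um^-2) at `n`.
#' @export
density_at <- function(dist, n) {
  stopifnot(inherits(dist, "size_distribution"))
  n <- check_cluster_sizes(n)
  out <- numeric(length(n))
  m <- match(n, dist$n)
  out[!is.na(m)] <- dist$density[m[!is.na(m)]]
  out
}

#' Read / write size distributions as CSV
#'
#' The on-disk schema is a comma-separated table with header
#' `n,density_per_um2[,count][,se]`; decimal point, UTF-8. Sizes absent from
#' the file are zero-density by convention. `area_um2` and `ctot_um2` are
#' carried in `# key: value` comment lines above the header.
#'
#' @param path File path.
#' @return `read_distribution` returns a [size_distribution];
#'   `write_distribution` returns `path` invisibly.
#' @export
read_distribution <- function(path) {
  meta <- read_meta_comments(path)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  need <- c("n", "density_per_um2")
  if (!all(need %in% names(df))) {
    stop("distribution CSV needs columns n, density_per_um2", call. = FALSE)
  }
  if (any(df$density_per_um2 < 0)) stop("negative densities in ", path, call. = FALSE)
  size_distribution(
    n = df$n, density = df$density_per_um2,
    counts = if ("count" %in% names(df)) df$count,
    se = if ("se" %in% names(df)) df$se,
    area = meta[["area_um2"]], ctot = meta[["ctot_um2"]]
  )
}

#' @rdname read_distribution
#' @param dist A [size_distribution] to write.
#' @export
write_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "size_distribution"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(attr(dist, "area"))) {
    writeLines(sprintf("# area_um2: %.15g", attr(dist, "area")), con)
  }
  writeLines(sprintf("# ctot_um2: %.15g", attr(dist, "ctot")), con)
  df <- as.data.frame(dist)
  names(df)[names(df) == "density"] <- "density_per_um2"
  names(df)[names(df) == "counts"] <- "count"
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# "# key: value" comment lines -> named numeric list
read_meta_comments <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- lines[startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_]+)\\s*:\\s*([-0-9.eE+]+)", ln))[[1]]
    if (length(m) == 3L) out[[m[2]]] <- as.numeric(m[3])
  }
  out
}

#' Subtract a nonspecific-background size distribution
#'
#' Per-size density subtraction with clamping at zero, emulating the
#' correction of immunogold size distributions by a no-expression control.
#' Sizes present in only one table are padded with zeros. Bins where the
#' background exceeded the signal are clamped to 0 and recorded in the
#' `clamped` attribute (a warning is emitted).
#'
#' @param dist Signal [size_distribution] (um^-2).
#' @param background Background [size_distribution] (um^-2).
#' @return A [size_distribution] of the difference.
#' @export
subtract_background <- function(dist, background) {
  stopifnot(inherits(dist, "size_distribution"),
            inherits(background, "size_distribution"))
  n_all <- sort(union(dist$n, background$n))
  diff <- density_at(dist, n_all) - density_at(background, n_all)
  clamped <- n_all[diff < 0]
  if (length(clamped)) {
    warning("background exceeds signal in ", length(clamped),
            " size bin(s); clamped to 0", call. = FALSE)
    diff[diff < 0] <- 0
  }
  out <- size_distribution(n = n_all, density = diff, area = {
    a <- attr(dist, "area"); if (is.na(a)) NULL else a
  })
  attr(out, "clamped") <- clamped
  out
}
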