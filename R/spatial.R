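#' Planar point pattern of labeled proteins on a membrane sheet
#'
#' Coordinates (nm) of detected labels inside a membrane-region polygon.
#' Membership is checked with the even-odd rule; points exactly on the
#' boundary count as inside.
#'
#' @param x,y Coordinates in nm.
#' @param region A two-column matrix of polygon vertices in nm (not
#'   necessarily closed), or a [rect_region()].
#' @param channel Optional per-point label identity (e.g. gold size class).
#' @param precision Optional per-point localization precision in nm.
#' @return A `point_pattern`: data frame of points with the region and its
#'   area (um^2) attached.
#' @examples
#' pp <- point_pattern(c(100, 200), c(100, 150), rect_region(1, 1))
#' pattern_area(pp)
#' @export
point_pattern <- function(x, y, region, channel = NULL, precision = NULL) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  region <- as_region(region)
  if (length(x) && !all(points_in_polygon(x, y, region))) {
    stop("all points must lie inside the membrane region", call. = FALSE)
  }
  df <- data.frame(x = as.numeric(x), y = as.numeric(y))
  if (!is.null(channel)) {
    stopifnot(length(channel) == length(x))
    df$channel <- channel
  }
  if (!is.null(precision)) {
    stopifnot(is.numeric(precision), length(precision) == length(x))
    df$precision <- as.numeric(precision)
  }
  structure(df, region = region, area = polygon_area_um2(region),
            class = c("point_pattern", "data.frame"))
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("Point pattern: %d points in a %.4g um^2 region (%.4g um^-2)\n",
              nrow(x), attr(x, "area"), nrow(x) / attr(x, "area")))
  invisible(x)
}

#' Membrane area of a point pattern (um^2)
#' @param pattern A [point_pattern()].
#' @export
pattern_area <- function(pattern) {
  stopifnot(inherits(pattern, "point_pattern"))
  attr(pattern, "area")
}

#' Rectangular membrane region
#' @param width_um,height_um Rectangle dimensions in um.
#' @return A vertex matrix (nm) usable as `region`.
#' @export
rect_region <- function(width_um, height_um = width_um) {
  stopifnot(width_um > 0, height_um > 0)
  w <- width_um * 1e3
  h <- height_um * 1e3
  cbind(x = c(0, w, w, 0), y = c(0, 0, h, h))
}

as_region <- function(region) {
  region <- as.matrix(region)
  if (ncol(region) != 2L || nrow(region) < 3L || any(!is.finite(region))) {
    stop("region must be a matrix of >= 3 finite (x, y) vertices in nm",
         call. = FALSE)
  }
  # drop an explicit closing vertex
  if (all(region[1, ] == region[nrow(region), ])) {
    region <- region[-nrow(region), , drop = FALSE]
  }
  if (nrow(region) < 3L || polygon_area_um2(region) <= 0) {
    stop("degenerate region polygon (zero area)", call. = FALSE)
  }
  unname(region)
}

# shoelace area, nm^2 -> um^2
polygon_area_um2 <- function(region) {
  xv <- region[, 1]
  yv <- region[, 2]
  j <- c(seq_len(nrow(region))[-1], 1L)
  abs(sum(xv * yv[j] - xv[j] * yv)) / 2 / 1e6
}

# even-odd (ray casting) membership; boundary points are inside
points_in_polygon <- function(x, y, region, tol = 1e-9) {
  xv <- region[, 1]
  yv <- region[, 2]
  nv <- length(xv)
  inside <- rep(FALSE, length(x))
  boundary <- rep(FALSE, length(x))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- xv[i]; yi <- yv[i]; xj <- xv[j]; yj <- yv[j]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    # on-segment check (boundary counts as inside)
    dx <- xj - xi; dy <- yj - yi
    L2 <- dx^2 + dy^2
    t <- pmin(1, pmax(0, ((x - xi) * dx + (y - yi) * dy) / L2))
    d2 <- (x - (xi + t * dx))^2 + (y - (yi + t * dy))^2
    boundary <- boundary | (d2 <= tol^2 * pmax(L2, 1))
    j <- i
  }
  inside | boundary
}

#' Single-linkage clustering of a point pattern
#'
#' Groups labels into clusters as the connected components of the graph
#' linking every pair of points at distance `<= cutoff` (distances exactly
#' equal to the cutoff link). This is the operational cluster definition of
#' the pipeline; the cutoff is a first-class parameter recorded in the
#' output, with a suggested scale of about three label diameters.
#'
#' @param pattern A [point_pattern()].
#' @param cutoff Linkage distance in nm, positive.
#' @return A `cluster_set`: `membership` (cluster id per point), `sizes`
#'   (per-cluster point counts), `centroids` (mean x, y per cluster),
#'   `cutoff`, `area` (um^2), `n_points`.
#' @export
link_clusters <- function(pattern, cutoff) {
  stopifnot(inherits(pattern, "point_pattern"), is.numeric(cutoff),
            length(cutoff) == 1L, cutoff > 0)
  if (nrow(pattern) == 0L) {
    return(structure(list(membership = integer(0), sizes = integer(0),
                          centroids = matrix(numeric(0), 0, 2,
                                             dimnames = list(NULL, c("x", "y"))),
                          cutoff = cutoff, area = pattern_area(pattern),
                          n_points = 0L),
                     class = "cluster_set"))
  }
  lab <- link_points_cpp(pattern$x, pattern$y, cutoff)
  sizes <- tabulate(lab)
  cx <- vapply(split(pattern$x, lab), mean, numeric(1))
  cy <- vapply(split(pattern$y, lab), mean, numeric(1))
  ord <- as.integer(names(cx))
  centroids <- matrix(NA_real_, max(lab), 2, dimnames = list(NULL, c("x", "y")))
  centroids[ord, 1] <- cx
  centroids[ord, 2] <- cy
  structure(list(membership = lab, sizes = sizes, centroids = centroids,
                 cutoff = cutoff, area = pattern_area(pattern),
                 n_points = nrow(pattern)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("Cluster set: %d points -> %d clusters (cutoff %.3g nm)\n",
              x$n_points, length(x$sizes), x$cutoff))
  invisible(x)
}

#' Cluster size distribution of a cluster set
#'
#' Tabulates the per-size cluster density: `density[n]` is the number of
#' clusters of exactly `n` labels divided by the membrane area.
#'
#' @param clusters A `cluster_set` from [link_clusters()].
#' @param area Membrane area in um^2 (default: the pattern's area).
#' @return A [size_distribution] with raw counts and Poisson standard
#'   errors (`sqrt(count)/area`); `sum(n * density)` equals the label
#'   density.
#' @export
cluster_size_distribution <- function(clusters, area = clusters$area) {
  stopifnot(inherits(clusters, "cluster_set"), is.numeric(area), area > 0)
  if (!length(clusters$sizes)) {
    return(size_distribution(1L, 0, area = area))
  }
  tab <- tabulate(clusters$sizes)
  n <- which(tab > 0)
  size_distribution(n = n, density = tab[n] / area, counts = tab[n],
                    se = sqrt(tab[n]) / area, area = area)
}

#' Nearest-neighbor distances between cluster centroids
#'
#' For every cluster of at least `min_size` labels, the distance from its
#' centroid to the nearest other qualifying centroid. The default
#' `min_size = 3` restricts to unambiguous clusters.
#'
#' @param clusters A `cluster_set`.
#' @param min_size Minimum labels per qualifying cluster (default 3).
#' @return Distances in nm, one per qualifying cluster (empty, with a
#'   warning, when fewer than 2 clusters qualify).
#' @export
nnd_centroids <- function(clusters, min_size = 3L) {
  stopifnot(inherits(clusters, "cluster_set"), min_size >= 1)
  keep <- which(clusters$sizes >= min_size)
  if (length(keep) < 2L) {
    warning("fewer than 2 clusters of size >= ", min_size, call. = FALSE)
    return(numeric(0))
  }
  nnd_cpp(clusters$centroids[keep, 1], clusters$centroids[keep, 2])
}

#' Nearest-neighbor distances under complete spatial randomness
#'
#' Monte-Carlo null for centroid nearest-neighbor distances: `n_reps`
#' independent placements of `n_clusters` points uniformly in the region
#' (rejection sampling within the bounding box), pooling the per-point NND
#' samples. On large homogeneous regions the pooled sample follows the 2D
#' Poisson nearest-neighbor law with density `lambda = n_clusters / area`:
#' pdf `2 pi lambda r exp(-pi lambda r^2)`.
#'
#' @param region Polygon vertex matrix in nm (or [rect_region()]).
#' @param n_clusters Points per placement, >= 2.
#' @param n_reps Number of independent placements.
#' @param seed Optional integer seed ([set.seed()]).
#' @return Pooled NND samples in nm (length `n_clusters * n_reps`).
#' @export
csr_null <- function(region, n_clusters, n_reps = 1L, seed = NULL) {
  region <- as_region(region)
  stopifnot(n_clusters >= 2, n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    pts <- runif_in_polygon(n_clusters, region)
    out[[r]] <- nnd_cpp(pts[, 1], pts[, 2])
  }
  unlist(out)
}

# uniform points in a polygon by rejection from the bounding box
runif_in_polygon <- function(n, region) {
  bx <- range(region[, 1])
  by <- range(region[, 2])
  got <- 0L
  xs <- numeric(n)
  ys <- numeric(n)
  while (got < n) {
    m <- max(16L, 2L * (n - got))
    cx <- stats::runif(m, bx[1], bx[2])
    cy <- stats::runif(m, by[1], by[2])
    ok <- points_in_polygon(cx, cy, region)
    take <- min(n - got, sum(ok))
    if (take > 0L) {
      idx <- which(ok)[seq_len(take)]
      xs[got + seq_len(take)] <- cx[idx]
      ys[got + seq_len(take)] <- cy[idx]
      got <- got + take
    }
  }
  cbind(x = xs, y = ys)
}

#' Histogram of short pairwise distances
#'
#' All unordered pairwise distances up to `max_distance` between points of a
#' pattern (optionally restricted to points whose stated localization
#' precision is at most `precision_filter`), binned at `binwidth`. This is
#' the intra-cluster packing observable: for closely packed clusters its
#' main peak sits near the protein diameter.
#'
#' @param pattern A [point_pattern()].
#' @param max_distance Largest distance retained, nm.
#' @param binwidth Histogram bin width in nm (default 0.5).
#' @param precision_filter Optional precision ceiling in nm; requires a
#'   `precision` column.
#' @return A `distance_histogram`: `mid` (bin centers), `counts`, `breaks`,
#'   and the raw `distances`.
#' @export
pairwise_distance_histogram <- function(pattern, max_distance,
                                        binwidth = 0.5,
                                        precision_filter = NULL) {
  stopifnot(inherits(pattern, "point_pattern"), max_distance > 0, binwidth > 0)
  df <- pattern
  if (!is.null(precision_filter)) {
    if (!"precision" %in% names(df)) {
      stop("pattern has no precision column to filter on", call. = FALSE)
    }
    df <- df[!is.na(df$precision) & df$precision <= precision_filter, ,
             drop = FALSE]
  }
  d <- if (nrow(df) >= 2L) pair_distances_cpp(df$x, df$y, max_distance)
       else numeric(0)
  breaks <- seq(0, max_distance + binwidth, by = binwidth)
  counts <- if (length(d)) tabulate(findInterval(d, breaks, left.open = TRUE),
                                    nbins = length(breaks) - 1L)
            else integer(length(breaks) - 1L)
  structure(list(mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 counts = counts, breaks = breaks, distances = d),
            class = "distance_histogram")
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat(sprintf("Distance histogram: %d pair distances in [0, %.3g] nm\n",
              length(x$distances), max(x$breaks)))
  invisible(x)
}

#' Fit a single Gaussian to the main peak of a histogram
#'
#' Least-squares Gaussian fit (amplitude, mean, sd) restricted to the
#' contiguous region around the tallest interior bin where counts stay above
#' a fifth of the peak. Errors on monotone (peakless) histograms; on
#' multi-modal input the tallest peak is fitted and `multimodal = TRUE` is
#' flagged.
#'
#' @param hist A `distance_histogram` (or any list with `mid` and `counts`).
#' @return A list: `mean` (nm), `sd` (nm), `amplitude`, `multimodal`.
#' @export
fit_gaussian_peak <- function(hist) {
  mid <- hist$mid
  counts <- as.numeric(hist$counts)
  stopifnot(length(mid) == length(counts), length(mid) >= 5)
  i_max <- which.max(counts)
  if (i_max == 1L || i_max == length(counts) || all(diff(counts) <= 0)) {
    stop("histogram has no interior peak to fit", call. = FALSE)
  }
  thresh <- counts[i_max] / 5
  lo <- i_max
  while (lo > 1L && counts[lo - 1L] > thresh && counts[lo - 1L] <= counts[lo]) lo <- lo - 1L
  hi <- i_max
  while (hi < length(counts) && counts[hi + 1L] > thresh &&
         counts[hi + 1L] <= counts[hi]) hi <- hi + 1L
  win <- lo:hi
  if (length(win) < 4L) win <- max(1L, lo - 2L):min(length(counts), hi + 2L)
  df <- data.frame(x = mid[win], yy = counts[win])
  start <- list(a = counts[i_max], mu = mid[i_max],
                sg = max(diff(range(df$x)) / 4, diff(mid)[1]))
  fit <- minpack.lm::nlsLM(yy ~ a * exp(-(x - mu)^2 / (2 * sg^2)),
                           data = df, start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  # second substantial local maximum outside the fitted window?
  outside <- counts
  outside[win] <- 0
  multimodal <- any(outside > 0.5 * counts[i_max])
  list(mean = unname(co["mu"]), sd = abs(unname(co["sg"])),
       amplitude = unname(co["a"]), multimodal = multimodal)
}

#' Binomial thinning of a point pattern (labeling efficiency)
#'
#' Retains each point independently with probability `efficiency`, the
#' standard model of sub-unity labeling efficiency: a true size-n cluster is
#' observed as Binomial(n, efficiency) labels.
#'
#' @param pattern A [point_pattern()].
#' @param efficiency Retention probability in (0, 1].
#' @param seed Optional integer seed ([set.seed()]).
#' @return The thinned [point_pattern()].
#' @export
thin_labels <- function(pattern, efficiency, seed = NULL) {
  stopifnot(inherits(pattern, "point_pattern"),
            is.numeric(efficiency), length(efficiency) == 1L,
            efficiency > 0, efficiency <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (efficiency == 1) return(pattern)
  keep <- stats::runif(nrow(pattern)) < efficiency
  subset_pattern(pattern, keep)
}

subset_pattern <- function(pattern, idx) {
  df <- as.data.frame(pattern)[idx, , drop = FALSE]
  rownames(df) <- NULL
  point_pattern(df$x, df$y, attr(pattern, "region"),
                channel = df$channel, precision = df$precision)
}
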