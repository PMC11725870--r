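#' Configuration of the synthetic point-pattern generator
#'
#' Generates membrane-sheet label patterns with known ground truth, emulating
#' immunogold-style data: cluster sizes drawn from a generating model
#' (reversible-aggregation HOTS, attractor, or pure monomers), cluster
#' centroids placed uniformly (CSR), labels packed hexagonally inside each
#' cluster at a protein-diameter spacing, then an observation model of
#' binomial labeling efficiency and uniform nonspecific background.
#'
#' Defaults reflect the experimental regime being emulated: a 50 x 50 um
#' membrane sheet, 5.2 nm packing (the measured most-probable neighbor
#' spacing inside clusters), full labeling efficiency and no background
#' unless asked for.
#'
#' @param model `"hots"`, `"attractor"` or `"monomers"`.
#' @param params An [aggregation_params()] (hots) or [attractor_params()]
#'   (attractor); ignored for monomers.
#' @param ctot Total protein density, um^-2.
#' @param region Polygon vertex matrix in nm; default `rect_region(50, 50)`.
#' @param packing_distance Intra-cluster nearest-neighbor spacing, nm
#'   (default 5.2).
#' @param packing_jitter Gaussian positional jitter inside clusters, nm sd
#'   (default 0.3).
#' @param labeling_efficiency Probability a protein carries a label, (0, 1].
#' @param background_density Uniform nonspecific label density, um^-2.
#' @return A `synth_config` object.
#' @export
synth_config <- function(model = c("hots", "attractor", "monomers"),
                         params = NULL, ctot,
                         region = rect_region(50, 50),
                         packing_distance = 5.2, packing_jitter = 0.3,
                         labeling_efficiency = 1, background_density = 0) {
  model <- match.arg(model)
  stopifnot(is.numeric(ctot), length(ctot) == 1L, ctot >= 0,
            packing_distance > 0, packing_jitter >= 0,
            labeling_efficiency > 0, labeling_efficiency <= 1,
            background_density >= 0)
  if (model == "hots" && !inherits(params, "aggregation_params")) {
    stop("hots model needs `params` of class aggregation_params", call. = FALSE)
  }
  if (model == "attractor" && !inherits(params, "attractor_params")) {
    stop("attractor model needs `params` of class attractor_params", call. = FALSE)
  }
  structure(list(model = model, params = params, ctot = ctot,
                 region = as_region(region),
                 packing_distance = packing_distance,
                 packing_jitter = packing_jitter,
                 labeling_efficiency = labeling_efficiency,
                 background_density = background_density),
            class = "synth_config")
}

# expected per-size cluster densities of the generating model
model_densities <- function(config, nmax = NULL) {
  if (config$model == "monomers") {
    return(list(n = 1L, density = config$ctot))
  }
  if (config$model == "attractor") {
    lam <- attr(attractor_distribution(config$params, config$ctot, 2L), "lambda")
    if (is.null(nmax)) nmax <- max(20L, ceiling(lam + 12 * sqrt(lam + 1)))
    d <- attractor_distribution(config$params, config$ctot, nmax)
    return(list(n = d$n, density = d$density))
  }
  p <- config$params
  ctot_crit <- tryCatch(critical_total_concentration(p), error = function(e) Inf)
  if (config$ctot > ctot_crit) {
    stop(sprintf(paste0(
      "requested ctot = %.4g um^-2 exceeds the critical total concentration ",
      "%.4g um^-2 (see critical_total_concentration); the subcritical HOTS ",
      "distribution cannot hold that much protein"),
      config$ctot, ctot_crit), call. = FALSE)
  }
  if (is.null(nmax)) {
    # extend until the expected count over the region is negligible
    area <- polygon_area_um2(config$region)
    nmax <- 64L
    cmon <- solve_monomer_from_total(p, config$ctot, nmax)
    while (nmer_density(p, cmon, nmax) * area > 1e-8 && nmax < 1e5) {
      nmax <- nmax * 2L
      cmon <- solve_monomer_from_total(p, config$ctot, nmax)
    }
  } else {
    cmon <- solve_monomer_from_total(p, config$ctot, nmax)
  }
  n <- seq_len(nmax)
  list(n = n, density = nmer_density(p, cmon, n), cmon = cmon)
}

#' Draw cluster sizes from the generating model
#'
#' Cluster counts per size are independent Poisson draws with mean
#' `density[n] * area`, the grand-canonical picture of clusters that are
#' independent of, but in equilibrium with, each other. The expected total
#' label density is `ctot`.
#'
#' @param config A [synth_config()].
#' @param seed Optional integer seed ([set.seed()]).
#' @return An integer vector of cluster sizes (one entry per cluster).
#' @export
sample_sizes <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(seed)
  md <- model_densities(config)
  area <- polygon_area_um2(config$region)
  counts <- stats::rpois(length(md$n), md$density * area)
  rep(md$n, counts)
}

#' Lay out clusters as a point pattern
#'
#' Places one uniformly random centroid per cluster (CSR), then fills each
#' size-n cluster with a compact hexagonal packing at nearest-neighbor
#' spacing `packing_distance`, randomly rotated, with Gaussian jitter of sd
#' `packing_jitter`; cluster layouts falling partly outside the region are
#' re-drawn at a fresh centroid.
#'
#' @param sizes Integer cluster sizes (from [sample_sizes()]).
#' @param config A [synth_config()].
#' @param seed Optional integer seed ([set.seed()]).
#' @return A [point_pattern()] whose `channel` records the cluster index.
#' @export
place_clusters <- function(sizes, config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(seed)
  region <- config$region
  if (!length(sizes)) {
    return(point_pattern(numeric(0), numeric(0), region,
                         channel = integer(0)))
  }
  sizes <- check_cluster_sizes(sizes)
  xs <- vector("list", length(sizes))
  ys <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    template <- hex_packing(sizes[i]) * config$packing_distance
    for (attempt in 1:1000) {
      th <- stats::runif(1, 0, 2 * pi)
      rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      pts <- template %*% rot
      if (config$packing_jitter > 0) {
        pts <- pts + matrix(stats::rnorm(2 * sizes[i], 0, config$packing_jitter),
                            ncol = 2)
      }
      ctr <- runif_in_polygon(1L, region)
      px <- pts[, 1] + ctr[1]
      py <- pts[, 2] + ctr[2]
      if (all(points_in_polygon(px, py, region))) break
      if (attempt == 1000) {
        stop("could not place a cluster inside the region (region too small?)",
             call. = FALSE)
      }
    }
    xs[[i]] <- px
    ys[[i]] <- py
  }
  point_pattern(unlist(xs), unlist(ys), region,
                channel = rep(seq_along(sizes), sizes))
}

# first n sites of a unit-spacing hexagonal lattice, closest to the origin
hex_packing <- function(n) {
  if (n == 1L) return(matrix(0, 1, 2))
  r <- ceiling(sqrt(n / 3)) + 1L
  idx <- expand.grid(i = -r:r, j = -r:r)
  px <- idx$i + idx$j / 2
  py <- idx$j * sqrt(3) / 2
  ord <- order(px^2 + py^2)
  cbind(px[ord][seq_len(n)], py[ord][seq_len(n)])
}

#' Apply the observation model: label thinning plus nonspecific background
#'
#' Thins each point independently at the labeling efficiency, then
#' superimposes uniform background points at `background_density`. The
#' `channel` column annotates `"signal"` versus `"background"` for
#' ground-truth evaluation; `blind = TRUE` strips it.
#'
#' @param pattern A [point_pattern()] of true label positions.
#' @param config A [synth_config()].
#' @param seed Optional integer seed ([set.seed()]).
#' @param blind Strip the ground-truth channel annotation (default FALSE).
#' @return A [point_pattern()].
#' @export
apply_observation_model <- function(pattern, config, seed = NULL,
                                    blind = FALSE) {
  stopifnot(inherits(pattern, "point_pattern"), inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(seed)
  thinned <- thin_labels(pattern, config$labeling_efficiency)
  n_bg <- stats::rpois(1, config$background_density * pattern_area(pattern))
  bg <- runif_in_polygon(n_bg, attr(pattern, "region"))
  x <- c(thinned$x, bg[, 1])
  y <- c(thinned$y, bg[, 2])
  channel <- rep(c("signal", "background"), c(nrow(thinned), n_bg))
  point_pattern(x, y, attr(pattern, "region"),
                channel = if (blind) NULL else channel)
}

#' Generate a blind synthetic pattern in one call
#'
#' Convenience composition of [sample_sizes()], [place_clusters()] and
#' [apply_observation_model()].
#'
#' @param config A [synth_config()].
#' @param seed Optional integer seed controlling all three stages.
#' @param blind Strip ground-truth annotation (default TRUE).
#' @return A [point_pattern()] with the generating cluster sizes attached as
#'   attribute `true_sizes`.
#' @export
simulate_point_pattern <- function(config, seed = NULL, blind = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- sample_sizes(config)
  pat <- place_clusters(sizes, config)
  out <- apply_observation_model(pat, config, blind = blind)
  attr(out, "true_sizes") <- sizes
  out
}

#' Panel of noisy size-distribution tables sharing one cohesion energy
#'
#' Emulates an expression-series experiment: several membranes expressing
#' the same self-assembling protein to different total densities. Cluster
#' counts per size are Poisson draws around the model's expected densities
#' over the given area; each table records counts, densities and Poisson
#' standard errors.
#'
#' @param dG Shared cohesion free energy, RT (negative).
#' @param A0 Configurational unit area, um^2.
#' @param ctots Total densities of the panel members, um^-2.
#' @param area Membrane area per member, um^2.
#' @param seed Optional integer seed.
#' @return A list of [size_distribution]s.
#' @export
make_distribution_panel <- function(dG, A0, ctots, area = 2500, seed = NULL) {
  stopifnot(dG < 0, A0 > 0, all(ctots > 0), area > 0)
  if (!is.null(seed)) set.seed(seed)
  p <- aggregation_params(dG, A0)
  lapply(ctots, function(ct) {
    cfg <- synth_config("hots", p, ctot = ct,
                        region = rect_region(sqrt(area), sqrt(area)))
    md <- model_densities(cfg)
    counts <- stats::rpois(length(md$n), md$density * area)
    keep <- which(counts > 0)
    size_distribution(n = md$n[keep], density = counts[keep] / area,
                      counts = counts[keep],
                      se = sqrt(counts[keep]) / area, area = area)
  })
}
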