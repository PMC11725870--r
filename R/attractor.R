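#' Attractor-model parameters
#'
#' The competing mechanism of membrane-protein clustering: instead of binding
#' each other, proteins partition into discrete attractive membrane regions
#' (scaffolds, rafts, curvature patches). The implementation is a
#' grand-canonical Poisson-occupancy variant: attractors at density `mtot`
#' bind proteins independently with association constant `Ka`, so the
#' occupancy of one attractor is Poisson with mean `Ka * c_free`. This form
#' reproduces the mechanism's signature predictions: Poisson-like per-region
#' occupancy, a peaked cluster size distribution when the attracted protein
#' is abundant, and a monotonically decreasing one when it is scarce.
#'
#' @param Ka Association constant of a protein for an attractor region, in
#'   um^2 (occupancy per unit free-protein density). Positive.
#' @param mtot Attractor density in um^-2. Positive.
#' @param saturable Finite-capacity scaffold variant; not implemented
#'   (must be FALSE).
#' @return An `attractor_params` object.
#' @examples
#' attractor_params(Ka = 200, mtot = 5)
#' @export
attractor_params <- function(Ka, mtot, saturable = FALSE) {
  stopifnot(is.numeric(Ka), length(Ka) == 1L, is.finite(Ka), Ka > 0,
            is.numeric(mtot), length(mtot) == 1L, is.finite(mtot), mtot > 0)
  if (isTRUE(saturable)) {
    stop("the saturable finite-site variant is not implemented", call. = FALSE)
  }
  structure(list(Ka = Ka, mtot = mtot, saturable = FALSE),
            class = "attractor_params")
}

#' @export
print.attractor_params <- function(x, ...) {
  cat(sprintf("Attractor parameters: Ka = %.4g um^2, mtot = %.4g um^-2\n",
              x$Ka, x$mtot))
  invisible(x)
}

#' Cluster size distribution predicted by the attractor model
#'
#' Solves the mass balance `ctot = c_free + mtot * lambda` with mean
#' occupancy `lambda = Ka * c_free` (linear, non-saturable binding), then
#' reports the observable cluster size distribution: an attractor carrying
#' `n >= 1` proteins is seen as a size-n cluster (density
#' `mtot * dpois(n, lambda)`), and free unbound proteins add to the `n = 1`
#' bin, since the experiment cannot distinguish a bound singleton from a free
#' monomer. Total protein is conserved exactly across the full (untruncated)
#' distribution.
#'
#' @param params An [attractor_params()] object.
#' @param ctot Total density of the attracted protein, um^-2, >= 0.
#' @param nmax Largest cluster size to tabulate.
#' @return A [size_distribution]; empty (all-zero n = 1 bin) when `ctot = 0`.
#' @examples
#' p <- attractor_params(Ka = 200, mtot = 5)
#' is_peaked(attractor_distribution(p, ctot = 20, nmax = 30))  # peaked
#' is_peaked(attractor_distribution(p, ctot = 0.5, nmax = 30)) # monotone
#' @export
attractor_distribution <- function(params, ctot, nmax = 50L) {
  stopifnot(inherits(params, "attractor_params"))
  stopifnot(is.numeric(ctot), length(ctot) == 1L, is.finite(ctot), ctot >= 0)
  nmax <- check_cluster_sizes(nmax)
  n <- seq_len(nmax)
  if (ctot == 0) {
    return(size_distribution(n = 1L, density = 0))
  }
  c_free <- ctot / (1 + params$Ka * params$mtot)
  lambda <- params$Ka * c_free
  dens <- params$mtot * stats::dpois(n, lambda)
  dens[1] <- dens[1] + c_free
  out <- size_distribution(n = n, density = dens)
  attr(out, "c_free") <- c_free
  attr(out, "lambda") <- lambda
  out
}

#' Is a size distribution peaked?
#'
#' Classifies a distribution as "peaked" (interior mode, the attractor
#' signature) versus "monotonically decreasing from n = 1" (the HOTS
#' signature): peaked iff the size of maximal density exceeds 1. The first
#' maximum wins on exact ties.
#'
#' @param dist A nonempty [size_distribution].
#' @return A logical with attribute `mode` (the size of maximal density).
#' @examples
#' is_peaked(size_distribution(1:3, c(0.1, 0.3, 0.2)))  # TRUE, mode 2
#' @export
is_peaked <- function(dist) {
  stopifnot(inherits(dist, "size_distribution"), nrow(dist) >= 1)
  mode_n <- dist$n[which.max(dist$density)]
  structure(mode_n > 1L, mode = mode_n)
}

#' Fit the attractor model to a size distribution
#'
#' Least-squares fit of the attractor prediction at the dataset's total
#' density, over `(Ka, mtot)` on the log scale (Nelder-Mead from a small
#' deterministic multi-start). Shares the loss configuration of the HOTS
#' fitter so the two models can be compared on equal residuals.
#'
#' @param dist A [size_distribution] with a derivable total density.
#' @param config A [fit_config()] (loss settings only).
#' @return A list: `Ka`, `mtot` (fitted), `objective`, `converged`.
#' @seealso [discriminate_models()]
#' @export
fit_attractor <- function(dist, config = fit_config()) {
  stopifnot(inherits(dist, "size_distribution"))
  if (config$loss == "auto") {
    config$loss <- if ("se" %in% names(dist)) "density" else "log"
  }
  ob <- fit_observations(dist, config)
  f <- function(par) {
    p <- attractor_params(Ka = exp(par[1]), mtot = exp(par[2]))
    model <- attractor_distribution(p, ob$ctot, nmax = ob$nmax)
    curve_loss(density_at(model, ob$n), ob, config)
  }
  starts <- list(c(log(10), log(1)), c(log(200), log(5)), c(log(1), log(20)))
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, f, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(Ka = exp(best$par[1]), mtot = exp(best$par[2]),
       objective = best$value, converged = best$convergence == 0)
}

#' Decide whether a measured distribution is self-assembly or attractor-like
#'
#' Fits both the mass-constrained HOTS model ([fit_single()]) and the
#' attractor model ([fit_attractor()]) to the same distribution with the
#' same loss, and returns the model with the smaller residual objective.
#'
#' @param dist A [size_distribution].
#' @param config A [fit_config()].
#' @return A list: `model` (`"hots"` or `"attractor"`), both objectives, and
#'   both fitted objects.
#' @export
discriminate_models <- function(dist, config = fit_config()) {
  hots_fit <- fit_single(dist, config)
  attr_fit <- fit_attractor(dist, config)
  list(model = if (hots_fit$objective <= attr_fit$objective) "hots" else "attractor",
       hots_objective = hots_fit$objective,
       attractor_objective = attr_fit$objective,
       hots = hots_fit, attractor = attr_fit)
}
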