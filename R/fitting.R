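#' Fitting configuration
#'
#' Controls for the mass-constrained fit of the reversible-aggregation size
#' distribution. The model curve for a dataset is fully determined by the
#' cohesion free energy `dG_bulk` once the dataset's observed monomer density
#' and total density are imposed: the monomer density pins `cmon`, and the
#' mass constraint `sum(n * c_n) = ctot` then resolves `A0`. Fitting is
#' therefore a 1D profile optimization over `dG_bulk`.
#'
#' @param loss `"auto"` (default): least squares on densities with
#'   inverse-variance weights when every dataset carries standard errors,
#'   otherwise unweighted least squares on `log(density + floor)`, which
#'   balances the many-decade dynamic range of the tails; `"log"` or
#'   `"density"` select one explicitly.
#' @param weights For the `"density"` loss: `"inverse_se"` (weights `1/se^2`
#'   where available) or `"none"` (plain least squares).
#' @param log_floor Floor added inside the log loss (um^-2, default 1e-6).
#' @param dG_bounds Search interval for `dG_bulk` (RT), default `c(-10, -1e-3)`.
#' @param A0_bounds Admissible interval for the resolved `A0` (um^2);
#'   candidate energies whose resolved `A0` falls outside are rejected.
#' @param nmax_policy `"observed"` (default): per dataset, the largest size
#'   with nonzero observed density; or a fixed integer.
#' @param fill_zeros Retain zero-density sizes inside `1..nmax` in the loss
#'   (default TRUE; dropping them would bias the tails).
#' @param n_grid Number of coarse grid points over `dG_bounds` used to seed
#'   the deterministic local refinement (default 81).
#' @param n_bootstrap Bootstrap replicates for the CI on `dG_bulk`
#'   (cluster-level resampling; default 0 = none).
#' @param seed Integer seed used for the bootstrap only.
#' @return A `fit_config` object.
#' @export
fit_config <- function(loss = c("auto", "log", "density"),
                       weights = c("inverse_se", "none"), log_floor = 1e-6,
                       dG_bounds = c(-10, -1e-3), A0_bounds = c(1e-4, 10),
                       nmax_policy = "observed", fill_zeros = TRUE,
                       n_grid = 81L, n_bootstrap = 0L, seed = 1L) {
  loss <- match.arg(loss)
  weights <- match.arg(weights)
  stopifnot(length(dG_bounds) == 2L, dG_bounds[1] < dG_bounds[2],
            dG_bounds[2] < 0, length(A0_bounds) == 2L,
            A0_bounds[1] > 0, A0_bounds[1] < A0_bounds[2],
            log_floor > 0, n_grid >= 5L, n_bootstrap >= 0L)
  structure(list(loss = loss, weights = weights, log_floor = log_floor,
                 dG_bounds = dG_bounds,
                 A0_bounds = A0_bounds, nmax_policy = nmax_policy,
                 fill_zeros = fill_zeros, n_grid = as.integer(n_grid),
                 n_bootstrap = as.integer(n_bootstrap),
                 seed = as.integer(seed)),
            class = "fit_config")
}

# resolve the nmax used for one dataset
fit_nmax <- function(dist, config) {
  if (identical(config$nmax_policy, "observed")) {
    max(dist$n[dist$density > 0])
  } else {
    as.integer(config$nmax_policy)
  }
}

# observed densities on the 1..nmax lattice (zeros filled in)
fit_observations <- function(dist, config) {
  nmax <- fit_nmax(dist, config)
  n <- seq_len(nmax)
  obs <- density_at(dist, n)
  se <- NULL
  if ("se" %in% names(dist)) {
    se <- rep(NA_real_, nmax)
    m <- match(dist$n, n)
    se[m[!is.na(m)]] <- dist$se[!is.na(m)]
  }
  keep <- if (config$fill_zeros) rep(TRUE, nmax) else obs > 0
  list(n = n, obs = obs, se = se, keep = keep, nmax = nmax,
       ctot = attr(dist, "ctot"), cmon = obs[1])
}

# loss of a model curve against prepared observations
curve_loss <- function(model, ob, config) {
  if (config$loss == "log") {
    r <- log(model[ob$keep] + config$log_floor) -
      log(ob$obs[ob$keep] + config$log_floor)
    sum(r^2)
  } else {
    w <- rep(1, ob$nmax)
    if (config$weights == "inverse_se" && !is.null(ob$se)) {
      ok <- !is.na(ob$se) & ob$se > 0
      w[ok] <- 1 / ob$se[ok]^2
      w[!ok] <- stats::median(w[ok])
    }
    sum(w[ob$keep] * (model[ob$keep] - ob$obs[ob$keep])^2)
  }
}

# model curve for one dataset at candidate dG: cmon pinned to the observed
# monomer density, A0 resolved by the mass constraint. Returns NULL when no
# admissible A0 exists.
profile_curve <- function(dG, ob, config, alpha = 0.5) {
  A0 <- solve_A0_from_total(dG, ob$cmon, ob$ctot, ob$nmax, alpha = alpha,
                            lower = config$A0_bounds[1],
                            upper = config$A0_bounds[2])
  if (is.na(A0)) return(NULL)
  p <- aggregation_params(dG, A0, alpha)
  list(A0 = A0, params = p, model = nmer_density(p, ob$cmon, ob$n))
}

# summed profile objective across datasets; attributes carry per-dataset A0
profile_objective <- function(dG, obs_list, config, alpha = 0.5) {
  total <- 0
  A0s <- numeric(length(obs_list))
  for (i in seq_along(obs_list)) {
    pc <- profile_curve(dG, obs_list[[i]], config, alpha)
    if (is.null(pc)) return(structure(Inf, A0 = NA_real_))
    total <- total + curve_loss(pc$model, obs_list[[i]], config)
    A0s[i] <- pc$A0
  }
  structure(total, A0 = A0s)
}

# deterministic 1D minimization: coarse grid then local golden-section refine
profile_minimize <- function(obs_list, config, alpha = 0.5) {
  f <- function(dG) as.numeric(profile_objective(dG, obs_list, config, alpha))
  grid <- seq(config$dG_bounds[1], config$dG_bounds[2], length.out = config$n_grid)
  vals <- vapply(grid, f, numeric(1))
  if (all(!is.finite(vals))) {
    return(list(dG = NA_real_, value = Inf, converged = FALSE))
  }
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(f, c(lo, hi), tol = 1e-8)
  # guard against a boundary minimum of the refinement window
  if (opt$objective <= vals[i]) {
    list(dG = opt$minimum, value = opt$objective,
         converged = is.finite(opt$objective) &&
           opt$minimum > config$dG_bounds[1] + 1e-6 &&
           opt$minimum < config$dG_bounds[2] - 1e-6)
  } else {
    list(dG = grid[i], value = vals[i], converged = FALSE)
  }
}

#' Fit the aggregation model to one measured size distribution
#'
#' Fits the HOTS size-distribution law under the mass constraint that the
#' fitted curve holds exactly the dataset's total protein density. The
#' observed monomer density fixes `cmon`; for each candidate cohesion energy
#' the configurational area `A0` is resolved from the constraint, so
#' determining either of (`dG_bulk`, `A0`) specifies the other and the fit
#' reduces to a deterministic 1D profile search over `dG_bulk`.
#'
#' @param dist A [size_distribution] with at least 3 nonzero size bins,
#'   nonzero monomer density, and a declared/derivable total density.
#' @param config A [fit_config()].
#' @return A `hots_fit` object: `dG_bulk`, per-dataset `A0`, `cmon`,
#'   `objective`, `converged`, residual curves, and bootstrap CI when
#'   requested.
#' @examples
#' p <- aggregation_params(-2, 0.04)
#' cmon <- solve_monomer_from_total(p, ctot = 5, nmax = 60)
#' d <- size_distribution(1:60, nmer_density(p, cmon, 1:60))
#' fit_single(d)
#' @export
fit_single <- function(dist, config = fit_config()) {
  fit_global(list(dist), config)
}

#' Fit several size distributions with one shared cohesion energy
#'
#' As [fit_single()], but a single global `dG_bulk` is shared across all
#' datasets while each dataset's `A0` is resolved from its own observed
#' monomer and total densities; the objective is the sum of per-dataset
#' losses.
#'
#' @param dists A list of [size_distribution]s (>= 1; >= 2 for a genuinely
#'   global fit).
#' @param config A [fit_config()].
#' @return A `hots_fit` object (see [fit_single()]).
#' @export
fit_global <- function(dists, config = fit_config()) {
  stopifnot(is.list(dists), length(dists) >= 1,
            all(vapply(dists, inherits, TRUE, "size_distribution")))
  stopifnot(inherits(config, "fit_config"))
  for (d in dists) {
    if (sum(d$density > 0) < 3L) {
      stop("underdetermined: a dataset has fewer than 3 nonzero size bins",
           call. = FALSE)
    }
    if (density_at(d, 1L) <= 0) {
      stop("dataset has zero observed monomer density; cmon cannot be pinned",
           call. = FALSE)
    }
  }
  if (config$loss == "auto") {
    config$loss <- if (all(vapply(dists, function(d) "se" %in% names(d), TRUE)))
      "density" else "log"
  }
  obs_list <- lapply(dists, fit_observations, config = config)
  best <- profile_minimize(obs_list, config)
  if (!is.finite(best$value)) {
    stop("fit failed: no admissible (dG_bulk, A0) under the mass constraint",
         call. = FALSE)
  }
  at <- profile_objective(best$dG, obs_list, config)
  A0s <- attr(at, "A0")
  curves <- vector("list", length(dists))
  resid <- vector("list", length(dists))
  for (i in seq_along(dists)) {
    pc <- profile_curve(best$dG, obs_list[[i]], config)
    curves[[i]] <- pc
    resid[[i]] <- pc$model - obs_list[[i]]$obs
  }
  ci <- NULL
  if (config$n_bootstrap > 0L) {
    ci <- bootstrap_dG(dists, config)
  }
  structure(list(
    dG_bulk = best$dG,
    A0 = A0s,
    cmon = vapply(obs_list, function(o) o$cmon, numeric(1)),
    ctot = vapply(obs_list, function(o) o$ctot, numeric(1)),
    nmax = vapply(obs_list, function(o) o$nmax, numeric(1)),
    objective = as.numeric(at),
    converged = isTRUE(best$converged),
    residuals = resid,
    config = config,
    boot = ci,
    n_datasets = length(dists)
  ), class = "hots_fit")
}

#' @export
print.hots_fit <- function(x, ...) {
  cat("Mass-constrained reversible-aggregation fit\n")
  cat(sprintf("  datasets: %d   converged: %s\n", x$n_datasets, x$converged))
  cat(sprintf("  dG_bulk (global): %.4g RT", x$dG_bulk))
  if (!is.null(x$boot)) {
    cat(sprintf("   [boot 95%% CI %.4g, %.4g]", x$boot$ci[1], x$boot$ci[2]))
  }
  cat("\n")
  cat(sprintf("  A0 per dataset (um^2): %s\n",
              paste(sprintf("%.3g", x$A0), collapse = ", ")))
  cat(sprintf("  cmon per dataset (um^-2): %s\n",
              paste(sprintf("%.3g", x$cmon), collapse = ", ")))
  cat(sprintf("  objective: %.6g\n", x$objective))
  invisible(x)
}

# cluster-level nonparametric bootstrap of the global dG estimate.
# Requires counts (or counts reconstructable from density * area).
bootstrap_dG <- function(dists, config) {
  set.seed(config$seed)
  reps <- numeric(config$n_bootstrap)
  for (b in seq_len(config$n_bootstrap)) {
    res <- lapply(dists, function(d) {
      area <- attr(d, "area")
      counts <- if ("counts" %in% names(d)) d$counts
                else if (!is.na(area)) d$density * area
                else stop("bootstrap needs counts or an area", call. = FALSE)
      if (is.na(area)) area <- 1
      sizes <- rep(d$n, round(counts))
      resampled <- sample(sizes, replace = TRUE)
      tab <- table(factor(resampled, levels = sort(unique(resampled))))
      nn <- as.integer(names(tab))
      size_distribution(n = nn, density = as.numeric(tab) / area, area = area)
    })
    fit <- tryCatch(fit_global(res, strip_bootstrap(config)),
                    error = function(e) NULL)
    reps[b] <- if (is.null(fit)) NA_real_ else fit$dG_bulk
  }
  reps <- reps[!is.na(reps)]
  list(replicates = reps,
       ci = stats::quantile(reps, c(0.025, 0.975), names = FALSE))
}

strip_bootstrap <- function(config) {
  config$n_bootstrap <- 0L
  config
}

#' Model curve implied by a fit
#'
#' Evaluates the fitted size-distribution law for one dataset of a fit over
#' `n = 1..nmax`.
#'
#' @param fit A `hots_fit` from [fit_single()] or [fit_global()].
#' @param dataset_index Which dataset's (`A0`, `cmon`) to use (default 1).
#' @param nmax Largest size to tabulate (default: the nmax used in the fit).
#' @return A [size_distribution] of model densities.
#' @export
predict_curve <- function(fit, dataset_index = 1L, nmax = NULL) {
  stopifnot(inherits(fit, "hots_fit"))
  if (dataset_index < 1L || dataset_index > fit$n_datasets) {
    stop("dataset_index out of range", call. = FALSE)
  }
  if (is.null(nmax)) nmax <- fit$nmax[dataset_index]
  p <- aggregation_params(fit$dG_bulk, fit$A0[dataset_index])
  n <- seq_len(nmax)
  size_distribution(n = n, density = nmer_density(p, fit$cmon[dataset_index], n))
}

#' Refit a panel with one shared configurational area
#'
#' With the cohesion energy held fixed (typically at a global estimate from
#' [fit_global()]), finds the single `A0` shared by all datasets that best
#' matches the low-n cluster densities as functions of total density. For a
#' candidate `A0`, each dataset's `cmon` is resolved from its total density
#' via [solve_monomer_from_total()]; the loss is summed over sizes
#' `n = 1..n_match` across datasets.
#'
#' @param dists A list of [size_distribution]s.
#' @param dG_bulk Fixed cohesion energy (RT).
#' @param n_match Sizes entering the loss (default `1:6`).
#' @param config A [fit_config()] (its loss settings are reused;
#'   `A0_bounds` bound the search).
#' @return A list: `A0` (shared), `dG_bulk`, per-dataset `cmon`, `objective`.
#' @export
fit_shared_A0 <- function(dists, dG_bulk, n_match = 1:6, config = fit_config()) {
  stopifnot(is.list(dists), length(dists) >= 1, dG_bulk < 0)
  if (config$loss == "auto") {
    config$loss <- if (all(vapply(dists, function(d) "se" %in% names(d), TRUE)))
      "density" else "log"
  }
  obs_list <- lapply(dists, fit_observations, config = config)
  n_match <- check_cluster_sizes(n_match)
  f <- function(logA0) {
    A0 <- exp(logA0)
    p <- aggregation_params(dG_bulk, A0)
    total <- 0
    for (ob in obs_list) {
      cmon <- solve_monomer_from_total(p, ob$ctot, ob$nmax)
      model <- nmer_density(p, cmon, n_match)
      obs <- ob$obs[n_match[n_match <= ob$nmax]]
      mod <- model[n_match <= ob$nmax]
      if (config$loss == "log") {
        total <- total + sum((log(mod + config$log_floor) -
                                log(obs + config$log_floor))^2)
      } else {
        total <- total + sum((mod - obs)^2)
      }
    }
    total
  }
  opt <- stats::optimize(f, log(config$A0_bounds), tol = 1e-9)
  A0 <- exp(opt$minimum)
  p <- aggregation_params(dG_bulk, A0)
  cmons <- vapply(obs_list, function(ob) solve_monomer_from_total(p, ob$ctot, ob$nmax),
                  numeric(1))
  list(A0 = A0, dG_bulk = dG_bulk, cmon = cmons, objective = opt$objective)
}
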