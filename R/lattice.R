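#' Configuration of the sticky lattice random walk
#'
#' Toy Monte-Carlo model of self-binding diffusing membrane proteins:
#' excluded-volume random walkers on a square grid whose probability of
#' staying put is higher when they have at least one occupied 4-neighbor.
#' Transient clusters emerge purely from this kinetic stickiness; the model
#' carries no explicit n-mer energy.
#'
#' Per sweep, every particle (in a freshly shuffled order) draws among
#' \{stay, up, down, left, right\} with weights \{w, 1, 1, 1, 1\}, where
#' `w = pwait_bound` if a 4-neighbor site is occupied and `pwait_free`
#' otherwise; a draw into an occupied or out-of-bounds site becomes a stay.
#' With the default `pwait_free = 1` an isolated interior particle takes each
#' of the five outcomes with probability 1/5.
#'
#' @param n_particles Number of walkers; at most `width * height`.
#' @param width,height Grid dimensions in sites (default 100 x 100).
#' @param pwait_bound Stay weight with >= 1 occupied 4-neighbor (default 50).
#' @param pwait_free Stay weight with no neighbor (default 1).
#' @param rpg Real distance per grid unit in um (default 0.1, so one site
#'   covers 0.01 um^2 and the default grid spans 100 um^2).
#' @param D Optional diffusion coefficient (um^2/s); maps one sweep to
#'   `rpg^2 / (4 D)` seconds. Not used by the dynamics.
#' @param boundary `"reflecting"` (blocked at walls, the default) or
#'   `"periodic"`.
#' @return A `lattice_config` object.
#' @export
lattice_config <- function(n_particles, width = 100L, height = 100L,
                           pwait_bound = 50, pwait_free = 1, rpg = 0.1,
                           D = NULL, boundary = c("reflecting", "periodic")) {
  boundary <- match.arg(boundary)
  stopifnot(width >= 1, height >= 1, n_particles >= 1,
            n_particles <= width * height,
            pwait_bound >= 1, pwait_free >= 1, rpg > 0)
  structure(list(
    width = as.integer(width), height = as.integer(height),
    n_particles = as.integer(n_particles),
    pwait_bound = pwait_bound, pwait_free = pwait_free,
    rpg = rpg, D = D, boundary = boundary
  ), class = "lattice_config")
}

#' @export
print.lattice_config <- function(x, ...) {
  cat(sprintf("Lattice config: %d particles on %d x %d grid (%s)\n",
              x$n_particles, x$width, x$height, x$boundary))
  cat(sprintf("  stay weights: bound %.3g / free %.3g; site length %.3g um\n",
              x$pwait_bound, x$pwait_free, x$rpg))
  cat(sprintf("  area %.4g um^2, density %.4g um^-2\n",
              lattice_area(x), x$n_particles / lattice_area(x)))
  invisible(x)
}

#' Physical membrane area represented by a lattice
#' @param config A [lattice_config()].
#' @return Area in um^2 (`width * height * rpg^2`).
#' @export
lattice_area <- function(config) {
  config$width * config$height * config$rpg^2
}

#' Initial lattice state with uniformly placed particles
#'
#' Particles are dropped on distinct sites chosen uniformly at random
#' (exclusion respected). Uses the current R RNG stream.
#'
#' @param config A [lattice_config()].
#' @return A `lattice_state`: integer matrix of 0-based (row, col) positions
#'   with the config attached.
#' @export
lattice_init <- function(config) {
  stopifnot(inherits(config, "lattice_config"))
  sites <- sample.int(config$width * config$height, config$n_particles) - 1L
  pos <- cbind(row = sites %/% config$width, col = sites %% config$width)
  new_lattice_state(pos, config, step = 0L)
}

new_lattice_state <- function(pos, config, step) {
  structure(pos, config = config, step = as.integer(step),
            class = c("lattice_state", class(pos)))
}

#' @export
print.lattice_state <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Lattice state: %d particles on %d x %d grid after %d sweep(s)\n",
              nrow(x), cfg$width, cfg$height, attr(x, "step")))
  invisible(x)
}

#' Advance a lattice state by whole sweeps
#'
#' @param state A `lattice_state` (from [lattice_init()] or a previous call).
#' @param n_sweeps Number of sweeps to advance (default 1).
#' @return The advanced `lattice_state`.
#' @export
lattice_step <- function(state, n_sweeps = 1L) {
  cfg <- attr(state, "config")
  stopifnot(inherits(state, "lattice_state"), n_sweeps >= 1)
  pos <- lattice_sweep_cpp(cfg$width, cfg$height, state[, 1], state[, 2],
                           cfg$pwait_bound, cfg$pwait_free,
                           cfg$boundary == "periodic", as.integer(n_sweeps))
  colnames(pos) <- c("row", "col")
  new_lattice_state(pos, cfg, attr(state, "step") + n_sweeps)
}

#' Run a seeded lattice trajectory and sample cluster statistics
#'
#' Runs `n_sweeps` sweeps from a fresh uniform initial placement, discarding
#' the first `burn_in` sweeps and sampling every `sample_every` sweeps
#' thereafter. At each sample the 4-connected cluster-size histogram is
#' accumulated; optionally the sampled particle positions are kept.
#'
#' The defaults equilibrate generously: burn-in of ten sweeps per grid site
#' is far beyond the observed relaxation of the cluster-size histogram on the
#' default grid.
#'
#' @param config A [lattice_config()].
#' @param n_sweeps Total sweeps.
#' @param burn_in Sweeps discarded before sampling (default `10 * width * height`).
#' @param sample_every Sampling stride in sweeps (default 10).
#' @param seed Optional integer seed applied via [set.seed()].
#' @param keep_states Keep sampled `lattice_state`s (memory-heavy; default FALSE).
#' @return A list with `hist`: mean cluster count per size and sample (length
#'   `n_particles`); `n_samples`; `final`: final `lattice_state`; `states`:
#'   sampled states (if kept); `config`.
#' @export
lattice_run <- function(config, n_sweeps, burn_in = 10L * config$width * config$height,
                        sample_every = 10L, seed = NULL, keep_states = FALSE) {
  stopifnot(inherits(config, "lattice_config"), n_sweeps > burn_in)
  if (!is.null(seed)) set.seed(seed)
  init <- lattice_init(config)
  res <- lattice_run_cpp(config$width, config$height, init[, 1], init[, 2],
                         config$pwait_bound, config$pwait_free,
                         as.integer(n_sweeps), as.integer(burn_in),
                         as.integer(sample_every),
                         config$boundary == "periodic", keep_states)
  final <- res$final
  colnames(final) <- c("row", "col")
  states <- NULL
  if (keep_states) {
    states <- lapply(res$states, function(p) {
      colnames(p) <- c("row", "col")
      new_lattice_state(p, config, NA_integer_)
    })
  }
  list(hist = res$hist_total / res$n_samples, n_samples = res$n_samples,
       final = new_lattice_state(final, config, n_sweeps),
       states = states, config = config)
}

#' Exact move-outcome probabilities for one particle
#'
#' Enumerates the five weighted outcomes \{stay, up, down, left, right\} of a
#' single particle in a given state, folding blocked draws (occupied target
#' or wall under reflecting boundaries) into the stay outcome. Useful for
#' verifying the update rule against hand enumeration: an isolated interior
#' particle with unit weights has probability 1/5 for each outcome; a bound
#' particle with stay weight 50 and one blocked move stays with probability
#' (50 + 1)/54.
#'
#' @param state A `lattice_state`.
#' @param index Particle index (row of the state matrix).
#' @return Named numeric vector of probabilities (stay, up, down, left,
#'   right) summing to 1; blocked directions have probability 0.
#' @export
step_outcome_probs <- function(state, index) {
  stopifnot(inherits(state, "lattice_state"),
            index >= 1, index <= nrow(state))
  cfg <- attr(state, "config")
  occ <- matrix(FALSE, cfg$height, cfg$width)
  occ[state[, 1] + 1L + state[, 2] * cfg$height] <- TRUE
  r <- state[index, 1]
  cc <- state[index, 2]
  look <- function(dr, dc) {
    rr <- r + dr
    c2 <- cc + dc
    if (cfg$boundary == "periodic") {
      rr <- rr %% cfg$height
      c2 <- c2 %% cfg$width
      list(blocked = occ[rr + 1L, c2 + 1L], neighbor = occ[rr + 1L, c2 + 1L])
    } else if (rr < 0 || rr >= cfg$height || c2 < 0 || c2 >= cfg$width) {
      list(blocked = TRUE, neighbor = FALSE) # walls block but do not bind
    } else {
      list(blocked = occ[rr + 1L, c2 + 1L], neighbor = occ[rr + 1L, c2 + 1L])
    }
  }
  dirs <- list(up = c(-1L, 0L), down = c(1L, 0L), left = c(0L, -1L),
               right = c(0L, 1L))
  info <- lapply(dirs, function(d) look(d[1], d[2]))
  bound <- any(vapply(info, `[[`, TRUE, "neighbor"))
  w <- if (bound) cfg$pwait_bound else cfg$pwait_free
  total <- w + 4
  probs <- c(stay = w / total,
             vapply(info, function(i) if (i$blocked) 0 else 1 / total,
                    numeric(1)))
  probs["stay"] <- probs["stay"] +
    sum(vapply(info, function(i) if (i$blocked) 1 / total else 0, numeric(1)))
  probs
}

#' Cluster-size histogram of a lattice state
#'
#' Bins particles into 4-connected components of occupied sites.
#'
#' @param state A `lattice_state`.
#' @return A [size_distribution] with raw counts over the physical area
#'   of the grid; `sum(n * counts)` equals the particle number.
#' @export
extract_clusters <- function(state) {
  stopifnot(inherits(state, "lattice_state"))
  cfg <- attr(state, "config")
  lab <- lattice_components_cpp(cfg$width, cfg$height, state[, 1], state[, 2],
                                cfg$boundary == "periodic")
  sizes <- tabulate(tabulate(lab))
  n <- which(sizes > 0)
  area <- lattice_area(cfg)
  size_distribution(n = n, density = sizes[n] / area, counts = sizes[n],
                    area = area)
}

#' Time-averaged cluster size distributions across protein densities
#'
#' Runs one seeded trajectory per requested density (particle number =
#' density x grid area, rounded with a warning if fractional) and converts
#' the time-averaged 4-connected cluster-size histograms into physical
#' densities (um^-2). This reproduces, in silico, a dataset panel of
#' cluster-size distributions at increasing expression level.
#'
#' @param base A [lattice_config()] supplying grid and weights (its
#'   `n_particles` is ignored).
#' @param densities Total protein densities in um^-2.
#' @param n_sweeps,burn_in,sample_every Passed to [lattice_run()].
#' @param seed Optional integer; density i runs with `seed + i - 1`.
#' @return A list of [size_distribution]s, one per density, each with the
#'   per-size Monte-Carlo standard error of the time average (`se`).
#' @export
density_sweep <- function(base, densities, n_sweeps,
                          burn_in = 10L * base$width * base$height,
                          sample_every = 10L, seed = NULL) {
  stopifnot(inherits(base, "lattice_config"), length(densities) >= 1)
  area <- lattice_area(base)
  out <- vector("list", length(densities))
  for (i in seq_along(densities)) {
    n_part <- densities[i] * area
    if (abs(n_part - round(n_part)) > 1e-9) {
      warning(sprintf("density %.4g um^-2 implies %.4g particles; rounding",
                      densities[i], n_part), call. = FALSE)
    }
    n_part <- as.integer(round(n_part))
    cfg <- lattice_config(n_particles = n_part, width = base$width,
                          height = base$height, pwait_bound = base$pwait_bound,
                          pwait_free = base$pwait_free, rpg = base$rpg,
                          D = base$D, boundary = base$boundary)
    run <- lattice_run(cfg, n_sweeps = n_sweeps, burn_in = burn_in,
                       sample_every = sample_every,
                       seed = if (is.null(seed)) NULL else seed + i - 1L)
    h <- run$hist
    keep <- which(h > 0)
    # crude MC error: treat samples as independent (they are thinned);
    # per-sample counts are ~Poisson, so var ~ mean
    se <- sqrt(h[keep] / run$n_samples) / area
    out[[i]] <- size_distribution(n = keep, density = h[keep] / area, se = se,
                                  area = area)
  }
  out
}
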