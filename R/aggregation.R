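#' Reversible-aggregation model parameters
#'
#' Bundle the two parameters of the two-dimensional reversible-aggregation
#' (HOTS) model: the standard free energy of transferring a monomer into an
#' infinite close-packed "bulk phase", and the configurational unit area that
#' sets the standard-state concentration on the membrane.
#'
#' All energies are dimensionless multiples of RT; conversion to kJ/mol is a
#' presentation concern only. The boundary energy of an n-mer is
#' `n^boundary_exponent * dG_bulk`: the default exponent 1/2 corresponds to
#' compact two-dimensional clusters whose perimeter grows as the square root
#' of their area. An exponent of 0 models linear aggregates (polymer chains),
#' whose unbonded ends do not grow with n; such models support no phase
#' transition (see [is_phase_transition_capable()]).
#'
#' @param dG_bulk Monomer-to-bulk standard free energy in RT units. Negative
#'   values mean cohesive self-interaction.
#' @param A0 Configurational unit area in um^2; `1/A0` is the standard-state
#'   concentration in um^-2. Must be positive.
#' @param boundary_exponent Exponent alpha of the boundary-energy term
#'   `n^alpha * dG_bulk`, in `[0, 1)`. Default 0.5.
#' @return An object of class `aggregation_params`.
#' @examples
#' aggregation_params(dG_bulk = -1.24, A0 = 0.58)
#' @seealso [critical_monomer_concentration()], [nmer_density()]
#' @export
aggregation_params <- function(dG_bulk, A0, boundary_exponent = 0.5) {
  stopifnot(is.numeric(dG_bulk), length(dG_bulk) == 1L, is.finite(dG_bulk))
  if (!is.numeric(A0) || length(A0) != 1L || !is.finite(A0) || A0 <= 0) {
    stop("`A0` must be a single positive, finite area (um^2)", call. = FALSE)
  }
  stopifnot(is.numeric(boundary_exponent), length(boundary_exponent) == 1L)
  if (boundary_exponent < 0 || boundary_exponent >= 1) {
    stop("`boundary_exponent` must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(dG_bulk = as.numeric(dG_bulk), A0 = as.numeric(A0),
         boundary_exponent = as.numeric(boundary_exponent)),
    class = "aggregation_params"
  )
}

#' @export
print.aggregation_params <- function(x, ...) {
  cat("Reversible-aggregation parameters\n")
  cat(sprintf("  dG(mon -> bulk): %.4g RT\n", x$dG_bulk))
  cat(sprintf("  A0:              %.4g um^2  (standard state 1/A0 = %.4g um^-2)\n",
              x$A0, 1 / x$A0))
  cat(sprintf("  boundary exponent: %.3g\n", x$boundary_exponent))
  if (is_phase_transition_capable(x)) {
    cat(sprintf("  critical monomer concentration: %.4g um^-2\n",
                critical_monomer_concentration(x)))
  } else {
    cat("  no phase transition (requires dG_bulk < 0 and exponent > 0)\n")
  }
  invisible(x)
}

#' Can the model undergo a 2D phase transition?
#'
#' The infinite series for the total protein density of the critical cluster
#' distribution converges -- i.e. a bulk phase can condense out of a finite
#' protein density -- only when the cohesion free energy is negative and the
#' boundary energy grows with cluster size (exponent > 0). Linear aggregates
#' (exponent 0, boundary energy independent of n) are flagged non-critical.
#'
#' @param params An [aggregation_params()] object.
#' @return `TRUE` if a finite critical total concentration exists.
#' @export
is_phase_transition_capable <- function(params) {
  stopifnot(inherits(params, "aggregation_params"))
  params$dG_bulk < 0 && params$boundary_exponent > 0
}

#' Standard free energy of forming an n-mer from n monomers
#'
#' Thermodynamic-cycle result for a compact two-dimensional cluster: the
#' monomer-to-n-mer standard free energy is `(n - n^alpha) * dG_bulk`,
#' the bulk-transfer term less a perimeter (boundary) correction.
#'
#' @inheritParams is_phase_transition_capable
#' @param n Cluster size(s), positive integers.
#' @return Free energy in RT units, same length as `n`; zero at `n = 1`.
#' @examples
#' delta_g_nmer(aggregation_params(-2, 1), n = 4)  # (4 - 2) * (-2) = -4 RT
#' @export
delta_g_nmer <- function(params, n) {
  stopifnot(inherits(params, "aggregation_params"))
  n <- check_cluster_sizes(n)
  (n - n^params$boundary_exponent) * params$dG_bulk
}

#' Equilibrium n-mer density at a given monomer density
#'
#' The central closed form of the model: the density of clusters of n copies
#' in equilibrium with free monomers at density `cmon` is
#' \deqn{c_n = A_0^{-1} (A_0 c_{mon})^n \exp[(n^\alpha - n)\,\Delta G^0/RT].}
#' Evaluation is in log space so very large `n` underflow gracefully to 0.
#'
#' @inheritParams delta_g_nmer
#' @param cmon Monomer density in um^-2, a single non-negative number.
#' @return Density (um^-2) of n-mers, same length as `n`; equals `cmon`
#'   exactly at `n = 1`.
#' @examples
#' p <- aggregation_params(-1.24, 0.58)
#' nmer_density(p, cmon = 0.45, n = 1:5)
#' @export
nmer_density <- function(params, cmon, n) {
  stopifnot(inherits(params, "aggregation_params"))
  stopifnot(is.numeric(cmon), length(cmon) == 1L, is.finite(cmon), cmon >= 0)
  n <- check_cluster_sizes(n)
  if (cmon == 0) return(rep(0, length(n)))
  log_c <- -log(params$A0) + n * log(params$A0 * cmon) +
    (n^params$boundary_exponent - n) * params$dG_bulk
  out <- exp(log_c)
  out[n == 1L] <- cmon # exact identity, avoids round trip through log
  out
}

#' Critical monomer concentration
#'
#' Monomer density at equilibrium with an infinite bulk phase:
#' `1/A0 * exp(dG_bulk)`. Above the associated critical total density,
#' excess protein partitions into bulk-phase sheets.
#'
#' @inheritParams is_phase_transition_capable
#' @return Density in um^-2.
#' @examples
#' critical_monomer_concentration(aggregation_params(-1.24, 0.58)) # ~0.50
#' @export
critical_monomer_concentration <- function(params) {
  stopifnot(inherits(params, "aggregation_params"))
  exp(params$dG_bulk) / params$A0
}

#' Cluster size distribution at the critical point
#'
#' At `cmon = cmon_crit` the n-mer density reduces to
#' `1/A0 * exp(n^alpha * dG_bulk)`; this is the largest (over cmon)
#' monotonically decreasing HOTS distribution the model supports.
#'
#' @inheritParams is_phase_transition_capable
#' @param nmax Largest cluster size to tabulate.
#' @return A [size_distribution] over `n = 1..nmax` (its `ctot` is the mass of
#'   the tabulated part only, not the full series; see
#'   [critical_total_concentration()]).
#' @export
critical_distribution <- function(params, nmax) {
  stopifnot(inherits(params, "aggregation_params"))
  nmax <- check_cluster_sizes(nmax)
  stopifnot(length(nmax) == 1L)
  n <- seq_len(nmax)
  dens <- exp(n^params$boundary_exponent * params$dG_bulk) / params$A0
  size_distribution(n = n, density = dens)
}

#' Critical total concentration (series sum)
#'
#' Total protein density held in the critical cluster distribution,
#' \deqn{c_{tot}^{crit} = A_0^{-1} \sum_{n\ge1} n\, e^{n^\alpha \Delta G^0/RT},}
#' the precise location of the 2D phase transition: protein in excess of this
#' density enters the bulk phase. The series converges only for
#' `dG_bulk < 0` with `boundary_exponent > 0`; otherwise this errors.
#'
#' Terms are summed until an analytic tail bound (an incomplete-gamma
#' integral bound on the remainder, valid once the summand is decreasing)
#' falls below `rel_tol` times the partial sum.
#'
#' @inheritParams is_phase_transition_capable
#' @param rel_tol Relative tolerance on the truncation error.
#' @return Density in um^-2.
#' @export
critical_total_concentration <- function(params, rel_tol = 1e-10) {
  stopifnot(inherits(params, "aggregation_params"))
  if (!is_phase_transition_capable(params)) {
    stop("no finite critical total concentration: the series sum(n * exp(n^alpha * dG)) ",
         "diverges unless dG_bulk < 0 and boundary_exponent > 0 ",
         "(linear aggregates never condense)", call. = FALSE)
  }
  stopifnot(is.numeric(rel_tol), rel_tol > 0)
  a <- params$boundary_exponent
  b <- -params$dG_bulk # > 0
  # summand f(n) = n * exp(-b * n^a); decreasing once n^a > 1/(a*b)
  n_dec <- ceiling((1 / (a * b))^(1 / a))
  total <- 0
  n <- 1L
  block <- 1024L
  repeat {
    idx <- seq.int(n, n + block - 1L)
    total <- total + sum(idx * exp(-b * idx^a))
    n <- n + block
    if (n > n_dec) {
      # tail over m > N bounded by integral_N^inf x exp(-b x^a) dx
      tail_bound <- series_tail_integral(n - 1L, a, b)
      if (tail_bound <= rel_tol * total) break
    }
    if (n > 1e9) stop("series did not converge within 1e9 terms", call. = FALSE)
  }
  total / params$A0
}

# integral_N^inf x exp(-b x^a) dx  via the substitution u = b x^a:
# (1 / (a b^(2/a))) * Gamma(2/a) * Q(2/a, b N^a)
series_tail_integral <- function(N, a, b) {
  s <- 2 / a
  exp(lgamma(s) + pgamma(b * N^a, s, lower.tail = FALSE, log.p = TRUE)) /
    (a * b^s)
}

#' Solve for the monomer density from a total density (mass constraint)
#'
#' Inverts the mass-balance constraint
#' \deqn{c_{tot} = \sum_{n=1}^{n_{max}} n\, c_n(c_{mon})}
#' for `cmon`. The left side is strictly increasing in `cmon`, so the root is
#' unique; it always lies in `(0, ctot]` because the monomer term alone equals
#' `cmon`. Solved by bisection (robust to overflow of the high-n terms) and
#' polished to a relative tolerance of 1e-12.
#'
#' @inheritParams is_phase_transition_capable
#' @param ctot Total protein density in um^-2, positive.
#' @param nmax Largest cluster size entering the mass balance.
#' @return The monomer density `cmon` in um^-2.
#' @examples
#' p <- aggregation_params(-1.24, 0.58)
#' cmon <- solve_monomer_from_total(p, ctot = 4.3, nmax = 50)
#' sum(1:50 * nmer_density(p, cmon, 1:50)) # = 4.3
#' @export
solve_monomer_from_total <- function(params, ctot, nmax) {
  stopifnot(inherits(params, "aggregation_params"))
  stopifnot(is.numeric(ctot), length(ctot) == 1L, is.finite(ctot), ctot > 0)
  nmax <- check_cluster_sizes(nmax)
  stopifnot(length(nmax) == 1L)
  n <- seq_len(nmax)
  mass <- function(cmon) sum(n * nmer_density(params, cmon, n))
  lo <- 0
  hi <- ctot
  # bisection: mass(0) = 0 < ctot, mass(ctot) >= ctot (may be Inf)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    m <- mass(mid)
    if (is.finite(m) && m < ctot) lo <- mid else hi <- mid
    if ((hi - lo) <= 1e-13 * hi) break
  }
  root <- (lo + hi) / 2
  if (abs(mass(root) - ctot) > 1e-9 * ctot) {
    stop(sprintf(
      "mass-balance solve failed: residual %.3g at cmon = %.6g (attainable total at bracket top: %.6g)",
      mass(root) - ctot, root, mass(ctot)), call. = FALSE)
  }
  root
}

# Inverse problem used by the fitter: given dG and a *measured* cmon, find the
# A0 that makes the truncated mass balance hit ctot. Increasing in A0.
# Returns NA (with attribute) when no A0 in [lower, upper] attains ctot.
solve_A0_from_total <- function(dG, cmon, ctot, nmax, alpha = 0.5,
                                lower = 1e-4, upper = 10) {
  stopifnot(cmon > 0, ctot >= cmon)
  n <- seq_len(nmax)
  mass <- function(A0) {
    p <- aggregation_params(dG, A0, alpha)
    sum(n * nmer_density(p, cmon, n))
  }
  m_lo <- mass(lower)
  m_hi <- mass(upper)
  if (is.finite(m_lo) && m_lo > ctot) {
    out <- NA_real_
    attr(out, "reason") <- sprintf("total %.4g at smallest A0 exceeds ctot %.4g", m_lo, ctot)
    return(out)
  }
  if (is.finite(m_hi) && m_hi < ctot) {
    out <- NA_real_
    attr(out, "reason") <- sprintf("maximum attainable total %.4g < ctot %.4g", m_hi, ctot)
    return(out)
  }
  lo <- lower
  hi <- upper
  for (i in 1:200) {
    mid <- sqrt(lo * hi) # geometric bisection: A0 spans decades
    m <- mass(mid)
    if (is.finite(m) && m < ctot) lo <- mid else hi <- mid
    if ((hi - lo) <= 1e-13 * hi) break
  }
  (lo + hi) / 2
}

# shared validation of cluster-size vectors
check_cluster_sizes <- function(n) {
  if (!is.numeric(n) || length(n) == 0 || any(!is.finite(n)) ||
      any(n < 1) || any(n != floor(n))) {
    stop("cluster sizes `n` must be positive integers", call. = FALSE)
  }
  as.integer(n)
}
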