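# Shared fixtures and independent oracles used across test files.

# Reference parameter sets exercised throughout: a cardiomyocyte-like
# near-critical receptor fit, an expression-series fit, and the
# model-comparison demo set.
params_hl1 <- function() aggregation_params(dG_bulk = -1.24, A0 = 0.58)
params_cho <- function() aggregation_params(dG_bulk = -1.82, A0 = 0.08)
params_demo <- function() aggregation_params(dG_bulk = -2.0, A0 = 0.04)

# A0 giving a requested critical total concentration at a given dG:
# ctot_crit = S(dG) / A0, with S the boundary-energy series.
a0_for_critical_total <- function(dG, ctot_crit) {
  critical_total_concentration(aggregation_params(dG, 1)) / ctot_crit
}

# O(N^2) single-linkage oracle: repeated transitive closure over the
# pairwise adjacency matrix (independent of the cell-list implementation).
brute_force_linkage <- function(x, y, cutoff) {
  n <- length(x)
  if (n == 0) return(integer(0))
  adj <- as.matrix(stats::dist(cbind(x, y))) <= cutoff
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      linked <- which(adj[i, ])
      m <- min(lab[linked])
      if (m < lab[i]) {
        lab[linked] <- m
        lab[i] <- m
        changed <- TRUE
      } else if (any(lab[linked] > lab[i])) {
        lab[linked] <- lab[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# O(N^2) oracle for 4-connected components of lattice particles.
brute_force_grid_components <- function(row, col) {
  n <- length(row)
  adj <- outer(row, row, function(a, b) abs(a - b)) +
    outer(col, col, function(a, b) abs(a - b)) == 1
  diag(adj) <- TRUE
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      linked <- which(adj[i, ])
      m <- min(lab[linked])
      if (any(lab[linked] != m)) {
        lab[linked] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# Sizes of clusters from a membership vector, as a named count table
sizes_of <- function(labels) sort(as.integer(table(labels)), decreasing = TRUE)
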