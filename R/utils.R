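## Shared internal helpers and physical constants.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Boltzmann constant in kcal/(mol K)
#'
#' Used only to convert thermal energies (kcal/mol) to temperatures (K);
#' the simulator itself works with thermal energies throughout.
#' @export
KB_KCAL_MOL_K <- 0.0019872041

#' Convert a thermal energy to a temperature
#'
#' The Langevin thermostat is parameterized by the thermal energy
#' \eqn{\beta^{-1} = k_B T} in kcal/mol.  This helper reports the
#' corresponding temperature in Kelvin, e.g. \eqn{\beta^{-1}} = 0.6 kcal/mol
#' corresponds to roughly 300 K.
#'
#' @param beta_inv thermal energy \eqn{k_B T} in kcal/mol (positive).
#' @return temperature in Kelvin.
#' @examples
#' thermal_energy_to_temperature(0.6)
#' @export
thermal_energy_to_temperature <- function(beta_inv) {
  if (!is.numeric(beta_inv) || any(!is.finite(beta_inv)) || any(beta_inv <= 0))
    stop("'beta_inv' must be a positive finite thermal energy in kcal/mol")
  beta_inv / KB_KCAL_MOL_K
}

## Squared distances between all rows of A and all rows of B (n_A x n_B).
pair_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A * A), rowSums(B * B), `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0 # guard tiny negative round-off
  d2
}

## Evaluate `code` under a temporary seed with a pinned generator kind
## (so results do not depend on the session's current RNG kind), restoring
## the caller's RNG state afterwards.  Used for deterministic structure
## generation.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  suppressWarnings(set.seed(seed, kind = "Mersenne-Twister",
                            normal.kind = "Inversion"))
  force(code)
}

## Add per-pair force contributions onto atom rows of F; idx may repeat.
accumulate_rows <- function(F, idx, contrib) {
  agg <- rowsum(contrib, idx, reorder = FALSE)
  ii <- as.integer(rownames(agg))
  F[ii, ] <- F[ii, ] + agg
  F
}

## Batch-means standard error of the mean of a (possibly autocorrelated)
## series.  Returns list(mean, se).
batch_mean_se <- function(x, n_batches = 40L) {
  n <- length(x)
  n_batches <- min(n_batches, n)
  size <- floor(n / n_batches)
  x <- x[seq_len(size * n_batches)]
  bm <- colMeans(matrix(x, nrow = size))
  list(mean = mean(bm), se = stats::sd(bm) / sqrt(n_batches))
}

## Central-difference gradient of a scalar function of an n x 3 matrix.
## Returns the NEGATIVE gradient (i.e. the force) for direct comparison
## with analytic forces.
finite_difference_forces <- function(energy_fn, x, h = 1e-5) {
  g <- x * 0
  for (i in seq_len(nrow(x))) {
    for (j in 1:3) {
      xp <- x; xp[i, j] <- xp[i, j] + h
      xm <- x; xm[i, j] <- xm[i, j] - h
      g[i, j] <- (energy_fn(xp) - energy_fn(xm)) / (2 * h)
    }
  }
  -g
}
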