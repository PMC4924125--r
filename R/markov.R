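# Markov-chain model of the residue network: row-stochastic transition
# matrix, stationary distribution, and per-node dynamical Shannon entropy.

#' Row-stochastic transition matrix from a weighted adjacency
#'
#' Normalizes each row of the non-negative weight matrix to sum to one:
#' `p_ij = a_ij / sum_k a_ik`. The zero diagonal of the adjacency is
#' preserved, so the chain never rests on a node.
#'
#' @param A Square non-negative weight matrix with zero diagonal.
#' @return The row-stochastic matrix P.
#' @export
row_stochastic <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) abort("adjacency must be square")
  if (any(A < 0)) abort("adjacency entries must be non-negative")
  rs <- rowSums(A)
  if (any(rs == 0)) {
    abort(sprintf("node(s) %s have zero total weight; the chain is singular there",
                  paste(which(rs == 0), collapse = ", ")))
  }
  A / rs
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Solves `pi P = pi` for the dominant left eigenvector: a dense
#' eigen-decomposition of `t(P)` takes the eigenvector whose eigenvalue is
#' closest to 1, clips negligible negative components, and renormalizes to
#' sum 1. The result is verified against the stationarity residual
#' `max |pi P - pi|`; if the eigen route fails the tolerance, power
#' iteration is used as a fallback before erroring.
#'
#' For the symmetric adjacencies produced by [node_adjacency()] the chain is
#' reversible and `pi_i` is proportional to the row sum of A; the solver
#' reproduces that closed form to high accuracy.
#'
#' @param P Row-stochastic matrix.
#' @param tol Maximum allowed stationarity residual.
#' @return Numeric vector `pi` (non-negative, sums to 1) with attributes
#'   `residual` and `eigenvalue_gap` (1 minus the modulus of the second
#'   eigenvalue, a mixing diagnostic).
#' @export
stationary_distribution <- function(P, tol = 1e-10) {
  P <- as.matrix(P)
  n <- nrow(P)
  if (n == 1L) return(structure(1, residual = 0, eigenvalue_gap = 1))
  if (max(abs(rowSums(P) - 1)) > 1e-8) abort("P is not row-stochastic")

  e <- eigen(t(P))
  k <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, k])
  v[abs(v) < 1e-12] <- 0
  if (all(v <= 0)) v <- -v
  if (any(v < 0)) v <- abs(v)
  pi_vec <- v / sum(v)
  gap <- 1 - sort(Mod(e$values), decreasing = TRUE)[2L]

  residual <- max(abs(drop(pi_vec %*% P) - pi_vec))
  if (residual > tol) {
    # power-iteration fallback
    pi_vec <- rep(1 / n, n)
    for (it in seq_len(100000L)) {
      nxt <- drop(pi_vec %*% P)
      nxt <- nxt / sum(nxt)
      if (max(abs(nxt - pi_vec)) < tol / 10) {
        pi_vec <- nxt
        break
      }
      pi_vec <- nxt
    }
    residual <- max(abs(drop(pi_vec %*% P) - pi_vec))
    if (residual > tol) {
      abort(sprintf("stationary distribution did not converge (residual %.3g > tol %.3g)",
                    residual, tol))
    }
  }
  structure(pi_vec, residual = residual, eigenvalue_gap = gap)
}

#' Build the full Markov chain from a weight matrix
#'
#' Convenience wrapper returning transition matrix, stationary distribution
#' and diagnostics together.
#'
#' @param A Weight matrix from [node_adjacency()].
#' @param tol Stationarity tolerance passed to [stationary_distribution()].
#' @return An object of class `markov_chain`: list with `P`, `pi`,
#'   `residual`, `eigenvalue_gap`.
#' @export
markov_chain <- function(A, tol = 1e-10) {
  P <- row_stochastic(A)
  pi_vec <- stationary_distribution(P, tol = tol)
  structure(
    list(P = P, pi = as.numeric(pi_vec),
         residual = attr(pi_vec, "residual"),
         eigenvalue_gap = attr(pi_vec, "eigenvalue_gap")),
    class = "markov_chain"
  )
}

#' @export
print.markov_chain <- function(x, ...) {
  cat(sprintf("<markov_chain> %d states, stationarity residual %.2g, eigenvalue gap %.3g\n",
              nrow(x$P), x$residual, x$eigenvalue_gap))
  invisible(x)
}

#' Per-node dynamical Shannon entropy
#'
#' The dynamical entropy of node i is its contribution to the chain's
#' entropy rate: `H_i = -pi_i * sum_j p_ij log p_ij`, with `0 log 0 := 0`.
#' Highly connected nodes that the stationary walker visits often carry
#' large H. Summed over nodes, H equals the Markov entropy rate.
#'
#' @param chain A `markov_chain` (or a weight matrix, which is converted).
#' @param log_base `"e"` for nats (default) or `"2"` for bits. The choice
#'   rescales every H_i by the same constant, so rankings are unaffected.
#' @return A tibble with columns `node`, `pi`, `H`, carrying the log base
#'   and entropy rate as attributes.
#' @export
dynamical_entropy <- function(chain, log_base = c("e", "2")) {
  log_base <- match.arg(as.character(log_base), c("e", "2"))
  if (!inherits(chain, "markov_chain")) chain <- markov_chain(chain)
  P <- chain$P
  lp <- P
  pos <- P > 0
  lp[pos] <- log(P[pos])
  if (log_base == "2") lp <- lp / log(2)
  lp[!pos] <- 0
  H <- unname(-chain$pi * rowSums(P * lp))
  out <- tibble::tibble(node = seq_along(H), pi = chain$pi, H = H)
  attr(out, "log_base") <- log_base
  attr(out, "entropy_rate") <- sum(H)
  attr(out, "residual") <- chain$residual
  out
}
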