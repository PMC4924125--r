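# SDRI scoring: combine per-node dynamical entropy with per-node RMSF,
# normalize, rank, derive the disorder profile, distribution statistics and
# correlation reports against experimental stability data.

#' Score nodes by entropy over flexibility (SDRI)
#'
#' The structure-determining residue identifier of node i is
#' `SDRI_i = H_i / RMSF_i`: a highly connected node (large dynamical
#' entropy) whose movement is restricted (small fluctuation) scores high
#' and is predicted to be critical for global stability. Raw scores are
#' min-max normalized to `[0, 1]`, ranked (rank 1 = highest raw score, ties
#' broken by node index), and complemented into the per-residue disorder
#' profile `1 - SDRI_norm`.
#'
#' @param entropy Entropy tibble from [dynamical_entropy()] (columns `node`,
#'   `H`), or a bare numeric vector.
#' @param flexibility Flexibility tibble from [node_rmsf()] /
#'   [read_rmsf_table()] (columns `node`, `rmsf`), or a bare numeric vector.
#' @param nodes Optional node tibble (`ensemble$nodes`) merged into the
#'   output for reporting.
#' @return A tibble of class `sdri_profile` with columns `node`, `H`,
#'   `rmsf`, `sdri` (raw), `sdri_norm`, `rank`, `disorder` (plus node
#'   metadata columns when `nodes` is given).
#' @export
#' @examples
#' sdri_score(c(0.2, 0.4), c(2, 2))
sdri_score <- function(entropy, flexibility, nodes = NULL) {
  H <- if (is.data.frame(entropy)) entropy$H else as.numeric(entropy)
  rmsf <- if (is.data.frame(flexibility)) flexibility$rmsf else as.numeric(flexibility)
  if (length(H) != length(rmsf)) {
    abort(sprintf("entropy (%d) and flexibility (%d) profiles are not aligned",
                  length(H), length(rmsf)))
  }
  if (is.data.frame(entropy) && is.data.frame(flexibility) &&
      !identical(entropy$node, flexibility$node)) {
    abort("entropy and flexibility profiles index different nodes")
  }
  if (any(rmsf == 0)) {
    abort(sprintf(
      "RMSF is zero for node(s) %s: SDRI = H/RMSF is undefined; use an external flexibility table or more frames",
      paste(which(rmsf == 0), collapse = ", ")
    ))
  }
  raw <- H / rmsf
  rng <- range(raw)
  if (length(raw) >= 2L && diff(rng) == 0) {
    abort("all SDRI scores are identical: min-max normalization is undefined")
  }
  norm <- if (length(raw) < 2L) rep(1, length(raw)) else (raw - rng[1L]) / diff(rng)
  rk <- rank(-raw, ties.method = "first")

  out <- tibble::tibble(node = seq_along(raw), H = H, rmsf = rmsf,
                        sdri = raw, sdri_norm = norm,
                        rank = as.integer(rk), disorder = 1 - norm)
  if (!is.null(nodes)) {
    out <- dplyr::left_join(nodes, out, by = "node")
  }
  if (is.data.frame(entropy)) {
    attr(out, "log_base") <- attr(entropy, "log_base")
  }
  if (is.data.frame(flexibility)) {
    attr(out, "rmsf_source") <- attr(flexibility, "source")
  }
  class(out) <- c("sdri_profile", class(out))
  out
}

#' Distribution statistics of SDRI scores
#'
#' Bias-corrected sample skewness and excess kurtosis plus the Shapiro-Wilk
#' normality statistic W, computed on the raw scores. Well-packed globular
#' proteins give near-normal SDRI distributions (small skew/kurtosis, W near
#' 1); intrinsically disordered chains give strongly right-skewed,
#' heavy-tailed distributions with low W. Skewness and excess kurtosis are
#' affine-invariant, so raw and min-max-normalized scores give identical
#' values; W is computed on whatever is passed in.
#'
#' @param profile An `sdri_profile`, or a bare numeric vector of scores
#'   (length 3..5000 for the Shapiro-Wilk statistic).
#' @return A one-row tibble with columns `n`, `skewness`, `kurtosis`
#'   (excess), `shapiro_w`, `shapiro_p`.
#' @export
distribution_stats <- function(profile) {
  x <- if (is.data.frame(profile)) profile$sdri else as.numeric(profile)
  n <- length(x)
  if (n < 3L) abort("distribution statistics need at least 3 scores")
  if (sd(x) == 0) abort("scores are constant: distribution statistics undefined")
  sw <- shapiro.test(x)
  tibble::tibble(
    n = n,
    skewness = e1071::skewness(x, type = 2L),
    kurtosis = e1071::kurtosis(x, type = 2L),
    shapiro_w = unname(sw$statistic),
    shapiro_p = sw$p.value
  )
}

#' Correlate SDRI scores with experimental stability values
#'
#' Pairs the raw SDRI of selected nodes with experimental per-mutant values
#' (stability differences in kcal/mol, or dissociation-constant percentage
#' differences, consumed as-is) and reports the Pearson correlation
#' coefficient and the coefficient of determination `R^2 = r^2`.
#'
#' @param profile An `sdri_profile`.
#' @param experiments A data frame with columns `node` (continuous node
#'   index) and `value` (experimental measurement); extra columns such as a
#'   mutation `label` are carried through.
#' @return An object of class `sdri_validation`: list with `pairs` (tibble
#'   `node`, `sdri`, `value`, ...), `pearson_r`, `r_squared`, `n`.
#' @export
correlate_with_experiment <- function(profile, experiments) {
  stopifnot(is.data.frame(experiments))
  if (!all(c("node", "value") %in% names(experiments))) {
    abort("experiments must have 'node' and 'value' columns")
  }
  if (nrow(experiments) < 3L) abort("need at least 3 experimental pairs")
  idx <- match(experiments$node, profile$node)
  if (anyNA(idx)) {
    abort(sprintf("experimental rows reference unknown node(s): %s",
                  paste(experiments$node[is.na(idx)], collapse = ", ")))
  }
  pairs <- tibble::as_tibble(experiments)
  pairs$sdri <- profile$sdri[idx]
  pairs <- pairs[, c("node", "sdri", "value",
                     setdiff(names(pairs), c("node", "sdri", "value")))]
  r <- cor(pairs$sdri, pairs$value)
  structure(
    list(pairs = pairs, pearson_r = r, r_squared = r^2, n = nrow(pairs)),
    class = "sdri_validation"
  )
}

#' @export
print.sdri_validation <- function(x, ...) {
  cat(sprintf("<sdri_validation> %d pairs, Pearson r = %.3f, R^2 = %.3f\n",
              x$n, x$pearson_r, x$r_squared))
  invisible(x)
}

#' @rdname correlate_with_experiment
#' @param x An `sdri_validation` object.
#' @param ... Unused.
#' @method tidy sdri_validation
#' @export
tidy.sdri_validation <- function(x, ...) x$pairs

#' @rdname correlate_with_experiment
#' @method glance sdri_validation
#' @export
glance.sdri_validation <- function(x, ...) {
  tibble::tibble(pearson_r = x$pearson_r, r_squared = x$r_squared, n = x$n)
}
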