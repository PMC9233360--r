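# Regression-based correction of the multiplicative downward bias of the
# raw likelihood-based relationship matrices.
#
# Model: the expected point-wise estimate of a pair at variant j is
#   (z1 + z2 * tau) * (1 + g(u_i, u_i')),
# tau the pair's target coefficient (2*phi on the kinship scale, psi on the
# fraternity scale), u the per-individual fuzziness at the variant, and g a
# second-order polynomial (sum, product and per-individual quadratic terms)
# vanishing at zero fuzziness. Extrapolating each pair's regression to zero
# fuzziness (the intercept) removes the fuzziness-driven part of the bias;
# the diagonal elements, whose target is exactly 1 in a non-inbred sample,
# anchor the intercept scale, and a second regression of the raw entries on
# the intercepts converts that anchor into the multiplicative bias beta of
# the raw estimator.

#' Point-wise relationship estimates of one pair
#'
#' Per-variant products of the two individuals' scores; their mean over the
#' variants non-missing in both is the pair's raw matrix entry.
#'
#' @param X score matrix (individuals x variants), e.g. from
#'   [build_scores()].
#' @param i,j row indices of the pair (equal for a diagonal element).
#' @return numeric vector of per-variant products (`NA` where either
#'   individual is missing).
#' @export
pointwise_estimates <- function(X, i, j) X[i, ] * X[j, ]

#' Fuzziness regression of one pair
#'
#' Ordinary least squares of the point-wise estimates on the fuzziness sum
#' `u_i + u_j`, the product `u_i * u_j`, and the per-individual quadratic
#' `u_i^2 + u_j^2`; the intercept is the zero-fuzziness extrapolation of the
#' pair's estimate. The quadratic term absorbs the convexity of the
#' depth-driven bias along each individual's fuzziness axis (on the
#' diagonal, where `u_i = u_j`, it is collinear with the product term and
#' dropped). Degenerate designs (fewer than 3 complete variants, or constant
#' covariates) fall back to the plain mean with zero slopes.
#'
#' @param pointwise per-variant point-wise estimates.
#' @param u_i,u_j per-variant fuzziness of the two individuals.
#' @return list with `intercept`, `coef` (length 3: sum, product,
#'   quadratic; collinear terms reported as 0), `n`, and `fallback`.
#' @export
pair_regression <- function(pointwise, u_i, u_j) {
  s <- u_i + u_j
  pr <- u_i * u_j
  q2 <- u_i^2 + u_j^2
  ok <- is.finite(pointwise) & is.finite(s) & is.finite(pr)
  y <- pointwise[ok]; s <- s[ok]; pr <- pr[ok]; q2 <- q2[ok]
  n <- length(y)
  fallback <- n < 3L || stats::var(s) < 1e-12
  if (!fallback) {
    fit <- tryCatch(stats::lm.fit(cbind(1, s, pr, q2), y),
                    error = function(e) NULL)
    if (is.null(fit) || any(is.na(fit$coefficients[1:2]))) fallback <- TRUE
  }
  if (fallback)
    return(list(intercept = mean(y), coef = c(0, 0, 0), n = n,
                fallback = TRUE))
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  list(intercept = unname(cf[1]), coef = unname(cf[2:4]), n = n,
       fallback = FALSE)
}

#' Select the pair subset used for bias calibration
#'
#' The calibration regressions are run on a representative subset of pairs:
#' the `n_top` off-diagonal pairs with the highest raw estimates, the
#' `n_bottom` with the lowest, and all pairs among a random draw of
#' `n_random` individuals, deduplicated; all diagonal elements are always
#' included (they anchor the calibration). Ties at the selection boundaries
#' are broken lexicographically by pair index.
#'
#' @param K raw symmetric relationship matrix.
#' @param n_top,n_bottom,n_random subset sizes; all three zero is rejected.
#' @param seed integer seed for the random-individuals draw (`NULL` to use
#'   the current RNG state).
#' @return 2-column integer matrix of pair indices `(i, j)` with `i <= j`;
#'   off-diagonal pairs first, then the `N` diagonal pairs.
#' @export
select_pairs <- function(K, n_top = 20, n_bottom = 20, n_random = 100,
                         seed = NULL) {
  N <- nrow(K)
  if (N < 2L) stop("need at least two individuals")
  if (n_top <= 0 && n_bottom <= 0 && n_random <= 0)
    stop("degenerate pair selection: all of n_top, n_bottom, n_random are 0")
  idx <- which(upper.tri(K), arr.ind = TRUE)
  val <- K[idx]
  chosen <- logical(nrow(idx))
  if (n_top > 0) {
    ord <- order(-val, idx[, 1], idx[, 2])
    chosen[ord[seq_len(min(n_top, length(ord)))]] <- TRUE
  }
  if (n_bottom > 0) {
    ord <- order(val, idx[, 1], idx[, 2])
    chosen[ord[seq_len(min(n_bottom, length(ord)))]] <- TRUE
  }
  if (n_random > 0) {
    .maybe_seed(seed)
    inds <- sort(sample.int(N, min(n_random, N)))
    chosen[idx[, 1] %in% inds & idx[, 2] %in% inds] <- TRUE
  }
  off <- idx[chosen, , drop = FALSE]
  off <- off[order(off[, 1], off[, 2]), , drop = FALSE]
  rbind(unname(off), cbind(seq_len(N), seq_len(N)))
}

#' Multiplicative biases from pair intercepts
#'
#' Two-step calibration. Step 1: the mean zero-fuzziness intercept of the
#' diagonal elements, whose target coefficient is exactly 1 in a non-inbred
#' sample, fixes the intercept value `c_bar` corresponding to a target of 1.
#' Step 2: a line relating raw entries to intercepts across the selected
#' off-diagonal pairs, evaluated at `c_bar`, gives the raw estimator's
#' expected value for an off-diagonal pair with true coefficient 1 — the
#' multiplicative bias `beta`. Because the per-pair intercepts are far
#' noisier than the raw entries (they extrapolate to zero fuzziness), the
#' line's slope is estimated by regressing the intercepts on the raw
#' entries and inverting — the standard errors-in-variables orientation —
#' rather than the attenuation-prone direct regression; the line passes
#' through the centroid of the off-diagonal pairs.
#'
#' The diagonal is calibrated by its own cluster: a raw diagonal entry is a
#' mean of squares and keeps an additive noise-variance contribution that
#' the cross-products of two independent individuals average away, so its
#' multiplicative bias differs from the off-diagonal one. Evaluating the
#' diagonal elements' own raw-on-intercept regression at `c_bar` (which is
#' the mean of their intercepts, hence the fitted value is their mean raw
#' entry) gives `beta_diag`.
#'
#' @param values raw matrix entries of the selected pairs.
#' @param intercepts their zero-fuzziness regression intercepts.
#' @param is_diag logical: which entries are diagonal elements.
#' @return list with `beta` (off-diagonal bias), `beta_diag` (diagonal
#'   bias), the anchor `c_bar`, the step-2 coefficients `coef`, and
#'   `r_squared`; `beta` is `NA` (calibration failure) when fewer than 2
#'   diagonal or 3 off-diagonal finite pairs are available. A degenerate
#'   off-diagonal regression (no spread in the intercepts, e.g. a sample
#'   with no related pairs and little noise) falls back to `beta_diag`.
#' @export
calibrate_beta <- function(values, intercepts, is_diag) {
  ok <- is.finite(values) & is.finite(intercepts)
  if (sum(ok & is_diag) < 2L || sum(ok & !is_diag) < 3L)
    return(list(beta = NA_real_, beta_diag = NA_real_, c_bar = NA_real_,
                coef = c(NA, NA), r_squared = NA_real_))
  c_bar <- mean(intercepts[ok & is_diag])
  beta_diag <- mean(values[ok & is_diag])
  x <- intercepts[ok & !is_diag]; y <- values[ok & !is_diag]
  gamma <- stats::cov(x, y) / stats::var(y)
  if (!is.finite(gamma) || gamma <= 0)
    return(list(beta = beta_diag, beta_diag = beta_diag, c_bar = c_bar,
                coef = c(NA, NA), r_squared = NA_real_))
  b <- 1 / gamma
  a <- mean(y) - b * mean(x)
  beta <- a + b * c_bar
  r2 <- stats::cor(x, y)^2
  list(beta = beta, beta_diag = beta_diag, c_bar = c_bar, coef = c(a, b),
       r_squared = r2)
}

#' Adjust a raw relationship matrix
#'
#' Runs the full bias correction on one matrix: per-pair fuzziness
#' regressions on the selected pair subset, diagonal-anchored calibration of
#' the multiplicative biases ([calibrate_beta()]), division of the
#' off-diagonal entries by `beta` and of the diagonal by `beta_diag`, and
#' (optionally) shifting the first quartile of the off-diagonal entries to
#' zero. The quartile shift assumes a large fraction of unrelated pairs,
#' whose coefficients should sit at zero; the diagonal is never shifted.
#' If calibration fails (non-finite or non-positive `beta`) the matrix is
#' returned unadjusted with a warning.
#'
#' @param raw raw symmetric relationship matrix ([accumulate_grm()]).
#' @param X the score matrix it was accumulated from.
#' @param U fuzziness matrix over the same variants ([fuzziness()]).
#' @param n_top,n_bottom,n_random pair-subset sizes, see [select_pairs()].
#' @param snp_subsample per-pair regressions use at most this many variants
#'   (a seeded subsample); `Inf` for all.
#' @param quartile_shift apply the final off-diagonal quartile shift.
#' @param seed integer seed for pair selection and SNP subsampling.
#' @return list with `adjusted` (the corrected matrix), `beta`, `shift`, and
#'   a `diagnostics` list (`c_bar`, step-2 coefficients, `r_squared`,
#'   `n_pairs`, `n_snps`, fallback count).
#' @export
adjust_grm <- function(raw, X, U, n_top = 20, n_bottom = 20, n_random = 100,
                       snp_subsample = 20000, quartile_shift = TRUE,
                       seed = NULL) {
  .maybe_seed(seed)
  pairs <- select_pairs(raw, n_top, n_bottom, n_random, seed = NULL)
  M <- ncol(X)
  snp_idx <- if (is.finite(snp_subsample) && snp_subsample < M)
    sort(sample.int(M, snp_subsample)) else seq_len(M)
  Xs <- X[, snp_idx, drop = FALSE]
  Us <- U[, snp_idx, drop = FALSE]
  n_pairs <- nrow(pairs)
  intercepts <- numeric(n_pairs)
  n_fallback <- 0L
  for (p in seq_len(n_pairs)) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    fit <- pair_regression(Xs[i, ] * Xs[j, ], Us[i, ], Us[j, ])
    intercepts[p] <- fit$intercept
    n_fallback <- n_fallback + fit$fallback
  }
  is_diag <- pairs[, 1] == pairs[, 2]
  cal <- calibrate_beta(raw[pairs], intercepts, is_diag)
  diagnostics <- list(c_bar = cal$c_bar, beta_diag = cal$beta_diag,
                      coef = cal$coef, r_squared = cal$r_squared,
                      n_pairs = n_pairs, n_snps = length(snp_idx),
                      n_fallback = n_fallback)
  if (!is.finite(cal$beta) || cal$beta <= 0 ||
      !is.finite(cal$beta_diag) || cal$beta_diag <= 0) {
    warning("bias calibration failed (beta not positive finite); ",
            "returning the unadjusted matrix")
    return(list(adjusted = raw, beta = NA_real_, shift = 0,
                diagnostics = diagnostics))
  }
  adj <- raw / cal$beta
  diag(adj) <- diag(raw) / cal$beta_diag
  shift <- 0
  if (quartile_shift) {
    off <- adj[upper.tri(adj)]
    shift <- stats::quantile(off[is.finite(off)], 0.25, names = FALSE,
                             type = 7)
    d <- diag(adj)
    adj <- adj - shift
    diag(adj) <- d
  }
  list(adjusted = adj, beta = cal$beta, shift = shift,
       diagnostics = diagnostics)
}
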