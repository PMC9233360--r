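#' Classical additive and dominance codings from allele frequencies
#'
#' For a biallelic variant with alternate-allele frequency `q` (and
#' `p = 1 - q`), the classical standardized codings under Hardy-Weinberg
#' proportions are
#' \deqn{\alpha_k = (k - 2q)/\sqrt{2pq},\qquad
#'       (\delta_0,\delta_1,\delta_2) = (q/p,\, -1,\, p/q).}
#' Averaged cross-products of these codings give the additive (kinship-scale)
#' and dominance (fraternity-scale) relationship matrices.
#'
#' @param q numeric vector of alternate-allele frequencies.
#' @return an object of class `gl_components`: list with `alpha` and `delta`
#'   (n x 3 matrices of per-genotype codings), logical keep-masks `keep_add`
#'   and `keep_dom` (frequencies in (0,1) only), and `mode = "classical"`.
#' @export
classical_components <- function(q) {
  q <- as.numeric(q)
  p <- 1 - q
  ok <- is.finite(q) & q > 0 & q < 1
  sd_a <- sqrt(2 * p * q)
  alpha <- cbind((0 - 2 * q) / sd_a, (1 - 2 * q) / sd_a, (2 - 2 * q) / sd_a)
  delta <- cbind(q / p, rep(-1, length(q)), p / q)
  alpha[!ok, ] <- NA_real_
  delta[!ok, ] <- NA_real_
  structure(list(alpha = alpha, delta = delta,
                 keep_add = ok, keep_dom = ok, q = q, mode = "classical"),
            class = "gl_components")
}

#' Genotype-frequency-based codings from likelihood summaries
#'
#' Builds the additive and dominance codings directly from the sample
#' genotype-frequency triplet \eqn{(\bar P_{AA}, \bar P_{Aa}, \bar P_{aa})},
#' without assuming Hardy-Weinberg proportions:
#' \deqn{\tilde\alpha = v_A^{-1/2}(-m,\ 1-m,\ 2-m), \quad
#'   m = \bar P_{Aa} + 2\bar P_{aa},\ \
#'   v_A = \bar P_{Aa} + 4\bar P_{aa}\bar P_{AA} - \bar P_{Aa}^2}
#' \deqn{\tilde\delta = v_D^{-1/2}\left(\sqrt{\bar P_{aa}/\bar P_{AA}},\
#'   -2\sqrt{\bar P_{aa}\bar P_{AA}}/\bar P_{Aa},\
#'   \sqrt{\bar P_{AA}/\bar P_{aa}}\right), \quad
#'   v_D = \bar P_{aa} + 4\bar P_{aa}\bar P_{AA}/\bar P_{Aa} + \bar P_{AA}.}
#' Under the categorical distribution with probabilities \eqn{\bar P} both
#' codings have mean 0, variance 1 and zero cross-moment, and when \eqn{\bar
#' P} follows exact Hardy-Weinberg proportions they reduce to
#' [classical_components()].
#'
#' @param summaries output of [variant_summaries()] (or any data frame with
#'   columns `p_AA`, `p_Aa`, `p_aa`).
#' @param tol variants whose additive variance term, or any genotype
#'   frequency entering the dominance coding, falls at or below `tol` are
#'   flagged unusable for the affected component.
#' @return an object of class `gl_components` with `mode =
#'   "genotype-frequency"`.
#' @export
gl_components <- function(summaries, tol = 1e-8) {
  a <- summaries$p_AA; b <- summaries$p_Aa; c2 <- summaries$p_aa
  m <- b + 2 * c2
  v_add <- b + 4 * c2 * a - b^2
  keep_add <- is.finite(v_add) & v_add > tol
  s <- ifelse(keep_add, sqrt(v_add), NA_real_)
  alpha <- cbind(-m, 1 - m, 2 - m) / s
  keep_dom <- is.finite(a) & is.finite(b) & is.finite(c2) &
    a > tol & b > tol & c2 > tol
  v_dom <- c2 + 4 * c2 * a / b + a
  sD <- ifelse(keep_dom, sqrt(v_dom), NA_real_)
  delta <- cbind(sqrt(c2 / a), -2 * sqrt(c2 * a) / b, sqrt(a / c2)) / sD
  alpha[!keep_add, ] <- NA_real_
  delta[!keep_dom, ] <- NA_real_
  structure(list(alpha = alpha, delta = delta,
                 keep_add = keep_add, keep_dom = keep_dom,
                 mode = "genotype-frequency"),
            class = "gl_components")
}

#' Individual-level additive and dominance scores
#'
#' Applies per-variant codings to the genotype probability triplets:
#' \eqn{\tilde X_A^{ij} = \tilde\alpha_0 P_{AA}^{ij} + \tilde\alpha_1
#' P_{Aa}^{ij} + \tilde\alpha_2 P_{aa}^{ij}} (dominance analogue with
#' \eqn{\tilde\delta}). Certain (hard-call) triplets reduce to the classical
#' indicator coding. Missing entries yield `NA`.
#'
#' @param x a [gl_tensor()].
#' @param components a `gl_components` object for the same variants.
#' @return list with matrices `X_A` and `X_D` (individuals x variants);
#'   variants unusable for a component are wholly `NA` in that matrix.
#' @export
build_scores <- function(x, components) {
  stopifnot(inherits(x, "gl_tensor"), inherits(components, "gl_components"))
  if (nrow(components$alpha) != ncol(x$p_AA))
    stop("components and tensor disagree on the number of variants")
  score <- function(coef) {
    x$p_AA * matrix(coef[, 1], nrow(x$p_AA), ncol(x$p_AA), byrow = TRUE) +
      x$p_Aa * matrix(coef[, 2], nrow(x$p_AA), ncol(x$p_AA), byrow = TRUE) +
      x$p_aa * matrix(coef[, 3], nrow(x$p_AA), ncol(x$p_AA), byrow = TRUE)
  }
  list(X_A = score(components$alpha), X_D = score(components$delta))
}

#' Average cross-products of scores into a relationship matrix
#'
#' For each pair of individuals, averages the per-variant products of their
#' scores over the variants non-missing in both (pair-specific denominators),
#' giving the additive or dominance relationship matrix. Pairs that share no
#' variant get `NA`.
#'
#' @param X score matrix (individuals x variants) with `NA` for
#'   missing/unusable entries.
#' @return symmetric matrix of averaged cross-products, with the matrix of
#'   per-pair variant counts in attribute `"n_shared"`.
#' @export
accumulate_grm <- function(X) {
  X <- as.matrix(X)
  obs <- !is.na(X)
  X0 <- X
  X0[!obs] <- 0
  cp <- tcrossprod(X0)
  n <- tcrossprod(obs * 1)
  out <- cp / n
  out[n == 0] <- NA_real_
  attr(out, "n_shared") <- n
  out
}

#' EM estimation of allele frequencies from genotype likelihoods
#'
#' Maximum-likelihood alternate-allele frequencies under a per-variant
#' Hardy-Weinberg model, by EM: given the current frequency, each
#' individual's posterior genotype distribution is the likelihood triplet
#' reweighted by the Hardy-Weinberg prior, and the updated frequency is half
#' the mean posterior dosage over non-missing individuals.
#'
#' @param x a [gl_tensor()].
#' @param init initial frequency (scalar or per-variant vector); defaults to
#'   half the mean expected dosage under the flat-prior triplets, clamped to
#'   (0.001, 0.999).
#' @param max_iter,tol iteration cap and convergence threshold on the largest
#'   per-variant frequency change.
#' @return numeric vector of frequency estimates with logical attribute
#'   `"converged"`; variants with no data get `NA`. A warning is raised when
#'   the iteration cap is hit.
#' @export
em_allele_freq <- function(x, init = NULL, max_iter = 100L, tol = 1e-8) {
  stopifnot(inherits(x, "gl_tensor"))
  n_obs <- colSums(!x$missing)
  if (is.null(init)) {
    init <- colMeans(expected_dosage(x), na.rm = TRUE) / 2
    init[!is.finite(init)] <- 0.5
  }
  q <- rep_len(pmin(pmax(init, 0.001), 0.999), ncol(x$p_AA))
  if (any(q <= 0 | q >= 1)) stop("init must lie in (0, 1)")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    pr0 <- (1 - q)^2; pr1 <- 2 * q * (1 - q); pr2 <- q^2
    rep_row <- function(v) matrix(v, nrow(x$p_AA), ncol(x$p_AA), byrow = TRUE)
    w0 <- x$p_AA * rep_row(pr0)
    w1 <- x$p_Aa * rep_row(pr1)
    w2 <- x$p_aa * rep_row(pr2)
    tot <- w0 + w1 + w2
    dose <- (w1 + 2 * w2) / tot
    q_new <- colSums(dose, na.rm = TRUE) / (2 * n_obs)
    q_new[n_obs == 0L] <- q[n_obs == 0L]
    delta <- max(abs(q_new - q), 0)
    q <- q_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("EM allele-frequency estimation hit max_iter")
  q[n_obs == 0L] <- NA_real_
  attr(q, "converged") <- converged
  q
}
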