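#' Kinship and fraternity estimation from genotype likelihoods
#'
#' The main fitting function. Takes per-individual genotype probability
#' triplets for a panel of biallelic SNPs — from a VCF with `PL`/`GL` fields,
#' a [gl_tensor()], or a [sim_sib_study()] — and estimates the pairwise
#' kinship matrix `K` (estimating twice the kinship coefficient,
#' \eqn{2\varphi}) and fraternity matrix `D` (estimating the IBD2 probability
#' \eqn{\psi}) by the method of moments, without calling genotypes.
#'
#' The pipeline is: (1) filter variants by mean expected minor-allele count
#' ([maf_filter()]); (2) build per-variant additive and dominance codings —
#' from the sample genotype frequencies ([gl_components()]) by default, or
#' the classical Hardy-Weinberg codings ([classical_components()]) when
#' external allele frequencies are supplied; (3) score every individual
#' ([build_scores()]) and average cross-products over pairs
#' ([accumulate_grm()]); (4) optionally correct the depth-dependent downward
#' bias of the raw matrices by fuzziness-regression extrapolation
#' ([adjust_grm()]), independently for `K` and `D`.
#'
#' @param x input genotype probabilities: a [gl_tensor()], a
#'   [sim_sib_study()], or the path to a VCF file (read with
#'   [read_vcf_gl()]).
#' @param freq optional external alternate-allele frequencies: a numeric
#'   vector (named by variant id, or positional), or a two-column data frame
#'   `(variant_id, freq)`. When given, Hardy-Weinberg proportions are
#'   assumed and the codings reduce to the classical ones.
#' @param field VCF likelihood field preference when `x` is a path.
#' @param filter `c(lo, hi)` bounds of the expected minor-allele-count
#'   filter, or `NULL` to disable.
#' @param adjust run the bias correction (recommended whenever the input is
#'   genuine low-depth data).
#' @param adjust_par `c(n_top, n_bottom, n_random)` pair-subset sizes of the
#'   calibration, see [select_pairs()].
#' @param snp_subsample cap on the number of variants used per calibration
#'   regression.
#' @param quartile_shift shift the first quartile of the off-diagonal
#'   coefficients to zero after adjustment (assumes mostly-unrelated
#'   samples).
#' @param tol degeneracy tolerance for the coding denominators.
#' @param seed integer seed for the calibration subsampling.
#' @return an object of class `glkin` with elements `K`, `D` (adjusted when
#'   `adjust = TRUE`, raw otherwise), `K_raw`, `D_raw`, `beta`
#'   (multiplicative biases), `shift` (quartile shifts), `adjusted`,
#'   `samples`, `m` (variants used per matrix), `mode`, `diagnostics`. Use
#'   [coef.glkin()] for the per-pair kinship/fraternity table.
#' @examples
#' study <- sim_sib_study(n_sib_pairs = 2, n_unrelated = 8,
#'                        n_variants = 300, mean_depth = 5,
#'                        map = sim_genetic_map(2, 100), seed = 7)
#' fit <- glkin(study, adjust_par = c(3, 3, 10), seed = 7)
#' fit
#' head(coef(fit))
#' @export
glkin <- function(x, freq = NULL, field = c("PL", "GL"),
                  filter = c(0.05, 1.95), adjust = TRUE,
                  adjust_par = c(20, 20, 100), snp_subsample = 20000,
                  quartile_shift = TRUE, tol = 1e-8, seed = 1L) {
  cl <- match.call()
  if (is.character(x)) x <- read_vcf_gl(x, field = match.arg(field))
  if (inherits(x, "sib_study")) x <- x$tensor
  stopifnot(inherits(x, "gl_tensor"))
  smry <- variant_summaries(x)
  keep <- if (is.null(filter)) smry$usable
          else maf_filter(smry, filter[1], filter[2])
  mode <- if (is.null(freq)) "internal" else "external"
  if (mode == "external") {
    q <- .match_freq(freq, x$variants$variant_id)
    comp <- classical_components(q)
  } else {
    comp <- gl_components(smry, tol = tol)
  }
  keep_A <- keep & comp$keep_add
  keep_D <- keep & comp$keep_dom
  if (!any(keep_A)) stop("no variants survive filtering")
  scores <- build_scores(x, comp)
  X_A <- scores$X_A[, keep_A, drop = FALSE]
  X_D <- scores$X_D[, keep_D, drop = FALSE]
  K_raw <- accumulate_grm(X_A)
  D_raw <- if (any(keep_D)) accumulate_grm(X_D) else NULL
  rownames(K_raw) <- colnames(K_raw) <- x$samples
  if (!is.null(D_raw)) rownames(D_raw) <- colnames(D_raw) <- x$samples
  out <- list(K = K_raw, D = D_raw, K_raw = K_raw, D_raw = D_raw,
              beta = c(kinship = NA_real_, fraternity = NA_real_),
              shift = c(kinship = 0, fraternity = 0),
              adjusted = FALSE, samples = x$samples,
              m = c(kinship = sum(keep_A), fraternity = sum(keep_D)),
              mode = mode, filter = filter, diagnostics = list(),
              seed = seed, call = cl)
  if (adjust) {
    U <- fuzziness(x)
    U[x$missing] <- NA_real_
    adjK <- adjust_grm(K_raw, X_A, U[, keep_A, drop = FALSE],
                       n_top = adjust_par[1], n_bottom = adjust_par[2],
                       n_random = adjust_par[3],
                       snp_subsample = snp_subsample,
                       quartile_shift = quartile_shift,
                       seed = .sub_seed(seed, "adjust"))
    out$K <- adjK$adjusted
    out$beta["kinship"] <- adjK$beta
    out$shift["kinship"] <- adjK$shift
    out$diagnostics$kinship <- adjK$diagnostics
    if (!is.null(D_raw)) {
      adjD <- adjust_grm(D_raw, X_D, U[, keep_D, drop = FALSE],
                         n_top = adjust_par[1], n_bottom = adjust_par[2],
                         n_random = adjust_par[3],
                         snp_subsample = snp_subsample,
                         quartile_shift = quartile_shift,
                         seed = .sub_seed(seed + 1, "adjust"))
      out$D <- adjD$adjusted
      out$beta["fraternity"] <- adjD$beta
      out$shift["fraternity"] <- adjD$shift
      out$diagnostics$fraternity <- adjD$diagnostics
    }
    out$adjusted <- TRUE
  }
  class(out) <- "glkin"
  out
}

.match_freq <- function(freq, variant_ids) {
  if (is.data.frame(freq)) freq <- stats::setNames(freq[[2]], freq[[1]])
  if (!is.null(names(freq))) {
    q <- unname(freq[variant_ids])
  } else {
    if (length(freq) != length(variant_ids))
      stop("unnamed frequency vector must match the number of variants")
    q <- as.numeric(freq)
  }
  q
}

#' Classical relationship matrices from hard genotypes
#'
#' Benchmark estimator on complete genotypes: classical additive and
#' dominance codings from allele frequencies (estimated from the sample by
#' default), accumulated into kinship-scale and fraternity matrices. Returns
#' the same class of object as [glkin()], unadjusted.
#'
#' @param G integer genotype matrix (individuals x variants, values 0/1/2;
#'   `NA` allowed and handled with pair-specific denominators).
#' @param q optional external alternate-allele frequencies (default: sample
#'   frequencies `colMeans(G)/2`).
#' @return a `glkin` object with `mode = "hard-call"`.
#' @export
grm_genotypes <- function(G, q = NULL) {
  G <- as.matrix(G)
  if (is.null(q)) q <- colMeans(G, na.rm = TRUE) / 2
  comp <- classical_components(q)
  keep <- comp$keep_add
  if (!any(keep)) stop("all variants are monomorphic")
  tens <- gl_tensor((G == 0L) * 1, (G == 1L) * 1, (G == 2L) * 1,
                    missing = is.na(G),
                    samples = rownames(G), validate = FALSE)
  scores <- build_scores(tens, comp)
  K <- accumulate_grm(scores$X_A[, keep, drop = FALSE])
  D <- accumulate_grm(scores$X_D[, keep, drop = FALSE])
  rownames(K) <- colnames(K) <- tens$samples
  rownames(D) <- colnames(D) <- tens$samples
  structure(list(K = K, D = D, K_raw = K, D_raw = D,
                 beta = c(kinship = NA_real_, fraternity = NA_real_),
                 shift = c(kinship = 0, fraternity = 0), adjusted = FALSE,
                 samples = tens$samples,
                 m = c(kinship = sum(keep), fraternity = sum(keep)),
                 mode = "hard-call", filter = NULL, diagnostics = list(),
                 seed = NA_integer_, call = match.call()),
            class = "glkin")
}

#' @export
#' @method print glkin
print.glkin <- function(x, ...) {
  N <- length(x$samples)
  cat("Genotype-likelihood relatedness estimates (", x$mode, " frequencies)\n",
      sep = "")
  cat(sprintf("  %d individuals; %d (kinship) / %d (fraternity) variants\n",
              N, x$m["kinship"], x$m["fraternity"]))
  if (x$adjusted)
    cat(sprintf("  bias-adjusted: beta = %.3f (kinship), %.3f (fraternity)\n",
                x$beta["kinship"], x$beta["fraternity"]))
  else cat("  unadjusted moment estimates\n")
  off <- x$K[upper.tri(x$K)] / 2
  cat(sprintf("  phi-hat off-diagonal: min %.4f, median %.4f, max %.4f\n",
              min(off, na.rm = TRUE), stats::median(off, na.rm = TRUE),
              max(off, na.rm = TRUE)))
  invisible(x)
}

#' Per-pair kinship and fraternity table
#'
#' @param object a [glkin()] fit.
#' @param diagonal include self-pairs (marked in column `self`; their
#'   `phi_hat` is on the kinship scale, 0.5 for a non-inbred individual).
#' @param ... unused.
#' @return data frame with `id1`, `id2` (sample order, `id1` before `id2`),
#'   `phi_hat` (= `K/2`), `psi_hat` (= `D`), shared-variant counts `n_kin`,
#'   `n_frat`, and `self`.
#' @export
coef.glkin <- function(object, diagonal = FALSE, ...) {
  N <- length(object$samples)
  idx <- which(upper.tri(object$K, diag = diagonal), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  nK <- attr(object$K_raw, "n_shared")
  nD <- if (!is.null(object$D_raw)) attr(object$D_raw, "n_shared")
  data.frame(id1 = object$samples[idx[, 1]], id2 = object$samples[idx[, 2]],
             phi_hat = object$K[idx] / 2,
             psi_hat = if (!is.null(object$D)) object$D[idx] else NA_real_,
             n_kin = if (!is.null(nK)) nK[idx] else NA_integer_,
             n_frat = if (!is.null(nD)) nD[idx] else NA_integer_,
             self = idx[, 1] == idx[, 2],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
#' @method summary glkin
summary.glkin <- function(object, n_top = 10, ...) {
  tab <- coef(object)
  tab <- tab[order(-tab$phi_hat), ]
  structure(list(fit = object, top = utils::head(tab, n_top),
                 phi_quartiles = stats::quantile(tab$phi_hat, na.rm = TRUE)),
            class = "summary.glkin")
}

#' @export
#' @method print summary.glkin
print.summary.glkin <- function(x, ...) {
  print(x$fit)
  cat("\nTop pairs by estimated kinship:\n")
  print(x$top, row.names = FALSE, digits = 4)
  cat("\nOff-diagonal phi-hat quartiles:\n")
  print(round(x$phi_quartiles, 4))
  invisible(x)
}

#' Kinship-fraternity scatter of a fit
#'
#' Plots estimated fraternity against estimated kinship for all off-diagonal
#' pairs, with reference crosses at the expectation for unrelated pairs
#' (0, 0) and full siblings (0.25, 0.25).
#'
#' @param x a [glkin()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
#' @method plot glkin
plot.glkin <- function(x, ...) {
  tab <- coef(x)
  graphics::plot(tab$phi_hat, tab$psi_hat,
                 xlab = expression(hat(phi)), ylab = expression(hat(psi)),
                 main = "Pairwise relatedness estimates", ...)
  graphics::abline(h = c(0, 0.25), v = c(0, 0.25), col = "grey70", lty = 3)
  invisible(x)
}
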