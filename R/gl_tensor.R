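#' Genotype probability tensor
#'
#' The central data container of the package: per-individual, per-variant
#' genotype probability triplets \eqn{(P_{AA}, P_{Aa}, P_{aa})} for a set of
#' biallelic SNPs, together with a missingness mask. Rows are individuals,
#' columns are variants. Missing entries carry `NA` in all three probability
#' matrices.
#'
#' @param p_AA,p_Aa,p_aa numeric matrices (individuals x variants) of genotype
#'   probabilities; each non-missing triplet must be non-negative and sum to 1
#'   (within `1e-6`).
#' @param missing optional logical matrix flagging missing entries; by default
#'   an entry is missing when any of its three probabilities is not finite.
#' @param samples optional character vector of sample ids (defaults to
#'   rownames or `S1..SN`).
#' @param variants optional data frame of per-variant metadata with at least a
#'   `variant_id` column; a minimal one is created when absent.
#' @param validate check the probability invariants (disable only for trusted
#'   internal construction of large tensors).
#' @return an object of class `gl_tensor`.
#' @seealso [normalize_likelihoods()] to build a tensor from log-scaled
#'   likelihoods, [variant_summaries()], [fuzziness()], [glkin()].
#' @export
gl_tensor <- function(p_AA, p_Aa, p_aa, missing = NULL, samples = NULL,
                      variants = NULL, validate = TRUE) {
  p_AA <- as.matrix(p_AA); p_Aa <- as.matrix(p_Aa); p_aa <- as.matrix(p_aa)
  if (!all(dim(p_AA) == dim(p_Aa)) || !all(dim(p_AA) == dim(p_aa)))
    stop("probability matrices must share dimensions")
  n <- nrow(p_AA); m <- ncol(p_AA)
  if (is.null(missing))
    missing <- !(is.finite(p_AA) & is.finite(p_Aa) & is.finite(p_aa))
  missing <- as.matrix(missing)
  if (!all(dim(missing) == c(n, m))) stop("missing mask has wrong dimensions")
  if (any(missing)) {
    p_AA[missing] <- NA_real_; p_Aa[missing] <- NA_real_; p_aa[missing] <- NA_real_
  }
  if (is.null(samples)) samples <- rownames(p_AA)
  if (is.null(samples)) samples <- paste0("S", seq_len(n))
  if (is.null(variants))
    variants <- data.frame(variant_id = paste0("V", seq_len(m)),
                           stringsAsFactors = FALSE)
  if (nrow(variants) != m) stop("variants metadata has wrong number of rows")
  if (validate && m > 0L && n > 0L) {
    ok <- !missing
    if (any(ok)) {
      if (min(p_AA[ok], p_Aa[ok], p_aa[ok]) < -1e-9)
        stop("negative genotype probabilities")
      s <- p_AA[ok] + p_Aa[ok] + p_aa[ok]
      if (max(abs(s - 1)) > 1e-6)
        stop("genotype probability triplets must sum to 1")
    }
  }
  dimnames(p_AA) <- dimnames(p_Aa) <- dimnames(p_aa) <- dimnames(missing) <- NULL
  structure(list(p_AA = p_AA, p_Aa = p_Aa, p_aa = p_aa, missing = missing,
                 samples = as.character(samples), variants = variants),
            class = "gl_tensor")
}

#' @export
dim.gl_tensor <- function(x) dim(x$p_AA)

#' @export
#' @method print gl_tensor
print.gl_tensor <- function(x, ...) {
  d <- dim(x)
  cat("Genotype probability tensor:", d[1], "individuals x", d[2], "variants\n")
  cat(sprintf("  missing entries: %d (%.2f%%)\n", sum(x$missing),
              100 * mean(x$missing)))
  invisible(x)
}

# subset variants (and optionally individuals) of a tensor, keeping metadata
tensor_subset <- function(x, i = NULL, j = NULL) {
  if (is.null(i)) i <- seq_len(nrow(x$p_AA))
  if (is.null(j)) j <- seq_len(ncol(x$p_AA))
  gl_tensor(x$p_AA[i, j, drop = FALSE], x$p_Aa[i, j, drop = FALSE],
            x$p_aa[i, j, drop = FALSE], missing = x$missing[i, j, drop = FALSE],
            samples = x$samples[i], variants = x$variants[j, , drop = FALSE],
            validate = FALSE)
}

#' Rescale log-scaled genotype likelihoods to probability triplets
#'
#' Converts per-genotype likelihoods stored on a log scale — VCF `GL` fields
#' (log10 likelihoods) or `PL` fields (phred-scaled, \eqn{-10 \log_{10} L}) —
#' into normalized genotype probability triplets under a flat prior. Each
#' triplet is shifted by its maximum on the log scale before exponentiation,
#' so arbitrarily scaled likelihoods are handled stably.
#'
#' @param raw a list of three matrices `(AA, Aa, aa)` (individuals x
#'   variants), or a numeric vector of length 3 for a single triplet.
#' @param dialect `"GL"` for log10-scaled likelihoods, `"PL"` for
#'   phred-scaled ones.
#' @param samples,variants passed to [gl_tensor()].
#' @return a [gl_tensor()] (or a numeric triplet when `raw` was one). Triplets
#'   with any non-finite value, or that are uniformly `-Inf`, are missing.
#' @examples
#' normalize_likelihoods(c(0, 30, 300), dialect = "PL")
#' normalize_likelihoods(c(-1, -1, -4), dialect = "GL")
#' @export
normalize_likelihoods <- function(raw, dialect = c("PL", "GL"),
                                  samples = NULL, variants = NULL) {
  dialect <- match.arg(dialect)
  single <- is.numeric(raw) && is.null(dim(raw))
  if (single) {
    if (length(raw) != 3L) stop("a single triplet must have length 3")
    raw <- list(matrix(raw[1]), matrix(raw[2]), matrix(raw[3]))
  }
  if (!is.list(raw) || length(raw) != 3L)
    stop("raw must be a list of three matrices (AA, Aa, aa)")
  ll <- lapply(raw, function(m) {
    m <- as.matrix(m)
    if (dialect == "PL") -m / 10 else m
  })
  # flat prior: subtract the per-triplet maximum, exponentiate, normalize
  mx <- pmax(ll[[1]], ll[[2]], ll[[3]])
  p <- lapply(ll, function(m) 10^(m - mx))
  tot <- p[[1]] + p[[2]] + p[[3]]
  p <- lapply(p, function(m) m / tot)
  miss <- !is.finite(p[[1]]) | !is.finite(p[[2]]) | !is.finite(p[[3]])
  out <- gl_tensor(p[[1]], p[[2]], p[[3]], missing = miss,
                   samples = samples, variants = variants, validate = FALSE)
  if (single) {
    tr <- c(out$p_AA[1, 1], out$p_Aa[1, 1], out$p_aa[1, 1])
    names(tr) <- c("p_AA", "p_Aa", "p_aa")
    return(tr)
  }
  out
}

#' Genotype fuzziness
#'
#' The fuzziness of a genotype probability triplet is the variance of the
#' genotype value (0, 1 or 2 copies of the alternate allele) under the
#' triplet:
#' \deqn{\upsilon = P_{Aa}(1-P_{Aa}) + 4P_{aa}(1-P_{aa}) - 4P_{Aa}P_{aa}.}
#' It is 0 exactly when the triplet puts all mass on one genotype, and attains
#' its maximum of 1 at (1/2, 0, 1/2). Fuzziness is the covariate of the bias
#' adjustment: low-depth reads yield fuzzy triplets, and the downward bias of
#' the raw moment estimators grows with fuzziness.
#'
#' @param x a [gl_tensor()] or a numeric probability triplet.
#' @return a matrix of per-entry fuzziness values (`NA` where missing), or a
#'   scalar for a single triplet.
#' @export
fuzziness <- function(x) {
  if (is.numeric(x) && length(x) == 3L)
    return(unname(x[2] * (1 - x[2]) + 4 * x[3] * (1 - x[3]) - 4 * x[2] * x[3]))
  stopifnot(inherits(x, "gl_tensor"))
  b <- x$p_Aa; c2 <- x$p_aa
  b * (1 - b) + 4 * c2 * (1 - c2) - 4 * b * c2
}

#' Expected minor-allele dosage
#'
#' The expected count of the alternate allele under a genotype probability
#' triplet, \eqn{\tilde G = P_{Aa} + 2 P_{aa}}, in `[0, 2]`.
#'
#' @inheritParams fuzziness
#' @return a matrix (or scalar) of dosages, `NA` where missing.
#' @export
expected_dosage <- function(x) {
  if (is.numeric(x) && length(x) == 3L) return(unname(x[2] + 2 * x[3]))
  stopifnot(inherits(x, "gl_tensor"))
  x$p_Aa + 2 * x$p_aa
}

#' Per-variant genotype-frequency summaries
#'
#' Averages the genotype probability triplets over the non-missing
#' individuals of each variant, giving sample genotype-frequency estimates
#' \eqn{\bar P_{AA}, \bar P_{Aa}, \bar P_{aa}} and the mean dosage
#' \eqn{\bar P_{Aa} + 2\bar P_{aa}}. Variants with no non-missing individual
#' are flagged unusable.
#'
#' @param x a [gl_tensor()].
#' @return a data frame with columns `variant_id`, `p_AA`, `p_Aa`, `p_aa`,
#'   `mean_dosage`, `n_obs`, `usable`.
#' @export
variant_summaries <- function(x) {
  stopifnot(inherits(x, "gl_tensor"))
  n_obs <- colSums(!x$missing)
  pAA <- colMeans(x$p_AA, na.rm = TRUE)
  pAa <- colMeans(x$p_Aa, na.rm = TRUE)
  paa <- colMeans(x$p_aa, na.rm = TRUE)
  usable <- n_obs > 0L
  pAA[!usable] <- NA_real_; pAa[!usable] <- NA_real_; paa[!usable] <- NA_real_
  data.frame(variant_id = x$variants$variant_id,
             p_AA = pAA, p_Aa = pAa, p_aa = paa,
             mean_dosage = pAa + 2 * paa,
             n_obs = n_obs, usable = usable,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Expected minor-allele-count filter
#'
#' Keeps variants whose mean expected dosage lies in `[lo, hi]` (inclusive
#' bounds). Rare variants with very small — or, after allele flips, very large
#' — expected minor-allele counts destabilize the moment estimators and are
#' removed by default.
#'
#' @param summaries output of [variant_summaries()].
#' @param lo,hi inclusive dosage bounds, `0 <= lo < hi <= 2`; defaults 0.05
#'   and 1.95.
#' @return a logical keep-mask over variants (unusable variants are `FALSE`).
#' @export
maf_filter <- function(summaries, lo = 0.05, hi = 1.95) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi)
    stop("filter bounds must satisfy lo < hi")
  if (lo < 0 || hi > 2) stop("filter bounds must lie in [0, 2]")
  keep <- summaries$usable & summaries$mean_dosage >= lo &
    summaries$mean_dosage <= hi
  keep[is.na(keep)] <- FALSE
  keep
}
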