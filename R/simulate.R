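# Gene-dropping simulator with IBD tracking, and the Poisson read model that
# turns true genotypes into low-depth genotype likelihoods.
#
# Haplotypes are stored as label mosaics: per chromosome, a vector of segment
# right-ends (cM, last end = chromosome length) and the ancestral founder
# label of each segment. IBD ground truth is read off label identity.

# deterministic sub-seeds so each simulation component is independently
# reproducible from one user seed (kept below 2^31 - 1)
.sub_seed <- function(seed, stream) {
  offs <- c(founders = 1, genedrop = 2, depths = 3, errors = 4, reads = 5,
            adjust = 6)
  as.integer((as.numeric(seed) %% 67108864) * 31 + offs[[stream]])
}

.maybe_seed <- function(seed) if (!is.null(seed)) set.seed(as.integer(seed))

#' Genetic map
#'
#' A minimal genetic map: chromosome names and lengths in centimorgans. The
#' default test genome is 10 chromosomes of 100 cM.
#'
#' @param n_chrom number of chromosomes.
#' @param length_cM chromosome length(s) in cM (recycled).
#' @return data frame with columns `chrom`, `length_cM`.
#' @export
sim_genetic_map <- function(n_chrom = 10, length_cM = 100) {
  length_cM <- rep_len(length_cM, n_chrom)
  if (any(length_cM <= 0)) stop("chromosome lengths must be positive")
  data.frame(chrom = paste0("chr", seq_len(n_chrom)), length_cM = length_cM,
             stringsAsFactors = FALSE)
}

#' Sibling-study pedigree
#'
#' Builds a pedigree of independent nuclear families (two founder parents,
#' two full-sibling offspring) plus unrelated founder singletons. Parents are
#' not part of the analysis sample; siblings and singletons are.
#'
#' @param n_sib_pairs number of families contributing a full-sibling pair.
#' @param n_unrelated number of additional unrelated sampled founders.
#' @return data frame with columns `id`, `father`, `mother` (`NA` for
#'   founders) and `sampled`; parents precede children.
#' @export
sim_pedigree_sibs <- function(n_sib_pairs, n_unrelated = 0) {
  rows <- list()
  for (k in seq_len(n_sib_pairs)) {
    f <- sprintf("fam%02d", k)
    rows[[length(rows) + 1L]] <- data.frame(
      id = paste0(f, c("_p1", "_p2", "_s1", "_s2")),
      father = c(NA, NA, paste0(f, "_p1"), paste0(f, "_p1")),
      mother = c(NA, NA, paste0(f, "_p2"), paste0(f, "_p2")),
      sampled = c(FALSE, FALSE, TRUE, TRUE), stringsAsFactors = FALSE)
  }
  if (n_unrelated > 0)
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("unr%03d", seq_len(n_unrelated)),
      father = NA_character_, mother = NA_character_, sampled = TRUE,
      stringsAsFactors = FALSE)
  ped <- do.call(rbind, rows)
  rownames(ped) <- NULL
  ped
}

# fresh single-segment haplotypes for a set of founders; labels 2k-1, 2k
founder_haplotypes <- function(ids, map) {
  haps <- vector("list", length(ids))
  names(haps) <- ids
  for (k in seq_along(ids)) {
    haps[[k]] <- lapply(seq_len(nrow(map)), function(cc) {
      L <- map$length_cM[cc]
      list(h1 = list(ends = L, labels = 2L * k - 1L),
           h2 = list(ends = L, labels = 2L * k))
    })
  }
  haps
}

#' Simulate founder haplotypes and variant panel
#'
#' Draws per-variant alternate-allele frequencies from `maf_spec`, founder
#' haplotype alleles independently as Bernoulli(q), and places variants
#' uniformly along the genetic map (variant counts per chromosome
#' proportional to map length). Every founder haplotype carries a unique
#' ancestral label used for IBD tracking downstream.
#'
#' @param n_founders number of diploid founders, or a character vector of
#'   founder ids.
#' @param n_variants number of biallelic variants (0 allowed for
#'   recombination-only studies).
#' @param maf_spec allele-frequency specification: a single frequency, a
#'   `c(lo, hi)` range for uniform draws, or a `function(n)` returning `n`
#'   frequencies. All frequencies must be positive.
#' @param map a [sim_genetic_map()] data frame.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return an object of class `gl_founders`: founder mosaics (`haps`),
#'   variant metadata (`variants`: `variant_id`, `chrom`, `pos_cM`, `pos`,
#'   `ref`, `alt`), frequencies `q`, and the label-by-variant allele matrix
#'   `alleles` (0/1).
#' @export
simulate_founders <- function(n_founders, n_variants,
                              maf_spec = c(0.05, 0.5),
                              map = sim_genetic_map(), seed = NULL) {
  ids <- if (is.character(n_founders)) n_founders
         else paste0("F", seq_len(n_founders))
  if (length(ids) < 1L) stop("need at least one founder")
  .maybe_seed(seed)
  q <- if (is.function(maf_spec)) maf_spec(n_variants)
       else if (length(maf_spec) == 1L) rep(maf_spec, n_variants)
       else stats::runif(n_variants, maf_spec[1], maf_spec[2])
  if (n_variants > 0 && (any(!is.finite(q)) || any(q <= 0) || any(q >= 1)))
    stop("maf_spec must yield frequencies strictly inside (0, 1)")
  variants <- NULL; alleles <- NULL
  if (n_variants > 0) {
    # allocate variants to chromosomes proportionally to genetic length
    share <- map$length_cM / sum(map$length_cM)
    n_c <- floor(share * n_variants)
    rem <- n_variants - sum(n_c)
    if (rem > 0) n_c[seq_len(rem)] <- n_c[seq_len(rem)] + 1L
    chrom <- rep(map$chrom, n_c)
    pos_cM <- unlist(lapply(seq_len(nrow(map)), function(cc)
      sort(stats::runif(n_c[cc], 0, map$length_cM[cc]))), use.names = FALSE)
    variants <- data.frame(
      variant_id = sprintf("V%06d", seq_len(n_variants)),
      chrom = chrom, pos_cM = pos_cM, pos = as.integer(round(pos_cM * 1e6)) + 1L,
      ref = "A", alt = "G", stringsAsFactors = FALSE)
    n_lab <- 2L * length(ids)
    alleles <- matrix(stats::rbinom(n_lab * n_variants, 1L,
                                    rep(q, each = n_lab)),
                      nrow = n_lab, ncol = n_variants)
  }
  structure(list(ids = ids, map = map, variants = variants, q = q,
                 alleles = alleles, haps = founder_haplotypes(ids, map),
                 n_labels = 2L * length(ids)),
            class = "gl_founders")
}

# label of the segment covering each query position (positions in (0, L])
.labels_at <- function(h, pos) {
  idx <- findInterval(pos, h$ends, left.open = TRUE) + 1L
  h$labels[pmin(idx, length(h$labels))]
}

# one meiosis: crossover count Poisson(L/100), uniform positions, no
# interference (Haldane); returns the transmitted gamete mosaic
.meiosis <- function(h1, h2, L) {
  nx <- stats::rpois(1L, L / 100)
  cur <- sample.int(2L, 1L)
  if (nx == 0L) return(if (cur == 1L) h1 else h2)
  x <- sort(stats::runif(nx, 0, L))
  haps <- list(h1, h2)
  ends <- numeric(0); labels <- integer(0)
  lo <- 0
  for (hi in c(x, L)) {
    if (hi > lo) {
      h <- haps[[cur]]
      i1 <- findInterval(lo, h$ends) + 1L
      i2 <- findInterval(hi, h$ends, left.open = TRUE) + 1L
      idx <- i1:i2
      e <- h$ends[idx]
      e[length(e)] <- hi
      ends <- c(ends, e)
      labels <- c(labels, h$labels[idx])
    }
    cur <- 3L - cur
    lo <- hi
  }
  keep <- c(labels[-length(labels)] != labels[-1L], TRUE)
  list(ends = ends[keep], labels = labels[keep])
}

#' Gene-dropping along a pedigree
#'
#' Propagates labelled founder haplotypes down the pedigree: each transmitted
#' gamete is a crossover mosaic of the parent's two haplotypes, with
#' per-chromosome crossover counts Poisson(length/100 cM) and uniform
#' crossover positions (Haldane model, no interference).
#'
#' @param ped pedigree data frame (`id`, `father`, `mother`); parents must
#'   precede children, founders have `NA` parents.
#' @param founders a [simulate_founders()] object covering all pedigree
#'   founders.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return an object of class `gl_drop` holding the haplotype mosaics of
#'   every pedigree member plus the founder object and map.
#' @seealso [ibd_truth()] for realized IBD fractions, [drop_genotypes()] for
#'   variant genotypes.
#' @export
gene_drop <- function(ped, founders, seed = NULL) {
  stopifnot(inherits(founders, "gl_founders"))
  .maybe_seed(seed)
  map <- founders$map
  is_founder <- is.na(ped$father) & is.na(ped$mother)
  if (!all(ped$id[is_founder] %in% founders$ids))
    stop("pedigree founders missing from the founder set")
  haps <- list()
  for (r in seq_len(nrow(ped))) {
    id <- ped$id[r]
    if (is_founder[r]) {
      haps[[id]] <- founders$haps[[id]]
    } else {
      fa <- haps[[ped$father[r]]]; mo <- haps[[ped$mother[r]]]
      if (is.null(fa) || is.null(mo))
        stop("parents must precede children in the pedigree: ", id)
      haps[[id]] <- lapply(seq_len(nrow(map)), function(cc) {
        L <- map$length_cM[cc]
        list(h1 = .meiosis(fa[[cc]]$h1, fa[[cc]]$h2, L),
             h2 = .meiosis(mo[[cc]]$h1, mo[[cc]]$h2, L))
      })
    }
  }
  structure(list(ped = ped, map = map, haps = haps, founders = founders),
            class = "gl_drop")
}

#' Realized IBD sharing of simulated pairs
#'
#' Computes, for each requested pair, the length-weighted genome fractions in
#' IBD states 0, 1 and 2 from ancestral-label identity along the haplotype
#' mosaics, and the implied true kinship \eqn{\varphi = f_1/4 + f_2/2} and
#' fraternity \eqn{\psi = f_2}.
#'
#' @param drop a [gene_drop()] object.
#' @param pairs data frame or 2-column matrix of id pairs (self-pairs
#'   allowed); default: all unordered distinct pairs of pedigree members.
#' @return data frame with columns `id1`, `id2`, `f0`, `f1`, `f2`,
#'   `phi_true`, `psi_true`.
#' @export
ibd_truth <- function(drop, pairs = NULL) {
  stopifnot(inherits(drop, "gl_drop"))
  ids <- drop$ped$id
  if (is.null(pairs)) {
    idx <- which(upper.tri(matrix(0, length(ids), length(ids))), arr.ind = TRUE)
    pairs <- cbind(ids[idx[, 1]], ids[idx[, 2]])
  }
  pairs <- as.matrix(pairs)
  L_tot <- sum(drop$map$length_cM)
  out <- data.frame(id1 = pairs[, 1], id2 = pairs[, 2],
                    f0 = NA_real_, f1 = NA_real_, f2 = NA_real_,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(pairs))) {
    A <- drop$haps[[pairs[r, 1]]]; B <- drop$haps[[pairs[r, 2]]]
    if (is.null(A) || is.null(B)) stop("unknown individual in pairs")
    l1 <- 0; l2 <- 0
    for (cc in seq_len(nrow(drop$map))) {
      cuts <- sort(unique(c(0, A[[cc]]$h1$ends, A[[cc]]$h2$ends,
                            B[[cc]]$h1$ends, B[[cc]]$h2$ends)))
      mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
      len <- diff(cuts)
      a1 <- .labels_at(A[[cc]]$h1, mids); a2 <- .labels_at(A[[cc]]$h2, mids)
      b1 <- .labels_at(B[[cc]]$h1, mids); b2 <- .labels_at(B[[cc]]$h2, mids)
      ibd2 <- (a1 == b1 & a2 == b2) | (a1 == b2 & a2 == b1)
      ibd1p <- a1 == b1 | a1 == b2 | a2 == b1 | a2 == b2
      l2 <- l2 + sum(len[ibd2])
      l1 <- l1 + sum(len[ibd1p & !ibd2])
    }
    out$f2[r] <- l2 / L_tot
    out$f1[r] <- l1 / L_tot
    out$f0[r] <- 1 - out$f1[r] - out$f2[r]
  }
  out$phi_true <- out$f1 / 4 + out$f2 / 2
  out$psi_true <- out$f2
  out
}

#' True genotypes from a gene-dropping run
#'
#' Looks up, for each individual and variant, the founder alleles carried by
#' the two haplotype segments covering the variant position.
#'
#' @param drop a [gene_drop()] object.
#' @param ids individuals to genotype (default: all pedigree members).
#' @return integer matrix (individuals x variants) of alternate-allele
#'   counts, with `ids` as rownames.
#' @export
drop_genotypes <- function(drop, ids = NULL) {
  stopifnot(inherits(drop, "gl_drop"))
  founders <- drop$founders
  if (is.null(founders$alleles)) stop("founder set carries no variants")
  if (is.null(ids)) ids <- drop$ped$id
  v <- founders$variants
  G <- matrix(0L, length(ids), nrow(v))
  rownames(G) <- ids
  for (cc in seq_len(nrow(drop$map))) {
    jj <- which(v$chrom == drop$map$chrom[cc])
    if (!length(jj)) next
    pos <- v$pos_cM[jj]
    for (k in seq_along(ids)) {
      H <- drop$haps[[ids[k]]][[cc]]
      a1 <- founders$alleles[cbind(.labels_at(H$h1, pos), jj)]
      a2 <- founders$alleles[cbind(.labels_at(H$h2, pos), jj)]
      G[k, jj] <- a1 + a2
    }
  }
  G
}

#' Poisson read-rate parameters
#'
#' Rates of the three independent Poisson read counts (reference-allele
#' reads, alternate-allele reads, error reads) at a site with mean depth `d`
#' and per-base error rate `eps`, given the true genotype: the rate triplet
#' is \eqn{(\rho_A d, \rho_a d, \rho_\varepsilon d)} with
#' \eqn{\rho_A = 1-\varepsilon,\ \varepsilon/3} for genotypes 0 and 2 (and
#' the average \eqn{(1-\varepsilon)/2 + \varepsilon/6} for heterozygotes),
#' mirrored for \eqn{\rho_a}, and \eqn{\rho_\varepsilon = 2\varepsilon/3}
#' throughout. The three rates sum to `d` for every genotype.
#'
#' @param G genotype(s) in `{0, 1, 2}`.
#' @param eps per-base error rate(s) in `[0, 1)`.
#' @param d mean read depth(s), positive.
#' @return named numeric vector `(lambda_A, lambda_a, lambda_eps)` for scalar
#'   input, otherwise a 3-column matrix.
#' @export
poisson_rates <- function(G, eps, d) {
  n <- max(length(G), length(eps), length(d))
  G <- rep_len(as.integer(G), n); eps <- rep_len(eps, n); d <- rep_len(d, n)
  if (any(is.na(G)) || any(!G %in% 0:2)) stop("genotypes must be 0, 1 or 2")
  if (any(eps < 0 | eps >= 1)) stop("error rates must lie in [0, 1)")
  if (any(d <= 0)) stop("depths must be positive")
  het <- (1 - eps) / 2 + eps / 6
  rho_A <- ifelse(G == 0L, 1 - eps, ifelse(G == 1L, het, eps / 3))
  rho_a <- ifelse(G == 2L, 1 - eps, ifelse(G == 1L, het, eps / 3))
  out <- cbind(lambda_A = rho_A * d, lambda_a = rho_a * d,
               lambda_eps = (2 * eps / 3) * d)
  if (n == 1L) out[1, ] else out
}

#' Draw Poisson read counts
#'
#' @param rates output of [poisson_rates()] (vector of 3 or 3-column matrix).
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return named vector or 3-column matrix of counts `(R_A, R_a, R_eps)`.
#' @export
draw_reads <- function(rates, seed = NULL) {
  .maybe_seed(seed)
  single <- is.null(dim(rates))
  if (single) rates <- matrix(rates, 1)
  out <- cbind(R_A = stats::rpois(nrow(rates), rates[, 1]),
               R_a = stats::rpois(nrow(rates), rates[, 2]),
               R_eps = stats::rpois(nrow(rates), rates[, 3]))
  if (single) out[1, ] else out
}

#' Genotype likelihoods from read counts
#'
#' Computes, for each candidate genotype, the likelihood of the observed read
#' counts, proportional to
#' \eqn{\rho_A^{R_A}\,\rho_a^{R_a}\,\rho_\varepsilon^{R_\varepsilon}} with
#' the rate fractions of [poisson_rates()], applies a flat prior and
#' normalizes to a genotype probability triplet. Sites with no allele-bearing
#' read (`R_A = R_a = 0`) are set missing.
#'
#' @param counts read counts: vector of 3 or a 3-column matrix.
#' @param eps per-variant error rate(s) in (0, 1), recycled over rows.
#' @return probability triplet(s) `(p_AA, p_Aa, p_aa)`; `NA` where missing.
#' @export
reads_to_likelihoods <- function(counts, eps) {
  single <- is.null(dim(counts))
  if (single) counts <- matrix(counts, 1)
  n <- nrow(counts)
  eps <- rep_len(eps, n)
  if (any(eps <= 0 | eps >= 1)) stop("error rates must lie in (0, 1)")
  het <- (1 - eps) / 2 + eps / 6
  # per-genotype log-likelihoods; the error-read factor is common to all
  # genotypes and kept for completeness
  lle <- counts[, 3] * log(2 * eps / 3)
  ll0 <- counts[, 1] * log(1 - eps) + counts[, 2] * log(eps / 3) + lle
  ll1 <- (counts[, 1] + counts[, 2]) * log(het) + lle
  ll2 <- counts[, 1] * log(eps / 3) + counts[, 2] * log(1 - eps) + lle
  mx <- pmax(ll0, ll1, ll2)
  p0 <- exp(ll0 - mx); p1 <- exp(ll1 - mx); p2 <- exp(ll2 - mx)
  tot <- p0 + p1 + p2
  out <- cbind(p_AA = p0 / tot, p_Aa = p1 / tot, p_aa = p2 / tot)
  out[counts[, 1] + counts[, 2] == 0L, ] <- NA_real_
  if (single) out[1, ] else out
}

#' Per-variant mean depths
#'
#' Either rescales a template of per-variant depths multiplicatively so its
#' mean equals `target_mean`, or, absent a template, draws depths from a
#' Gamma distribution with mean `target_mean` and shape 2 — a stand-in for
#' the right-skewed depth profiles of real sequencing panels.
#'
#' @param n_variants number of variants.
#' @param target_mean desired global mean depth (> 0).
#' @param template optional length-`n_variants` vector of reference depths.
#' @param shape Gamma shape for the template-free draw.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return numeric vector of per-variant mean depths.
#' @export
simulate_depths <- function(n_variants, target_mean, template = NULL,
                            shape = 2, seed = NULL) {
  if (target_mean <= 0) stop("target_mean must be positive")
  if (!is.null(template)) {
    if (length(template) != n_variants) stop("template of wrong length")
    return(template * target_mean / mean(template))
  }
  .maybe_seed(seed)
  stats::rgamma(n_variants, shape = shape, rate = shape / target_mean)
}

#' Per-variant sequencing error rates
#'
#' Draws error rates as \eqn{10^{-u}} with `u` uniform on (2, 3), i.e. rates
#' between 0.1% and 1%.
#'
#' @param n_variants number of variants.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return numeric vector of error rates in `[1e-3, 1e-2]`.
#' @export
draw_error_rates <- function(n_variants, seed = NULL) {
  .maybe_seed(seed)
  10^(-stats::runif(n_variants, 2, 3))
}

#' Low-depth likelihood tensor from true genotypes
#'
#' Vectorized application of the Poisson read model: draws the three read
#' counts for every individual-variant cell, converts them to flat-prior
#' genotype probability triplets, and flags cells without allele-bearing
#' reads as missing.
#'
#' @param G integer genotype matrix (individuals x variants).
#' @param depths per-variant mean depths (length `ncol(G)`).
#' @param error_rates per-variant error rates in (0, 1).
#' @param depth_mult optional per-individual depth multipliers (default 1),
#'   for depth-heterogeneous samples.
#' @param samples,variants metadata passed to [gl_tensor()].
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return a [gl_tensor()].
#' @export
sim_reads_tensor <- function(G, depths, error_rates, depth_mult = NULL,
                             samples = NULL, variants = NULL, seed = NULL) {
  .maybe_seed(seed)
  N <- nrow(G); M <- ncol(G)
  stopifnot(length(depths) == M, length(error_rates) == M)
  if (any(error_rates <= 0 | error_rates >= 1))
    stop("error rates must lie in (0, 1)")
  e <- error_rates
  het <- (1 - e) / 2 + e / 6
  tabA <- cbind(1 - e, het, e / 3)
  taba <- cbind(e / 3, het, 1 - e)
  jj <- rep(seq_len(M), each = N)
  gi <- as.vector(G) + 1L
  dm <- if (is.null(depth_mult)) rep(1, N) else rep_len(depth_mult, N)
  lam <- dm %o% depths
  R_A <- matrix(stats::rpois(N * M, matrix(tabA[cbind(jj, gi)], N, M) * lam), N, M)
  R_a <- matrix(stats::rpois(N * M, matrix(taba[cbind(jj, gi)], N, M) * lam), N, M)
  rep_row <- function(v) matrix(v, N, M, byrow = TRUE)
  # the error-read factor is genotype-independent and cancels in the
  # normalization, so error reads need not be drawn for the likelihoods
  ll0 <- R_A * rep_row(log(1 - e)) + R_a * rep_row(log(e / 3))
  ll1 <- (R_A + R_a) * rep_row(log(het))
  ll2 <- R_A * rep_row(log(e / 3)) + R_a * rep_row(log(1 - e))
  mx <- pmax(ll0, ll1, ll2)
  p0 <- exp(ll0 - mx); p1 <- exp(ll1 - mx); p2 <- exp(ll2 - mx)
  tot <- p0 + p1 + p2
  miss <- R_A + R_a == 0L
  gl_tensor(p0 / tot, p1 / tot, p2 / tot, missing = miss,
            samples = samples, variants = variants, validate = FALSE)
}

#' Simulate a sibling study at low depth
#'
#' End-to-end fixture generator: gene-drops nuclear families and unrelated
#' singletons over a genetic map, records the realized IBD sharing of each
#' sibling pair, and converts the sampled individuals' true genotypes into
#' low-depth genotype likelihoods via the Poisson read model. Cross-family
#' pairs share no ancestry by construction (true kinship and fraternity 0),
#' so the returned truth table covers the sibling pairs.
#'
#' @param n_sib_pairs,n_unrelated sample composition (sampled individuals:
#'   `2 * n_sib_pairs + n_unrelated`).
#' @param n_variants number of biallelic SNPs.
#' @param mean_depth global mean read depth.
#' @param map a [sim_genetic_map()].
#' @param maf allele-frequency specification, see [simulate_founders()].
#' @param depth_template,depth_mult optional depth profile and per-individual
#'   multipliers, see [simulate_depths()] and [sim_reads_tensor()].
#' @param seed integer seed driving named sub-streams for founders,
#'   gene-dropping, depths, error rates and reads.
#' @return an object of class `sib_study`: `tensor` (the [gl_tensor()]),
#'   `genotypes` (true genotype matrix of the sampled individuals), `truth`
#'   (sibling-pair [ibd_truth()] table), `sib_pairs`, `ped`, `samples`,
#'   `variants`, `q`, `depths`, `error_rates`, `mean_depth`.
#' @export
sim_sib_study <- function(n_sib_pairs = 20, n_unrelated = 160,
                          n_variants = 50000, mean_depth = 2.5,
                          map = sim_genetic_map(), maf = c(0.05, 0.5),
                          depth_template = NULL, depth_mult = NULL,
                          seed = 1) {
  ped <- sim_pedigree_sibs(n_sib_pairs, n_unrelated)
  founder_ids <- ped$id[is.na(ped$father)]
  founders <- simulate_founders(founder_ids, n_variants, maf, map,
                                seed = .sub_seed(seed, "founders"))
  drop <- gene_drop(ped, founders, seed = .sub_seed(seed, "genedrop"))
  samples <- ped$id[ped$sampled]
  G <- if (n_variants > 0) drop_genotypes(drop, samples) else NULL
  sib_pairs <- if (n_sib_pairs > 0)
    data.frame(id1 = sprintf("fam%02d_s1", seq_len(n_sib_pairs)),
               id2 = sprintf("fam%02d_s2", seq_len(n_sib_pairs)),
               stringsAsFactors = FALSE)
  else data.frame(id1 = character(0), id2 = character(0))
  truth <- if (nrow(sib_pairs)) ibd_truth(drop, sib_pairs) else NULL
  depths <- eps <- NULL
  tensor <- NULL
  if (n_variants > 0) {
    depths <- simulate_depths(n_variants, mean_depth,
                              template = depth_template,
                              seed = .sub_seed(seed, "depths"))
    eps <- draw_error_rates(n_variants, seed = .sub_seed(seed, "errors"))
    tensor <- sim_reads_tensor(G, depths, eps, depth_mult = depth_mult,
                               samples = samples,
                               variants = founders$variants,
                               seed = .sub_seed(seed, "reads"))
  }
  structure(list(tensor = tensor, genotypes = G, truth = truth,
                 sib_pairs = sib_pairs, ped = ped, samples = samples,
                 variants = founders$variants, q = founders$q,
                 depths = depths, error_rates = eps, mean_depth = mean_depth,
                 seed = seed),
            class = "sib_study")
}

#' @export
#' @method print sib_study
print.sib_study <- function(x, ...) {
  cat("Simulated low-depth sibling study\n")
  cat(sprintf("  %d sampled individuals (%d sibling pairs), %d variants\n",
              length(x$samples), nrow(x$sib_pairs),
              if (is.null(x$variants)) 0L else nrow(x$variants)))
  if (!is.null(x$error_rates))
    cat(sprintf("  mean depth %.2fx, error rates in [%.1e, %.1e]\n",
                x$mean_depth, min(x$error_rates), max(x$error_rates)))
  invisible(x)
}
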