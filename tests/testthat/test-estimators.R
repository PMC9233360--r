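test_that("classical codings match the closed form and its constraints", {
  cc <- classical_components(0.5)
  expect_equal(cc$alpha[1, ], c(-sqrt(2), 0, sqrt(2)))
  expect_equal(cc$delta[1, ], c(1, -1, 1))
  expect_equal(classical_components(0.25)$alpha[1, 1], -0.5 / sqrt(0.375))
  # orthonormality under HWE weights for a q grid
  for (q in seq(0.05, 0.95, by = 0.1)) {
    p <- 1 - q
    w <- c(p^2, 2 * p * q, q^2)
    cc <- classical_components(q)
    expect_equal(sum(w * cc$alpha[1, ]), 0, tolerance = 1e-12)
    expect_equal(sum(w * cc$alpha[1, ]^2), 1, tolerance = 1e-12)
    expect_equal(sum(w * cc$delta[1, ]), 0, tolerance = 1e-12)
    expect_equal(sum(w * cc$delta[1, ]^2), 1, tolerance = 1e-12)
    expect_equal(sum(w * cc$alpha[1, ] * cc$delta[1, ]), 0, tolerance = 1e-12)
  }
  expect_false(classical_components(0)$keep_add)
  expect_false(classical_components(1)$keep_dom)
})

test_that("genotype-frequency codings are orthonormal under the P-bar law", {
  set.seed(21)
  for (rep in 1:30) {
    w <- stats::runif(3, 0.02, 1); w <- w / sum(w)
    s <- data.frame(p_AA = w[1], p_Aa = w[2], p_aa = w[3], usable = TRUE)
    gc <- gl_components(s)
    expect_equal(sum(w * gc$alpha[1, ]), 0, tolerance = 1e-8)
    expect_equal(sum(w * gc$alpha[1, ]^2), 1, tolerance = 1e-8)
    expect_equal(sum(w * gc$delta[1, ]), 0, tolerance = 1e-8)
    expect_equal(sum(w * gc$delta[1, ]^2), 1, tolerance = 1e-8)
    expect_equal(sum(w * gc$alpha[1, ] * gc$delta[1, ]), 0, tolerance = 1e-8)
  }
})

test_that("genotype-frequency codings reduce to the classical ones in HWE", {
  s05 <- data.frame(p_AA = 0.25, p_Aa = 0.5, p_aa = 0.25, usable = TRUE)
  gc <- gl_components(s05)
  expect_equal(gc$alpha[1, ], c(-1, 0, 1) / sqrt(0.5), tolerance = 1e-12)
  expect_equal(gc$delta[1, ], c(1, -1, 1), tolerance = 1e-12)
  for (q in seq(0.05, 0.95, by = 0.06)) {
    p <- 1 - q
    s <- data.frame(p_AA = p^2, p_Aa = 2 * p * q, p_aa = q^2, usable = TRUE)
    gc <- gl_components(s)
    cc <- classical_components(q)
    expect_equal(gc$alpha[1, ], cc$alpha[1, ], tolerance = 1e-10)
    expect_equal(gc$delta[1, ], cc$delta[1, ], tolerance = 1e-10)
  }
})

test_that("degenerate genotype frequencies disable the affected component", {
  s <- data.frame(p_AA = 0.5, p_Aa = 0, p_aa = 0.5, usable = TRUE)
  gc <- gl_components(s)
  expect_false(gc$keep_dom)
  expect_true(gc$keep_add)
  s2 <- data.frame(p_AA = 1, p_Aa = 0, p_aa = 0, usable = TRUE)
  gc2 <- gl_components(s2)
  expect_false(gc2$keep_add)
})

test_that("scores are linear in the triplet and reduce on hard calls", {
  x <- tensor_from_triplets(rbind(c(0, 1, 0), c(1 / 3, 1 / 3, 1 / 3)))
  comp <- gl_components(data.frame(p_AA = 0.25, p_Aa = 0.5, p_aa = 0.25,
                                   usable = TRUE))
  sc <- build_scores(x, comp)
  expect_equal(sc$X_D[1, 1], -1)                       # certain heterozygote
  expect_equal(sc$X_A[2, 1], 0, tolerance = 1e-12)     # flat triplet

  # hard-call tensor in exact HWE: likelihood pipeline equals classical GRM
  G <- hwe_exact_genotypes(c(0.5, 0.2, 0.4))
  fit_gl <- glkin(tensor_from_genotypes(G), filter = NULL, adjust = FALSE)
  fit_hard <- grm_genotypes(G)
  expect_equal(fit_gl$K, fit_hard$K, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit_gl$D, fit_hard$D, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("cross-product accumulation uses pair-specific denominators", {
  X <- rbind(c(1, 2, NA), c(2, NA, 1))
  K <- accumulate_grm(X)
  expect_equal(K[1, 2], 2)          # only variant 1 shared
  expect_equal(K[1, 1], 2.5)
  expect_equal(attr(K, "n_shared")[1, 2], 1)
  expect_equal(K, t(K), ignore_attr = TRUE)

  X2 <- rbind(c(1, NA), c(NA, 1))   # no shared variants
  expect_true(is.na(accumulate_grm(X2)[1, 2]))
  expect_equal(unname(accumulate_grm(matrix(0, 3, 4))),
               matrix(0, 3, 3), ignore_attr = TRUE)

  # identical rows give equal diagonal and off-diagonal entries
  X3 <- rbind(c(1, -1, 2), c(1, -1, 2))
  K3 <- accumulate_grm(X3)
  expect_equal(K3[1, 2], K3[1, 1])
})

test_that("EM allele frequencies hit the closed-form fixed points", {
  # certain genotypes: EM lands on the sample allele frequency
  G <- matrix(c(0, 1, 2, 1, 0, 0), 6, 1)
  q <- em_allele_freq(tensor_from_genotypes(G))
  expect_equal(as.numeric(q), mean(G) / 2, tolerance = 1e-7)
  # two individuals AA and Aa: one alternate allele among four
  x2 <- tensor_from_triplets(rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(as.numeric(em_allele_freq(x2)), 0.25, tolerance = 1e-7)
  # flat likelihoods: every q is a fixed point, the initial value persists
  xf <- tensor_from_triplets(matrix(1 / 3, 4, 3))
  expect_equal(as.numeric(em_allele_freq(xf, init = 0.37)), 0.37,
               tolerance = 1e-7)
})

test_that("relatedness matrices are invariant to allele relabelling", {
  set.seed(33)
  st <- sim_sib_study(n_sib_pairs = 3, n_unrelated = 10, n_variants = 400,
                      mean_depth = 3, map = sim_genetic_map(2, 100), seed = 6)
  x <- st$tensor
  flip <- gl_tensor(x$p_aa, x$p_Aa, x$p_AA, missing = x$missing,
                    samples = x$samples, validate = FALSE)
  f1 <- glkin(x, adjust = FALSE)
  f2 <- glkin(flip, adjust = FALSE)
  expect_equal(f1$K, f2$K, tolerance = 1e-10)
  expect_equal(f1$D, f2$D, tolerance = 1e-10)
  expect_equal(f1$m, f2$m)
})

test_that("external frequencies reduce to the classical estimator", {
  G <- hwe_exact_genotypes(c(0.5, 0.2, 0.4, 0.3))
  x <- tensor_from_genotypes(G)
  q <- colMeans(G) / 2
  ext <- glkin(x, freq = q, filter = NULL, adjust = FALSE)
  hard <- grm_genotypes(G)
  expect_equal(ext$K, hard$K, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ext$D, hard$D, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ext$mode, "external")
})

test_that("unadjusted bias grows as depth falls, on shared genotypes", {
  st <- pipeline_study()
  G <- st$genotypes
  sib <- sib_index(st)
  phi_by_depth <- sapply(c(10, 5, 2.5), function(d) {
    x <- sim_reads_tensor(G, depths = simulate_depths(ncol(G), d, seed = 91),
                          error_rates = draw_error_rates(ncol(G), seed = 92),
                          samples = st$samples, seed = 93)
    fit <- glkin(x, adjust = FALSE)
    mean(fit$K[sib]) / 2
  })
  expect_true(all(diff(phi_by_depth) < 0))
  hard <- grm_genotypes(G)
  expect_true(all(phi_by_depth < mean(hard$K[sib]) / 2))
})

test_that("complete-genotype matrices track the simulated IBD truth", {
  st <- pipeline_study()
  hard <- grm_genotypes(st$genotypes)
  sib <- sib_index(st)
  # per-pair regression of estimate on realized truth across sib pairs plus
  # a zero-truth unrelated batch
  unrel <- cbind(1:16, 17:32)
  phi_est <- c(hard$K[sib] / 2, hard$K[unrel] / 2)
  phi_tru <- c(st$truth$phi_true, rep(0, nrow(unrel)))
  fitk <- stats::lm(phi_est ~ phi_tru)
  expect_equal(unname(stats::coef(fitk)[2]), 1, tolerance = 0.2)
  psi_est <- c(hard$D[sib], hard$D[unrel])
  psi_tru <- c(st$truth$psi_true, rep(0, nrow(unrel)))
  fitd <- stats::lm(psi_est ~ psi_tru)
  expect_equal(unname(stats::coef(fitd)[2]), 1, tolerance = 0.35)
})
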