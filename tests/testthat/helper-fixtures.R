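# Shared fixture builders. Everything is generated in code at test time.

# a tiny tensor from explicit triplets: trips is a list of c(pAA, pAa, paa)
# per individual for a single variant, or a 3-column matrix
tensor_from_triplets <- function(trips) {
  m <- if (is.list(trips)) do.call(rbind, trips) else trips
  gl_tensor(m[, 1, drop = FALSE], m[, 2, drop = FALSE], m[, 3, drop = FALSE])
}

# certain-genotype tensor from a hard genotype matrix
tensor_from_genotypes <- function(G) {
  gl_tensor((G == 0L) * 1, (G == 1L) * 1, (G == 2L) * 1,
            missing = is.na(G), samples = rownames(G))
}

# genotype matrix with exact HWE proportions at each q (q a multiple of 0.1
# and n = 100 give integer genotype counts)
hwe_exact_genotypes <- function(q, n = 100) {
  sapply(q, function(qq) {
    counts <- round(n * c((1 - qq)^2, 2 * qq * (1 - qq), qq^2))
    stopifnot(sum(counts) == n)
    rep(0:2, counts)
  })
}

sib_index <- function(study) {
  cbind(match(study$sib_pairs$id1, study$samples),
        match(study$sib_pairs$id2, study$samples))
}

# medium-sized study shared by the slower pipeline tests (built once)
.fixture_env <- new.env(parent = emptyenv())
pipeline_study <- function() {
  if (is.null(.fixture_env$study))
    .fixture_env$study <- sim_sib_study(n_sib_pairs = 8, n_unrelated = 24,
                                        n_variants = 4000, mean_depth = 2.5,
                                        map = sim_genetic_map(5, 100),
                                        seed = 42)
  .fixture_env$study
}
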