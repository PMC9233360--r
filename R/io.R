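#' Read genotype likelihoods from a VCF
#'
#' Loads a multi-sample VCF (optionally gzipped), keeps biallelic SNP
#' records, and decodes the per-sample `PL` (phred-scaled) or `GL`
#' (log10-scaled) likelihood field into a genotype probability tensor via
#' [normalize_likelihoods()]. Samples with a missing field at a site are
#' missing there; multiallelic and non-SNP records are skipped and counted.
#'
#' @param path VCF file path.
#' @param field preferred likelihood field; with the default `"PL"`, `GL` is
#'   used as a fallback when no record carries `PL`.
#' @return a [gl_tensor()]; the number of skipped records is in attribute
#'   `"n_skipped"` and the field used in `"field"`.
#' @export
read_vcf_gl <- function(path, field = c("PL", "GL")) {
  field <- match.arg(field)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(fix[, "REF"]) == 1L & nchar(alt) == 1L
  n_skipped <- sum(!keep)
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  v <- v[keep, ]
  used <- field
  gm <- tryCatch(vcfR::extract.gt(v, element = field),
                 error = function(e) NULL)
  if (is.null(gm) || all(is.na(gm))) {
    fallback <- setdiff(c("PL", "GL"), field)
    gm <- tryCatch(vcfR::extract.gt(v, element = fallback),
                   error = function(e) NULL)
    if (is.null(gm) || all(is.na(gm)))
      stop("no usable ", field, " (or fallback) FORMAT field in ", path)
    used <- fallback
  }
  tri <- lapply(1:3, function(k)
    t(vcfR::masplit(gm, record = k, sort = 0, decreasing = 0)))
  fix <- v@fix
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  variants <- data.frame(variant_id = ids, chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  out <- normalize_likelihoods(tri, dialect = used,
                               samples = colnames(gm), variants = variants)
  attr(out, "n_skipped") <- n_skipped
  attr(out, "field") <- used
  out
}

#' Read hard genotypes from a VCF
#'
#' Decodes the `GT` field of the biallelic SNP records of a VCF into an
#' alternate-allele count matrix, for benchmarking against hard-call
#' relationship matrices ([grm_genotypes()]).
#'
#' @param path VCF file path.
#' @return integer matrix (individuals x variants) with `NA` for missing
#'   calls.
#' @export
read_vcf_gt <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(fix[, "REF"]) == 1L & nchar(alt) == 1L
  v <- v[keep, ]
  gt <- vcfR::extract.gt(v, element = "GT")
  cnt <- function(s) {
    out <- rep(NA_integer_, length(s))
    out[s %in% c("0/0", "0|0")] <- 0L
    out[s %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    out[s %in% c("1/1", "1|1")] <- 2L
    out
  }
  G <- t(apply(gt, 2, cnt))
  G <- matrix(as.integer(G), nrow = ncol(gt),
              dimnames = list(colnames(gt), NULL))
  G
}

#' Write a simulated study as VCF plus truth table
#'
#' Emits the simulated genotype likelihoods as a multi-sample VCF
#' (`<prefix>.vcf.gz`, FORMAT `GT:PL`, with the true genotypes in `GT`) and
#' the sibling-pair IBD ground truth as `<prefix>_truth.tsv`.
#'
#' @param study a [sim_sib_study()] object.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @importClassesFrom vcfR vcfR
#' @export
write_sim_vcf <- function(study, prefix) {
  stopifnot(inherits(study, "sib_study"))
  x <- study$tensor
  v <- study$variants
  N <- nrow(x$p_AA); M <- ncol(x$p_AA)
  # phred-scale the probability triplets, anchored at the maximum
  pl <- function(p, mx) {
    out <- round(-10 * (log10(p) - log10(mx)))
    pmin(out, 100000)
  }
  mx <- pmax(x$p_AA, x$p_Aa, x$p_aa)
  pl0 <- pl(x$p_AA, mx); pl1 <- pl(x$p_Aa, mx); pl2 <- pl(x$p_aa, mx)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[study$genotypes + 1L], N, M)
  cell <- paste0(gt_str, ":", pl0, ",", pl1, ",", pl2)
  cell[x$missing] <- paste0(gt_str[x$missing], ":.,.,.")
  gt <- t(matrix(cell, N, M))
  colnames(gt) <- x$samples
  gt <- cbind(FORMAT = "GT:PL", gt)
  fix <- cbind(CHROM = v$chrom, POS = as.character(v$pos), ID = v$variant_id,
               REF = v$ref, ALT = v$alt, QUAL = ".", FILTER = "PASS",
               INFO = ".")
  meta <- c("##fileformat=VCFv4.2",
            "##source=glkin simulator",
            paste0("##contig=<ID=", unique(v$chrom), ">"),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"True simulated genotype\">",
            "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">")
  obj <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcf_path <- paste0(prefix, ".vcf.gz")
  vcfR::write.vcf(obj, vcf_path)
  truth_path <- paste0(prefix, "_truth.tsv")
  truth <- study$truth
  if (is.null(truth))
    truth <- data.frame(id1 = character(0), id2 = character(0))
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(vcf = vcf_path, truth = truth_path))
}

#' Write relatedness results to disk
#'
#' Writes (a) square tab-delimited kinship-scale (`2*phi`) and fraternity
#' matrices with sample ids, (b) a long-format pair table with `phi_hat` and
#' `psi_hat` (diagonal rows marked `self`), and (c) a JSON run report with
#' the bias factors, filters, counts and seed.
#'
#' @param fit a [glkin()] object.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_result <- function(fit, prefix) {
  stopifnot(inherits(fit, "glkin"))
  paths <- c(kinship = paste0(prefix, "_kinship.tsv"),
             fraternity = paste0(prefix, "_fraternity.tsv"),
             pairs = paste0(prefix, "_pairs.tsv"),
             report = paste0(prefix, "_report.json"))
  wm <- function(m, path) {
    df <- data.frame(id = rownames(m), round(m, 6), check.names = FALSE)
    colnames(df) <- c("id", colnames(m))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wm(fit$K, paths["kinship"])
  if (!is.null(fit$D)) wm(fit$D, paths["fraternity"])
  tab <- coef(fit, diagonal = TRUE)
  tab$phi_hat <- round(tab$phi_hat, 6)
  tab$psi_hat <- round(tab$psi_hat, 6)
  utils::write.table(tab, paths["pairs"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  report <- list(package = "glkin",
                 version = as.character(utils::packageVersion("glkin")),
                 adjusted = fit$adjusted,
                 beta = as.list(fit$beta), shift = as.list(fit$shift),
                 mode = fit$mode, filter = fit$filter,
                 n_samples = length(fit$samples),
                 n_variants_used = as.list(fit$m), seed = fit$seed)
  jsonlite::write_json(report, paths["report"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(paths)
}

#' Read an external allele-frequency table
#'
#' Two tab-delimited columns with a header: variant id and alternate-allele
#' frequency.
#'
#' @param path file path.
#' @return named numeric vector of frequencies.
#' @export
read_freq_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("frequency table needs two columns")
  stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}
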