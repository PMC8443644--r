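# Shared fixture builders: all test data is constructed in code.

# Build a long locus table from per-locus allele/count specifications.
# counts_list: list of (n_samples x k_alleles) matrices, columns aligned to
# alleles_list entries (reference allele first).
make_loci <- function(counts_list, alleles_list, samples,
                      contig = "c1", pos = NULL) {
  stopifnot(length(counts_list) == length(alleles_list))
  if (is.null(pos)) pos <- seq_along(counts_list) * 10L
  n_s <- length(samples)
  rows <- lapply(seq_along(counts_list), function(i) {
    al <- alleles_list[[i]]
    cm <- counts_list[[i]]
    stopifnot(nrow(cm) == n_s, ncol(cm) == length(al))
    tibble::tibble(
      locus_id = i,
      contig = contig,
      pos = pos[i],
      allele = rep(al, each = n_s),
      is_ref = rep(c(TRUE, rep(FALSE, length(al) - 1L)), each = n_s),
      sample = rep(samples, length(al)),
      count = as.integer(as.vector(cm))
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "samples") <- samples
  out
}

# A filtered-like table (what filter_loci() with subsample off and
# min_count 1 would keep): all samples with positive depth included.
make_filtered <- function(counts_list, alleles_list, samples, ...) {
  loci <- make_loci(counts_list, alleles_list, samples, ...)
  poolpg::filter_loci(loci, min_count = 1, subsample = 0, min_found = 1)
}

# Write VCF text lines (with standard header prepended) to a temp file.
write_vcf_text <- function(body_lines, samples,
                           format_defs = c(
  '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">')) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    format_defs,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body_lines
  ), path)
  path
}

# Brute-force diversity oracle: fraction of unordered read pairs that
# differ, by explicit pair enumeration.
brute_pi <- function(counts) {
  reads <- rep(seq_along(counts), counts)
  n <- length(reads)
  d <- outer(reads, reads, "!=")
  mean(d[upper.tri(d)])
}

# Independent single-pair FST oracles on two count vectors.
oracle_nei_fst <- function(ca, cb) {
  fa <- ca / sum(ca); fb <- cb / sum(cb)
  hs <- ((1 - sum(fa^2)) + (1 - sum(fb^2))) / 2
  ht <- 1 - sum(((fa + fb) / 2)^2)
  (ht - hs) / ht
}
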