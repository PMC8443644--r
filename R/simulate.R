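# Synthetic fixtures with known ground truth: a stop-free coding genome,
# Balding-Nichols population allele frequencies and binomial read counts.

FOURFOLD_PREFIXES <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")

#' Simulate a reference genome with annotated CDS genes
#'
#' Generates one random contig and `n_genes` equally spaced, non-overlapping
#' CDS gene models on a mix of strands. Gene bodies are built from uniform
#' draws over the 61 sense codons, so designed CDSs contain no internal stop
#' codons on the coding strand; intergenic sequence is uniform ACGT.
#'
#' @param genome_length Total contig length in bp (default 50000).
#' @param n_genes Number of genes (default 40).
#' @param gene_length Gene length in bp, rounded down to a codon multiple
#'   (default 900).
#' @param frac_minus Fraction of genes placed on the minus strand
#'   (default 0.5).
#' @param seed Optional integer seed.
#' @param contig Contig name (default `"contig_1"`).
#' @param code_id Translation table id (default `"11"`).
#' @return List with `genome` (named character vector, `genome_size`
#'   attribute) and `genes` (gene model tibble, phase 0).
#' @export
simulate_genome <- function(genome_length = 50000, n_genes = 40,
                            gene_length = 900, frac_minus = 0.5,
                            seed = NULL, contig = "contig_1",
                            code_id = "11") {
  local_seed(seed)
  gene_length <- (gene_length %/% 3L) * 3L
  slot <- genome_length %/% n_genes
  if (gene_length + 10L > slot) {
    abort(sprintf("%d genes of %d bp do not fit in %d bp",
                  n_genes, gene_length, genome_length))
  }
  code <- genetic_code(code_id)
  sense <- names(code)[code != "*"]

  seq_chars <- sample(BASES, genome_length, replace = TRUE)
  starts <- (seq_len(n_genes) - 1L) * slot + 6L
  ends <- starts + gene_length - 1L
  n_minus <- round(frac_minus * n_genes)
  strand <- rep("+", n_genes)
  if (n_minus > 0) {
    strand[unique(round(seq(1, n_genes, length.out = n_minus)))] <- "-"
  }
  for (i in seq_len(n_genes)) {
    cds <- paste(sample(sense, gene_length / 3L, replace = TRUE),
                 collapse = "")
    if (strand[i] == "-") cds <- revcomp(cds)
    seq_chars[starts[i]:ends[i]] <- strsplit(cds, "", fixed = TRUE)[[1]]
  }
  genome <- setNames(paste(seq_chars, collapse = ""), contig)
  attr(genome, "genome_size") <- as.integer(genome_length)
  genes <- tibble(
    gene_id = sprintf("gene_%03d", seq_len(n_genes)),
    contig = contig, start = starts, end = ends, strand = strand,
    phase = 0L
  )
  list(genome = genome, genes = genes)
}

# Coding-strand position p (1..gene_length) -> genomic coordinate.
coding_to_genomic <- function(gene, p) {
  if (gene$strand == "+") gene$start + gene$phase + p - 1L
  else gene$end - gene$phase - p + 1L
}

# Pick a variant site inside a gene of the requested consequence type and
# return list(pos, ref (genomic base), alt (genomic base)). "syn" uses the
# third position of a 4-fold degenerate codon; "nonsyn" any position whose
# substitution changes the amino acid.
pick_coding_site <- function(gene, genome, type, code) {
  nc <- (gene$end - gene$start + 1L - gene$phase) %/% 3L
  for (attempt in 1:50) {
    ci <- sample.int(nc, 1)
    cstart_coding <- 3L * (ci - 1L) + 1L
    cod_pos <- if (type == "syn") 3L else sample(1:2, 1)
    p <- cstart_coding + cod_pos - 1L
    gpos <- coding_to_genomic(gene, p)
    # reference codon on the coding strand
    cod <- paste(vapply(0:2, function(o) {
      g <- coding_to_genomic(gene, cstart_coding + o)
      b <- substring(genome[[gene$contig]], g, g)
      if (gene$strand == "-") complement_base(b) else b
    }, character(1)), collapse = "")
    if (type == "syn" && !(substr(cod, 1, 2) %in% FOURFOLD_PREFIXES)) next
    ref_coding <- substr(cod, cod_pos, cod_pos)
    cands <- setdiff(BASES, ref_coding)
    if (type == "nonsyn") {
      ok <- vapply(cands, function(b) {
        mut <- cod; substr(mut, cod_pos, cod_pos) <- b
        code[[mut]] != code[[cod]] && code[[mut]] != "*"
      }, logical(1))
      if (!any(ok)) next
      cands <- cands[ok]
    }
    alt_coding <- sample(cands, 1)
    flip <- function(b) if (gene$strand == "-") complement_base(b) else b
    return(list(pos = gpos, ref = flip(ref_coding), alt = flip(alt_coding)))
  }
  NULL
}

#' Simulate pooled allele counts for a multi-sample experiment
#'
#' Places variant sites over the simulated genome, draws an ancestral
#' frequency `p ~ Uniform(0.05, 0.95)` per site, population frequencies
#' from the Balding-Nichols model
#' `Beta(p (1 - F)/F, (1 - p)(1 - F)/F)` with `F = target_fst` (shared
#' `p` across populations when `target_fst = 0`), and per-sample alternate
#' read counts `Binomial(depth, f_pop)` with the reference taking the
#' remaining reads. Genic sites are placed as synonymous (third position
#' of 4-fold degenerate codons) or amino-acid-changing according to
#' `fraction_nonsynonymous`; genes named in `signal_genes` instead receive
#' `signal_loci` sites fixed for the reference in population 1 and for the
#' alternate in population 2 (gene-wise F_ST of 1). Sites where no sample
#' observes an alternate read are flagged unemitted and left out of the
#' returned loci.
#'
#' @param sim Genome simulation from [simulate_genome()].
#' @param n_samples Number of samples (default 4), assigned to populations
#'   round-robin.
#' @param n_populations Number of populations (default 2).
#' @param target_fst Balding-Nichols differentiation parameter in
#'   \[0, 1) (default 0.2).
#' @param snv_density Variant sites per bp (default 0.005).
#' @param depth Reads per sample per site (default 20).
#' @param fraction_nonsynonymous Fraction of genic sites placed as
#'   amino-acid-changing (default 0.5).
#' @param signal_genes Character vector of gene ids given fixed
#'   inter-population differences (default none).
#' @param signal_loci Fixed-difference sites per signal gene (default 5).
#' @param seed Optional integer seed.
#' @param code_id Translation table id (default `"11"`).
#' @return List: `loci` (long locus tibble as from [read_loci()]),
#'   `truth` (site table: `contig`, `pos`, `ref`, `alt`, `type`, `p_anc`,
#'   `f_pop<k>` columns, `emitted`), `metadata` (`sample`, `population`,
#'   `gradient`), `samples`.
#' @export
simulate_allele_counts <- function(sim, n_samples = 4, n_populations = 2,
                                   target_fst = 0.2, snv_density = 0.005,
                                   depth = 20,
                                   fraction_nonsynonymous = 0.5,
                                   signal_genes = NULL, signal_loci = 5,
                                   seed = NULL, code_id = "11") {
  if (target_fst < 0 || target_fst >= 1) {
    abort("`target_fst` must be in [0, 1)")
  }
  if (depth < 2) abort("`depth` must be at least 2")
  local_seed(seed)
  genome <- sim$genome
  genes <- sim$genes
  gsize <- genome_size(genome)
  contig <- names(genome)[1]
  code <- genetic_code(code_id)

  n_sites <- max(1L, round(snv_density * gsize))
  genic_bp <- sum(genes$end - genes$start + 1L)
  n_genic <- round(n_sites * genic_bp / gsize)

  sites <- list()
  used <- integer(0)
  add_site <- function(pos, ref, alt, type) {
    if (pos %in% used) return(FALSE)
    used <<- c(used, pos)
    sites[[length(sites) + 1L]] <<- tibble(contig = contig, pos = pos,
                                           ref = ref, alt = alt, type = type)
    TRUE
  }

  bg_genes <- genes %>% filter(!(.data$gene_id %in% signal_genes))
  for (i in seq_len(n_genic)) {
    type <- if (runif(1) < fraction_nonsynonymous) "nonsyn" else "syn"
    g <- bg_genes[sample.int(nrow(bg_genes), 1), ]
    s <- pick_coding_site(as.list(g), genome, type, code)
    if (!is.null(s)) add_site(s$pos, s$ref, s$alt, type)
  }
  n_inter <- n_sites - length(sites)
  genic_mask <- rep(FALSE, gsize)
  for (i in seq_len(nrow(genes))) {
    genic_mask[genes$start[i]:genes$end[i]] <- TRUE
  }
  inter_pos <- which(!genic_mask)
  if (n_inter > 0 && length(inter_pos) > 0) {
    draw <- sample(inter_pos, min(n_inter, length(inter_pos)))
    draw <- setdiff(draw, used)
    if (length(draw) > 0) {
      refs <- substring(genome[[contig]], draw, draw)
      alts <- vapply(refs, function(r) sample(setdiff(BASES, r), 1),
                     character(1), USE.NAMES = FALSE)
      used <- c(used, draw)
      sites[[length(sites) + 1L]] <- tibble(contig = contig, pos = draw,
                                            ref = refs, alt = alts,
                                            type = "intergenic")
    }
  }
  for (gid in signal_genes) {
    g <- genes %>% filter(.data$gene_id == gid)
    if (nrow(g) == 0) abort(sprintf("signal gene %s not in gene models", gid))
    for (i in seq_len(signal_loci)) {
      s <- pick_coding_site(as.list(g), genome, "nonsyn", code)
      if (!is.null(s)) add_site(s$pos, s$ref, s$alt, "signal")
    }
  }

  truth <- bind_rows(sites) %>% arrange(.data$pos)
  n_site <- nrow(truth)

  samples <- sprintf("sample_%02d", seq_len(n_samples))
  pop <- ((seq_len(n_samples) - 1L) %% n_populations) + 1L
  metadata <- tibble(sample = samples, population = pop,
                     gradient = pop + (seq_len(n_samples) - 1) * 1e-3)

  p_anc <- runif(n_site, 0.05, 0.95)
  fmat <- matrix(0, n_site, n_populations)   # alt-allele frequency per pop
  for (k in seq_len(n_populations)) {
    fmat[, k] <- if (target_fst == 0) p_anc else
      rbeta(n_site, p_anc * (1 - target_fst) / target_fst,
            (1 - p_anc) * (1 - target_fst) / target_fst)
  }
  is_signal <- truth$type == "signal"
  if (any(is_signal)) {
    fmat[is_signal, ] <- 0
    if (n_populations >= 2) fmat[is_signal, 2] <- 1
    p_anc[is_signal] <- NA_real_
  }

  alt_counts <- matrix(0L, n_site, n_samples)
  for (s in seq_len(n_samples)) {
    alt_counts[, s] <- rbinom(n_site, depth, fmat[, pop[s]])
  }
  emitted <- rowSums(alt_counts) > 0

  truth$p_anc <- p_anc
  for (k in seq_len(n_populations)) {
    truth[[sprintf("f_pop%d", k)]] <- fmat[, k]
  }
  truth$emitted <- emitted

  idx <- which(emitted)
  n_loc <- length(idx)
  loci <- tibble(
    locus_id = rep(seq_len(n_loc), each = 2L * n_samples),
    contig = contig,
    pos = rep(truth$pos[idx], each = 2L * n_samples),
    allele = as.vector(vapply(idx, function(i) {
      rep(c(truth$ref[i], truth$alt[i]), each = n_samples)
    }, character(2L * n_samples))),
    is_ref = rep(rep(c(TRUE, FALSE), each = n_samples), n_loc),
    sample = rep(rep(samples, 2L), n_loc),
    count = as.vector(vapply(idx, function(i) {
      as.integer(c(depth - alt_counts[i, ], alt_counts[i, ]))
    }, integer(2L * n_samples)))
  )
  loci <- set_loci_attrs(loci, samples)
  list(loci = loci, truth = truth, metadata = metadata, samples = samples)
}

#' Write a complete synthetic data set to disk
#'
#' Runs [simulate_genome()] and [simulate_allele_counts()] and writes
#' `genome.fasta`, `genes.gff`, `variants.vcf`, `metadata.tsv` and
#' `truth.tsv` under `dir` in standard formats readable by [read_genome()],
#' [read_gene_models()] and [read_loci()].
#'
#' @param dir Output directory (created if needed).
#' @param seed Optional integer seed covering both stages.
#' @param ... Passed on to [simulate_genome()] and
#'   [simulate_allele_counts()] (arguments are routed by name).
#' @return Invisibly, a list with the simulation objects and file paths.
#' @export
simulate_dataset <- function(dir, seed = NULL, ...) {
  dots <- list(...)
  local_seed(seed)
  gen_args <- dots[names(dots) %in% names(formals(simulate_genome))]
  cnt_args <- dots[names(dots) %in% names(formals(simulate_allele_counts))]
  sim <- do.call(simulate_genome, gen_args)
  counts <- do.call(simulate_allele_counts, c(list(sim = sim), cnt_args))

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    fasta = file.path(dir, "genome.fasta"),
    gff = file.path(dir, "genes.gff"),
    vcf = file.path(dir, "variants.vcf"),
    metadata = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_genome_fasta(sim$genome, paths$fasta)
  write_gene_gff(sim$genes, paths$gff)
  write_loci_vcf(counts$loci, paths$vcf,
                 contig_lengths = setNames(nchar(sim$genome),
                                           names(sim$genome)))
  readr::write_tsv(counts$metadata, paths$metadata)
  readr::write_tsv(counts$truth, paths$truth)
  invisible(c(sim, counts, list(paths = paths)))
}

#' Write a genome as FASTA
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unclass(genome)[seq_along(genome)])
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' @param genes Gene model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_gff <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand,
    type = "CDS",
    source = "poolpg",
    phase = genes$phase,
    ID = genes$gene_id
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
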