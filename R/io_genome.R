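#' Read a reference genome FASTA
#'
#' @param path Path to a (multi-)FASTA file.
#' @return Named character vector of uppercase contig sequences; names are
#'   the first whitespace-delimited token of each FASTA header. Attribute
#'   `genome_size` holds the summed contig length.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  attr(seqs, "genome_size") <- sum(nchar(seqs))
  seqs
}

#' Total genome size in bp
#'
#' @param genome Named character vector of contig sequences (from
#'   [read_genome()] or the simulator).
#' @return Integer total length.
#' @export
genome_size <- function(genome) {
  gs <- attr(genome, "genome_size")
  if (!is.null(gs)) return(as.integer(gs))
  as.integer(sum(nchar(genome)))
}

#' Read CDS gene models from a GFF3 file
#'
#' Extracts CDS features as gene models with 1-based inclusive coordinates,
#' strand and phase. The gene identifier is taken from the `ID` attribute,
#' then `locus_tag`, falling back to `contig_start_end`. Features on contigs
#' absent from the genome (when one is supplied) are dropped with a warning,
#' as are CDS with missing phase (treated as 0).
#'
#' @param path Path to a GFF3 file.
#' @param genome Optional genome from [read_genome()] used to validate
#'   contigs and coordinates.
#' @return Tibble of gene models: `gene_id`, `contig`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), `phase` (0/1/2).
#' @export
read_gene_models <- function(path, genome = NULL) {
  if (!file.exists(path)) abort(sprintf("GFF file not found: %s", path))
  gr <- rtracklayer::import(path)
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "CDS"]
  if (length(gr) == 0) {
    return(tibble(gene_id = character(), contig = character(),
                  start = integer(), end = integer(), strand = character(),
                  phase = integer()))
  }
  meta <- as.data.frame(S4Vectors::mcols(gr))
  pick_id <- function(col) {
    if (col %in% names(meta)) as.character(meta[[col]]) else
      rep(NA_character_, length(gr))
  }
  gene_id <- pick_id("ID")
  lt <- pick_id("locus_tag")
  gene_id <- ifelse(is.na(gene_id) | gene_id == "", lt, gene_id)

  genes <- tibble(
    gene_id = gene_id,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    phase = if ("phase" %in% names(meta)) as.integer(meta$phase) else
      rep(NA_integer_, length(gr))
  )
  genes$gene_id <- ifelse(
    is.na(genes$gene_id) | genes$gene_id == "",
    paste(genes$contig, genes$start, genes$end, sep = "_"), genes$gene_id)
  if (anyNA(genes$phase)) {
    warn(sprintf("%d CDS feature(s) with missing phase; assuming 0",
                 sum(is.na(genes$phase))))
    genes$phase[is.na(genes$phase)] <- 0L
  }
  if (any(genes$strand == "*")) {
    warn("CDS feature(s) with unknown strand treated as '+'")
    genes$strand[genes$strand == "*"] <- "+"
  }
  bad <- genes$start > genes$end | genes$start < 1
  if (any(bad)) {
    abort(sprintf("Malformed CDS coordinates for gene %s",
                  genes$gene_id[which(bad)[1]]))
  }
  if (!is.null(genome)) {
    unknown <- !(genes$contig %in% names(genome))
    if (any(unknown)) {
      warn(sprintf("Dropping %d CDS on contig(s) absent from genome: %s",
                   sum(unknown),
                   paste(unique(genes$contig[unknown]), collapse = ", ")))
      genes <- genes[!unknown, , drop = FALSE]
    }
    too_long <- genes$end > nchar(genome)[match(genes$contig, names(genome))]
    if (any(too_long)) {
      abort(sprintf("CDS %s extends past the end of contig %s",
                    genes$gene_id[which(too_long)[1]],
                    genes$contig[which(too_long)[1]]))
    }
  }
  if (anyDuplicated(genes$gene_id)) {
    genes$gene_id <- make.unique(genes$gene_id, sep = "_")
  }
  genes
}

#' Number of complete codons in a gene model
#'
#' Counts complete codons after trimming `phase` bases from the 5' end of
#' the CDS; a trailing partial codon is ignored (with the reader's warning).
#'
#' @param genes Gene model tibble.
#' @return Integer vector of codon counts, one per gene.
#' @export
n_codons <- function(genes) {
  (genes$end - genes$start + 1L - genes$phase) %/% 3L
}
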