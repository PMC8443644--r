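# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Acidic / alkaline residue sets used for proteome charge summaries.
ACIDIC_AA <- c("D", "E")
ALKALINE_AA <- c("K", "R", "H")

#' Genetic code lookup table
#'
#' Returns the codon -> amino-acid map for a translation table, as a named
#' character vector over the 64 codons (stop codons map to `"*"`).
#'
#' @param code_id Translation table identifier as understood by
#'   [Biostrings::getGeneticCode()]; default `"11"` (bacteria/archaea).
#'   Tables 1 and 11 translate all codons identically; they differ only in
#'   initiation codons, which play no role here.
#' @return Named character vector of length 64.
#' @export
genetic_code <- function(code_id = "11") {
  Biostrings::getGeneticCode(code_id)
}

translate_codon <- function(codon, code) {
  unname(code[codon])
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(unname(COMPLEMENT[strsplit(s, "", fixed = TRUE)[[1]]])),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

complement_base <- function(x) unname(COMPLEMENT[x])

# Fixed-point serialization used by all output tables.
format_num <- function(x, digits = 6L) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_loci_tbl <- function(loci, arg = "loci", need_id = TRUE) {
  req <- c(if (need_id) "locus_id", "contig", "pos", "allele", "is_ref",
           "sample", "count")
  missing_cols <- setdiff(req, names(loci))
  if (length(missing_cols) > 0) {
    abort(sprintf("`%s` is missing column(s): %s", arg,
                  paste(missing_cols, collapse = ", ")))
  }
  invisible(loci)
}

sample_ids <- function(loci) {
  attr(loci, "samples") %||% unique(loci$sample)
}

set_loci_attrs <- function(loci, samples, class_extra = NULL) {
  attr(loci, "samples") <- samples
  if (!is.null(class_extra)) {
    class(loci) <- unique(c(class_extra, class(loci)))
  }
  loci
}
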