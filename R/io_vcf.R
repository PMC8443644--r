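#' Read a multi-sample VCF of pooled variant calls
#'
#' Parses a VCF file and extracts per-sample allele observation counts for
#' every record. Counts are taken from the per-sample `AD` field (allelic
#' depths, reference first) when present, falling back to `RO`/`AO`
#' (reference/alternate observation counts, as written by Freebayes in
#' pooled-continuous mode). A sample with missing data at a record gets an
#' all-zero count vector there, so it is excluded by downstream minimum-count
#' filtering rather than silently imputed.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param samples Optional character vector of sample names to keep, in the
#'   desired output order (the `--sample_file` idea). Default: all samples in
#'   VCF header order.
#' @param count_fields Preference order of per-sample count sources. Supported
#'   values: `"AD"` and `"RO/AO"`.
#' @return A tibble of raw variant records with one row per VCF data line:
#'   `contig`, `pos` (1-based), `ref`, `alt` (list of alternate allele
#'   strings), `counts` (list of integer matrices, samples x alleles, allele
#'   columns ordered reference first), `missing_samples` (integer, number of
#'   samples with no usable counts at the record). Attribute `samples` holds
#'   the ordered sample ids.
#' @seealso [split_haplotypes()], [merge_colocated()], [read_loci()]
#' @export
read_vcf <- function(path, samples = NULL, count_fields = c("AD", "RO/AO")) {
  if (!file.exists(path)) {
    abort(sprintf("VCF file not found: %s", path))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  all_samples <- colnames(vcf@gt)[-1]
  if (length(all_samples) == 0) {
    abort("VCF contains no sample columns")
  }
  if (is.null(samples)) {
    samples <- all_samples
  } else {
    absent <- setdiff(samples, all_samples)
    if (length(absent) > 0) {
      abort(sprintf("Requested sample(s) absent from VCF: %s",
                    paste(absent, collapse = ", ")))
    }
  }

  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))   # single-record VCF
  n_rec <- nrow(fix)
  if (n_rec == 0) {
    out <- tibble(contig = character(), pos = integer(), ref = character(),
                  alt = list(), counts = list(), missing_samples = integer())
    return(set_loci_attrs(out, samples))
  }

  extract_field <- function(el) {
    m <- tryCatch(vcfR::extract.gt(vcf, element = el),
                  error = function(e) NULL)
    if (is.null(m)) return(NULL)
    m[, samples, drop = FALSE]
  }
  field_mats <- list()
  for (f in count_fields) {
    if (f == "AD") {
      field_mats$AD <- extract_field("AD")
    } else if (f == "RO/AO") {
      field_mats$RO <- extract_field("RO")
      field_mats$AO <- extract_field("AO")
    }
  }

  alt_list <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",",
                       fixed = TRUE)
  n_s <- length(samples)

  parse_counts <- function(i, n_alleles) {
    # returns list(mat = n_s x n_alleles integer matrix, missing = int)
    mat <- matrix(0L, nrow = n_s, ncol = n_alleles,
                  dimnames = list(samples, NULL))
    miss <- 0L
    got_any <- FALSE
    for (s in seq_len(n_s)) {
      v <- NULL
      if (!is.null(field_mats$AD)) {
        ad <- field_mats$AD[i, s]
        if (!is.na(ad) && ad != ".") {
          v <- suppressWarnings(as.integer(strsplit(ad, ",", fixed = TRUE)[[1]]))
        }
      }
      if (is.null(v) && !is.null(field_mats$RO) && !is.null(field_mats$AO)) {
        ro <- field_mats$RO[i, s]
        ao <- field_mats$AO[i, s]
        if (!is.na(ro) && !is.na(ao) && ro != "." && ao != ".") {
          v <- suppressWarnings(as.integer(c(
            ro, strsplit(ao, ",", fixed = TRUE)[[1]])))
        }
      }
      if (is.null(v) || anyNA(v) || length(v) != n_alleles) {
        miss <- miss + 1L
      } else {
        mat[s, ] <- v
        got_any <- TRUE
      }
    }
    list(mat = mat, missing = miss, usable = got_any)
  }

  counts <- vector("list", n_rec)
  missing_samples <- integer(n_rec)
  for (i in seq_len(n_rec)) {
    k <- 1L + length(alt_list[[i]])
    pc <- parse_counts(i, k)
    if (!pc$usable) {
      abort(sprintf(
        "No usable allele-count field (%s) for any sample at %s:%s",
        paste(count_fields, collapse = " or "),
        fix[i, "CHROM"], fix[i, "POS"]))
    }
    counts[[i]] <- pc$mat
    missing_samples[i] <- pc$missing
  }

  out <- tibble(
    contig = unname(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = unname(fix[, "REF"]),
    alt = alt_list,
    counts = counts,
    missing_samples = missing_samples
  )
  set_loci_attrs(out, samples)
}

#' Split haplotype/MNP records into per-position single-nucleotide loci
#'
#' Variant callers run in haplotype mode can emit multi-nucleotide REF/ALT
#' pairs. Each equal-length REF/ALT pair is compared column-wise and one
#' locus is emitted per position where any alternate allele differs from the
#' reference; read counts are inherited from the parent record (reads
#' supporting an allele support its base at every position). Alternate
#' alleles whose length differs from REF (indels) and alleles containing
#' non-ACGT characters are skipped and tallied in the skip log, never fatal.
#'
#' @param records Raw record tibble from [read_vcf()].
#' @return A long locus tibble with one row per (position, allele, sample):
#'   columns `contig`, `pos`, `allele` (single base), `is_ref`, `sample`,
#'   `count`. Attributes: `samples` (ordered ids) and `skip_log` (named
#'   integer vector: `alt_skipped`, `records_skipped`).
#' @export
split_haplotypes <- function(records) {
  samples <- sample_ids(records)
  n_s <- length(samples)
  alt_skipped <- 0L
  records_skipped <- 0L

  # Emitted loci accumulate as parallel lists, assembled vectorized at the end.
  e_contig <- list(); e_pos <- list(); e_alleles <- list(); e_counts <- list()

  for (i in seq_len(nrow(records))) {
    ref <- records$ref[i]
    alts <- records$alt[[i]]
    cnt <- records$counts[[i]]
    keep <- nchar(alts) == nchar(ref) & !grepl("[^ACGT]", alts)
    if (grepl("[^ACGT]", ref)) keep[] <- FALSE
    alt_skipped <- alt_skipped + sum(!keep)
    if (!any(keep)) {
      records_skipped <- records_skipped + 1L
      next
    }
    alts <- alts[keep]
    cnt <- cnt[, c(TRUE, keep), drop = FALSE]   # ref column always first

    if (nchar(ref) == 1L) {
      e_contig[[length(e_contig) + 1L]] <- records$contig[i]
      e_pos[[length(e_pos) + 1L]] <- records$pos[i]
      e_alleles[[length(e_alleles) + 1L]] <- c(ref, alts)
      e_counts[[length(e_counts) + 1L]] <- cnt
      next
    }

    ref_chars <- strsplit(ref, "", fixed = TRUE)[[1]]
    alt_chars <- matrix(unlist(strsplit(alts, "", fixed = TRUE)),
                        nrow = length(alts), byrow = TRUE)
    for (j in seq_along(ref_chars)) {
      col <- c(ref_chars[j], alt_chars[, j])
      if (all(col[-1] == col[1])) next   # no alt differs here
      states <- unique(col)              # ref base first by construction
      cmat <- matrix(0L, nrow = n_s, ncol = length(states),
                     dimnames = list(samples, NULL))
      for (k in seq_along(states)) {
        cmat[, k] <- rowSums(cnt[, col == states[k], drop = FALSE])
      }
      e_contig[[length(e_contig) + 1L]] <- records$contig[i]
      e_pos[[length(e_pos) + 1L]] <- records$pos[i] + j - 1L
      e_alleles[[length(e_alleles) + 1L]] <- states
      e_counts[[length(e_counts) + 1L]] <- cmat
    }
  }

  n_loc <- length(e_contig)
  if (n_loc == 0) {
    out <- tibble(contig = character(), pos = integer(), allele = character(),
                  is_ref = logical(), sample = character(), count = integer())
  } else {
    k_i <- lengths(e_alleles)
    rows_i <- k_i * n_s
    out <- tibble(
      contig = rep(unlist(e_contig), rows_i),
      pos = rep(as.integer(unlist(e_pos)), rows_i),
      # counts matrices are column-major (sample fastest), so allele repeats
      # each n_s times and sample cycles
      allele = unlist(lapply(e_alleles, rep, each = n_s)),
      is_ref = unlist(lapply(k_i, function(k) {
        rep(c(TRUE, rep(FALSE, k - 1L)), each = n_s)
      })),
      sample = unlist(lapply(k_i, function(k) rep(samples, k))),
      count = as.integer(unlist(lapply(e_counts, as.vector)))
    )
  }
  out <- set_loci_attrs(out, samples)
  attr(out, "skip_log") <- c(alt_skipped = alt_skipped,
                             records_skipped = records_skipped)
  out
}

#' Merge loci that decompose to the same genomic position
#'
#' Two VCF rows (e.g. a plain SNV and an overlapping haplotype record) can
#' decompose to the same position. Their allele lists are unioned; alternate
#' allele counts are summed while the reference count is taken as the maximum
#' across the merged rows, because the reference-supporting reads are the
#' same physical reads reported once per row. Conflicting reference states at
#' one position are a format error.
#'
#' @param loci Long locus tibble from [split_haplotypes()].
#' @return Long locus tibble sorted by (contig, pos) with unique positions
#'   and a dense integer `locus_id` column added.
#' @export
merge_colocated <- function(loci) {
  assert_loci_tbl(loci, need_id = FALSE)
  samples <- sample_ids(loci)
  skip_log <- attr(loci, "skip_log")

  conflict <- loci %>%
    filter(.data$is_ref) %>%
    distinct(.data$contig, .data$pos, .data$allele) %>%
    count(.data$contig, .data$pos) %>%
    filter(.data$n > 1)
  if (nrow(conflict) > 0) {
    abort(sprintf("Conflicting reference allele at %s:%d",
                  conflict$contig[1], conflict$pos[1]))
  }

  out <- loci %>%
    group_by(.data$contig, .data$pos, .data$sample, .data$allele,
             .data$is_ref) %>%
    summarise(count = if (first(.data$is_ref)) max(.data$count)
              else sum(.data$count), .groups = "drop") %>%
    arrange(.data$contig, .data$pos, dplyr::desc(.data$is_ref),
            .data$allele, match(.data$sample, samples))

  key <- paste(out$contig, formatC(out$pos, width = 12, flag = "0"))
  out$locus_id <- match(key, unique(key[order(out$contig, out$pos)]))
  out <- out %>%
    select("locus_id", "contig", "pos", "allele", "is_ref", "sample", "count")
  out <- set_loci_attrs(out, samples)
  attr(out, "skip_log") <- skip_log
  out
}

#' Read a VCF straight into the merged long locus table
#'
#' Convenience chain of [read_vcf()], [split_haplotypes()] and
#' [merge_colocated()].
#'
#' @inheritParams read_vcf
#' @return Long locus tibble (see [merge_colocated()]).
#' @export
read_loci <- function(path, samples = NULL, count_fields = c("AD", "RO/AO")) {
  read_vcf(path, samples = samples, count_fields = count_fields) %>%
    split_haplotypes() %>%
    merge_colocated()
}

#' Write a long locus table as a minimal multi-sample VCF
#'
#' Serializes loci as VCF 4.2 with a single per-sample `AD` (allelic depth)
#' field, reference allele first. Used by the synthetic-data generator and
#' for round-trip testing; [read_loci()] reproduces the table exactly.
#'
#' @param loci Long locus tibble (with or without `locus_id`).
#' @param path Output file path.
#' @param contig_lengths Optional named integer vector for `##contig` header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_loci_vcf <- function(loci, path, contig_lengths = NULL) {
  assert_loci_tbl(loci, need_id = FALSE)
  samples <- sample_ids(loci)

  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=poolpg",
    if (!is.null(contig_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              as.integer(contig_lengths))
    },
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths (ref first)\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )

  per_locus <- loci %>%
    arrange(.data$contig, .data$pos, dplyr::desc(.data$is_ref), .data$allele)
  keys <- paste(per_locus$contig, per_locus$pos)
  blocks <- split(per_locus, factor(keys, levels = unique(keys)))
  lines <- vapply(blocks, function(b) {
    alleles <- unique(b$allele[order(!b$is_ref, b$allele)])
    ref <- alleles[1]
    alt <- paste(alleles[-1], collapse = ",")
    ad <- vapply(samples, function(s) {
      cc <- b$count[match(paste(s, alleles), paste(b$sample, b$allele))]
      cc[is.na(cc)] <- 0L
      paste(cc, collapse = ",")
    }, character(1))
    paste(c(b$contig[1], b$pos[1], ".", ref, alt, ".", "PASS", ".", "AD", ad),
          collapse = "\t")
  }, character(1))

  writeLines(c(hdr, lines), path)
  invisible(path)
}
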