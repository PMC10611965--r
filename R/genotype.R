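#' Extract raw indels from an alignment
#'
#' One raw indel per insertion/deletion operation in the alignment:
#' inserted bases are taken from the (oriented) read, deleted bases from
#' the region. Substitution (mismatch) operations are ignored -- point
#' errors introduced by PCR never enter a genotype.
#'
#' @param aln A `read_alignment` that passed [alignment_passes_filter()].
#' @param region The [ref_region()] the read was aligned to.
#' @return A list of raw indels, each a list with `kind`
#'   (`"insertion"`/`"deletion"`), `offset` (1-based region offset: first
#'   deleted base for deletions; the base after which the insertion occurs
#'   for insertions, 0 for an insertion before the region) and `seq`
#'   (inserted or deleted bases).
#' @export
extract_indels <- function(aln, region) {
  ops <- aln$ops
  out <- list()
  for (k in seq_len(nrow(ops))) {
    op <- ops[k, ]
    if (op$kind == "insertion") {
      out[[length(out) + 1L]] <- list(
        kind = "insertion", offset = op$region_off,
        seq = substr(aln$read_oriented, op$read_off, op$read_off + op$length - 1L))
    } else if (op$kind == "deletion") {
      out[[length(out) + 1L]] <- list(
        kind = "deletion", offset = op$region_off,
        seq = substr(region$sequence, op$region_off, op$region_off + op$length - 1L))
    }
  }
  out
}

#' Left-normalize a raw indel into a VCF record
#'
#' Shifts the indel left while the base preceding the event equals its last
#' base (standard VCF left-alignment within a repeat context), then anchors
#' it on the base before the event, producing a CHR-POS-REF-ALT record with
#' a genomic POS. An indel reaching the region's left boundary with no
#' anchor base available is emitted with a right anchor and flagged. The
#' operation is idempotent on already-normalized events.
#'
#' @param indel A raw indel as returned by [extract_indels()].
#' @param region The [ref_region()].
#' @return A one-row data frame (class `indel_variant`) with columns
#'   `chrom`, `pos`, `ref`, `alt`, `kind`, `length`, `right_anchored`.
#' @export
left_normalize <- function(indel, region) {
  S <- region$sequence
  L <- nchar(indel$seq)
  if (L < 1L) stop("indel has empty sequence")
  if (indel$kind == "deletion") {
    a <- indel$offset; b <- a + L - 1L
    if (a < 1L || b > nchar(S)) stop("deletion outside region")
    while (a > 1L && substr(S, b, b) == substr(S, a - 1L, a - 1L)) {
      a <- a - 1L; b <- b - 1L
    }
    if (a > 1L) {
      pos_off <- a - 1L
      ref <- substr(S, a - 1L, b)
      alt <- substr(S, a - 1L, a - 1L)
      right <- FALSE
    } else {
      if (b + 1L > nchar(S)) stop("deletion spans the whole region; no anchor base")
      pos_off <- 1L
      ref <- substr(S, 1L, b + 1L)
      alt <- substr(S, b + 1L, b + 1L)
      right <- TRUE
    }
  } else if (indel$kind == "insertion") {
    a <- indel$offset
    ins <- indel$seq
    if (a < 0L || a > nchar(S)) stop("insertion point outside region")
    while (a >= 1L && substr(S, a, a) == substr(ins, L, L)) {
      ins <- paste0(substr(S, a, a), substr(ins, 1L, L - 1L))
      a <- a - 1L
    }
    if (a >= 1L) {
      pos_off <- a
      ref <- substr(S, a, a)
      alt <- paste0(ref, ins)
      right <- FALSE
    } else {
      pos_off <- 1L
      ref <- substr(S, 1L, 1L)
      alt <- paste0(ins, ref)
      right <- TRUE
    }
  } else stop(sprintf("unknown indel kind '%s'", indel$kind))
  structure(data.frame(chrom = region$chrom,
                       pos = region$start + pos_off - 1L,
                       ref = ref, alt = alt, kind = indel$kind,
                       length = L, right_anchored = right,
                       stringsAsFactors = FALSE),
            class = c("indel_variant", "data.frame"))
}

# convert a normalized variant row back to raw-indel form (internal; used
# to verify idempotence and by the simulator)
variant_to_raw <- function(v, region) {
  off <- v$pos - region$start + 1L
  if (v$kind == "deletion") {
    if (!v$right_anchored)
      list(kind = "deletion", offset = off + 1L,
           seq = substr(v$ref, 2L, nchar(v$ref)))
    else
      list(kind = "deletion", offset = off,
           seq = substr(v$ref, 1L, nchar(v$ref) - 1L))
  } else {
    if (!v$right_anchored)
      list(kind = "insertion", offset = off,
           seq = substr(v$alt, 2L, nchar(v$alt)))
    else
      list(kind = "insertion", offset = off - 1L,
           seq = substr(v$alt, 1L, nchar(v$alt) - 1L))
  }
}

empty_variants <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), kind = character(), length = integer(),
             right_anchored = logical(), stringsAsFactors = FALSE)
}

#' Genotype signature of an aligned read
#'
#' The complete, ordered set of left-normalized indels carried by one read;
#' the empty set is the wild-type signature. Two reads from the same edited
#' allele that differ only by substitution-level sequencing/PCR errors
#' yield the same signature. Overlapping normalized indels on one read are
#' kept verbatim and flagged as complex.
#'
#' @param aln A filtered `read_alignment`.
#' @param region The [ref_region()].
#' @return An object of class `genotype_signature`: list with `variants`
#'   (data frame sorted by `pos`) and `complex` flag.
#' @export
signature_of_read <- function(aln, region) {
  raws <- extract_indels(aln, region)
  if (length(raws) == 0L) {
    return(structure(list(variants = empty_variants(), complex = FALSE),
                     class = "genotype_signature"))
  }
  vars <- do.call(rbind, lapply(raws, left_normalize, region = region))
  vars <- vars[order(vars$pos, vars$ref, vars$alt), , drop = FALSE]
  rownames(vars) <- NULL
  # overlap check on the reference footprint [pos, pos + nchar(ref) - 1]
  complex <- FALSE
  if (nrow(vars) > 1L) {
    ends <- vars$pos + nchar(vars$ref) - 1L
    complex <- any(vars$pos[-1L] <= ends[-nrow(vars)])
  }
  structure(list(variants = vars, complex = complex),
            class = "genotype_signature")
}

#' Canonical text key of a genotype signature
#'
#' Semicolon-joined `CHR-POS-REF-ALT` of the signature's variants, or
#' `"WT"` for the empty (wild-type) signature.
#'
#' @param sig A `genotype_signature`, or its `variants` data frame.
#' @return A single string.
#' @export
signature_key <- function(sig) {
  vars <- if (inherits(sig, "genotype_signature")) sig$variants else sig
  if (is.null(vars) || nrow(vars) == 0L) return("WT")
  paste(paste(vars$chrom, vars$pos, vars$ref, vars$alt, sep = "-"),
        collapse = ";")
}

#' Call the genotypes of one sample
#'
#' Aligns each retained unique read to the region, applies the alignment
#' quality filter, computes its indel signature, and sums the counts of
#' unique reads sharing a signature into one genotype call. Proportions use
#' the sample's total processed reads as the denominator; a call is major
#' when its proportion is `>= major_threshold` (inclusive). The wild-type
#' (empty) signature is a callable genotype like any other, so
#' insufficiently edited clones are visible.
#'
#' @param uniques_retained Data frame from [apply_cutoff()].
#' @param n_total_reads Total processed reads of the sample (the read-count
#'   denominator; must be `>=` the retained count sum).
#' @param region A [ref_region()].
#' @param params An [align_params()].
#' @param major_threshold Major-genotype threshold as a fraction of total
#'   reads (default 0.01, i.e. 1%).
#' @param sample_id Sample label carried into the report.
#' @param cutoff The read-count cutoff that produced `uniques_retained`
#'   (recorded in the report).
#' @param aln_cache Optional environment caching signature lookups by read
#'   sequence across calls (used by [cutoff_sweep()]).
#' @return An object of class `sample_report`: list with `sample_id`,
#'   `n_total_reads`, `n_unique_reads`, `cutoff`, `n_retained_reads`,
#'   `n_filtered_reads` (retained reads whose alignment failed the
#'   filter), `calls` (data frame: signature key, n_variants, n_supporting,
#'   proportion, major, complex, sorted by descending proportion),
#'   `signatures` (named list of variant data frames keyed by signature),
#'   `read_contribution`.
#' @export
call_genotypes <- function(uniques_retained, n_total_reads, region,
                           params = align_params(), major_threshold = 0.01,
                           sample_id = "sample", cutoff = NA_integer_,
                           aln_cache = NULL) {
  stopifnot(inherits(region, "ref_region"))
  if (major_threshold <= 0 || major_threshold > 1)
    stop("major_threshold must lie in (0, 1]")
  n_total_reads <- as.integer(n_total_reads)
  n_retained <- sum(uniques_retained$count)
  if (n_total_reads < n_retained)
    stop("n_total_reads is smaller than the retained read count")

  counts <- new.env(parent = emptyenv())
  sigs <- new.env(parent = emptyenv())
  cplx <- new.env(parent = emptyenv())
  n_filtered <- 0L
  if (nrow(uniques_retained) == 0L)
    warning(sprintf("sample '%s': no reads retained for genotyping", sample_id))

  for (k in seq_len(nrow(uniques_retained))) {
    sq <- uniques_retained$sequence[k]
    ct <- uniques_retained$count[k]
    entry <- if (!is.null(aln_cache)) aln_cache[[sq]] else NULL
    if (is.null(entry)) {
      aln <- align_read(sq, region, params)
      if (!alignment_passes_filter(aln, params)) {
        entry <- list(key = NA_character_)
      } else {
        sig <- signature_of_read(aln, region)
        entry <- list(key = signature_key(sig), variants = sig$variants,
                      complex = sig$complex)
      }
      if (!is.null(aln_cache)) aln_cache[[sq]] <- entry
    }
    if (is.na(entry$key)) { n_filtered <- n_filtered + ct; next }
    key <- entry$key
    counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + ct
    if (is.null(sigs[[key]])) {
      sigs[[key]] <- entry$variants
      cplx[[key]] <- entry$complex
    }
  }

  keys <- ls(counts)
  if (length(keys)) {
    n_supporting <- vapply(keys, function(k) counts[[k]], integer(1L))
    proportion <- n_supporting / n_total_reads
    calls <- data.frame(
      signature = keys,
      n_variants = vapply(keys, function(k) nrow(sigs[[k]]), integer(1L)),
      n_supporting = n_supporting,
      proportion = proportion,
      major = n_supporting >= n_total_reads * major_threshold - 1e-9,
      complex = vapply(keys, function(k) cplx[[k]], logical(1L)),
      stringsAsFactors = FALSE)
    calls <- calls[order(-calls$proportion, calls$signature), , drop = FALSE]
    rownames(calls) <- NULL
  } else {
    calls <- data.frame(signature = character(), n_variants = integer(),
                        n_supporting = integer(), proportion = numeric(),
                        major = logical(), complex = logical(),
                        stringsAsFactors = FALSE)
  }
  report <- structure(list(
    sample_id = sample_id,
    n_total_reads = n_total_reads,
    n_unique_reads = NA_integer_,
    cutoff = cutoff,
    n_retained_reads = n_retained,
    n_filtered_reads = n_filtered,
    calls = calls,
    signatures = mget(keys, envir = sigs),
    major_threshold = major_threshold,
    region = region
  ), class = "sample_report")
  report$read_contribution <- read_contribution(report)
  report
}

#' Read contribution to major genotypes
#'
#' The number of reads supporting all major genotypes divided by the number
#' of reads retained for genotyping (0 when no reads were retained). Values
#' near 1 indicate that essentially every retained read belongs to a major
#' genotype.
#'
#' @param report A `sample_report` from [call_genotypes()].
#' @return A fraction in `[0, 1]`.
#' @export
read_contribution <- function(report) {
  if (report$n_retained_reads == 0L) return(0)
  sum(report$calls$n_supporting[report$calls$major]) / report$n_retained_reads
}

#' @export
print.sample_report <- function(x, ...) {
  cat(sprintf("<sample_report> %s: %d reads, %s unique, cutoff %s -> %d retained\n",
              x$sample_id, x$n_total_reads,
              ifelse(is.na(x$n_unique_reads), "?", x$n_unique_reads),
              ifelse(is.na(x$cutoff), "?", x$cutoff), x$n_retained_reads))
  nmaj <- sum(x$calls$major)
  cat(sprintf("  %d genotype(s), %d major (>= %.2g%% of total reads); read contribution %.3f\n",
              nrow(x$calls), nmaj, 100 * x$major_threshold, x$read_contribution))
  if (nmaj > 0) {
    maj <- x$calls[x$calls$major, c("signature", "n_supporting", "proportion")]
    maj$proportion <- sprintf("%.1f%%", 100 * maj$proportion)
    print(maj, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.sample_report <- function(object, ...) {
  print(object)
  if (any(!object$calls$major)) {
    cat("minor genotypes:\n")
    print(object$calls[!object$calls$major, , drop = FALSE], row.names = FALSE)
  }
  invisible(object)
}
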