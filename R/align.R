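#' Alignment parameters
#'
#' Scoring and filtering parameters for the affine-gap local aligner. An
#' opened gap of length L costs `gap_open + L * gap_extend`. The defaults
#' (match +2, mismatch -3, open 5, extend 2) are the classic nucleotide
#' scoring used by megablast-style aligners.
#'
#' @param match Positive match reward (default 2).
#' @param mismatch Negative mismatch penalty (default -3).
#' @param gap_open Non-negative gap opening penalty (default 5).
#' @param gap_extend Non-negative per-base gap extension penalty (default 2).
#' @param min_aligned_frac Minimum fraction of the read inside the local
#'   alignment for the read to be genotyped (default 0.5; permissive enough
#'   to keep large-deletion alleles).
#' @param min_identity Minimum fraction of aligned (non-gap) columns that
#'   match (default 0.7).
#' @return An object of class `align_params`.
#' @export
align_params <- function(match = 2L, mismatch = -3L, gap_open = 5L,
                         gap_extend = 2L, min_aligned_frac = 0.5,
                         min_identity = 0.7) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  if (is.na(match) || match <= 0L) stop("match score must be positive")
  if (is.na(mismatch) || mismatch >= 0L) stop("mismatch score must be negative")
  if (is.na(gap_open) || gap_open < 0L) stop("gap_open must be non-negative")
  if (is.na(gap_extend) || gap_extend < 0L) stop("gap_extend must be non-negative")
  if (min_aligned_frac < 0 || min_aligned_frac > 1)
    stop("min_aligned_frac must lie in [0,1]")
  if (min_identity < 0 || min_identity > 1)
    stop("min_identity must lie in [0,1]")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_aligned_frac = min_aligned_frac,
                 min_identity = min_identity),
            class = "align_params")
}

op_kind_labels <- c("match", "mismatch", "insertion", "deletion")

as_ops_df <- function(ops) {
  out <- data.frame(kind = op_kind_labels[ops[, "kind"]],
                    length = ops[, "length"],
                    read_off = ops[, "read_off"],
                    region_off = ops[, "region_off"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Align one read to the reference region
#'
#' Optimal local alignment (Smith-Waterman with affine gaps) of the read
#' against the region, tried in both the given orientation and its reverse
#' complement; the higher-scoring orientation is returned (ties keep the
#' forward strand). Among equal-scoring optimal alignments the traceback
#' prefers fewer gap openings, then defers gaps leftward (diagonal moves
#' preferred at ties); residual placement ambiguity is canonicalized by
#' downstream left-normalization. A read that aligns nowhere returns score
#' 0 with no operations.
#'
#' @param read Read sequence (non-empty DNA text).
#' @param region A [ref_region()].
#' @param params An [align_params()].
#' @return An object of class `read_alignment`: list with `read_input`,
#'   `read_oriented` (the sequence as aligned; reverse complement of the
#'   input when `strand == "-"`), `strand`, `score`, `ops` (data frame of
#'   merged operations: kind, length, read_off, region_off; offsets 1-based
#'   in the oriented read / region; for insertions `region_off` is the
#'   region base immediately left of the insertion, for deletions
#'   `read_off` is the read base immediately left), `read_span`,
#'   `region_span` (1-based inclusive), `identity` (matches / aligned
#'   columns; 0 when empty), `aligned_frac` (read bases inside the
#'   alignment / read length), `n_gap_opens`.
#' @export
align_read <- function(read, region, params = align_params()) {
  stopifnot(inherits(region, "ref_region"))
  read <- toupper(as.character(read))
  if (length(read) != 1L || !nzchar(read)) stop("read must be one non-empty sequence")
  fwd <- cpp_sw_align(read, region$sequence, params$match, params$mismatch,
                      params$gap_open, params$gap_extend)
  rc <- revcomp(read)
  rev <- cpp_sw_align(rc, region$sequence, params$match, params$mismatch,
                      params$gap_open, params$gap_extend)
  if (rev$score > fwd$score) {
    res <- rev; strand <- "-"; oriented <- rc
  } else {
    res <- fwd; strand <- "+"; oriented <- read
  }
  n_aln_cols <- res$n_match + res$n_mismatch
  aligned_read_bases <- if (res$score > 0)
    res$read_span[2L] - res$read_span[1L] + 1L else 0L
  structure(list(
    read_input = read,
    read_oriented = oriented,
    strand = strand,
    score = res$score,
    ops = as_ops_df(res$ops),
    read_span = res$read_span,
    region_span = res$region_span,
    identity = if (n_aln_cols > 0) res$n_match / n_aln_cols else 0,
    aligned_frac = aligned_read_bases / nchar(read),
    n_gap_opens = res$n_gap_opens
  ), class = "read_alignment")
}

#' @export
print.read_alignment <- function(x, ...) {
  cat(sprintf("<read_alignment> strand %s, score %d, region %d-%d, identity %.3f, aligned_frac %.3f\n",
              x$strand, x$score, x$region_span[1L], x$region_span[2L],
              x$identity, x$aligned_frac))
  if (nrow(x$ops)) print(x$ops)
  invisible(x)
}

#' Alignment quality filter
#'
#' A read is genotyped only when enough of it aligns
#' (`aligned_frac >= min_aligned_frac`) and the aligned columns are similar
#' enough (`identity >= min_identity`). Failing reads contribute no
#' genotype but remain in the sample's total-read denominator.
#'
#' @param aln A `read_alignment` from [align_read()].
#' @param params An [align_params()].
#' @return Logical flag.
#' @export
alignment_passes_filter <- function(aln, params = align_params()) {
  aln$aligned_frac >= params$min_aligned_frac &&
    aln$identity >= params$min_identity
}

# recompute the alignment score from the operation list (consistency check)
score_from_ops <- function(aln, params) {
  if (nrow(aln$ops) == 0L) return(0L)
  s <- 0L
  for (k in seq_len(nrow(aln$ops))) {
    op <- aln$ops[k, ]
    s <- s + switch(op$kind,
      match = params$match * op$length,
      mismatch = params$mismatch * op$length,
      insertion = -(params$gap_open + params$gap_extend * op$length),
      deletion = -(params$gap_open + params$gap_extend * op$length))
  }
  s
}
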