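#' Read a FASTQ file
#'
#' Reads a (possibly gzip-compressed) 4-line-per-record FASTQ file into a
#' data frame of reads. `N` bases are preserved; sequences are uppercased.
#'
#' @param path FASTQ or FASTQ.gz file.
#' @return A data frame with columns `read_id`, `sequence`, `quality`
#'   (Phred+33 text; `NA` allowed for synthetic inputs with missing quality).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTQ file not found: %s", path))
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L)
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  if (length(lines) %% 4L != 0L)
    stop(sprintf("truncated FASTQ record at record %d in %s",
                 length(lines) %/% 4L + 1L, path))
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  seq <- toupper(lines[seq(2L, length(lines), by = 4L)])
  plus <- lines[seq(3L, length(lines), by = 4L)]
  qual <- lines[seq(4L, length(lines), by = 4L)]
  bad <- which(substr(hdr, 1L, 1L) != "@" | substr(plus, 1L, 1L) != "+")
  if (length(bad))
    stop(sprintf("malformed FASTQ record %d in %s", bad[1L], path))
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    stop(sprintf("sequence/quality length mismatch at record %d in %s",
                 bad[1L], path))
  bad <- which(!nzchar(seq) | grepl("[^ACGTN]", seq))
  if (length(bad))
    stop(sprintf("invalid sequence at record %d in %s", bad[1L], path))
  ids <- sub("^@", "", hdr)
  ids <- vapply(strsplit(ids, "[[:space:]]+"), `[`, "", 1L)
  data.frame(read_id = ids, sequence = seq, quality = qual,
             stringsAsFactors = FALSE)
}

#' Join paired-end mates by overlap
#'
#' Reverse-complements each mate-2 read and scans all overlap lengths
#' `>= min_overlap` between the mate-1 3' end and the reverse-complemented
#' mate-2 5' end (no indels within the overlap). The overlap with the
#' lowest mismatch fraction is chosen (ties broken toward the longest), and
#' is accepted when the mismatch fraction is `<= max_mismatch_frac`.
#' Overlap mismatches take the higher-quality base (mate 1 on ties or when
#' qualities are absent). Pairs with no acceptable overlap are dropped and
#' counted.
#'
#' @param r1,r2 Data frames of reads as returned by [read_fastq()], equal
#'   length, mate i of `r1` pairing mate i of `r2`.
#' @param min_overlap Minimum overlap length (default 6).
#' @param max_mismatch_frac Maximum allowed mismatch fraction within the
#'   overlap (default 0.08).
#' @return A list with `joined` (data frame of merged reads) and
#'   `n_unjoined` (count of pairs with no acceptable overlap).
#' @export
join_pairs <- function(r1, r2, min_overlap = 6L, max_mismatch_frac = 0.08) {
  if (nrow(r1) != nrow(r2))
    stop(sprintf("pairing error: %d mate-1 reads but %d mate-2 reads",
                 nrow(r1), nrow(r2)))
  if (nrow(r1) == 0L)
    return(list(joined = r1, n_unjoined = 0L))
  res <- cpp_join_pairs(r1$sequence, r1$quality, r2$sequence, r2$quality,
                        as.integer(min_overlap), max_mismatch_frac)
  ok <- res$joined
  list(joined = data.frame(read_id = r1$read_id[ok],
                           sequence = res$sequence[ok],
                           quality = res$quality[ok],
                           stringsAsFactors = FALSE),
       n_unjoined = sum(!ok))
}

#' Collapse reads to unique sequences with counts
#'
#' Exact full-length string identity on the sequence (quality ignored; no
#' trimming or N-masking -- the read-count cutoff is what absorbs error
#' reads). Output is sorted by descending count, ties broken
#' lexicographically by sequence, with 1-based ranks.
#'
#' @param reads Data frame with a `sequence` column, or a character vector
#'   of sequences.
#' @return A data frame with columns `sequence`, `count`, `rank`, one row
#'   per distinct sequence; the counts sum to the number of input reads.
#' @export
collapse_unique <- function(reads) {
  seqs <- if (is.data.frame(reads)) reads$sequence else as.character(reads)
  if (length(seqs) == 0L)
    return(data.frame(sequence = character(), count = integer(),
                      rank = integer(), stringsAsFactors = FALSE))
  tab <- table(seqs)
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Apply the read-count cutoff
#'
#' Retains exactly the unique reads whose count is `>= cutoff` (inclusive).
#' A cutoff of 0 retains everything. Input order (and original ranks) are
#' preserved.
#'
#' @param uniques Data frame from [collapse_unique()].
#' @param cutoff Non-negative integer (default 30).
#' @return The retained subset of `uniques`.
#' @export
apply_cutoff <- function(uniques, cutoff = 30L) {
  cutoff <- as.numeric(cutoff)
  if (is.na(cutoff) || cutoff < 0)
    stop("cutoff must be a non-negative integer")
  uniques[uniques$count >= cutoff, , drop = FALSE]
}

#' Reverse-complement DNA sequences
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) as.character(cpp_revcomp(as.character(x)))
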