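# Independent oracles and small generators used across the test suite.
# These are deliberately written without reference to the package internals
# so they can arbitrate disagreements.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

oracle_revcomp <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), ""))
}

# brute-force affine-gap local alignment score: three-state DP over the full
# matrix, gap of length L costs open + L * ext, local zero floor on the
# match state; single orientation
oracle_local_affine <- function(read, region, match = 2, mismatch = -3,
                                open = 5, ext = 2) {
  r <- strsplit(read, "")[[1]]
  g <- strsplit(region, "")[[1]]
  n <- length(r); m <- length(g)
  NEG <- -1e9
  M <- matrix(0, n + 1L, m + 1L)
  I <- matrix(NEG, n + 1L, m + 1L)
  D <- matrix(NEG, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (r[i] == g[j] && r[i] != "N") match else mismatch
      M[i + 1L, j + 1L] <- max(0, max(M[i, j], I[i, j], D[i, j]) + s)
      I[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - ext,
                               I[i, j + 1L] - ext,
                               D[i, j + 1L] - open - ext)
      D[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - ext,
                               D[i + 1L, j] - ext,
                               I[i + 1L, j] - open - ext)
      if (M[i + 1L, j + 1L] > best) best <- M[i + 1L, j + 1L]
    }
  }
  best
}

# best score over both orientations, as align_read reports it
oracle_align_score <- function(read, region, ...) {
  max(oracle_local_affine(read, region, ...),
      oracle_local_affine(oracle_revcomp(read), region, ...))
}

# enumeration-based left-normalization oracle: lists every placement of the
# indel that yields the same edited sequence and builds the VCF record from
# the minimum-position member directly
oracle_leftnorm <- function(indel, region) {
  S <- region$sequence
  L <- nchar(indel$seq)
  nS <- nchar(S)
  if (indel$kind == "deletion") {
    a0 <- indel$offset
    edited <- paste0(substr(S, 1L, a0 - 1L), substr(S, a0 + L, nS))
    cand <- Filter(function(a)
      paste0(substr(S, 1L, a - 1L), substr(S, a + L, nS)) == edited,
      seq_len(nS - L + 1L))
    a <- min(unlist(cand))
    if (a > 1L) {
      list(pos = region$start + a - 2L,
           ref = substr(S, a - 1L, a + L - 1L),
           alt = substr(S, a - 1L, a - 1L),
           edited = edited, right_anchored = FALSE)
    } else {
      list(pos = region$start,
           ref = substr(S, 1L, L + 1L),
           alt = substr(S, L + 1L, L + 1L),
           edited = edited, right_anchored = TRUE)
    }
  } else {
    a0 <- indel$offset
    edited <- paste0(substr(S, 1L, a0), indel$seq, substr(S, a0 + 1L, nS))
    cand <- Filter(function(a)
      substr(edited, 1L, a) == substr(S, 1L, a) &&
        substr(edited, a + L + 1L, nS + L) == substr(S, a + 1L, nS),
      0:nS)
    a <- min(unlist(cand))
    ins <- substr(edited, a + 1L, a + L)
    if (a >= 1L) {
      list(pos = region$start + a - 1L,
           ref = substr(S, a, a),
           alt = paste0(substr(S, a, a), ins),
           edited = edited, right_anchored = FALSE)
    } else {
      list(pos = region$start,
           ref = substr(S, 1L, 1L),
           alt = paste0(ins, substr(S, 1L, 1L)),
           edited = edited, right_anchored = TRUE)
    }
  }
}

# apply a single VCF-style variant to the region sequence (independent of
# the package's apply_signature)
oracle_apply_variant <- function(v, region) {
  S <- region$sequence
  off <- v$pos - region$start + 1L
  paste0(substr(S, 1L, off - 1L), v$alt,
         substr(S, off + nchar(v$ref), nchar(S)))
}

# a region rich in homopolymer and dinucleotide repeats, to stress
# normalization
make_repeat_region <- function(width = 120L, start = 101L, chrom = "chrR") {
  parts <- character()
  total <- 0L
  while (total < width) {
    piece <- switch(sample.int(3L, 1L),
      strrep(sample(c("A", "C", "G", "T"), 1L), sample(2:6, 1L)),
      strrep(paste(sample(c("A", "C", "G", "T"), 2L), collapse = ""),
             sample(2:4, 1L)),
      rand_dna(sample(2:5, 1L)))
    parts <- c(parts, piece)
    total <- total + nchar(piece)
  }
  seq <- substr(paste(parts, collapse = ""), 1L, width)
  ref_region(chrom, start, start + width - 1L, seq)
}

make_region <- function(width = 296L, chrom = "chrSim", start = 10001L,
                        genome_label = "synthetic") {
  ref_region(chrom, start, start + width - 1L, rand_dna(width), genome_label)
}

# write a small FASTQ file from sequences (constant quality)
write_test_fastq <- function(seqs, path, ids = NULL, qual = NULL) {
  if (is.null(ids)) ids <- paste0("r", seq_along(seqs))
  if (is.null(qual)) qual <- strrep("I", nchar(seqs))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), path)
  path
}
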