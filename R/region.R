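#' Parse a genomic region string
#'
#' Parses `"CHR:START-END"` (1-based inclusive coordinates, hyphen or
#' en-dash separated, optional whitespace) into its components.
#'
#' @param region_text Region as text, e.g. `"chr21:34715869-34716164"`.
#' @return A list with elements `chrom`, `start`, `end` (integers, 1-based
#'   inclusive).
#' @examples
#' parse_region("chr21:34715869-34716164")
#' @export
parse_region <- function(region_text) {
  if (!is.character(region_text) || length(region_text) != 1L || is.na(region_text))
    stop("region must be a single character string of the form CHR:START-END")
  m <- regmatches(region_text,
    regexec("^\\s*([^:[:space:]]+)\\s*:\\s*([0-9]+)\\s*[-–]\\s*([0-9]+)\\s*$",
            region_text))[[1L]]
  if (length(m) != 4L)
    stop(sprintf("malformed region '%s': expected CHR:START-END", region_text))
  start <- as.numeric(m[3L]); end <- as.numeric(m[4L])
  if (start < 1)
    stop(sprintf("region start '%s' must be a positive coordinate", m[3L]))
  if (end < start)
    stop(sprintf("region end '%s' lies before start '%s'", m[4L], m[3L]))
  list(chrom = m[2L], start = as.integer(start), end = as.integer(end))
}

#' Construct a reference region
#'
#' Builds the region object the pipeline genotypes against. Usually created
#' via [load_region()]; constructing one directly is convenient for
#' synthetic amplicons.
#'
#' @param chrom Chromosome/contig name.
#' @param start,end 1-based inclusive coordinates of the region.
#' @param sequence DNA sequence of the region (length `end - start + 1`,
#'   alphabet A/C/G/T/N; lowercase is uppercased).
#' @param genome_label Free-text genome label (e.g. `"GRCh37"`).
#' @return An object of class `ref_region`.
#' @export
ref_region <- function(chrom, start, end, sequence, genome_label = "") {
  start <- as.integer(start); end <- as.integer(end)
  sequence <- toupper(sequence)
  if (is.na(start) || is.na(end) || start < 1L || end < start)
    stop("invalid region coordinates: need 1 <= start <= end")
  if (nchar(sequence) != end - start + 1L)
    stop(sprintf("sequence length %d does not match region width %d",
                 nchar(sequence), end - start + 1L))
  if (grepl("[^ACGTN]", sequence))
    stop("region sequence contains characters outside A,C,G,T,N")
  structure(list(chrom = chrom, start = start, end = end,
                 sequence = sequence, genome_label = genome_label),
            class = "ref_region")
}

#' @export
print.ref_region <- function(x, ...) {
  cat(sprintf("<ref_region> %s:%d-%d (%d bp%s)\n", x$chrom, x$start, x$end,
              nchar(x$sequence),
              if (nzchar(x$genome_label)) paste0(", ", x$genome_label) else ""))
  invisible(x)
}

#' Load a reference region from a FASTA file
#'
#' Extracts the 1-based inclusive subsequence `start..end` of the FASTA
#' record whose identifier (first whitespace-delimited header token) equals
#' `chrom`. Both a full-genome FASTA and a single-amplicon FASTA are
#' accepted; plain or gzip-compressed, wrapped or unwrapped lines.
#' Soft-masked (lowercase) bases are uppercased. Chromosome naming must
#' match the FASTA header exactly (no "chr21" vs "21" aliasing).
#'
#' @param fasta_path Path to the FASTA file.
#' @param chrom Chromosome name; must equal a record identifier.
#' @param start,end 1-based inclusive coordinates.
#' @param genome_label Optional free-text genome label stored on the region.
#' @param max_width Guard on region width; amplicon-scale regions are held
#'   in memory, so widths above this are refused (default 100 kb).
#' @return A [ref_region()] object.
#' @export
load_region <- function(fasta_path, chrom, start, end, genome_label = "",
                        max_width = 100000L) {
  if (!file.exists(fasta_path))
    stop(sprintf("FASTA file not found: %s", fasta_path))
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start)
    stop("invalid region coordinates: need 1 <= start <= end")
  if (end - start + 1L > max_width)
    stop(sprintf("region width %d exceeds max_width %d", end - start + 1L, max_width))
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- vapply(strsplit(names(seqs), "[[:space:]]+"), `[`, "", 1L)
  hit <- which(ids == chrom)
  if (length(hit) == 0L)
    stop(sprintf("chromosome '%s' not found in %s (records: %s)",
                 chrom, fasta_path, paste(utils::head(ids, 5L), collapse = ", ")))
  rec <- seqs[[hit[1L]]]
  if (end > length(rec))
    stop(sprintf("region end %d beyond length %d of record '%s'",
                 end, length(rec), chrom))
  seq <- toupper(as.character(Biostrings::subseq(rec, start, end)))
  ref_region(chrom, start, end, seq, genome_label = genome_label)
}
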