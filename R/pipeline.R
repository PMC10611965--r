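#' Genotype one sample from FASTQ
#'
#' Runs the full per-sample pipeline: read FASTQ (joining paired-end mates
#' by overlap when two files are given), collapse to unique reads, apply
#' the read-count cutoff, align retained reads and call genotypes. The
#' total-read denominator is the number of successfully processed reads
#' entering collapsing (unjoined pairs are dropped and counted).
#'
#' @param fastq One FASTQ(.gz) path, or a length-2 vector `c(R1, R2)` for
#'   paired-end data.
#' @param region A [ref_region()].
#' @param params An [align_params()].
#' @param cutoff Read-count cutoff (default 30; 0 retains all reads).
#' @param major_threshold Major-genotype threshold (default 0.01).
#' @param sample_id Sample label; defaults to the FASTQ file stem.
#' @param min_overlap,max_mismatch_frac Pair-joining parameters, see
#'   [join_pairs()].
#' @return A `sample_report` (see [call_genotypes()]) with `n_unique_reads`
#'   and, for paired input, `n_unjoined_pairs` filled in.
#' @export
genotype_sample <- function(fastq, region, params = align_params(),
                            cutoff = 30L, major_threshold = 0.01,
                            sample_id = NULL, min_overlap = 6L,
                            max_mismatch_frac = 0.08) {
  if (is.null(sample_id)) sample_id <- sample_stem(fastq[1L])
  n_unjoined <- NA_integer_
  if (length(fastq) == 2L) {
    jp <- join_pairs(read_fastq(fastq[1L]), read_fastq(fastq[2L]),
                     min_overlap = min_overlap,
                     max_mismatch_frac = max_mismatch_frac)
    reads <- jp$joined
    n_unjoined <- jp$n_unjoined
  } else if (length(fastq) == 1L) {
    reads <- read_fastq(fastq)
  } else stop("fastq must be one file or a c(R1, R2) pair")
  uniques <- collapse_unique(reads)
  retained <- apply_cutoff(uniques, cutoff)
  report <- call_genotypes(retained, n_total_reads = nrow(reads),
                           region = region, params = params,
                           major_threshold = major_threshold,
                           sample_id = sample_id, cutoff = as.integer(cutoff))
  report$n_unique_reads <- nrow(uniques)
  report$n_unjoined_pairs <- n_unjoined
  report
}

sample_stem <- function(path) {
  stem <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  sub("(_R?[12])$", "", stem)
}

#' Discover demultiplexed samples in a directory
#'
#' Finds `*.fastq`, `*.fq` (optionally `.gz`) files; mates are matched by
#' the `_R1`/`_R2` or `_1`/`_2` suffix convention on the file stem.
#' Ambiguous pairing (e.g. an `_R1` file without its mate) is an error,
#' never a guess.
#'
#' @param dir Directory of demultiplexed per-sample FASTQ files.
#' @return A named list; each element is a length-1 (single-end) or
#'   length-2 (paired) vector of paths, named by sample.
#' @export
discover_samples <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("fastq directory not found: %s", dir))
  files <- list.files(dir, pattern = "\\.(fastq|fq)(\\.gz)?$",
                      ignore.case = TRUE, full.names = TRUE)
  files <- files[!grepl("_truth\\.tsv$", files)]
  if (length(files) == 0L) stop(sprintf("no FASTQ files found in %s", dir))
  stems <- vapply(files, function(f)
    sub("\\.(fastq|fq)(\\.gz)?$", "", basename(f), ignore.case = TRUE), "")
  mate <- ifelse(grepl("_R?1$", stems), 1L, ifelse(grepl("_R?2$", stems), 2L, 0L))
  base <- ifelse(mate > 0L, sub("_R?[12]$", "", stems), stems)
  out <- list()
  for (b in unique(base)) {
    idx <- which(base == b)
    if (length(idx) == 1L && mate[idx] == 0L) {
      out[[b]] <- files[idx]
    } else if (length(idx) == 2L && setequal(mate[idx], c(1L, 2L))) {
      out[[b]] <- files[idx][order(mate[idx])]
    } else {
      stop(sprintf("ambiguous FASTQ pairing for sample '%s': %s",
                   b, paste(basename(files[idx]), collapse = ", ")))
    }
  }
  out[order(names(out))]
}

#' Run the genotyping pipeline over one or many samples
#'
#' End-to-end driver: loads the reference region, genotypes every sample,
#' and writes the four outputs -- `summary.tsv` plus a per-sample VCF, a
#' per-sample genotype plot, a per-sample genotype-vs-WT alignment text,
#' and the cohort genotype matrix `matrix.tsv` -- together with a run log
#' recording versions, parameters and per-sample totals. A directory with
#' one merged FASTQ is processed identically (bulk-population mode).
#'
#' @param reference Path to a FASTA file, or a ready [ref_region()] (in
#'   which case `region` may be omitted).
#' @param region Region string `"CHR:START-END"` (1-based inclusive).
#' @param fastq_dir Directory of demultiplexed FASTQ files; or use `fastq`.
#' @param fastq Explicit FASTQ path(s): one file, or `c(R1, R2)`.
#' @param out_dir Output directory (default `"editcall_out"`).
#' @param cutoff Read-count cutoff (default 30).
#' @param major_threshold Major-genotype threshold (default 0.01).
#' @param params An [align_params()].
#' @param genome_label Genome label recorded in output headers.
#' @param strict Abort on the first failing sample instead of skipping it
#'   (default FALSE).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `reports`, `matrix`, `region`, `out_dir`,
#'   and `failed` (named error messages of skipped samples).
#' @export
run_pipeline <- function(reference, region = NULL, fastq_dir = NULL,
                         fastq = NULL, out_dir = "editcall_out",
                         cutoff = 30L, major_threshold = 0.01,
                         params = align_params(), genome_label = "",
                         strict = FALSE, quiet = FALSE) {
  if (inherits(reference, "ref_region")) {
    reg <- reference
  } else {
    if (is.null(region)) stop("region (CHR:START-END) is required")
    spec <- parse_region(region)
    reg <- load_region(reference, spec$chrom, spec$start, spec$end,
                       genome_label = genome_label)
  }
  if (is.null(fastq_dir) == is.null(fastq))
    stop("provide exactly one of fastq_dir or fastq")
  samples <- if (!is.null(fastq_dir)) discover_samples(fastq_dir)
             else stats::setNames(list(fastq), sample_stem(fastq[1L]))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  reports <- list(); failed <- character()
  for (nm in names(samples)) {
    res <- tryCatch(
      genotype_sample(samples[[nm]], reg, params = params, cutoff = cutoff,
                      major_threshold = major_threshold, sample_id = nm),
      error = function(e) e)
    if (inherits(res, "error")) {
      if (strict) stop(sprintf("sample '%s': %s", nm, conditionMessage(res)))
      failed[nm] <- conditionMessage(res)
      if (!quiet) message(sprintf("skipping sample '%s': %s", nm,
                                  conditionMessage(res)))
      next
    }
    reports[[nm]] <- res
    if (!quiet)
      message(sprintf("%s: %d reads, %d unique, %d retained, %d major genotype(s)",
                      nm, res$n_total_reads, res$n_unique_reads,
                      res$n_retained_reads, sum(res$calls$major)))
  }
  if (length(reports) == 0L) stop("no sample could be genotyped")

  write_summary(reports, out_dir)
  for (r in reports) {
    plot_sample(r, file.path(out_dir, paste0(r$sample_id, "_genotypes.png")))
    majors <- r$calls[r$calls$major, , drop = FALSE]
    blocks <- vapply(seq_len(nrow(majors)), function(k) {
      key <- majors$signature[k]
      paste0("# ", r$sample_id, " genotype ", k, ": ", key,
             sprintf(" (%.1f%% of reads)\n", 100 * majors$proportion[k]),
             render_alignment_text(
               if (key == "WT") empty_variants() else r$signatures[[key]],
               reg),
             "\n")
    }, "")
    writeLines(blocks, file.path(out_dir, paste0(r$sample_id, "_alignment.txt")))
  }
  m <- build_matrix(reports)
  write_matrix(m, file.path(out_dir, "matrix.tsv"))

  log_lines <- c(
    sprintf("editcall %s / R %s", as.character(packageVersion("editcall")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("region: %s:%d-%d (%d bp)%s", reg$chrom, reg$start, reg$end,
            nchar(reg$sequence),
            if (nzchar(reg$genome_label)) paste0(" [", reg$genome_label, "]") else ""),
    sprintf("cutoff: %d; major_threshold: %g", as.integer(cutoff), major_threshold),
    sprintf("alignment: match %d, mismatch %d, gap_open %d, gap_extend %d, min_aligned_frac %g, min_identity %g",
            params$match, params$mismatch, params$gap_open, params$gap_extend,
            params$min_aligned_frac, params$min_identity),
    vapply(reports, function(r)
      sprintf("sample %s: total %d, unique %d, retained %d, genotypes %d, major %d, read_contribution %.4f",
              r$sample_id, r$n_total_reads, r$n_unique_reads,
              r$n_retained_reads, nrow(r$calls), sum(r$calls$major),
              r$read_contribution), ""),
    if (length(failed))
      paste0("failed sample ", names(failed), ": ", failed))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(reports = reports, matrix = m, region = reg,
                 out_dir = out_dir, failed = failed))
}

#' Read-count-cutoff sweep diagnostics
#'
#' Genotypes the same sample at several read-count cutoffs, aligning each
#' unique read only once. Reports, per cutoff, the retained read fraction,
#' the number of distinct genotypes, the number and identity of major
#' genotypes, and the read contribution to major genotypes.
#'
#' @param uniques All unique reads of the sample ([collapse_unique()]).
#' @param n_total_reads The sample's total processed reads.
#' @param region A [ref_region()].
#' @param cutoffs Cutoffs to evaluate (default `c(0, 1, 5, 10, 30, 50)`).
#' @param params An [align_params()].
#' @param major_threshold Major-genotype threshold (default 0.01).
#' @return A data frame with one row per cutoff (`cutoff`,
#'   `n_retained_reads`, `retained_frac`, `n_genotypes`, `n_major`,
#'   `read_contribution`), with the per-cutoff major signature sets in
#'   `attr(, "major_sets")` and the reports in `attr(, "reports")`.
#' @export
cutoff_sweep <- function(uniques, n_total_reads, region,
                         cutoffs = c(0L, 1L, 5L, 10L, 30L, 50L),
                         params = align_params(), major_threshold = 0.01) {
  cache <- new.env(parent = emptyenv())
  rows <- list(); major_sets <- list(); reports <- list()
  for (ct in cutoffs) {
    retained <- apply_cutoff(uniques, ct)
    rep_ct <- call_genotypes(retained, n_total_reads, region, params = params,
                             major_threshold = major_threshold,
                             sample_id = sprintf("cutoff_%d", ct),
                             cutoff = as.integer(ct), aln_cache = cache)
    rows[[length(rows) + 1L]] <- data.frame(
      cutoff = as.integer(ct),
      n_retained_reads = rep_ct$n_retained_reads,
      retained_frac = rep_ct$n_retained_reads / n_total_reads,
      n_genotypes = nrow(rep_ct$calls),
      n_major = sum(rep_ct$calls$major),
      read_contribution = rep_ct$read_contribution)
    major_sets[[as.character(ct)]] <- sort(rep_ct$calls$signature[rep_ct$calls$major])
    reports[[as.character(ct)]] <- rep_ct
  }
  out <- do.call(rbind, rows)
  attr(out, "major_sets") <- major_sets
  attr(out, "reports") <- reports
  out
}
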