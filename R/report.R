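#' Write per-sample summary and VCF output
#'
#' Writes (a) `summary.tsv`, one row per genotype call across all samples
#' (sample, read totals, cutoff, signature, supporting reads, proportion,
#' major flag, read contribution), and (b) one VCF v4.2 file per sample
#' containing the major genotypes' variants. Multi-variant signatures link
#' their records through the `SIGID` INFO key (VCF has no native
#' haplotype-call record; this is the documented convention). INFO also
#' carries `SUPP` (supporting reads) and `PROP` (proportion of total
#' reads); right-anchored boundary indels carry the `RANCHOR` flag.
#'
#' @param reports List of `sample_report` objects.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `summary` (path) and `vcf` (named vector
#'   of per-sample paths).
#' @export
write_summary <- function(reports, out_dir) {
  if (length(reports) < 1L) stop("need at least one sample report")
  if (inherits(reports, "sample_report")) reports <- list(reports)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create directory %s", out_dir))

  rows <- lapply(reports, function(r) {
    if (nrow(r$calls) == 0L)
      return(data.frame(sample = r$sample_id, n_total_reads = r$n_total_reads,
                        n_unique_reads = r$n_unique_reads, cutoff = r$cutoff,
                        n_retained_reads = r$n_retained_reads,
                        read_contribution = r$read_contribution,
                        signature = NA_character_, n_variants = NA_integer_,
                        n_supporting = NA_integer_, proportion = NA_character_,
                        major = NA, stringsAsFactors = FALSE))
    data.frame(sample = r$sample_id, n_total_reads = r$n_total_reads,
               n_unique_reads = r$n_unique_reads, cutoff = r$cutoff,
               n_retained_reads = r$n_retained_reads,
               read_contribution = r$read_contribution,
               signature = r$calls$signature, n_variants = r$calls$n_variants,
               n_supporting = r$calls$n_supporting,
               proportion = sprintf("%.4f", r$calls$proportion),
               major = r$calls$major, stringsAsFactors = FALSE)
  })
  summary_path <- file.path(out_dir, "summary.tsv")
  write.table(do.call(rbind, rows), summary_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  vcf_paths <- vapply(reports, function(r) {
    p <- file.path(out_dir, paste0(r$sample_id, ".vcf"))
    write_vcf(r, p)
    p
  }, "")
  names(vcf_paths) <- vapply(reports, `[[`, "", "sample_id")
  invisible(list(summary = summary_path, vcf = vcf_paths))
}

#' Write one sample's major genotypes as VCF v4.2
#'
#' @param report A `sample_report`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_vcf <- function(report, path) {
  region <- report$region
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=editcall %s", as.character(packageVersion("editcall"))),
    if (nzchar(region$genome_label))
      sprintf("##reference=%s", region$genome_label),
    sprintf("##contig=<ID=%s,length=%d>", region$chrom, region$end),
    "##INFO=<ID=SIGID,Number=1,Type=String,Description=\"Genotype signature identifier; records sharing a SIGID lie on one allele\">",
    "##INFO=<ID=SUPP,Number=1,Type=Integer,Description=\"Reads supporting the signature\">",
    "##INFO=<ID=PROP,Number=1,Type=Float,Description=\"Supporting reads as a fraction of total reads\">",
    "##INFO=<ID=RANCHOR,Number=0,Type=Flag,Description=\"Indel at the region boundary, anchored on the right\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"))
  majors <- report$calls[report$calls$major & report$calls$signature != "WT", ,
                         drop = FALSE]
  recs <- character()
  if (nrow(majors)) {
    sigid <- paste0("SIG", seq_len(nrow(majors)))
    rows <- lapply(seq_len(nrow(majors)), function(k) {
      vars <- report$signatures[[majors$signature[k]]]
      info <- sprintf("SIGID=%s;SUPP=%d;PROP=%.4f%s", sigid[k],
                      majors$n_supporting[k], majors$proportion[k],
                      ifelse(vars$right_anchored, ";RANCHOR", ""))
      data.frame(chrom = vars$chrom, pos = vars$pos, id = sigid[k],
                 ref = vars$ref, alt = vars$alt, info = info,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$pos, tab$ref, tab$alt), , drop = FALSE]
    recs <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                    tab$chrom, tab$pos, tab$id, tab$ref, tab$alt, tab$info)
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Render a genotype-vs-wild-type alignment block
#'
#' Two-row gapped alignment (WT row, genotype row) covering all of the
#' signature's variants plus `flank` reference bases on each side, with a
#' coordinate ruler giving genomic positions of the flank boundaries.
#' Deletions appear as dashes in the genotype row, insertions as dashes in
#' the WT row.
#'
#' @param call A `genotype_signature`, a variant data frame, or a signature
#'   key present in `region`-compatible reports.
#' @param region The [ref_region()].
#' @param flank Reference bases of context on each side (default 20).
#' @return A single character string (multi-line text block).
#' @export
render_alignment_text <- function(call, region, flank = 20L) {
  vars <- if (inherits(call, "genotype_signature")) call$variants else call
  S <- region$sequence
  if (is.null(vars) || nrow(vars) == 0L) {
    w0 <- 1L; w1 <- nchar(S)
    wt <- substr(S, w0, w1)
    gt <- wt
  } else {
    vars <- vars[order(vars$pos), , drop = FALSE]
    offs <- vars$pos - region$start + 1L
    ends <- offs + nchar(vars$ref) - 1L
    w0 <- max(1L, min(offs) - flank)
    w1 <- min(nchar(S), max(ends) + flank)
    wt_parts <- character(); gt_parts <- character()
    cur <- w0
    for (k in seq_len(nrow(vars))) {
      off <- offs[k]
      # left-anchored events include the anchor base in the pre-event
      # context; right-anchored (boundary) events keep it after the event
      pre_end <- if (vars$right_anchored[k]) off - 1L else off
      if (pre_end >= cur) {
        wt_parts <- c(wt_parts, substr(S, cur, pre_end))
        gt_parts <- c(gt_parts, substr(S, cur, pre_end))
      }
      if (vars$kind[k] == "deletion") {
        del <- if (!vars$right_anchored[k])
          substr(vars$ref, 2L, nchar(vars$ref))
        else substr(vars$ref, 1L, nchar(vars$ref) - 1L)
        wt_parts <- c(wt_parts, del)
        gt_parts <- c(gt_parts, strrep("-", nchar(del)))
        cur <- if (vars$right_anchored[k]) ends[k] else ends[k] + 1L
      } else {
        ins <- if (!vars$right_anchored[k])
          substr(vars$alt, 2L, nchar(vars$alt))
        else substr(vars$alt, 1L, nchar(vars$alt) - 1L)
        wt_parts <- c(wt_parts, strrep("-", nchar(ins)))
        gt_parts <- c(gt_parts, ins)
        cur <- if (vars$right_anchored[k]) off else off + 1L
      }
    }
    wt_parts <- c(wt_parts, substr(S, cur, w1))
    gt_parts <- c(gt_parts, substr(S, cur, w1))
    wt <- paste(wt_parts, collapse = "")
    gt <- paste(gt_parts, collapse = "")
  }
  ruler <- sprintf("%s:%d..%d (%d columns)", region$chrom,
                   region$start + w0 - 1L, region$start + w1 - 1L, nchar(wt))
  marks <- vapply(strsplit(wt, "")[[1]] == strsplit(gt, "")[[1]],
                  function(same) if (same) " " else "*", "")
  paste(c(ruler,
          paste0("WT  ", wt),
          paste0("GT  ", gt),
          paste0("    ", paste(marks, collapse = ""))),
        collapse = "\n")
}

#' Plot a sample's major genotypes
#'
#' One horizontal glyph per major genotype along the genomic coordinate of
#' the region: deletions as bars spanning the deleted bases, insertions as
#' downward triangles at the insertion point, each row labeled with the
#' genotype's proportion (percent, 1 decimal). The layout is deterministic
#' for a given report.
#'
#' @param report A `sample_report`.
#' @param out_path Output image path (`.png`); `NULL` draws on the current
#'   device.
#' @param width,height Image size in pixels.
#' @return Invisibly, `out_path`.
#' @export
plot_sample <- function(report, out_path = NULL, width = 900L, height = 500L) {
  if (!is.null(out_path)) {
    grDevices::png(out_path, width = width, height = height)
    on.exit(grDevices::dev.off())
  }
  plot.sample_report(report)
  invisible(out_path)
}

#' @export
plot.sample_report <- function(x, ...) {
  region <- x$region
  majors <- x$calls[x$calls$major, , drop = FALSE]
  n <- nrow(majors)
  graphics::plot(NULL, xlim = c(region$start, region$end),
                 ylim = c(0.5, max(n, 1L) + 0.5),
                 xlab = sprintf("position on %s", region$chrom),
                 ylab = "", yaxt = "n",
                 main = sprintf("%s: major genotypes (cutoff %s, threshold %.2g%%)",
                                x$sample_id, ifelse(is.na(x$cutoff), "?", x$cutoff),
                                100 * x$major_threshold))
  if (n == 0L) {
    graphics::text(mean(c(region$start, region$end)), 1, "no major genotypes")
    return(invisible(x))
  }
  for (k in seq_len(n)) {
    y <- n - k + 1L
    key <- majors$signature[k]
    graphics::segments(region$start, y, region$end, y,
                       col = "grey85", lwd = 1)
    if (key != "WT") {
      vars <- x$signatures[[key]]
      for (v in seq_len(nrow(vars))) {
        if (vars$kind[v] == "deletion") {
          graphics::rect(vars$pos[v] + 1L, y - 0.22,
                         vars$pos[v] + nchar(vars$ref[v]) - 1L, y + 0.22,
                         col = "firebrick", border = NA)
        } else {
          graphics::points(vars$pos[v], y, pch = 25, bg = "dodgerblue",
                           col = "dodgerblue", cex = 1.4)
        }
      }
    }
    graphics::text(region$end, y,
                   sprintf("%s  %.1f%%",
                           ifelse(key == "WT", "WT", sprintf("%d variant(s)", majors$n_variants[k])),
                           100 * majors$proportion[k]),
                   pos = 4, xpd = NA, cex = 0.8)
  }
  graphics::axis(2, at = rev(seq_len(n)), labels = paste0("G", seq_len(n)),
                 las = 1)
  invisible(x)
}

#' Build the cohort genotype-by-sample proportion matrix
#'
#' Union of signature keys across samples (ordered by total supporting
#' reads, descending), with each sample's call proportions filled in and 0
#' where a genotype is absent from a sample.
#'
#' @param reports List of `sample_report` objects with distinct sample ids.
#' @param majors_only Restrict to major genotypes (default TRUE).
#' @return A numeric matrix (class `cohort_matrix`) with samples as rows
#'   and signature keys as columns.
#' @export
build_matrix <- function(reports, majors_only = TRUE) {
  if (inherits(reports, "sample_report")) reports <- list(reports)
  if (length(reports) < 1L) stop("need at least one sample report")
  ids <- vapply(reports, `[[`, "", "sample_id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sample id '%s'", ids[duplicated(ids)][1L]))
  calls <- lapply(reports, function(r)
    if (majors_only) r$calls[r$calls$major, , drop = FALSE] else r$calls)
  keys <- unlist(lapply(calls, `[[`, "signature"))
  supp <- unlist(lapply(calls, `[[`, "n_supporting"))
  if (length(keys)) {
    tot <- tapply(supp, keys, sum)
    cols <- names(sort(tot, decreasing = TRUE))
    # deterministic tie order: by total support, then key text
    cols <- cols[order(-tot[cols], cols)]
  } else cols <- character()
  m <- matrix(0, nrow = length(ids), ncol = length(cols),
              dimnames = list(ids, cols))
  for (i in seq_along(reports)) {
    cc <- calls[[i]]
    if (nrow(cc)) m[i, cc$signature] <- cc$proportion
  }
  class(m) <- c("cohort_matrix", class(m))
  m
}

#' Write the cohort matrix as TSV
#'
#' @param m A matrix from [build_matrix()].
#' @param path Output TSV path (samples as rows, 4-decimal proportions).
#' @return Invisibly, the path.
#' @export
write_matrix <- function(m, path) {
  out <- as.data.frame(apply(unclass(m), 2L, function(x) sprintf("%.4f", x),
                             simplify = FALSE),
                       check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(m) == 0L) out <- data.frame(row.names = rownames(m))
  out <- cbind(sample = rownames(m), out)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
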