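fixture_reports <- function(seed = 61, n_total = 10000L) {
  set.seed(seed)
  region <- make_region(296, start = 10001)
  sigs <- list(random_signature(region, n_indels = 2),
               random_signature(region, cut_offset = 80),
               random_signature(region, cut_offset = 220))
  haps <- vapply(sigs, function(s) apply_signature(region, s), "")
  mk <- function(id, idx, counts) {
    u <- data.frame(sequence = haps[idx], count = as.integer(counts),
                    rank = seq_along(idx), stringsAsFactors = FALSE)
    call_genotypes(u, n_total, region, sample_id = id)
  }
  list(region = region, sigs = sigs,
       reports = list(mk("S1", c(1L, 2L), c(6000L, 3000L)),
                      mk("S2", c(2L, 3L), c(5000L, 4000L))))
}

test_that("VCF output is v4.2, parseable, and round-trips all variant fields", {
  fx <- fixture_reports()
  out <- tempfile(); dir.create(out)
  paths <- write_summary(fx$reports, out)
  expect_true(file.exists(paths$summary))

  r1 <- fx$reports[[1]]
  vcf <- suppressWarnings(vcfR::read.vcfR(paths$vcf[["S1"]], verbose = FALSE))
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  want <- do.call(rbind, r1$signatures[r1$calls$signature[r1$calls$major]])
  want <- want[order(want$pos, want$ref, want$alt), ]
  expect_identical(nrow(fix), nrow(want))
  expect_identical(fix$CHROM, want$chrom)
  expect_identical(as.integer(fix$POS), want$pos)
  expect_identical(fix$REF, want$ref)
  expect_identical(fix$ALT, want$alt)
  # positions sorted, INFO carries support and proportion
  expect_true(!is.unsorted(as.integer(fix$POS)))
  info <- vcfR::getINFO(vcf)
  expect_true(all(grepl("SIGID=SIG\\d+;SUPP=\\d+;PROP=0\\.\\d{4}", info)))
  # records of one multi-variant signature share a SIGID
  sig2 <- r1$calls$signature[r1$calls$n_variants == 2][1]
  expect_identical(length(unique(sub(".*SIGID=(SIG\\d+);.*", "\\1", info))),
                   sum(r1$calls$major))
})

test_that("a WT-only sample writes a VCF header with zero records", {
  set.seed(62)
  region <- make_region(120, start = 1)
  u <- data.frame(sequence = region$sequence, count = 900L, rank = 1L,
                  stringsAsFactors = FALSE)
  rep <- call_genotypes(u, 1000L, region, sample_id = "wt")
  out <- tempfile(); dir.create(out)
  paths <- write_summary(list(rep), out)
  lines <- readLines(paths$vcf[["wt"]])
  expect_true(any(grepl("^##fileformat=VCFv4.2", lines)))
  expect_identical(sum(!grepl("^#", lines)), 0L)
  smry <- read.delim(paths$summary)
  expect_identical(nrow(smry), 1L)
  expect_identical(smry$signature, "WT")
})

test_that("alignment text blocks show deletions and insertions as gap columns", {
  region <- ref_region("chrT", 1001, 1030, "ACGTTGCAGGATCCATTGCATCAGGCATGC")
  # WT signature: identical rows
  txt <- render_alignment_text(editcall:::empty_variants(), region)
  rows <- strsplit(txt, "\n")[[1]]
  expect_identical(sub("^WT  ", "", rows[2]), sub("^GT  ", "", rows[3]))
  expect_false(grepl("-", rows[2], fixed = TRUE))

  # 3-bp deletion: exactly 3 dashes in the genotype row
  del <- left_normalize(list(kind = "deletion", offset = 12L, seq = "TCC"),
                        region)
  txt2 <- render_alignment_text(del, region, flank = 5)
  rows2 <- strsplit(txt2, "\n")[[1]]
  expect_identical(lengths(regmatches(rows2[3], gregexpr("-", rows2[3]))), 3L)
  expect_false(grepl("-", rows2[2], fixed = TRUE))
  wt_row <- strsplit(sub("^WT  ", "", rows2[2]), "")[[1]]
  gt_row <- strsplit(sub("^GT  ", "", rows2[3]), "")[[1]]
  dash <- which(gt_row == "-")
  # outside the gap the rows agree; the gap columns show reference bases
  expect_identical(gt_row[-dash], wt_row[-dash])
  expect_true(all(wt_row[dash] %in% c("A", "C", "G", "T")))

  # 1-bp insertion: exactly 1 dash in the WT row
  ins <- left_normalize(list(kind = "insertion", offset = 20L, seq = "T"),
                        region)
  txt3 <- render_alignment_text(ins, region, flank = 5)
  rows3 <- strsplit(txt3, "\n")[[1]]
  expect_identical(lengths(regmatches(rows3[2], gregexpr("-", rows3[2]))), 1L)
})

test_that("sample plots are written deterministically", {
  fx <- fixture_reports()
  p1 <- tempfile(fileext = ".png"); p2 <- tempfile(fileext = ".png")
  plot_sample(fx$reports[[1]], p1)
  plot_sample(fx$reports[[1]], p2)
  expect_true(file.exists(p1) && file.size(p1) > 0)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  # empty report still renders
  set.seed(63)
  region <- make_region(60, start = 1)
  empty <- data.frame(sequence = character(), count = integer(),
                      rank = integer(), stringsAsFactors = FALSE)
  rep <- suppressWarnings(call_genotypes(empty, 100L, region, sample_id = "e"))
  p3 <- tempfile(fileext = ".png")
  plot_sample(rep, p3)
  expect_true(file.size(p3) > 0)
})

test_that("the cohort matrix mirrors per-sample calls exactly", {
  fx <- fixture_reports()
  m <- build_matrix(fx$reports)
  keys <- colnames(m)
  expect_identical(nrow(m), 2L)
  expect_identical(length(keys), 3L)      # union of 2 + 2 with 1 shared
  for (i in 1:2) {
    r <- fx$reports[[i]]
    for (k in keys) {
      want <- r$calls$proportion[r$calls$signature == k & r$calls$major]
      expect_identical(m[r$sample_id, k],
                       if (length(want)) want else 0)
    }
  }
  expect_true(all(rowSums(m) <= 1 + 1e-12))
  # single sample: matrix equals that sample's proportions
  m1 <- build_matrix(fx$reports[1])
  expect_identical(as.numeric(sort(m1[1, ])),
                   as.numeric(sort(fx$reports[[1]]$calls$proportion)))
  expect_error(build_matrix(fx$reports[c(1, 1)]), "duplicate")
  # TSV round trip
  tsv <- tempfile(fileext = ".tsv")
  write_matrix(m, tsv)
  back <- read.delim(tsv, check.names = FALSE)
  expect_identical(back$sample, rownames(m))
  expect_equal(as.numeric(back[1, -1]), round(unname(m[1, ]), 4))
})
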