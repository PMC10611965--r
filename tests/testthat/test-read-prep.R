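test_that("FASTQ files parse in order, including gzip and empty input", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1 desc", "ACGTN", "+", "IIIII",
               "@r2", "GGCC", "+r2", "FFFF"), fq)
  rd <- read_fastq(fq)
  expect_identical(rd$read_id, c("r1", "r2"))
  expect_identical(rd$sequence, c("ACGTN", "GGCC"))
  expect_identical(rd$quality, c("IIIII", "FFFF"))

  empty <- tempfile(fileext = ".fastq")
  file.create(empty)
  expect_identical(nrow(read_fastq(empty)), 0L)

  gz <- tempfile(fileext = ".fastq.gz")
  con <- gzfile(gz, "wt")
  writeLines(c("@a", "ACGT", "+", "IIII"), con); close(con)
  expect_identical(read_fastq(gz)$sequence, "ACGT")
})

test_that("malformed FASTQ records are reported with their index", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+"), fq)
  expect_error(read_fastq(fq), "record 2")

  fq2 <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+", "III"), fq2)
  expect_error(read_fastq(fq2), "record 2")
})

test_that("collapsing counts exact duplicates and ranks by descending count", {
  u <- collapse_unique(c("AC", "AC", "GT"))
  expect_identical(u$sequence, c("AC", "GT"))
  expect_identical(u$count, c(2L, 1L))
  expect_identical(u$rank, c(1L, 2L))
  expect_identical(nrow(collapse_unique(character())), 0L)
  # ties broken lexicographically
  u2 <- collapse_unique(c("TT", "AA", "GG"))
  expect_identical(u2$sequence, c("AA", "GG", "TT"))
})

test_that("unique counts conserve the number of processed reads", {
  set.seed(21)
  for (k in 1:10) {
    n <- sample(500, 1)
    reads <- vapply(sample(50, n, replace = TRUE),
                    function(i) strrep("ACGT", i %% 5 + 1), "")
    u <- collapse_unique(reads)
    expect_identical(sum(u$count), n)
    expect_false(anyDuplicated(u$sequence) > 0)
  }
})

test_that("the read-count cutoff is inclusive and monotone", {
  u <- data.frame(sequence = c("A", "C", "G"), count = c(100L, 40L, 29L),
                  rank = 1:3, stringsAsFactors = FALSE)
  expect_identical(apply_cutoff(u, 30)$sequence, c("A", "C"))
  expect_identical(apply_cutoff(u, 0), u)          # cutoff 0 retains all
  expect_identical(apply_cutoff(u[3, ], 29)$count, 29L)  # boundary inclusive
  expect_error(apply_cutoff(u, -1), "non-negative")
  # nesting: retained at c2 is a subset of retained at c1 <= c2
  set.seed(3)
  u3 <- collapse_unique(sample(c("AA", "CC", "GG", "TT"), 200, replace = TRUE,
                               prob = c(.5, .3, .15, .05)))
  prev <- u3$sequence
  for (ct in c(0, 10, 40, 80, 200)) {
    cur <- apply_cutoff(u3, ct)$sequence
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("paired mates join by best overlap and report unjoined pairs", {
  # 5-base exact overlap reconstructing ACGTACGTGGG
  r1 <- data.frame(read_id = "p", sequence = "ACGTACGT",
                   quality = NA_character_, stringsAsFactors = FALSE)
  r2 <- data.frame(read_id = "p", sequence = revcomp("TACGTGGG"),
                   quality = NA_character_, stringsAsFactors = FALSE)
  jp <- join_pairs(r1, r2, min_overlap = 4)
  expect_identical(jp$joined$sequence, "ACGTACGTGGG")
  expect_identical(jp$n_unjoined, 0L)

  # no acceptable overlap
  r1b <- data.frame(read_id = "q", sequence = "AAAA", quality = NA_character_,
                    stringsAsFactors = FALSE)
  r2b <- data.frame(read_id = "q", sequence = revcomp("GGGG"),
                    quality = NA_character_, stringsAsFactors = FALSE)
  jpb <- join_pairs(r1b, r2b, min_overlap = 4)
  expect_identical(nrow(jpb$joined), 0L)
  expect_identical(jpb$n_unjoined, 1L)

  expect_error(join_pairs(r1, rbind(r2, r2b)), "pairing error")
})

test_that("overlap mismatches take the higher-quality base, mate 1 on ties", {
  frag <- "ACGTACGTAAGGCCTT"
  r1s <- substr(frag, 1, 12)                 # ACGTACGTAAGG
  r2s <- revcomp(substr(frag, 5, 16))        # covers ACGTAAGGCCTT
  # corrupt one overlap base on mate 1 (position 9 of r1, an A -> C)
  r1c <- r1s; substr(r1c, 9, 9) <- "C"
  mk <- function(s, q) data.frame(read_id = "x", sequence = s, quality = q,
                                  stringsAsFactors = FALSE)
  # mate 2 higher quality at every base -> mate 2 base wins
  jp <- join_pairs(mk(r1c, strrep("#", 12)), mk(r2s, strrep("I", 12)),
                   min_overlap = 6, max_mismatch_frac = 0.2)
  expect_identical(jp$joined$sequence, frag)
  # equal qualities -> mate 1 base kept
  jp2 <- join_pairs(mk(r1c, strrep("I", 12)), mk(r2s, strrep("I", 12)),
                    min_overlap = 6, max_mismatch_frac = 0.2)
  expect_identical(substr(jp2$joined$sequence, 9, 9), "C")
})

test_that("error-free simulated pairs rejoin to the exact amplicon", {
  set.seed(31)
  for (k in 1:20) {
    amp <- rand_dna(sample(60:120, 1))
    rl <- nchar(amp) - sample(5:20, 1)
    r1 <- substr(amp, 1, rl)
    r2 <- revcomp(substr(amp, nchar(amp) - rl + 1, nchar(amp)))
    jp <- join_pairs(
      data.frame(read_id = "k", sequence = r1, quality = NA_character_,
                 stringsAsFactors = FALSE),
      data.frame(read_id = "k", sequence = r2, quality = NA_character_,
                 stringsAsFactors = FALSE))
    expect_identical(jp$joined$sequence, amp)
  }
})
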