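make_flanked_region <- function(core, flank = 40L, start = 1001L,
                                chrom = "chrT") {
  seq <- paste0(rand_dna(flank), core, rand_dna(flank))
  ref_region(chrom, start, start + nchar(seq) - 1L, seq)
}

test_that("indel extraction separates insertions and deletions, ignores substitutions", {
  set.seed(51)
  region <- make_region(200, start = 1)
  # haplotype: 2-bp deletion at 60, 1-bp insertion after 120, one substitution
  hap <- paste0(substr(region$sequence, 1, 59),
                substr(region$sequence, 62, 120), "A",
                substr(region$sequence, 121, 200))
  substr(hap, 30, 30) <- if (substr(hap, 30, 30) == "A") "C" else "A"
  a <- align_read(hap, region)
  raws <- extract_indels(a, region)
  expect_identical(length(raws), 2L)
  kinds <- vapply(raws, `[[`, "", "kind")
  expect_setequal(kinds, c("deletion", "insertion"))
  del <- raws[[which(kinds == "deletion")]]
  expect_identical(del$seq, substr(region$sequence, del$offset, del$offset + 1L))

  wt <- align_read(region$sequence, region)
  expect_identical(length(extract_indels(wt, region)), 0L)
})

test_that("left-normalization shifts through homopolymers and is anchored", {
  region <- ref_region("chrT", 1, 6, "GCAAAT")
  # delete the A at offset 5 (rightmost of the run) -> leftmost is pos 2 CA>C
  v <- left_normalize(list(kind = "deletion", offset = 5L, seq = "A"), region)
  expect_identical(v$pos, 2L)
  expect_identical(v$ref, "CA")
  expect_identical(v$alt, "C")
  expect_false(v$right_anchored)

  # no repeat context: no shift possible
  region2 <- ref_region("chrT", 1, 5, "ATGCA")
  v2 <- left_normalize(list(kind = "deletion", offset = 3L, seq = "G"), region2)
  expect_identical(v2$pos, 2L)
  expect_identical(v2$ref, "TG")
  expect_identical(v2$alt, "T")

  # insertion into the homopolymer normalizes to its left edge
  v3 <- left_normalize(list(kind = "insertion", offset = 5L, seq = "A"), region)
  expect_identical(v3$pos, 2L)
  expect_identical(v3$ref, "C")
  expect_identical(v3$alt, "CA")

  # boundary indel with no left anchor gets a right anchor and a flag
  v4 <- left_normalize(list(kind = "deletion", offset = 1L, seq = "G"),
                       ref_region("chrT", 1, 4, "GGCA"))
  expect_true(v4$right_anchored)
  expect_identical(v4$pos, 1L)

  # idempotence: renormalizing a normalized event changes nothing
  raw <- editcall:::variant_to_raw(v, region)
  expect_identical(left_normalize(raw, region), v)
})

test_that("left-normalization agrees with the enumeration oracle on random repeat contexts", {
  set.seed(52)
  n_ok <- 0L
  for (k in 1:120) {
    region <- make_repeat_region(width = 100L, start = 201L)
    S <- region$sequence
    if (k %% 2 == 0) {
      l <- sample(1:4, 1); off <- sample(2:(100 - l), 1)
      raw <- list(kind = "deletion", offset = off,
                  seq = substr(S, off, off + l - 1L))
    } else {
      l <- sample(1:4, 1); off <- sample(1:99, 1)
      ins <- if (runif(1) < 0.5) substr(S, off, min(off + l - 1L, 100L))
             else rand_dna(l)
      raw <- list(kind = "insertion", offset = off, seq = ins)
    }
    got <- left_normalize(raw, region)
    exp <- oracle_leftnorm(raw, region)
    expect_identical(got$pos, as.integer(exp$pos))
    expect_identical(got$ref, exp$ref)
    expect_identical(got$alt, exp$alt)
    # REF -> ALT substitution at POS reconstructs the edited haplotype
    expect_identical(oracle_apply_variant(got, region), exp$edited)
    n_ok <- n_ok + 1L
  }
  expect_identical(n_ok, 120L)
})

test_that("signatures are invariant to substitution errors and sorted by position", {
  set.seed(53)
  region <- make_region(240, start = 5001)
  hap <- paste0(substr(region$sequence, 1, 80),
                substr(region$sequence, 83, 160), "TG",
                substr(region$sequence, 161, 240))
  a <- align_read(hap, region)
  sig <- signature_of_read(a, region)
  expect_identical(nrow(sig$variants), 2L)
  expect_true(all(diff(sig$variants$pos) > 0))

  # a PCR-style point error far from the edits leaves the signature unchanged
  noisy <- hap
  substr(noisy, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                   substr(noisy, 20, 20))[1]
  expect_identical(signature_key(signature_of_read(align_read(noisy, region), region)),
                   signature_key(sig))

  # wild-type read: empty signature, key "WT"
  wt_sig <- signature_of_read(align_read(region$sequence, region), region)
  expect_identical(nrow(wt_sig$variants), 0L)
  expect_identical(signature_key(wt_sig), "WT")
})

test_that("apply_signature and the pipeline are mutual inverses at zero error", {
  set.seed(54)
  region <- make_region(296, start = 10001)
  for (k in 1:15) {
    sig <- random_signature(region, n_indels = sample(1:2, 1))
    hap <- apply_signature(region, sig)
    back <- signature_of_read(align_read(hap, region), region)
    expect_identical(signature_key(back), signature_key(sig),
                     info = sprintf("case %d", k))
  }
})

test_that("genotype calls aggregate unique reads by signature with total-read proportions", {
  set.seed(55)
  region <- make_region(296, start = 10001)
  sigA <- random_signature(region, n_indels = 1)
  sigB <- random_signature(region, n_indels = 1)
  hapA <- apply_signature(region, sigA)
  hapB <- apply_signature(region, sigB)
  # error read of allele A: same signature, separate unique sequence
  hapAerr <- hapA
  substr(hapAerr, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(hapA, 5, 5))[1]
  uniques <- data.frame(
    sequence = c(hapA, hapB, hapAerr, region$sequence),
    count = c(5500L, 3900L, 500L, 100L),
    rank = 1:4, stringsAsFactors = FALSE)
  rep <- call_genotypes(uniques, n_total_reads = 10000L, region = region,
                        sample_id = "mix")
  expect_identical(nrow(rep$calls), 3L)
  bykey <- setNames(rep$calls$n_supporting, rep$calls$signature)
  expect_identical(bykey[[signature_key(sigA)]], 6000L)  # 5500 + 500 merged
  expect_identical(bykey[[signature_key(sigB)]], 3900L)
  expect_identical(bykey[["WT"]], 100L)
  props <- setNames(rep$calls$proportion, rep$calls$signature)
  expect_equal(props[[signature_key(sigA)]], 0.60)
  expect_equal(props[[signature_key(sigB)]], 0.39)
  # WT at exactly 1% of total reads is major (boundary inclusive)
  expect_true(rep$calls$major[rep$calls$signature == "WT"])
  expect_identical(sum(rep$calls$major), 3L)
  # calls sorted by descending proportion
  expect_true(all(diff(rep$calls$proportion) <= 0))
})

test_that("zero retained reads yield an empty-call report with a warning", {
  region <- make_region(60, start = 1)
  empty <- data.frame(sequence = character(), count = integer(),
                      rank = integer(), stringsAsFactors = FALSE)
  expect_warning(rep <- call_genotypes(empty, 1000L, region, sample_id = "e"),
                 "no reads retained")
  expect_identical(nrow(rep$calls), 0L)
  expect_identical(read_contribution(rep), 0)
})

test_that("read contribution is majors' support over retained reads", {
  set.seed(56)
  region <- make_region(296, start = 10001)
  sig <- random_signature(region)
  hap <- apply_signature(region, sig)
  minor <- apply_signature(region, random_signature(region, cut_offset = 60))
  uniques <- data.frame(sequence = c(hap, minor), count = c(800L, 100L),
                        rank = 1:2, stringsAsFactors = FALSE)
  # minor allele below the 1% major threshold of 100000 total reads
  rep <- call_genotypes(uniques, 100000L, region, sample_id = "rc")
  expect_identical(sum(rep$calls$major), 0L)
  expect_identical(read_contribution(rep), 0)
  rep2 <- call_genotypes(uniques, 10000L, region, sample_id = "rc2")
  expect_equal(read_contribution(rep2), 900 / 900)
  rep3 <- call_genotypes(uniques, 80000L, region, sample_id = "rc3")
  expect_equal(read_contribution(rep3), 800 / 900)
})
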