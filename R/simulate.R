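#' Apply a genotype signature to the reference region
#'
#' Builds the edited haplotype by applying the signature's variants
#' right-to-left (descending position) so that coordinates stay valid.
#'
#' @param region A [ref_region()].
#' @param variants A variant data frame (as in a `genotype_signature`), or
#'   a `genotype_signature`; variants must lie within the region and be
#'   non-overlapping.
#' @return The edited haplotype sequence (character).
#' @export
apply_signature <- function(region, variants) {
  if (inherits(variants, "genotype_signature")) variants <- variants$variants
  S <- region$sequence
  if (is.null(variants) || nrow(variants) == 0L) return(S)
  vars <- variants[order(-variants$pos), , drop = FALSE]
  ends <- variants$pos + nchar(variants$ref) - 1L
  o <- order(variants$pos)
  if (nrow(variants) > 1L &&
      any(variants$pos[o][-1L] <= ends[o][-length(o)]))
    stop("overlapping variants cannot be applied to one haplotype")
  for (k in seq_len(nrow(vars))) {
    v <- vars[k, ]
    off <- v$pos - region$start + 1L
    if (off < 1L || off + nchar(v$ref) - 1L > nchar(S))
      stop(sprintf("variant at pos %d lies outside the region", v$pos))
    if (substr(S, off, off + nchar(v$ref) - 1L) != v$ref)
      stop(sprintf("REF mismatch at pos %d: region has '%s', variant says '%s'",
                   v$pos, substr(S, off, off + nchar(v$ref) - 1L), v$ref))
    S <- paste0(substr(S, 1L, off - 1L), v$alt,
                substr(S, off + nchar(v$ref), nchar(S)))
  }
  S
}

#' Specify a simulated clone
#'
#' Describes a mixture of allele haplotypes over a reference region, the
#' error model, and the read geometry, for [simulate_clone_fastq()]. The
#' defaults emulate deep MiSeq amplicon sequencing of a CRISPR-edited
#' single-cell clone: tens of thousands of reads, substitution-dominated
#' polymerase/sequencer error with rare spurious 1-bp indels.
#'
#' @param region A [ref_region()].
#' @param alleles List of allele signatures (variant data frames or
#'   `genotype_signature` objects; an empty data frame is a WT allele).
#' @param proportions Target allele proportions (positive, sum `<= 1`; any
#'   remainder becomes uniformly random junk reads).
#' @param n_reads Total reads to emit (default 50000).
#' @param error_rate Per-base substitution error probability
#'   (default 0.003).
#' @param error_indel_rate Per-read probability of one spurious 1-bp indel
#'   (default 0.005).
#' @param read_length Read length; `NULL` (default) emits the full
#'   haplotype as one single-end read. In paired mode, the per-mate length.
#' @param paired Emit overlapping R1/R2 mate pairs covering the amplicon
#'   (default FALSE).
#' @param seed Random seed; a fixed seed gives byte-identical output.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(region, alleles, proportions, n_reads = 50000L,
                     error_rate = 0.003, error_indel_rate = 0.005,
                     read_length = NULL, paired = FALSE, seed = 1L) {
  stopifnot(inherits(region, "ref_region"))
  alleles <- lapply(alleles, function(a)
    if (inherits(a, "genotype_signature")) a$variants else a)
  if (length(alleles) != length(proportions))
    stop("alleles and proportions must have equal length")
  if (any(proportions <= 0) || sum(proportions) > 1 + 1e-9)
    stop("allele proportions must be positive and sum to at most 1")
  haps <- vapply(alleles, function(v) apply_signature(region, v), "")
  if (paired) {
    if (is.null(read_length)) stop("paired mode requires read_length")
    if (any(2L * read_length - 6L < nchar(haps)))
      stop("read_length too short to cover the longest haplotype with overlapping mates")
  }
  structure(list(region = region, alleles = alleles, haplotypes = haps,
                 proportions = proportions, n_reads = as.integer(n_reads),
                 error_rate = error_rate, error_indel_rate = error_indel_rate,
                 read_length = read_length, paired = isTRUE(paired),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

mutate_substitutions <- function(seqs, error_rate) {
  # returns list(seqs, clean): clean marks reads left untouched
  n <- length(seqs)
  lens <- nchar(seqs)
  nerr <- rbinom(n, lens, error_rate)
  idx <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(lens[i], nerr[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      repl <- sample(setdiff(bases, cur), 1L)
      substr(seqs[i], p, p) <- repl
    }
  }
  list(seqs = seqs, clean = nerr == 0L)
}

mutate_spurious_indels <- function(seqs, rate) {
  n <- length(seqs)
  hit <- runif(n) < rate
  bases <- c("A", "C", "G", "T")
  for (i in which(hit)) {
    L <- nchar(seqs[i])
    p <- sample.int(L, 1L)
    if (runif(1L) < 0.5 && L > 1L) {            # 1-bp deletion
      seqs[i] <- paste0(substr(seqs[i], 1L, p - 1L),
                        substr(seqs[i], p + 1L, L))
    } else {                                    # 1-bp insertion
      seqs[i] <- paste0(substr(seqs[i], 1L, p),
                        sample(bases, 1L),
                        substr(seqs[i], p + 1L, L))
    }
  }
  list(seqs = seqs, clean = !hit)
}

write_fastq <- function(ids, seqs, path, qual_char = "I") {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  quals <- strrep(qual_char, nchar(seqs))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con, sep = "\n")
  invisible(path)
}

#' Simulate one clone's amplicon FASTQ with known ground truth
#'
#' Draws each read's allele from the target proportions, applies
#' substitution errors and rare spurious 1-bp indels, and writes FASTQ
#' output plus a machine-readable truth table. The truth table records, per
#' allele, the signature key, the target proportion, the reads drawn
#' (`n_assigned`) and the reads emitted with zero errors (`n_exact`) --
#' i.e. the reads whose sequence is exactly the allele haplotype, which is
#' what a cutoff above the error-read noise floor retains.
#'
#' @param spec A [sim_spec()].
#' @param out_prefix Output path prefix; writes `<prefix>.fastq` (or
#'   `<prefix>_R1.fastq` / `<prefix>_R2.fastq` in paired mode) and
#'   `<prefix>_truth.tsv`.
#' @return Invisibly, a list with `fastq` (paths), `truth` (data frame) and
#'   `n_reads`.
#' @export
simulate_clone_fastq <- function(spec, out_prefix) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  K <- length(spec$alleles)
  p_junk <- max(0, 1 - sum(spec$proportions))
  counts <- as.vector(rmultinom(1L, spec$n_reads, c(spec$proportions, p_junk)))
  allele_of <- rep.int(seq_len(K + 1L), counts)

  seqs <- character(spec$n_reads)
  for (k in seq_len(K)) seqs[allele_of == k] <- spec$haplotypes[k]
  n_junk <- counts[K + 1L]
  if (n_junk > 0L) {
    jl <- if (!is.null(spec$read_length)) spec$read_length
          else as.integer(round(mean(nchar(spec$haplotypes))))
    junk <- vapply(seq_len(n_junk), function(i)
      paste(sample(c("A", "C", "G", "T"), jl, replace = TRUE), collapse = ""), "")
    seqs[allele_of == K + 1L] <- junk
  }

  ms <- mutate_substitutions(seqs, spec$error_rate)
  mi <- mutate_spurious_indels(ms$seqs, spec$error_indel_rate)
  seqs <- mi$seqs
  clean <- ms$clean & mi$clean

  perm <- sample.int(spec$n_reads)
  seqs <- seqs[perm]; allele_of <- allele_of[perm]; clean <- clean[perm]

  keys <- c(vapply(spec$alleles, signature_key, ""), "junk")
  truth <- data.frame(
    allele = keys,
    target_prop = c(spec$proportions, p_junk),
    n_assigned = counts,
    n_exact = vapply(seq_len(K + 1L), function(k)
      sum(allele_of == k & clean), integer(1L)),
    stringsAsFactors = FALSE)

  ids <- paste0("read_", seq_len(spec$n_reads))
  if (spec$paired) {
    rl <- spec$read_length
    r1 <- substr(seqs, 1L, rl)
    lens <- nchar(seqs)
    r2 <- revcomp(substr(seqs, pmax(1L, lens - rl + 1L), lens))
    fq <- c(paste0(out_prefix, "_R1.fastq"), paste0(out_prefix, "_R2.fastq"))
    write_fastq(paste0(ids, "/1"), r1, fq[1L])
    write_fastq(paste0(ids, "/2"), r2, fq[2L])
  } else {
    if (!is.null(spec$read_length))
      seqs <- substr(seqs, 1L, spec$read_length)
    fq <- paste0(out_prefix, ".fastq")
    write_fastq(ids, seqs, fq)
  }
  truth_path <- paste0(out_prefix, "_truth.tsv")
  write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fastq = fq, truth = truth, truth_path = truth_path,
                 n_reads = spec$n_reads))
}

#' Draw a random indel signature near a cut site
#'
#' Generates a plausible NHEJ editing outcome: `n_indels` non-overlapping
#' indels (deletions favored over insertions, as observed in Cas9-edited
#' clones) placed within `window` bases of the cut-site offset.
#'
#' @param region A [ref_region()].
#' @param cut_offset 1-based region offset of the cut site (default: region
#'   midpoint).
#' @param n_indels Number of indels in the signature (default 1).
#' @param max_del Maximum deletion length (default 15).
#' @param max_ins Maximum insertion length (default 3).
#' @param window Half-width of the placement window around the cut site
#'   (default 20).
#' @param p_deletion Probability that an indel is a deletion (default 0.9,
#'   matching the deletion-dominated spectra of Cas9 NHEJ outcomes).
#' @return A normalized variant data frame (a signature).
#'
#' @details The returned signature is always canonical: realigning its own
#'   haplotype against the region reproduces it exactly. Candidates for
#'   which the optimal alignment prefers a different representation (e.g.
#'   two nearby deletions that merge into one larger deletion at lower gap
#'   cost) are rejected and redrawn, because such outcomes are inherently
#'   indistinguishable from their canonical form in read data.
#' @export
random_signature <- function(region, cut_offset = NULL, n_indels = 1L,
                             max_del = 15L, max_ins = 3L, window = 20L,
                             p_deletion = 0.9) {
  if (is.null(cut_offset)) cut_offset <- nchar(region$sequence) %/% 2L
  vars <- empty_variants()
  tries <- 0L
  while (tries < 200L) {
    tries <- tries + 1L
    if (nrow(vars) == n_indels) {
      hap <- apply_signature(region, vars)
      back <- signature_of_read(align_read(hap, region), region)
      if (identical(signature_key(back), signature_key(vars))) break
      vars <- empty_variants()   # non-canonical representation: redraw
      next
    }
    off <- cut_offset + sample.int(2L * window + 1L, 1L) - window - 1L
    off <- max(2L, min(off, nchar(region$sequence) - max_del - 1L))
    if (runif(1L) < p_deletion) {
      len <- sample.int(max_del, 1L)
      raw <- list(kind = "deletion", offset = off,
                  seq = substr(region$sequence, off, off + len - 1L))
    } else {
      len <- sample.int(max_ins, 1L)
      ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
      raw <- list(kind = "insertion", offset = off, seq = ins)
    }
    v <- left_normalize(raw, region)
    cand <- rbind(vars, v)
    cand <- cand[order(cand$pos), , drop = FALSE]
    ends <- cand$pos + nchar(cand$ref) - 1L
    if (nrow(cand) == 1L || all(cand$pos[-1L] > ends[-nrow(cand)] + 1L)) {
      vars <- cand
      rownames(vars) <- NULL
    }
  }
  vars
}

#' Simulate a cohort of edited clones
#'
#' Writes per-clone FASTQ files plus truth tables for a cohort of
#' CRISPR-edited single-cell clones. Two presets are provided:
#' `"paper-scale"` emulates a 20-clone multiplexed MiSeq run (50,000 to
#' 70,000 reads per clone, 2 to 4 alleles per clone with one 10-allele
#' clone, and two 10-clone groups whose allele pools share 8 signatures);
#' `"validation"` fixes 50,000 reads per clone and cycles the allele count
#' through 2, 3, 4 with all allele proportions at least 5%, the
#' configuration used for parameter-recovery checks.
#'
#' @param dir Output directory (created if needed).
#' @param region A [ref_region()]; `NULL` generates a random 296-bp
#'   amplicon (the width of a typical MiSeq-covered CRISPR target window).
#' @param n_clones Number of clones (default 20).
#' @param preset `"paper-scale"` or `"validation"`.
#' @param n_reads Override the per-clone read count (recycled), e.g. to
#'   scale the cohort down.
#' @param error_rate,error_indel_rate Error model passed to [sim_spec()].
#' @param seed Random seed for the whole cohort.
#' @return Invisibly, a list with `region`, `samples` (per-clone list of
#'   fastq path, truth data frame, allele keys and proportions) and `dir`.
#' @export
simulate_cohort <- function(dir, region = NULL, n_clones = 20L,
                            preset = c("paper-scale", "validation"),
                            n_reads = NULL, error_rate = 0.003,
                            error_indel_rate = 0.005, seed = 1L) {
  preset <- match.arg(preset)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  if (is.null(region)) {
    seq <- paste(sample(c("A", "C", "G", "T"), 296L, replace = TRUE),
                 collapse = "")
    region <- ref_region("chrSim", 10001L, 10296L, seq, "synthetic")
  }

  # allele pool: enough distinct signatures for all clones, with a shared
  # block so the two halves of the cohort overlap in 8 signatures
  n_shared <- 8L
  pool_size <- 64L
  pool <- list(); keys <- character()
  while (length(pool) < pool_size) {
    sig <- random_signature(region, n_indels = sample(1:2, 1L, prob = c(.85, .15)))
    k <- signature_key(sig)
    if (nrow(sig) >= 1L && !(k %in% keys)) {
      pool[[length(pool) + 1L]] <- sig; keys <- c(keys, k)
    }
  }
  shared_idx <- seq_len(n_shared)
  groupA_idx <- c(shared_idx, (n_shared + 1L):36L)
  groupB_idx <- c(shared_idx, 37L:pool_size)

  samples <- vector("list", n_clones)
  for (i in seq_len(n_clones)) {
    if (preset == "paper-scale") {
      K <- if (i == 6L && n_clones >= 6L) 10L else sample(2:4, 1L)
      nr <- if (is.null(n_reads)) sample(50000:70000, 1L)
            else rep_len(n_reads, n_clones)[i]
    } else {
      K <- 2L + (i - 1L) %% 3L
      nr <- if (is.null(n_reads)) 50000L else rep_len(n_reads, n_clones)[i]
    }
    idx_pool <- if (i <= ceiling(n_clones / 2)) groupA_idx else groupB_idx
    take <- sample(idx_pool, K)
    props <- runif(K, 0.05, 1)
    props <- props / sum(props)
    # enforce a 5% floor after normalization
    while (any(props < 0.05)) {
      props[props < 0.05] <- 0.05
      props <- props / sum(props)
    }
    spec <- sim_spec(region, pool[take], props, n_reads = nr,
                     error_rate = error_rate,
                     error_indel_rate = error_indel_rate,
                     seed = sample.int(.Machine$integer.max %/% 2L, 1L))
    sim <- simulate_clone_fastq(spec, file.path(dir, sprintf("S%d", i)))
    samples[[i]] <- list(sample_id = sprintf("S%d", i), fastq = sim$fastq,
                         truth = sim$truth, alleles = keys[take],
                         proportions = props, n_reads = nr)
  }
  invisible(list(region = region, samples = samples, dir = dir))
}
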