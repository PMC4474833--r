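# Modification-aware alignment, species assignment, spike-in normalization
# and truncation profiling.

make_refs <- function(seed = 7) simulate_trna_refs(seed = seed)

test_that("adapter trimming removes full and partial 3' adapters", {
  adapter <- "AGATCGGAAGAGC"
  insert <- "ACGTACGTACGTACGTACGTACGTACGT"
  trimmed <- function(...) as.character(trim_adapters(...))
  expect_equal(trimmed(paste0(insert, adapter), adapter), insert)
  expect_equal(trimmed(insert, adapter), insert)
  # partial terminal adapter down to the 5-base seed
  for (k in 5:12) {
    rd <- paste0(insert, substr(adapter, 1, k))
    expect_equal(trimmed(rd, adapter), insert)
  }
  # below the seed the terminal bases are kept
  rd4 <- paste0(insert, substr(adapter, 1, 4))
  expect_equal(trimmed(rd4, adapter), rd4)
  expect_error(trim_adapters("ACGT", ""), "non-empty")
  short <- trim_adapters(paste0("ACGTACGT", adapter), adapter)
  expect_true(attr(short, "too_short")[1])
})

test_that("reads align exactly, via modified positions, and are rejected over the error cap", {
  refs <- make_refs()
  r1 <- refs[[5]]
  al <- align_read(r1$sequence, r1)
  expect_true(al$accepted)
  expect_equal(al$errors, 0L)
  expect_equal(al$three_prime_offset, 0L)
  expect_equal(al$aligned_length, nchar(r1$sequence))
  # a mismatch at a modified position costs nothing
  s <- strsplit(r1$sequence, "")[[1]]
  mp <- r1$modified_mask[2] + 1
  s[mp] <- setdiff(c("A", "C", "G", "T"), s[mp])[1]
  al2 <- align_read(paste(s, collapse = ""), r1)
  expect_equal(al2$errors, 0L)
  expect_true(al2$accepted)
  # four substitutions at unmodified positions exceed the cap
  s3 <- strsplit(r1$sequence, "")[[1]]
  um <- setdiff(seq_along(s3), r1$modified_mask + 1)[c(3, 13, 23, 33)]
  for (i in um) s3[i] <- setdiff(c("A", "C", "G", "T"), s3[i])[1]
  al3 <- align_read(paste(s3, collapse = ""), r1)
  expect_equal(al3$errors, 4L)
  expect_false(al3$accepted)
  # short reads rejected with a reason
  al4 <- align_read(substr(r1$sequence, 1, 20), r1)
  expect_false(al4$accepted)
  expect_match(al4$reason, "shorter than min_length")
  # truncation offset reflects missing 3' bases
  al5 <- align_read(substr(r1$sequence, 1, nchar(r1$sequence) - 4), r1)
  expect_equal(al5$three_prime_offset, 4L)
})

test_that("alignment error counts equal exhaustive enumeration", {
  set.seed(404)
  for (i in 1:250) {
    n <- sample(40:90, 1)
    ref <- random_dna(n)
    type <- i %% 4
    read <- if (type == 0) random_dna(sample(25:40, 1)) else {
      st <- substr(ref, sample(c(1, 1, 5), 1), sample(25:min(40, n), 1))
      if (type == 1) st else substitute_bases(st, sample(1:5, 1))
    }
    if (nchar(read) < 25) next
    mask <- if (i %% 3 == 0) sort(sample(seq_len(n), 6) - 1L) else integer(0)
    want <- oracle_min_errors(read, ref, mask, 3L)
    got <- align_read(read, ref, modified_positions = mask)
    expect_equal(min(got$errors, 4L), want,
                 label = sprintf("pair %d dp=%d", i, got$errors))
    expect_equal(got$accepted, want <= 3L)
  }
})

test_that("adding modified positions never increases the error count", {
  set.seed(505)
  for (i in 1:40) {
    n <- sample(50:90, 1)
    ref <- random_dna(n)
    read <- substitute_bases(substr(ref, 1, sample(30:min(45, n), 1)),
                             sample(0:4, 1))
    mask <- integer(0)
    e_prev <- align_read(read, ref, modified_positions = mask)$errors
    for (extra in sample(seq_len(n) - 1L, 8)) {
      mask <- sort(unique(c(mask, extra)))
      e_now <- align_read(read, ref, modified_positions = mask)$errors
      expect_lte(e_now, e_prev)
      e_prev <- e_now
    }
  }
})

test_that("read assignment is deterministic under ties", {
  seqs <- paste0(strrep("ACGT", 15), "GATTACAGATTACA", "CCA")
  refA <- trna_reference("A-tie", seqs)
  refB <- trna_reference("B-tie", seqs)
  read <- substr(seqs, 1, nchar(seqs) - 1)  # 1 error to both
  for (perm in list(list(refA, refB), list(refB, refA))) {
    al <- assign_read(read, perm)
    expect_equal(al$species_id, "A-tie")  # lexicographic winner
  }
  # unique reads go to their own species, garbage goes unassigned
  refs <- make_refs()
  r9 <- refs[[9]]
  expect_equal(assign_read(r9$sequence, refs)$species_id, r9$species_id)
  set.seed(3)
  un <- assign_read(random_dna(60), refs)
  expect_false(un$accepted)
  expect_true(is.na(un$species_id))
})

test_that("every read is either assigned, unassigned or spike-in", {
  refs <- make_refs()
  spec <- trna_sim_spec(refs, read_count = 1500, seed = 77)
  lib <- simulate_trna_reads(spec, "normal")
  allrefs <- c(refs, list(trna_reference("spike-in", spike_in_sequence())))
  aln <- align_reads(lib$reads, allrefs)
  cn <- species_counts(aln, condition = "normal", species_ids = names(refs))
  expect_equal(sum(cn$counts) + cn$spike_in_count + cn$unassigned,
               length(lib$reads))
})

test_that("fold changes are exact on constructed counts", {
  mk <- function(counts, spike, cond) {
    al <- data.frame(
      read_id = sprintf("r%d", seq_len(sum(counts) + spike)),
      species_id = c(rep(names(counts), counts), rep("spike-in", spike)),
      errors = 0L, aligned_length = 70L, ref_start = 0L, ref_end = 69L,
      three_prime_offset = 0L, accepted = TRUE, too_short = FALSE,
      stringsAsFactors = FALSE)
    species_counts(al, condition = cond, species_ids = names(counts))
  }
  base <- c(a = 100L, b = 40L, c = 60L)
  same <- normalize_and_fold_change(mk(base, 20L, "normal"),
                                    mk(base, 20L, "oxidative"))
  expect_equal(same$per_species$fold_decrease, rep(1, 3))
  expect_equal(same$mean_fold_change, 1)
  halved <- normalize_and_fold_change(mk(base, 20L, "normal"),
                                      mk(base / 2L, 20L, "oxidative"))
  expect_equal(halved$mean_fold_change, 2)
  expect_equal(halved$total_fold_change, 2)
  # zero stress counts are flagged and excluded from the mean
  zero <- normalize_and_fold_change(mk(base, 20L, "normal"),
                                    mk(c(a = 50L, b = 0L, c = 30L), 20L,
                                       "oxidative"))
  expect_equal(zero$excluded, "b")
  expect_equal(zero$mean_fold_change, 2)
  expect_error(normalize_and_fold_change(mk(base, 0L, "normal"),
                                         mk(base, 20L, "oxidative")),
               "spike-in")
})

test_that("truncation profiles recover constructed offsets", {
  al <- data.frame(
    read_id = sprintf("r%d", 1:40),
    species_id = "5-Arg(CCT)",
    errors = 0L, aligned_length = 70L, ref_start = 0L, ref_end = 69L,
    three_prime_offset = rep(c(0L, 3L), each = 20),
    accepted = TRUE, too_short = FALSE, stringsAsFactors = FALSE)
  pr <- truncation_profile(al, "5-Arg(CCT)", tandem_cca = TRUE)
  expect_equal(unname(pr$fractions[["0"]]), 0.5)
  expect_equal(unname(pr$fractions[["3"]]), 0.5)
  expect_equal(sum(pr$fractions), 1)
  expect_equal(pr$inner_cca_fraction, 0.5)
  al0 <- al[al$three_prime_offset == 0L, ]
  pr0 <- truncation_profile(al0, "5-Arg(CCT)")
  expect_equal(unname(pr0$fractions[["0"]]), 1)
  expect_error(truncation_profile(al, "nope"), "no accepted reads")
})

test_that("replicate concordance is exact for identical and rescaled libraries", {
  refs <- make_refs()
  spec <- trna_sim_spec(refs, read_count = 1200, seed = 31)
  lib <- simulate_trna_reads(spec, "normal")
  allrefs <- c(refs, list(trna_reference("spike-in", spike_in_sequence())))
  aln <- align_reads(lib$reads, allrefs)
  cn <- species_counts(aln, species_ids = names(refs))
  expect_equal(replicate_concordance(cn, cn)$pearson, 1)
  # a x10 library with x10 spike-in normalizes identically
  cn10 <- cn
  cn10$counts <- cn$counts * 10L
  cn10$spike_in_count <- cn$spike_in_count * 10L
  cn10$normalized <- cn10$counts / cn10$spike_in_count
  rc <- replicate_concordance(cn, cn10)
  expect_equal(rc$pearson, 1)
  expect_equal(rc$spearman, 1)
  few <- cn; few$normalized <- cn$normalized[1:2]
  expect_error(replicate_concordance(few, few), "3 shared")
})

test_that("references round-trip through FASTA and the modification table", {
  refs <- make_refs()[1:5]
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  write_trna_refs(refs, fa, tsv)
  back <- read_trna_refs(fa, tsv)
  expect_equal(length(back), 5)
  for (id in names(refs)) {
    expect_equal(back[[id]]$sequence, refs[[id]]$sequence)
    expect_equal(back[[id]]$modified_mask, refs[[id]]$modified_mask)
    expect_equal(back[[id]]$tandem_cca, refs[[id]]$tandem_cca)
  }
  unlink(c(fa, tsv))
})

test_that("reference invariants are enforced", {
  expect_error(trna_reference("x", "ACGTACGT"), "end in CCA")
  expect_error(trna_reference("x", "ACGTCCA", modified_positions = 9),
               "outside")
  tand <- trna_reference("t", paste0(random_dna(60), "CCACCA"))
  expect_true(tand$tandem_cca)
})
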