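# small reads-mode fixture shared across the demux/align tests
local_read_run <- function(junk = 0.2, seed = 9, coverage = 150) {
  scheme <- build_scheme(1, 2, 3)
  refs <- fixture_refs(n = 2, length = 120, seed = 11)
  barcodes <- barcode_table(scheme, seed = 2)
  truth <- plant_mutations(scheme, refs,
    mutations = fixture_mutation(refs, zygosity = "HOM"))
  fastq <- withr::local_tempfile(fileext = ".fastq",
    .local_envir = parent.frame())
  simulate_reads(scheme, truth, refs, barcodes,
    coverage = coverage_model(coverage, pool_cv = 0.2, end_dropoff_fraction = 0.1,
      junk_read_fraction = junk),
    error = error_model(), fastq = fastq, seed = seed)
  list(scheme = scheme, refs = refs, barcodes = barcodes, truth = truth,
    fastq = fastq)
}

test_that("simulated runs demultiplex cleanly and conserve reads", {
  run <- local_read_run(junk = 0)
  reads <- read_fastq(run$fastq)
  # with no junk reads, every read begins with a valid barcode
  expect_true(all(substr(reads$sequence, 1, 10) %in% run$barcodes$barcode))
  dem <- demultiplex(reads, run$barcodes)
  expect_equal(sum(is.na(dem$pool)), 0)
  summ <- demux_summary(dem)
  expect_equal(sum(summ$n_reads), nrow(reads))
  # identical seed -> byte-identical FASTQ
  f2 <- withr::local_tempfile(fileext = ".fastq")
  simulate_reads(run$scheme, run$truth, run$refs, run$barcodes,
    coverage = coverage_model(150, pool_cv = 0.2, end_dropoff_fraction = 0.1,
      junk_read_fraction = 0),
    error = error_model(), fastq = f2, seed = 9)
  expect_identical(readLines(run$fastq), readLines(f2))
})

test_that("all-junk runs map zero reads", {
  run <- local_read_run(junk = 1, coverage = 60)
  reads <- read_fastq(run$fastq)
  dem <- demultiplex(reads, run$barcodes)
  trimmed <- trim_reads(dem, run$refs)
  expect_equal(sum(trimmed$status == "ok"), 0)
  aln <- align_to_amplicons(trimmed, run$refs, seed = 1)
  expect_equal(nrow(aln), 0)
})

test_that("ambiguous and mismatched barcodes go unassigned", {
  close_pair <- tibble::tibble(pool = c("A1", "B1"), barcode = c("AAAAT", "AAAAG"))
  reads <- tibble::tibble(
    read_id = c("exact", "ambig", "alien"),
    sequence = c(
      paste0("AAAAT", strrep("ACGT", 10)),
      paste0("AAAAC", strrep("ACGT", 10)), # 1 mismatch from both barcodes
      paste0("GGGGG", strrep("ACGT", 10))
    ),
    quality = strrep("I", 45)
  )
  exact <- demultiplex(reads, close_pair, max_mismatch = 0)
  expect_equal(exact$pool, c("A1", NA, NA))
  expect_equal(nchar(exact$sequence[1]), 40) # barcode stripped
  # assignment demands a unique barcode within tolerance: at 1 mismatch every
  # read here is within reach of both barcodes, so all are ambiguous
  tol <- demultiplex(reads, close_pair, max_mismatch = 1)
  expect_equal(tol$pool, c(NA_character_, NA, NA))
  # well-separated barcodes tolerate a sequencing error in the barcode
  distant <- tibble::tibble(pool = c("A1", "B1"), barcode = c("AAAAT", "GGGGC"))
  tol2 <- demultiplex(reads, distant, max_mismatch = 1)
  expect_equal(tol2$pool, c("A1", "A1", "B1"))
  expect_error(demultiplex(reads, close_pair[0, ]), "empty")
})

test_that("trimming recovers the exact insert from a constructed read", {
  refs <- fixture_refs(n = 1, length = 90, seed = 31)
  tag <- attr(refs, "universal_tag")
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  full <- paste0(tag, refs$forward_primer, refs$sequence,
    rc(refs$reverse_primer), rc(attr(refs, "trp1_adapter")))
  reads <- tibble::tibble(
    read_id = c("full", "truncated", "dimer"),
    pool = "A1",
    sequence = c(
      full,
      # 3'-truncated: only the first 12 nt of the adapter survive
      paste0(tag, refs$forward_primer, refs$sequence,
        substr(rc(refs$reverse_primer), 1, 12)),
      # ~50 bp primer-dimer: no target between primer and adapter
      paste0(tag, refs$forward_primer, substr(rc(refs$reverse_primer), 1, 14))
    ),
    quality = NA_character_,
    original_length = NA_integer_
  )
  reads$quality <- strrep("I", nchar(reads$sequence))
  trimmed <- trim_reads(reads, refs)
  expect_equal(trimmed$status, c("ok", "ok", "short_insert"))
  expect_equal(trimmed$insert[1], refs$sequence)
  expect_equal(trimmed$insert[2], refs$sequence)
  expect_equal(nchar(trimmed$insert_quality[1]), nchar(refs$sequence))
  # a read with a garbled primer region is rejected
  bad <- dplyr::mutate(reads[1, ], sequence = paste0(strrep("A", 36),
    substring(sequence, 37)))
  expect_equal(trim_reads(bad, refs)$status, "no_tag")
})

test_that("alignment accepts exact segments and rejects short overlaps", {
  refs <- fixture_refs(n = 2, length = 200, seed = 41)
  exact <- substr(refs$sequence[1], 41, 160)
  # only 25 bp of this read can align; the rest is the other amplicon
  chimera <- paste0(substr(refs$sequence[1], 1, 25),
    substr(refs$sequence[2], 100, 174))
  trimmed <- tibble::tibble(
    read_id = c("exact", "chimera"), pool = "A1", status = "ok",
    amplicon_hint = "amp01",
    insert = c(exact, chimera),
    insert_quality = strrep("I", nchar(c(exact, chimera))),
    original_length = nchar(c(exact, chimera)) + 59L
  )
  aln <- align_to_amplicons(trimmed, refs, seed = 1)
  ex <- aln[aln$read_id == "exact", ]
  expect_true(ex$accepted)
  expect_equal(ex$similarity, 1.0)
  expect_equal(ex$aligned_fraction, 1.0)
  expect_equal(ex$amplicon, "amp01")
  expect_equal(ex$ref_start, 41)
  ch <- aln[aln$read_id == "chimera", ]
  expect_false(ch$accepted)
  expect_lt(ch$aligned_fraction, 0.8)
  expect_error(
    align_to_amplicons(trimmed, refs, costs = c(mismatch = 2, insertion = 3, deletion = 4)),
    "equal"
  )
})

test_that("non-specific matches are assigned randomly between tied references", {
  base <- fixture_refs(n = 1, length = 150, seed = 51)
  twins <- amplicon_set(c("copyA", "copyB"), rep(base$sequence, 2),
    rep(base$forward_primer, 2), rep(base$reverse_primer, 2))
  insert <- substr(base$sequence, 11, 140)
  trimmed <- tibble::tibble(
    read_id = sprintf("r%03d", 1:400), pool = "A1", status = "ok",
    amplicon_hint = "copyA", insert = insert,
    insert_quality = strrep("I", nchar(insert)),
    original_length = nchar(insert) + 59L
  )
  aln <- align_to_amplicons(trimmed, twins, seed = 1)
  share <- mean(aln$amplicon == "copyA")
  expect_gt(share, 0.4) # binomial(400, 0.5): +-3 SD is about 0.075
  expect_lt(share, 0.6)
  # and seeded tie-breaking reproduces
  aln2 <- align_to_amplicons(trimmed, twins, seed = 1)
  expect_identical(aln$amplicon, aln2$amplicon)
})

test_that("pileup applies the central and neighbourhood quality filters", {
  refs <- fixture_refs(n = 1, length = 100, seed = 71)
  perfect <- tibble::tibble(
    read_id = "r1", pool = "A1", status = "ok", amplicon_hint = refs$id,
    insert = refs$sequence, insert_quality = strrep("?", 100), # Q30
    original_length = 160L
  )
  aln <- align_to_amplicons(perfect, refs, seed = 1)
  counts <- pileup(aln, refs)
  cov <- counts$A + counts$C + counts$G + counts$T
  expect_equal(nrow(counts), 100)
  expect_true(all(cov == 1)) # one perfect read covers every position once

  # a base below the central quality threshold is excluded at its position
  qual <- rep(30L, 100)
  qual[50] <- 10L
  lowq <- dplyr::mutate(perfect,
    insert_quality = rawToChar(as.raw(qual + 33L)))
  counts2 <- pileup(align_to_amplicons(lowq, refs, seed = 1), refs)
  cov2 <- counts2$A + counts2$C + counts2$G + counts2$T
  expect_equal(cov2[counts2$position == 50], 0)
  expect_equal(cov2[counts2$position == 49], 1)

  # a read with many clustered mismatches loses that window: transversion at
  # every position 46..53 guarantees 8 mismatches within +-5 of position 50
  noisy_insert <- refs$sequence
  for (p in 46:53) {
    rb <- substr(refs$sequence, p, p)
    substr(noisy_insert, p, p) <- chartr("ACGT", "TGCA", rb)
  }
  noisy <- dplyr::mutate(perfect, insert = noisy_insert)
  aln3 <- align_to_amplicons(noisy, refs, seed = 1)
  counts3 <- pileup(aln3, refs)
  cov3 <- counts3$A + counts3$C + counts3$G + counts3$T
  expect_equal(cov3[counts3$position == 50], 0) # > 5 bad columns in window
  expect_equal(cov3[counts3$position == 1], 1)
})

test_that("read pipeline counts agree with direct count simulation", {
  run <- local_read_run(junk = 0.1, seed = 17, coverage = 250)
  reads <- read_fastq(run$fastq)
  dem <- demultiplex(reads, run$barcodes)
  trimmed <- trim_reads(dem, run$refs)
  aln <- align_to_amplicons(trimmed, run$refs, seed = 3)
  counts <- pileup(aln, run$refs)
  m <- run$truth$mutations
  hit <- counts[counts$amplicon == m$amplicon & counts$position == m$position, ]
  hit$cov <- hit$A + hit$C + hit$G + hit$T
  hit$freq <- hit[[m$alt]] / hit$cov
  # HOM singleton: expected fraction = 1/pool_size in each member pool
  sizes <- pool_sizes(run$scheme)
  pools3 <- unlist(pools_of_individual(run$scheme, m$plate, m$row, m$column))
  for (p in pools3) {
    expected <- 1 / sizes$size[sizes$pool == p]
    obs <- hit$freq[hit$pool == p]
    n <- hit$cov[hit$pool == p]
    expect_lt(abs(obs - expected), 4 * sqrt(expected * (1 - expected) / n) + 0.01)
  }
  # non-member pools stay near the error floor
  expect_true(all(hit$freq[!hit$pool %in% pools3] < 0.05))
})
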