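make_counts <- function(rows) {
  out <- tibble::as_tibble(rows)
  structure(out, class = c("allele_counts", class(out)))
}

test_that("frequency tables apply coverage, frequency and allele-cap rules", {
  counts <- make_counts(tibble::tibble(
    pool = "A1", amplicon = "g1", position = 1:3, ref = "C",
    A = c(5L, 2L, 0L), C = c(4995L, 78L, 5000L), G = 0L, T = 0L,
    ins = 0L, del = 0L
  ))
  freq <- frequency_table(counts)
  # 5 / 5000 = 0.001 is reported
  expect_equal(freq$frequency[freq$position == 1], 0.001)
  expect_equal(freq$change[freq$position == 1], "C>A")
  # coverage 80 is below the 100x call threshold -> position skipped
  expect_false(2 %in% freq$position)
  # no non-reference alleles at position 3
  expect_false(3 %in% freq$position)

  # allele cap: 5 variant alleles present, only the 4 most frequent retained
  many <- make_counts(tibble::tibble(
    pool = "A1", amplicon = "g1", position = 1L, ref = "C",
    A = 50L, C = 4000L, G = 40L, T = 30L, ins = 20L, del = 10L
  ))
  freq2 <- frequency_table(many)
  expect_equal(nrow(freq2), 4)
  expect_false("del" %in% freq2$allele)
  # denominator excludes indel observations
  expect_equal(freq2$coverage[1], 4120)
})

test_that("homopolymer filter removes only indels in/next to runs", {
  refs <- amplicon_set("g1", "ATCGGGGATCTAGCTAGCTACGATCGATCGTA",
    forward_primer = "ACGTACGTACGTACGTACGT",
    reverse_primer = "TGCATGCATGCATGCATGCA")
  base <- tibble::tibble(
    pool = "A1", amplicon = "g1", ref = "G",
    count = 50L, coverage = 5000, frequency = 0.01
  )
  freq <- dplyr::bind_rows(
    dplyr::mutate(base, position = 5L, allele = "del", type = "deletion", change = "G>del"),
    dplyr::mutate(base, position = 8L, allele = "ins", type = "insertion", change = "A>ins"),
    dplyr::mutate(base, position = 5L, allele = "A", type = "substitution", change = "G>A"),
    dplyr::mutate(base, position = 20L, allele = "del", type = "deletion", change = "C>del")
  )
  class(freq) <- c("frequency_table", class(freq))
  kept <- filter_homopolymer_indels(freq, refs)
  # deletion inside GGGG (pos 5) and insertion adjacent to it (pos 8) removed
  expect_false(any(kept$type == "deletion" & kept$position == 5))
  expect_false(any(kept$type == "insertion" & kept$position == 8))
  # substitutions are never removed, even inside the run
  expect_true(any(kept$type == "substitution" & kept$position == 5))
  # indel far from any run is retained
  expect_true(any(kept$type == "deletion" & kept$position == 20))
})

test_that("a single elevated pool is flagged with the documented z-score", {
  scheme <- build_scheme(8, 8, 12)
  freq <- fixture_frequency_table(scheme, c(rep(0.001, 27), 0.006))
  flags <- detect_outlier_pools(freq, scheme)
  flagged <- flags[flags$flagged, ]
  expect_equal(nrow(flagged), 1)
  expect_equal(flagged$pool, pool_ids(scheme)[28])
  expect_equal(flagged$z, 5.10, tolerance = 0.01)

  # all pools identical -> z = 0 everywhere, nothing flagged
  same <- fixture_frequency_table(scheme, rep(0.003, 28))
  expect_equal(sum(detect_outlier_pools(same, scheme)$flagged), 0)

  # with the scored pool included in mu/sigma, a lone outlier's z is capped
  # at (n-1)/sqrt(n) ~ 5.1 for 28 pools, so it always sits inside the band;
  # the upper cutoff bites in leave-one-out scoring, where the background SD
  # is tiny and a gross artifact shoots far past it
  extreme <- fixture_frequency_table(scheme, c(rep(0.0010, 26), 0.0011, 0.2))
  fl <- detect_outlier_pools(extreme, scheme)
  top <- fl[fl$frequency == 0.2, ]
  expect_lt(top$z, 27 / sqrt(28) + 1e-6)
  expect_true(top$flagged)
  fl_loo <- detect_outlier_pools(extreme, scheme, caller_config(loo = TRUE))
  top_loo <- fl_loo[fl_loo$frequency == 0.2, ]
  expect_gt(top_loo$z, 10)
  expect_false(top_loo$flagged)
  expect_true(top_loo$artifact)

  # degenerate sigma: identical frequencies above the candidate threshold
  # are flagged through the infinite-z sentinel
  degen <- fixture_frequency_table(scheme, rep(0.006, 28))
  fl2 <- detect_outlier_pools(degen, scheme)
  expect_true(all(is.infinite(fl2$z)))
  expect_equal(sum(fl2$flagged), 28)
})

test_that("outlier detection matches the brute-force oracle on random tables", {
  scheme <- build_scheme(8, 8, 12)
  for (seed in 1:8) {
    freq <- random_frequency_table(scheme, n_variants = 5, seed = seed)
    for (cfg in list(caller_config(), caller_config(loo = TRUE))) {
      got <- detect_outlier_pools(freq, scheme, cfg) |>
        dplyr::arrange(amplicon, position, change, pool)
      want <- oracle_outlier_pools(freq, scheme, cfg) |>
        dplyr::arrange(amplicon, position, change, pool)
      expect_equal(got$pool, want$pool)
      expect_equal(got$frequency, want$frequency)
      expect_equal(got$z, want$z, tolerance = 1e-8)
      expect_identical(got$flagged, want$flagged)
    }
  }
})

test_that("raising the candidate frequency threshold never adds flags", {
  scheme <- build_scheme(8, 8, 12)
  freq <- random_frequency_table(scheme, n_variants = 8, seed = 99)
  thresholds <- c(0.003, 0.005, 0.008)
  n_flags <- vapply(thresholds, function(t) {
    sum(detect_outlier_pools(freq, scheme,
      caller_config(min_frequency_candidate = t))$flagged)
  }, numeric(1))
  expect_true(all(diff(n_flags) <= 0))
})

test_that("candidates are deconvolved, tiered and sorted", {
  scheme <- build_scheme(8, 8, 12)
  base <- tibble::tibble(
    amplicon = "g1", ref = "G", allele = "A", type = "substitution",
    change = "G>A", frequency = 0.008, coverage = 5000, mu = 0.001,
    sigma = 0.001, z = 5, artifact = FALSE, flagged = TRUE
  )
  flags <- dplyr::bind_rows(
    dplyr::mutate(base[rep(1, 3), ], position = 54L, pool = c("A3", "B5", "C2")),
    dplyr::mutate(base[rep(1, 2), ], position = 70L, pool = c("A3", "B5"),
      frequency = 0.012),
    dplyr::mutate(base, position = 90L, pool = "A3", change = "T>C",
      ref = "T", allele = "C")
  )
  class(flags) <- c("pool_flags", class(flags))
  cands <- call_candidates(flags, scheme)
  expect_equal(nrow(cands), 3)
  three <- cands[cands$position == 54, ]
  expect_equal(three$tier, 99L)
  expect_equal(three$wells, "(3,2,5)")
  expect_equal(three$n_wells, 1L)
  expect_true(three$ems_consistent)
  two <- cands[cands$position == 70, ]
  expect_equal(two$tier, 85L)
  expect_equal(two$n_wells, 8L)
  one <- cands[cands$position == 90, ]
  expect_equal(one$tier, 75L)
  expect_equal(one$n_wells, 0L)
  expect_false(one$ems_consistent)
  # sorted by tier, then max frequency
  expect_equal(cands$tier, c(99L, 85L, 75L))
  # min_pools above 1 drops the single-pool candidate
  cands2 <- call_candidates(flags, scheme, caller_config(min_pools = 2))
  expect_false(90 %in% cands2$position)
})

test_that("complementary replicate flags merge before deconvolution", {
  scheme <- build_scheme(8, 8, 12)
  base <- tibble::tibble(
    amplicon = "g1", position = 54L, ref = "G", allele = "A",
    type = "substitution", change = "G>A", coverage = 5000,
    mu = 0.001, sigma = 0.001, artifact = FALSE
  )
  rep1 <- dplyr::mutate(base[rep(1, 2), ], pool = c("A3", "B5"),
    frequency = 0.008, z = 5, flagged = TRUE)
  rep2 <- dplyr::mutate(base[rep(1, 2), ], pool = c("B5", "C2"),
    frequency = 0.007, z = 4, flagged = TRUE)
  class(rep1) <- class(rep2) <- c("pool_flags", class(rep1))
  merged <- merge_flag_tables(rep1, rep2)
  cands <- call_candidates(merged, scheme)
  expect_equal(nrow(cands), 1)
  expect_equal(cands$tier, 99L) # three pools only by union of replicates
  expect_equal(cands$wells, "(3,2,5)")
})

test_that("candidate tables round-trip as TSV and emit valid VCF", {
  scheme <- build_scheme(8, 8, 12)
  base <- tibble::tibble(
    amplicon = "g1", position = 54L, ref = "G", allele = "A",
    type = "substitution", change = "G>A", frequency = 0.008,
    coverage = 5000, mu = 0.001, sigma = 0.001, z = 5,
    artifact = FALSE, flagged = TRUE
  )
  flags <- dplyr::mutate(base[rep(1, 3), ], pool = c("A3", "B5", "C2"))
  class(flags) <- c("pool_flags", class(flags))
  cands <- call_candidates(flags, scheme)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_candidates(cands, tsv)
  back <- read_candidates(tsv)
  expect_equal(as.data.frame(back), as.data.frame(cands))
  # header-only file for an empty candidate set
  empty <- cands[0, ]
  tsv0 <- withr::local_tempfile(fileext = ".tsv")
  write_candidates(empty, tsv0)
  expect_equal(nrow(read_candidates(tsv0)), 0)

  refs <- amplicon_set("g1", strrep("ACGT", 30),
    forward_primer = "ACGTACGTACGTACGTACGT",
    reverse_primer = "TGCATGCATGCATGCATGCA")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_candidates(cands, vcf, format = "vcf", refs = refs)
  lines <- readLines(vcf)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 1)
  fields <- strsplit(body, "\t")[[1]]
  expect_equal(fields[1], "g1")
  expect_equal(fields[2], "54")
  expect_equal(fields[4], "G")
  expect_equal(fields[5], "A")
  skip_if_not_installed("vcfR")
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  expect_equal(nrow(v@fix), 1)
  expect_equal(unname(v@fix[1, "POS"]), "54")
})
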