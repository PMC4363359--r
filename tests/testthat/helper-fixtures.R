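# Shared fixture builders; everything is generated in code at test time.

# small reference set with reproducible sequences
fixture_refs <- function(n = 2, length = 120, seed = 11) {
  demo_amplicons(n = n, length = length, seed = seed)
}

# k-th G position of an amplicon (guaranteed EMS-mutable site)
nth_base_position <- function(refs, amplicon, base = "G", k = 3) {
  ch <- strsplit(refs$sequence[refs$id == amplicon], "")[[1]]
  pos <- which(ch == base)
  pos[min(k, length(pos))]
}

# single explicit planted mutation in well (plate, row, column)
fixture_mutation <- function(refs, amplicon = refs$id[1], plate = 1, row = 1,
                             column = 1, zygosity = "HET", base = "G", k = 3) {
  tibble::tibble(
    plate = as.integer(plate), row = as.integer(row),
    column = as.integer(column), amplicon = amplicon,
    position = as.integer(nth_base_position(refs, amplicon, base, k)),
    zygosity = zygosity
  )
}

# hand-built frequency table over all pools of a scheme for one substitution
fixture_frequency_table <- function(scheme, frequencies, coverage = 5000,
                                    amplicon = "g1", position = 3L,
                                    ref = "G", allele = "A") {
  pools <- pool_ids(scheme)
  stopifnot(length(frequencies) == length(pools))
  out <- tibble::tibble(
    pool = pools, amplicon = amplicon, position = position, ref = ref,
    allele = allele, type = "substitution",
    change = paste0(ref, ">", allele),
    count = as.integer(round(frequencies * coverage)),
    coverage = coverage, frequency = frequencies
  )
  structure(out, class = c("frequency_table", class(out)))
}

# independent brute-force oracle for the SD-band outlier detector: plain
# loops over variants and pools, mean/sd/z computed directly
oracle_outlier_pools <- function(freq, scheme, config = caller_config()) {
  pools <- pool_ids(scheme)
  variants <- unique(freq[, c("amplicon", "position", "change")])
  out <- list()
  for (v in seq_len(nrow(variants))) {
    rows <- freq[freq$amplicon == variants$amplicon[v] &
      freq$position == variants$position[v] &
      freq$change == variants$change[v], ]
    f <- numeric(length(pools))
    cov <- numeric(length(pools))
    for (i in seq_along(pools)) {
      hit <- rows[rows$pool == pools[i], ]
      f[i] <- if (nrow(hit)) hit$frequency[1] else 0
      cov[i] <- if (nrow(hit)) hit$coverage[1] else 0
    }
    for (i in seq_along(pools)) {
      if (config$loo) {
        mu <- mean(f[-i]); sigma <- stats::sd(f[-i])
      } else {
        mu <- mean(f); sigma <- stats::sd(f)
      }
      degenerate <- is.na(sigma) || sigma < 1e-9
      z <- if (degenerate) (if (f[i] > 0) Inf else 0) else (f[i] - mu) / sigma
      gates <- cov[i] >= config$min_coverage_candidate &&
        f[i] >= config$min_frequency_candidate
      flagged <- gates && ((is.infinite(z) && z > 0) ||
        (is.finite(z) && z >= config$lower_sd_cutoff && z <= config$upper_sd_cutoff))
      out[[length(out) + 1]] <- tibble::tibble(
        amplicon = variants$amplicon[v], position = variants$position[v],
        change = variants$change[v], pool = pools[i],
        frequency = f[i], z = z, flagged = flagged
      )
    }
  }
  dplyr::bind_rows(out)
}

# randomized frequency table across all pools (several variants, zeros mixed in)
random_frequency_table <- function(scheme, n_variants = 6, seed = 1) {
  withr::with_seed(seed, {
    pools <- pool_ids(scheme)
    rows <- lapply(seq_len(n_variants), function(v) {
      ref <- sample(c("A", "C", "G", "T"), 1)
      allele <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      n_present <- sample.int(length(pools), 1)
      present <- sample(pools, n_present)
      tibble::tibble(
        pool = present, amplicon = "g1", position = v * 10L, ref = ref,
        allele = allele, type = "substitution",
        change = paste0(ref, ">", allele),
        count = 0L,
        coverage = sample(c(80, 400, 600, 3000, 5000), n_present, replace = TRUE),
        frequency = round(stats::runif(n_present, 0, 0.012), 5)
      )
    })
    out <- dplyr::bind_rows(rows)
    structure(out, class = c("frequency_table", class(out)))
  })
}
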