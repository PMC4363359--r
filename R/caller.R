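#' Variant-caller configuration
#'
#' Two threshold tiers mirror the screening workflow: permissive *call*
#' thresholds build the frequency table (coverage >= 100, frequency >= 0.1%,
#' at most 4 alleles per position), and stricter *candidate* thresholds gate
#' which pools can be flagged as carrying a rare variant (coverage >= 500,
#' frequency >= 0.5%). A pool is flagged when its frequency z-score across
#' all pools lies within the standard-deviation band
#' `[lower_sd_cutoff, upper_sd_cutoff]`: below the band is indistinguishable
#' from noise, above it is treated as a systematic artifact (e.g. recurrent
#' mismapping) rather than a one-individual allele.
#'
#' @param min_coverage_call,min_frequency_call Frequency-table thresholds.
#' @param min_coverage_candidate,min_frequency_candidate Pool-flagging
#'   thresholds.
#' @param max_alleles Maximum variant alleles kept per pool and position.
#' @param lower_sd_cutoff,upper_sd_cutoff z-score band for flagging.
#' @param min_pools Minimum flagged pools for a candidate to be reported.
#' @param homopolymer_min_run Minimum run length for the homopolymer-indel
#'   filter.
#' @param loo Use leave-one-out mean/SD when scoring each pool (default
#'   FALSE: the scored pool is included, matching the screening script's
#'   description).
#' @return List of class `caller_config`.
#' @export
caller_config <- function(min_coverage_call = 100,
                          min_frequency_call = 0.001,
                          min_coverage_candidate = 500,
                          min_frequency_candidate = 0.005,
                          max_alleles = 4,
                          lower_sd_cutoff = 2,
                          upper_sd_cutoff = 10,
                          min_pools = 1,
                          homopolymer_min_run = 3,
                          loo = FALSE) {
  if (min_coverage_candidate < min_coverage_call ||
    min_frequency_candidate < min_frequency_call) {
    abort("Candidate thresholds must be at least the call thresholds.")
  }
  if (lower_sd_cutoff >= upper_sd_cutoff) {
    abort("`lower_sd_cutoff` must be below `upper_sd_cutoff`.")
  }
  structure(list(
    min_coverage_call = min_coverage_call,
    min_frequency_call = min_frequency_call,
    min_coverage_candidate = min_coverage_candidate,
    min_frequency_candidate = min_frequency_candidate,
    max_alleles = as.integer(max_alleles),
    lower_sd_cutoff = lower_sd_cutoff,
    upper_sd_cutoff = upper_sd_cutoff,
    min_pools = as.integer(min_pools),
    homopolymer_min_run = as.integer(homopolymer_min_run),
    loo = isTRUE(loo)
  ), class = "caller_config")
}

#' Per-pool variant frequency table
#'
#' Converts an allele-count table into variant frequencies. The denominator
#' at each position is the total base coverage (`A+C+G+T`; indel observations
#' are excluded from the denominator). Positions below `min_coverage_call`
#' are skipped; non-reference alleles below `min_frequency_call` are dropped;
#' at most `max_alleles` alleles are kept per pool and position (highest
#' frequencies win).
#'
#' @param counts An `allele_counts` tibble.
#' @param config A [caller_config()].
#' @return Tibble of class `frequency_table` with columns `pool`, `amplicon`,
#'   `position`, `ref`, `allele`, `type` (substitution/insertion/deletion),
#'   `change` (e.g. `"G>A"`), `count`, `coverage`, `frequency`.
#' @export
frequency_table <- function(counts, config = caller_config()) {
  out <- as_tibble(counts) |>
    mutate(coverage = .data$A + .data$C + .data$G + .data$T) |>
    filter(.data$coverage >= config$min_coverage_call) |>
    tidyr::pivot_longer(all_of(c(BASES, "ins", "del")),
      names_to = "allele", values_to = "count") |>
    filter(.data$allele != .data$ref, .data$count > 0) |>
    mutate(
      frequency = .data$count / .data$coverage,
      type = case_when(
        .data$allele == "ins" ~ "insertion",
        .data$allele == "del" ~ "deletion",
        TRUE ~ "substitution"
      ),
      change = paste0(.data$ref, ">", .data$allele)
    ) |>
    filter(.data$frequency >= config$min_frequency_call) |>
    arrange(.data$pool, .data$amplicon, .data$position,
      dplyr::desc(.data$frequency)) |>
    # keep the max_alleles most frequent alleles per pool and position
    # (base rank within runs: far faster than grouped slice_max here)
    (\(x) {
      key <- paste(x$pool, x$amplicon, x$position, sep = "\r")
      rank_in_group <- sequence(rle(key)$lengths)
      x[rank_in_group <= config$max_alleles, ]
    })() |>
    select("pool", "amplicon", "position", "ref", "allele", "type", "change",
      "count", "coverage", "frequency") |>
    arrange(.data$amplicon, .data$position, .data$pool)
  structure(out, class = c("frequency_table", class(out)))
}

#' Remove indel variants in homopolymer context
#'
#' Spurious indels inside homopolymer tracts are the dominant artifact of
#' flow-based sequencing. This filter removes insertion/deletion variants
#' whose position lies within, or immediately adjacent to, a reference
#' homopolymer run of at least `homopolymer_min_run` bases. Substitutions
#' are never removed.
#'
#' @param freq A `frequency_table`.
#' @param refs An `amplicon_set`.
#' @param config A [caller_config()].
#' @return The filtered `frequency_table`.
#' @export
filter_homopolymer_indels <- function(freq, refs, config = caller_config()) {
  masks <- lapply(setNames(refs$sequence, refs$id), homopolymer_mask,
    min_run = config$homopolymer_min_run)
  in_hp <- purrr::map2_lgl(freq$amplicon, freq$position, function(a, p) {
    m <- masks[[a]]
    !is.null(m) && p >= 1 && p <= length(m) && m[p]
  })
  out <- freq[freq$type == "substitution" | !in_hp, ]
  structure(out, class = unique(c("frequency_table", class(out))))
}

#' Flag outlier pools per variant by a standard-deviation band
#'
#' For each (amplicon, position, substitution), the variant frequency of
#' every pool of the scheme (zero when the pool shows no such variant) is
#' summarised by its mean and standard deviation, and each pool receives a
#' z-score. A pool is flagged as carrying the variant when its coverage is
#' at least `min_coverage_candidate`, its frequency at least
#' `min_frequency_candidate`, and its z-score lies inside
#' `[lower_sd_cutoff, upper_sd_cutoff]`. When the across-pool SD is zero,
#' pools above the frequency threshold are flagged with an infinite z-score
#' sentinel. Pools whose finite z-score exceeds the upper cutoff are marked
#' `artifact` and not flagged.
#'
#' @param freq A `frequency_table`.
#' @param scheme The `pooling_scheme` the counts came from (at least 3 pools).
#' @param config A [caller_config()].
#' @return Tibble of class `pool_flags` with one row per pool and variant:
#'   frequencies, `mu`, `sigma`, `z`, `flagged`, `artifact`.
#' @export
detect_outlier_pools <- function(freq, scheme, config = caller_config()) {
  pools <- pool_ids(scheme)
  if (length(pools) < 3) {
    abort("Outlier detection needs at least 3 pools.", class = "poolscreen_insufficient_data")
  }
  variants <- distinct(freq, .data$amplicon, .data$position, .data$ref,
    .data$allele, .data$type, .data$change)
  if (!nrow(variants)) {
    empty <- tibble(
      amplicon = character(0), position = integer(0), ref = character(0),
      allele = character(0), type = character(0), change = character(0),
      pool = character(0), frequency = numeric(0), coverage = numeric(0),
      mu = numeric(0), sigma = numeric(0), z = numeric(0),
      flagged = logical(0), artifact = logical(0)
    )
    return(structure(empty, class = c("pool_flags", class(empty))))
  }
  full <- tidyr::expand_grid(variants, pool = pools) |>
    left_join(
      freq[, c("amplicon", "position", "change", "pool", "frequency", "coverage")],
      by = c("amplicon", "position", "change", "pool")
    ) |>
    mutate(
      frequency = dplyr::coalesce(.data$frequency, 0),
      coverage = dplyr::coalesce(.data$coverage, 0)
    )
  scored <- full |>
    group_by(.data$amplicon, .data$position, .data$change) |>
    mutate(
      n_pools_total = dplyr::n(),
      f_sum = sum(.data$frequency),
      f_sumsq = sum(.data$frequency^2)
    ) |>
    ungroup() |>
    mutate(z_band_scores(.data$frequency, .data$n_pools_total, .data$f_sum,
      .data$f_sumsq, loo = config$loo)) |>
    select(-"n_pools_total", -"f_sum", -"f_sumsq")
  scored |>
    mutate(
      over_gates = .data$coverage >= config$min_coverage_candidate &
        .data$frequency >= config$min_frequency_candidate,
      flagged = .data$over_gates & (
        (is.infinite(.data$z) & .data$z > 0) |
          (is.finite(.data$z) & .data$z >= config$lower_sd_cutoff &
            .data$z <= config$upper_sd_cutoff)
      ),
      artifact = .data$over_gates & is.finite(.data$z) &
        .data$z > config$upper_sd_cutoff
    ) |>
    select(-"over_gates") |>
    (\(x) structure(x, class = c("pool_flags", class(x))))()
}

# mean/sd/z across the pools of a variant group, vectorised over rows via
# per-group sums; sd == 0 (within floating-point tolerance) yields an
# infinite-z sentinel for any pool with a positive frequency
z_band_scores <- function(f, n, f_sum, f_sumsq, loo = FALSE) {
  if (loo) {
    mu <- (f_sum - f) / (n - 1)
    var <- (f_sumsq - f^2 - (n - 1) * mu^2) / (n - 2)
  } else {
    mu <- f_sum / n
    var <- (f_sumsq - n * mu^2) / (n - 1)
  }
  sigma <- sqrt(pmax(var, 0))
  degenerate <- sigma < 1e-9
  z <- ifelse(degenerate, ifelse(f > 0, Inf, 0), (f - mu) / sigma)
  tibble(mu = mu, sigma = ifelse(degenerate, 0, sigma), z = z)
}

#' Merge flag tables from replicate runs
#'
#' Technical replicates of the same screen may each flag a complementary
#' subset of a variant's intersecting pools; merging unions the flags before
#' deconvolution so complementary replicates still resolve the individual.
#'
#' @param ... Two or more `pool_flags` tibbles from the same scheme.
#' @return A merged `pool_flags` tibble (per pool and variant: `flagged` is
#'   the union, frequencies/coverage/z are the per-pool maxima).
#' @export
merge_flag_tables <- function(...) {
  tabs <- list(...)
  merged <- bind_rows(tabs) |>
    group_by(.data$amplicon, .data$position, .data$ref, .data$allele,
      .data$type, .data$change, .data$pool) |>
    summarise(
      frequency = max(.data$frequency), coverage = max(.data$coverage),
      mu = mean(.data$mu), sigma = mean(.data$sigma), z = max(.data$z),
      flagged = any(.data$flagged), artifact = any(.data$artifact),
      .groups = "drop"
    )
  structure(merged, class = c("pool_flags", class(merged)))
}

#' Call deconvolved, confidence-tiered variant candidates
#'
#' Flagged pools are grouped per variant and deconvolved against the pooling
#' scheme. Candidates resolved in all three dimensions get confidence tier
#' 99, two-dimensional intersections (re-sequence the whole subset) tier 85,
#' and single-pool signals tier 75. `ems_consistent` marks the canonical
#' mutagen signature (G>A / C>T).
#'
#' @param flags A `pool_flags` tibble (see [detect_outlier_pools()]).
#' @param scheme The `pooling_scheme`.
#' @param config A [caller_config()].
#' @return Tibble of class `variant_candidates`, sorted by tier then maximum
#'   pool frequency: `amplicon`, `position`, `ref`, `allele`, `change`,
#'   `type`, `n_pools`, `pools`, `frequencies`, `max_frequency`, `wells`,
#'   `n_wells`, `resolution`, `ambiguous`, `tier`, `ems_consistent`.
#' @export
call_candidates <- function(flags, scheme, config = caller_config()) {
  flagged <- flags[flags$flagged, ]
  groups <- flagged |>
    group_by(.data$amplicon, .data$position, .data$ref, .data$allele,
      .data$type, .data$change) |>
    dplyr::group_split()
  rows <- purrr::map_dfr(groups, function(g) {
    if (nrow(g) < config$min_pools) return(NULL)
    dec <- deconvolve(scheme, g$pool)
    tier <- switch(dec$resolution, INDIVIDUAL = 99L, SUBSET = 85L, 75L)
    tibble(
      amplicon = g$amplicon[1], position = g$position[1], ref = g$ref[1],
      allele = g$allele[1], change = g$change[1], type = g$type[1],
      n_pools = nrow(g),
      pools = paste(g$pool, collapse = ","),
      frequencies = paste(sprintf("%.5f", g$frequency), collapse = ","),
      max_frequency = max(g$frequency),
      wells = format_wells(dec$candidates),
      n_wells = dec$n_candidates,
      resolution = dec$resolution,
      ambiguous = dec$ambiguous,
      tier = tier,
      ems_consistent = g$change[1] %in% c("G>A", "C>T")
    )
  })
  if (is.null(rows) || !nrow(rows)) {
    rows <- tibble(
      amplicon = character(0), position = integer(0), ref = character(0),
      allele = character(0), change = character(0), type = character(0),
      n_pools = integer(0), pools = character(0), frequencies = character(0),
      max_frequency = numeric(0), wells = character(0), n_wells = integer(0),
      resolution = character(0), ambiguous = logical(0), tier = integer(0),
      ems_consistent = logical(0)
    )
  }
  rows <- arrange(rows, dplyr::desc(.data$tier), dplyr::desc(.data$max_frequency))
  structure(rows, class = c("variant_candidates", class(rows)))
}

#' Write candidates as TSV or VCF
#'
#' The TSV mirrors the screening report layout (gene, position, change,
#' flagged pools and frequencies, deconvolved wells, tier) and round-trips
#' through [read_candidates()]. The VCF (4.2) writes one record per
#' substitution candidate with the amplicon as contig and INFO fields for
#' pools, frequencies, tier, wells, resolution and the mutagen-signature
#' flag; insertion/deletion candidates have no allele sequence in the count
#' table and are skipped with a warning.
#'
#' @param candidates A `variant_candidates` tibble.
#' @param path Output path.
#' @param format `"tsv"` or `"vcf"`.
#' @param refs Optional `amplicon_set`, used for VCF contig lengths.
#' @return The path, invisibly.
#' @export
write_candidates <- function(candidates, path, format = c("tsv", "vcf"),
                             refs = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(as_tibble(candidates), path)
    return(invisible(path))
  }
  subs <- candidates[candidates$type == "substitution", ]
  if (nrow(subs) < nrow(candidates)) {
    warn("Indel candidates are not representable in VCF output; skipped.")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=poolscreen-%s", utils::packageVersion("poolscreen")),
    if (!is.null(refs)) {
      sprintf("##contig=<ID=%s,length=%d>", refs$id, nchar(refs$sequence))
    },
    "##INFO=<ID=POOLS,Number=.,Type=String,Description=\"Flagged pools\">",
    "##INFO=<ID=PFREQ,Number=.,Type=Float,Description=\"Variant frequency in each flagged pool\">",
    "##INFO=<ID=TIER,Number=1,Type=Integer,Description=\"Confidence tier (percent)\">",
    "##INFO=<ID=WELLS,Number=.,Type=String,Description=\"Deconvolved candidate wells (plate,row,column)\">",
    "##INFO=<ID=RES,Number=1,Type=String,Description=\"Deconvolution resolution\">",
    "##INFO=<ID=EMS,Number=0,Type=Flag,Description=\"EMS-consistent substitution (G>A or C>T)\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- if (nrow(subs)) {
    info <- sprintf(
      "POOLS=%s;PFREQ=%s;TIER=%d;WELLS=%s;RES=%s%s",
      subs$pools, subs$frequencies, subs$tier,
      ifelse(nzchar(subs$wells), gsub(";", "|", subs$wells), "."),
      subs$resolution,
      ifelse(subs$ems_consistent, ";EMS", "")
    )
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
      subs$amplicon, subs$position, subs$ref, subs$allele, info)
  } else {
    character(0)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  tab <- read_tsv_quiet(path, col_types = readr::cols(
    amplicon = "c", position = "i", ref = "c", allele = "c", change = "c",
    type = "c", n_pools = "i", pools = "c", frequencies = "c",
    max_frequency = "d", wells = "c", n_wells = "i", resolution = "c",
    ambiguous = "l", tier = "i", ems_consistent = "l"
  ))
  tab$wells <- dplyr::coalesce(tab$wells, "")
  structure(tab, class = c("variant_candidates", class(tab)))
}
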