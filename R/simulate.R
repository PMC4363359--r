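#' Ion-Torrent-like substitution/indel error model
#'
#' Substitution errors are parameterised by a mean per-base rate (default
#' 0.1%, the rate reported for the platform) and a multiplier per ordered
#' substitution type. The default multipliers elevate the G>A and T>C
#' transitions to twice the mean and scale the remaining ten types to 0.8 so
#' that the mean multiplier over all twelve types is exactly 1. In sampled
#' mode each run redraws every type's rate from a normal with standard
#' deviation `dispersion * rate` (truncated at zero), reflecting reported
#' run-to-run standard deviations of 26-56% of the mean substitution rate.
#' Spurious insertions/deletions concentrate in homopolymer tracts: positions
#' inside runs of at least `homopolymer_min_run` identical bases receive
#' indel observations at `homopolymer_factor` times the mean substitution
#' rate, all other positions at `indel_rate`.
#'
#' @param mean_substitution_rate Mean per-base substitution error (fraction).
#' @param multipliers Named positive vector over the 12 types `"X>Y"`;
#'   missing names default to 1.
#' @param dispersion Run-to-run SD of each type's rate as a fraction of it.
#' @param indel_rate Indel error rate outside homopolymer runs.
#' @param homopolymer_factor In-run indel rate as a multiple of the mean
#'   substitution rate.
#' @param homopolymer_min_run Minimum run length counted as a homopolymer.
#' @param max_rate Upper cap on any per-base rate.
#' @return List of class `error_model`.
#' @export
error_model <- function(mean_substitution_rate = 0.001,
                        multipliers = NULL,
                        dispersion = 0.4,
                        indel_rate = 0.0005,
                        homopolymer_factor = 5,
                        homopolymer_min_run = 3,
                        max_rate = 0.05) {
  if (mean_substitution_rate < 0 || mean_substitution_rate > max_rate) {
    abort("`mean_substitution_rate` must lie in [0, max_rate].")
  }
  types <- substitution_types()
  mult <- setNames(rep(0.8, length(types)), types)
  mult[c("G>A", "T>C")] <- 2
  if (!is.null(multipliers)) {
    bad <- setdiff(names(multipliers), types)
    if (length(bad)) abort(sprintf("Unknown substitution type(s): %s", paste(bad, collapse = ", ")))
    if (any(multipliers <= 0)) abort("Multipliers must be positive.")
    mult[names(multipliers)] <- multipliers
  }
  structure(list(
    mean_substitution_rate = mean_substitution_rate,
    multipliers = mult,
    dispersion = dispersion,
    indel_rate = indel_rate,
    homopolymer_factor = homopolymer_factor,
    homopolymer_min_run = as.integer(homopolymer_min_run),
    max_rate = max_rate
  ), class = "error_model")
}

# per-type substitution rates for one run; jittered in sampled mode
draw_run_rates <- function(err, sampled) {
  base <- pmin(err$mean_substitution_rate * err$multipliers, err$max_rate)
  if (!sampled || err$dispersion == 0) return(base)
  r <- rnorm(length(base), mean = base, sd = err$dispersion * base)
  setNames(pmin(pmax(r, 0), err$max_rate), names(base))
}

#' Coverage model for pooled amplicon sequencing
#'
#' Per-pool, per-amplicon sequencing depth is drawn lognormal with the given
#' mean and coefficient of variation (pools receive visibly unequal read
#' shares in practice). A fraction of 3' positions decays linearly to
#' `end_dropoff_floor` of full depth, emulating incomplete extensions. In
#' read simulation, `junk_read_fraction` of reads are ~50 bp primer-dimer
#' artifacts carrying no target sequence.
#'
#' @param mean_coverage Mean depth per pool and amplicon.
#' @param pool_cv Coefficient of variation of depth across pools (0 = fixed).
#' @param end_dropoff_fraction Fraction of 3' positions with decaying depth.
#' @param end_dropoff_floor Relative depth at the final position.
#' @param junk_read_fraction Fraction of artifact reads in FASTQ mode.
#' @return List of class `coverage_model`.
#' @export
coverage_model <- function(mean_coverage = 3000,
                           pool_cv = 0.5,
                           end_dropoff_fraction = 0.1,
                           end_dropoff_floor = 0.5,
                           junk_read_fraction = 0.2) {
  stopifnot(
    mean_coverage > 0, pool_cv >= 0,
    end_dropoff_fraction >= 0, end_dropoff_fraction <= 1,
    end_dropoff_floor >= 0, end_dropoff_floor <= 1,
    junk_read_fraction >= 0, junk_read_fraction <= 1
  )
  structure(list(
    mean_coverage = mean_coverage,
    pool_cv = pool_cv,
    end_dropoff_fraction = end_dropoff_fraction,
    end_dropoff_floor = end_dropoff_floor,
    junk_read_fraction = junk_read_fraction
  ), class = "coverage_model")
}

draw_depths <- function(cov, n, sampled) {
  if (!sampled || cov$pool_cv == 0) return(rep(cov$mean_coverage, n))
  sdlog <- sqrt(log(1 + cov$pool_cv^2))
  meanlog <- log(cov$mean_coverage) - sdlog^2 / 2
  rlnorm(n, meanlog, sdlog)
}

# multiplicative 3' coverage decay
dropoff_factor <- function(position, length, cov) {
  start <- ceiling((1 - cov$end_dropoff_fraction) * length)
  f <- rep(1, base::length(position))
  idx <- position > start & length > start
  if (any(idx)) {
    rel <- (position[idx] - start[idx]) / (length[idx] - start[idx])
    f[idx] <- 1 - rel * (1 - cov$end_dropoff_floor)
  }
  f
}

#' Plant EMS-style mutations in a screening population
#'
#' Either plants an explicit list of mutations or draws them at a genomic
#' density: the number of mutations per individual and amplicon is Poisson
#' with mean `density * amplicon_length` (the canonical EMS density is about
#' 1 mutation per 300 kb screened). With probability `ems_fraction` a
#' mutation is an EMS-type transition (G>A or C>T) planted at a random G/C
#' site; otherwise a random non-EMS substitution. Zygosity is homozygous with
#' probability `hom_fraction` (default 1/3, the expected segregation among
#' selfed M2 carriers).
#'
#' @param scheme A `pooling_scheme`.
#' @param refs An `amplicon_set`.
#' @param density Mutations per bp per individual (ignored when `mutations`
#'   is supplied).
#' @param mutations Optional explicit tibble with columns `plate`, `row`,
#'   `column`, `amplicon`, `position`, `alt` (optional: the EMS transition is
#'   used when omitted), `zygosity`.
#' @param ems_fraction Probability that a drawn mutation is G>A / C>T.
#' @param hom_fraction Probability that a carrier is homozygous.
#' @param seed Integer seed; drawing is deterministic given the seed.
#' @return Object of class `sim_truth`: a list carrying the `mutations`
#'   tibble (with `sample_id`, well, amplicon, `position`, `ref`, `alt`,
#'   `change`, `zygosity`) and the generating parameters.
#' @export
plant_mutations <- function(scheme, refs, density = 1 / 300000,
                            mutations = NULL, ems_fraction = 0.99,
                            hom_fraction = 1 / 3, seed = NULL) {
  stopifnot(nrow(refs) > 0, ems_fraction >= 0, ems_fraction <= 1,
    hom_fraction >= 0, hom_fraction <= 1, density >= 0)
  pos_tab <- ref_position_table(refs)
  if (!is.null(mutations)) {
    m <- as_tibble(mutations)
    req <- c("plate", "row", "column", "amplicon", "position", "zygosity")
    if (!all(req %in% names(m))) {
      abort(sprintf("Explicit `mutations` need columns: %s", paste(req, collapse = ", ")))
    }
    m <- left_join(m, pos_tab[, c("amplicon", "position", "ref")],
      by = c("amplicon", "position"))
    if (anyNA(m$ref)) abort("Explicit mutation at a position absent from the references.")
    if (!"alt" %in% names(m)) {
      m$alt <- unname(c(G = "A", C = "T", A = "G", T = "C")[m$ref])
    }
    if (any(m$alt == m$ref)) abort("`alt` must differ from the reference base.")
    if (any(!m$zygosity %in% c("HET", "HOM"))) abort("`zygosity` must be HET or HOM.")
    wells <- pools_of_individual(scheme, m$plate, m$row, m$column) # validates range
    ids <- left_join(m, as_tibble(scheme)[, c("sample_id", "plate", "row", "column")],
      by = c("plate", "row", "column"))
    if (anyNA(ids$sample_id)) abort("Explicit mutation in an unoccupied well.")
    m$sample_id <- ids$sample_id
    truth_tab <- m
  } else {
    truth_tab <- with_seed_if(seed, draw_density_mutations(
      scheme, refs, pos_tab, density, ems_fraction, hom_fraction))
  }
  truth_tab <- truth_tab |>
    mutate(change = paste0(.data$ref, ">", .data$alt)) |>
    select("sample_id", "plate", "row", "column", "amplicon", "position",
      "ref", "alt", "change", "zygosity") |>
    arrange(.data$amplicon, .data$position, .data$sample_id)
  structure(list(
    mutations = truth_tab,
    dims = scheme_dims(scheme),
    density = if (is.null(mutations)) density else NA_real_,
    ems_fraction = ems_fraction,
    hom_fraction = hom_fraction,
    seed = seed
  ), class = "sim_truth")
}

draw_density_mutations <- function(scheme, refs, pos_tab, density,
                                   ems_fraction, hom_fraction) {
  lens <- tibble(amplicon = refs$id, length = nchar(refs$sequence))
  grid <- tidyr::expand_grid(sample_id = scheme$sample_id, amplicon = lens$amplicon) |>
    left_join(lens, by = "amplicon")
  grid$n <- rpois(nrow(grid), density * grid$length)
  hits <- grid[grid$n > 0, ]
  if (!nrow(hits)) {
    empty <- tibble(
      sample_id = character(0), plate = integer(0), row = integer(0),
      column = integer(0), amplicon = character(0), position = integer(0),
      ref = character(0), alt = character(0), zygosity = character(0)
    )
    return(empty)
  }
  hits <- hits[rep(seq_len(nrow(hits)), hits$n), ]
  gc_sites <- split(pos_tab$position[pos_tab$ref %in% c("G", "C")],
    pos_tab$amplicon[pos_tab$ref %in% c("G", "C")])
  all_sites <- split(pos_tab$position, pos_tab$amplicon)
  ref_of <- setNames(pos_tab$ref, paste(pos_tab$amplicon, pos_tab$position))
  n <- nrow(hits)
  is_ems <- runif(n) < ems_fraction
  position <- integer(n)
  alt <- character(n)
  for (i in seq_len(n)) {
    amp <- hits$amplicon[i]
    sites <- if (is_ems[i] && length(gc_sites[[amp]])) gc_sites[[amp]] else all_sites[[amp]]
    position[i] <- sites[sample.int(length(sites), 1)]
    rb <- ref_of[[paste(amp, position[i])]]
    if (is_ems[i] && rb %in% c("G", "C")) {
      alt[i] <- if (rb == "G") "A" else "T"
    } else {
      # any substitution except the EMS transitions G>A and C>T
      opts <- setdiff(BASES, rb)
      if (rb == "G") opts <- setdiff(opts, "A")
      if (rb == "C") opts <- setdiff(opts, "T")
      alt[i] <- opts[sample.int(length(opts), 1)]
    }
  }
  out <- tibble(
    sample_id = hits$sample_id, amplicon = hits$amplicon,
    position = position,
    ref = unname(ref_of[paste(hits$amplicon, position)]),
    alt = alt,
    zygosity = ifelse(runif(n) < hom_fraction, "HOM", "HET")
  )
  out <- distinct(out, .data$sample_id, .data$amplicon, .data$position, .keep_all = TRUE)
  left_join(out, as_tibble(scheme)[, c("sample_id", "plate", "row", "column")],
    by = "sample_id")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("Simulated screen truth: %d planted mutation(s)\n", nrow(x$mutations)))
  print(x$mutations, ...)
  invisible(x)
}

#' Write / read planted-mutation truth as TSV
#'
#' @param truth A `sim_truth`.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  write_tsv_prov(truth$mutations, path, "plant-mutations", seed = truth$seed,
    params = list(density = truth$density, ems_fraction = truth$ems_fraction,
      hom_fraction = truth$hom_fraction))
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tab <- read_tsv_quiet(path, col_types = "ciiicicccc")
  structure(list(mutations = tab, dims = NULL, density = NA_real_,
    ems_fraction = NA_real_, hom_fraction = NA_real_, seed = NULL),
    class = "sim_truth")
}

# per-(pool, amplicon, position, alt) planted allele fraction:
# sum over carriers of dose / (2 * pool size)
planted_pool_fractions <- function(scheme, truth) {
  m <- truth$mutations
  if (!nrow(m)) {
    return(tibble(pool = character(0), amplicon = character(0),
      position = integer(0), alt = character(0), fraction = numeric(0)))
  }
  sizes <- pool_sizes(scheme)
  pools3 <- pools_of_individual(scheme, m$plate, m$row, m$column)
  dplyr::bind_cols(m, pools3) |>
    tidyr::pivot_longer(c("pool_A", "pool_B", "pool_C"),
      names_to = NULL, values_to = "pool") |>
    left_join(sizes, by = "pool") |>
    mutate(fraction = ifelse(.data$zygosity == "HOM", 2, 1) / (2 * .data$size)) |>
    group_by(.data$pool, .data$amplicon, .data$position, .data$alt) |>
    summarise(fraction = sum(.data$fraction), .groups = "drop")
}

#' Simulate per-pool allele-count tables
#'
#' For every pool, amplicon and position the simulator draws a sequencing
#' depth (lognormal across pools, with a linear 3' drop-off along the
#' amplicon), then allele counts: the true alternate fraction contributed by
#' planted carriers (allele dose over `2 x pool size`) plus the error-model
#' substitution rate. In `"sampled"` mode alternate counts are Binomial;
#' in `"expected"` mode every count is the rounded expectation and the table
#' is deterministic (error rates are not jittered). Base plus indel counts
#' sum exactly to the drawn depth at every position.
#'
#' @param scheme A `pooling_scheme`.
#' @param truth A `sim_truth` (see [plant_mutations()]).
#' @param refs The `amplicon_set` the truth was planted on.
#' @param coverage A [coverage_model()].
#' @param error An [error_model()].
#' @param mode `"sampled"` or `"expected"`.
#' @param seed Integer seed (sampled mode is deterministic given the seed).
#' @return Tibble of class `allele_counts` with columns `pool`, `amplicon`,
#'   `position`, `ref`, `A`, `C`, `G`, `T`, `ins`, `del`.
#' @export
simulate_counts <- function(scheme, truth, refs,
                            coverage = coverage_model(),
                            error = error_model(),
                            mode = c("sampled", "expected"),
                            seed = NULL) {
  mode <- match.arg(mode)
  sampled <- mode == "sampled"
  run <- function() {
    sizes <- pool_sizes(scheme)
    pos <- ref_position_table(refs, error$homopolymer_min_run)
    grid <- tidyr::expand_grid(pool = sizes$pool, amplicon = refs$id)
    grid$depth <- draw_depths(coverage, nrow(grid), sampled)
    tab <- inner_join(grid, pos, by = "amplicon", relationship = "many-to-many")
    tab$cov <- as.integer(round(tab$depth *
      dropoff_factor(tab$position, tab$length, coverage)))
    rates <- draw_run_rates(error, sampled)
    planted <- planted_pool_fractions(scheme, truth)
    frac_lookup <- setNames(planted$fraction,
      paste(planted$pool, planted$amplicon, planted$position, planted$alt, sep = "\r"))
    n <- nrow(tab)
    counts <- matrix(0L, n, 4, dimnames = list(NULL, BASES))
    draw <- function(cov, p) {
      if (sampled) rbinom(length(cov), cov, pmin(p, 1))
      else as.integer(round(cov * pmin(p, 1)))
    }
    for (b in BASES) {
      p <- unname(rates[paste0(tab$ref, ">", b)])
      p[is.na(p)] <- 0
      if (nrow(planted)) {
        f <- frac_lookup[paste(tab$pool, tab$amplicon, tab$position, b, sep = "\r")]
        p <- p + ifelse(is.na(f), 0, f)
      }
      nonref <- tab$ref != b
      cnt <- integer(n)
      cnt[nonref] <- draw(tab$cov[nonref], p[nonref])
      counts[, b] <- cnt
    }
    ind_rate <- ifelse(tab$homopolymer,
      error$homopolymer_factor * error$mean_substitution_rate, error$indel_rate)
    ins <- draw(tab$cov, ind_rate)
    del <- draw(tab$cov, ind_rate)
    used <- rowSums(counts) + ins + del
    over <- used > tab$cov
    if (any(over)) { # vanishingly rare at realistic rates; rescale to conserve
      scale <- tab$cov[over] / used[over]
      counts[over, ] <- floor(counts[over, , drop = FALSE] * scale)
      ins[over] <- floor(ins[over] * scale)
      del[over] <- floor(del[over] * scale)
      used <- rowSums(counts) + ins + del
    }
    counts[cbind(seq_len(n), match(tab$ref, BASES))] <- tab$cov - used
    out <- tibble(
      pool = tab$pool, amplicon = tab$amplicon, position = tab$position,
      ref = tab$ref,
      A = counts[, "A"], C = counts[, "C"], G = counts[, "G"], T = counts[, "T"],
      ins = as.integer(ins), del = as.integer(del)
    )
    structure(out, mode = mode, seed = seed,
      class = c("allele_counts", class(out)))
  }
  with_seed_if(seed, run())
}

#' Write / read an allele-count table as TSV
#'
#' @param counts An `allele_counts` tibble.
#' @param path File path.
#' @param seed Optional seed recorded in the provenance header.
#' @export
write_counts <- function(counts, path, seed = NULL) {
  write_tsv_prov(as_tibble(counts), path, "simulate-counts", seed = seed)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  tab <- read_tsv_quiet(path, col_types = "cciciiiiii")
  structure(tab, class = c("allele_counts", class(tab)))
}

#' Score called candidates against planted truth
#'
#' A candidate is a true positive when its amplicon, position and
#' substitution match a planted mutation and its deconvolved well set
#' contains the true carrier. `individual_accuracy` is the fraction of true
#' positives resolved to exactly the single correct well.
#'
#' @param truth A `sim_truth`.
#' @param candidates A `variant_candidates` tibble (see [call_candidates()]),
#'   or any tibble with columns `amplicon`, `position`, `change`, `wells`.
#' @return One-row tibble: `n_truth`, `n_candidates`, `true_positives`,
#'   `false_positives`, `false_negatives`, `recall`, `precision`,
#'   `individual_accuracy`.
#' @export
evaluate_calls <- function(truth, candidates) {
  m <- truth$mutations
  cand <- as_tibble(candidates)
  if (nrow(cand) == 0 || nrow(m) == 0) {
    tp <- 0L
    acc_hits <- 0L
    matched_truth <- logical(nrow(m))
    tp_flags <- logical(nrow(cand))
  } else {
    tp_flags <- logical(nrow(cand))
    acc_flags <- logical(nrow(cand))
    matched_truth <- logical(nrow(m))
    for (i in seq_len(nrow(cand))) {
      hit <- which(m$amplicon == cand$amplicon[i] &
        m$position == cand$position[i] &
        m$change == cand$change[i])
      if (!length(hit)) next
      wells <- parse_wells(cand$wells[i])
      for (j in hit) {
        in_set <- nrow(wells) > 0 && any(wells$plate == m$plate[j] &
          wells$row == m$row[j] & wells$column == m$column[j])
        if (in_set) {
          tp_flags[i] <- TRUE
          matched_truth[j] <- TRUE
          if (nrow(wells) == 1) acc_flags[i] <- TRUE
        }
      }
    }
    tp <- sum(tp_flags)
    acc_hits <- sum(acc_flags)
  }
  fp <- nrow(cand) - tp
  fn <- sum(!matched_truth)
  tibble(
    n_truth = nrow(m), n_candidates = nrow(cand),
    true_positives = as.integer(tp), false_positives = as.integer(fp),
    false_negatives = as.integer(fn),
    recall = if (nrow(m)) tp / nrow(m) else NA_real_,
    precision = if (nrow(cand)) tp / nrow(cand) else NA_real_,
    individual_accuracy = if (tp) acc_hits / tp else NA_real_
  )
}

# wells serialised as "(plate,row,column);(...)"
format_wells <- function(wells) {
  if (!nrow(wells)) return("")
  paste(sprintf("(%d,%d,%d)", wells$plate, wells$row, wells$column), collapse = ";")
}

parse_wells <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(tibble(plate = integer(0), row = integer(0), column = integer(0)))
  }
  parts <- strsplit(gsub("[()]", "", strsplit(x, ";")[[1]]), ",")
  tibble(
    plate = as.integer(vapply(parts, `[`, "", 1)),
    row = as.integer(vapply(parts, `[`, "", 2)),
    column = as.integer(vapply(parts, `[`, "", 3))
  )
}
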