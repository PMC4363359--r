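#' Configuration for an end-to-end simulated screen
#'
#' Bundles the scheme geometry, references, models and thresholds for
#' [run_end_to_end()]. All randomness flows from the single `seed`; stage
#' seeds are derived from it, so identical configurations yield identical
#' outputs.
#'
#' @param refs An `amplicon_set`, or `c(fasta = ..., primers = ...)` paths.
#' @param out_dir Output directory (created if needed).
#' @param scheme A `pooling_scheme`, a path to a scheme TSV, or a length-3
#'   integer vector `c(n_plates, n_rows, n_cols)`.
#' @param mode `"counts"` (simulate allele-count tables directly) or
#'   `"reads"` (simulate FASTQ, then demultiplex, trim, align and pile up).
#' @param barcodes Optional barcode table (`pool`, `barcode`) or path;
#'   generated from the seed when NULL and `mode = "reads"`.
#' @param mutations Optional explicit mutation tibble (see
#'   [plant_mutations()]); when NULL, mutations are drawn at `density`.
#' @param density,ems_fraction,hom_fraction Passed to [plant_mutations()].
#' @param coverage A [coverage_model()].
#' @param error An [error_model()].
#' @param caller A [caller_config()].
#' @param seed Integer master seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(refs, out_dir, scheme = c(8, 8, 12),
                       mode = c("counts", "reads"),
                       barcodes = NULL, mutations = NULL,
                       density = 1 / 300000, ems_fraction = 0.99,
                       hom_fraction = 1 / 3,
                       coverage = coverage_model(),
                       error = error_model(),
                       caller = caller_config(),
                       seed = 1) {
  mode <- match.arg(mode)
  if (is.character(refs)) {
    for (p in refs) {
      if (!file.exists(p)) {
        abort(sprintf("Config field `refs`: path does not exist: %s", p))
      }
    }
  }
  if (is.character(scheme) && !file.exists(scheme)) {
    abort(sprintf("Config field `scheme`: path does not exist: %s", scheme))
  }
  if (is.character(barcodes) && !file.exists(barcodes)) {
    abort(sprintf("Config field `barcodes`: path does not exist: %s", barcodes))
  }
  structure(list(
    refs = refs, out_dir = out_dir, scheme = scheme, mode = mode,
    barcodes = barcodes, mutations = mutations, density = density,
    ems_fraction = ems_fraction, hom_fraction = hom_fraction,
    coverage = coverage, error = error, caller = caller,
    seed = as.integer(seed)
  ), class = "run_config")
}

resolve_scheme <- function(scheme) {
  if (inherits(scheme, "pooling_scheme")) return(scheme)
  if (is.character(scheme)) return(read_scheme(scheme))
  if (is.numeric(scheme) && length(scheme) == 3) {
    return(build_scheme(scheme[1], scheme[2], scheme[3]))
  }
  abort("`scheme` must be a pooling_scheme, a TSV path, or c(n_plates, n_rows, n_cols).")
}

resolve_refs <- function(refs) {
  if (inherits(refs, "amplicon_set")) return(refs)
  if (is.character(refs) && length(refs) == 2) {
    return(read_reference(refs[[1]], refs[[2]]))
  }
  abort("`refs` must be an amplicon_set or c(fasta, primer_table) paths.")
}

#' Run a simulated pooled-amplicon screen end to end
#'
#' Executes simulate -> (demultiplex -> trim -> align -> pile up, in reads
#' mode) -> frequency table -> homopolymer filter -> outlier flagging ->
#' candidate calling/deconvolution -> evaluation against the planted truth.
#' Every artifact is written to `config$out_dir` with a provenance header
#' (package version, stage, seed); identical configuration and seed give
#' identical outputs.
#'
#' @param config A [run_config()].
#' @return Object of class `screen_run`: the scheme, truth, counts,
#'   frequency table, flags, candidates, evaluation, config and output paths.
#'   Use [generics::tidy()] for the candidate table and [generics::glance()]
#'   for the one-row evaluation summary.
#' @export
run_end_to_end <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$out_dir, f)
  scheme <- resolve_scheme(config$scheme)
  refs <- resolve_refs(config$refs)
  write_scheme(scheme, path("scheme.tsv"))
  truth <- plant_mutations(scheme, refs,
    density = config$density, mutations = config$mutations,
    ems_fraction = config$ems_fraction, hom_fraction = config$hom_fraction,
    seed = config$seed)
  write_truth(truth, path("truth.tsv"))
  if (config$mode == "reads") {
    barcodes <- if (is.null(config$barcodes)) {
      barcode_table(scheme, seed = config$seed)
    } else if (is.character(config$barcodes)) {
      read_barcodes(config$barcodes)
    } else {
      as_tibble(config$barcodes)
    }
    write_barcodes(barcodes, path("barcodes.tsv"))
    sim <- simulate_reads(scheme, truth, refs, barcodes,
      coverage = config$coverage, error = config$error,
      fastq = path("reads.fastq"), seed = config$seed + 1L)
    reads <- read_fastq(path("reads.fastq"))
    dem <- demultiplex(reads, barcodes)
    readr::write_tsv(demux_summary(dem), path("demux_summary.tsv"))
    trimmed <- trim_reads(dem, refs)
    alns <- align_to_amplicons(trimmed, refs, seed = config$seed + 2L)
    counts <- pileup(alns, refs)
  } else {
    counts <- simulate_counts(scheme, truth, refs,
      coverage = config$coverage, error = config$error,
      mode = "sampled", seed = config$seed + 1L)
  }
  write_counts(counts, path("counts.tsv"), seed = config$seed)
  freq <- frequency_table(counts, config$caller)
  freq <- filter_homopolymer_indels(freq, refs, config$caller)
  write_tsv_prov(as_tibble(freq), path("frequencies.tsv"), "frequency-table",
    seed = config$seed)
  flags <- detect_outlier_pools(freq, scheme, config$caller)
  candidates <- call_candidates(flags, scheme, config$caller)
  write_candidates(candidates, path("candidates.tsv"))
  write_candidates(candidates, path("candidates.vcf"), format = "vcf", refs = refs)
  evaluation <- evaluate_calls(truth, candidates)
  write_tsv_prov(evaluation, path("evaluation.tsv"), "evaluate", seed = config$seed)
  structure(list(
    scheme = scheme, refs = refs, truth = truth, counts = counts,
    frequencies = freq, flags = flags, candidates = candidates,
    evaluation = evaluation, config = config,
    paths = vapply(c("scheme.tsv", "truth.tsv", "counts.tsv",
      "frequencies.tsv", "candidates.tsv", "candidates.vcf",
      "evaluation.tsv"), path, "")
  ), class = "screen_run")
}

#' @export
print.screen_run <- function(x, ...) {
  d <- scheme_dims(x$scheme)
  cat(sprintf(
    "Pooled-amplicon screen run: %d individuals, %d pools, %d amplicon(s)\n",
    nrow(x$scheme), length(pool_ids(x$scheme)), nrow(x$refs)
  ))
  cat(sprintf("Planted mutations: %d; candidates called: %d\n",
    nrow(x$truth$mutations), nrow(x$candidates)))
  ev <- x$evaluation
  cat(sprintf(
    "TP %d / FP %d / FN %d; recall %.2f; individual accuracy %s\n",
    ev$true_positives, ev$false_positives, ev$false_negatives,
    ev$recall,
    ifelse(is.na(ev$individual_accuracy), "NA", sprintf("%.2f", ev$individual_accuracy))
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Candidate table of a screen run
#'
#' @param x A `screen_run`.
#' @param ... Unused.
#' @return The `variant_candidates` tibble.
#' @export
tidy.screen_run <- function(x, ...) x$candidates

#' One-row evaluation summary of a screen run
#'
#' @param x A `screen_run`.
#' @param ... Unused.
#' @return One-row tibble: counts of planted mutations and candidates,
#'   TP/FP/FN, recall, precision, individual accuracy, seed.
#' @export
glance.screen_run <- function(x, ...) {
  mutate(x$evaluation, seed = x$config$seed)
}
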