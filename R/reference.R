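DEFAULT_UNIVERSAL_TAG <- "CAGTCGGGCGTCATCA"
DEFAULT_TRP1_ADAPTER <- "CCTCTCTATGGGCAGTCGGTGAT"

#' Construct an amplicon reference set
#'
#' An amplicon set holds, per target gene region: the target sequence (the
#' region between, and excluding, the locus-specific primers) and its forward
#' and reverse primers. The two-step PCR layout prepends a pool barcode and a
#' universal tag to the forward primer and appends the trP1 adapter after the
#' reverse primer, so a full-length read is
#' `barcode + tag + forward_primer + target + revcomp(reverse_primer) +
#' revcomp(trP1)`.
#'
#' @param id Character vector of amplicon ids.
#' @param sequence Target sequences (A/C/G/T).
#' @param forward_primer,reverse_primer Locus-specific primers.
#' @param universal_tag,trp1_adapter Fixed second-step PCR sequences.
#' @return Tibble of class `amplicon_set` with attributes `universal_tag`
#'   and `trp1_adapter`.
#' @export
amplicon_set <- function(id, sequence, forward_primer, reverse_primer,
                         universal_tag = DEFAULT_UNIVERSAL_TAG,
                         trp1_adapter = DEFAULT_TRP1_ADAPTER) {
  if (length(id) != length(sequence) ||
    length(id) != length(forward_primer) ||
    length(id) != length(reverse_primer)) {
    abort("`id`, `sequence`, `forward_primer` and `reverse_primer` must have equal length.")
  }
  if (anyDuplicated(id)) abort("Amplicon ids must be unique.")
  if (length(id)) {
    check_dna(sequence, "sequence")
    check_dna(forward_primer, "forward_primer")
    check_dna(reverse_primer, "reverse_primer")
  }
  refs <- tibble(
    id = as.character(id), sequence = sequence,
    forward_primer = forward_primer, reverse_primer = reverse_primer
  )
  structure(refs,
    universal_tag = universal_tag, trp1_adapter = trp1_adapter,
    class = c("amplicon_set", class(refs))
  )
}

#' Read an amplicon reference set from FASTA plus a primer table
#'
#' @param fasta Path to a FASTA file of target sequences.
#' @param primer_table Path to a TSV with columns `id`, `forward`, `reverse`.
#'   Every FASTA record must have a primer row and vice versa.
#' @param universal_tag,trp1_adapter Fixed second-step PCR sequences.
#' @return An `amplicon_set`.
#' @export
read_reference <- function(fasta, primer_table,
                           universal_tag = DEFAULT_UNIVERSAL_TAG,
                           trp1_adapter = DEFAULT_TRP1_ADAPTER) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  primers <- read_tsv_quiet(primer_table, col_types = "ccc")
  if (!all(c("id", "forward", "reverse") %in% names(primers))) {
    abort("Primer table must have columns `id`, `forward`, `reverse`.")
  }
  ids <- sub("\\s.*", "", names(seqs))
  orphan <- setdiff(primers$id, ids)
  if (length(orphan)) {
    abort(sprintf("Primer row(s) reference unknown FASTA id(s): %s",
      paste(orphan, collapse = ", ")))
  }
  missing_primer <- setdiff(ids, primers$id)
  if (length(missing_primer)) {
    abort(sprintf("No primer row for FASTA record(s): %s",
      paste(missing_primer, collapse = ", ")))
  }
  primers <- primers[match(ids, primers$id), ]
  amplicon_set(ids, unname(as.character(seqs)), primers$forward,
    primers$reverse,
    universal_tag = universal_tag, trp1_adapter = trp1_adapter)
}

#' Write an amplicon reference set to FASTA plus a primer table
#'
#' @param refs An `amplicon_set`.
#' @param fasta,primer_table Output paths.
#' @return The FASTA path, invisibly.
#' @export
write_reference <- function(refs, fasta, primer_table) {
  seqs <- Biostrings::DNAStringSet(setNames(refs$sequence, refs$id))
  Biostrings::writeXStringSet(seqs, fasta)
  readr::write_tsv(
    tibble(id = refs$id, forward = refs$forward_primer, reverse = refs$reverse_primer),
    primer_table
  )
  invisible(fasta)
}

#' Generate a synthetic amplicon reference set
#'
#' Random target sequences and primers for simulation demos and tests. Not
#' derived from any real locus.
#'
#' @param n Number of amplicons.
#' @param length Target length in bp (recycled).
#' @param gc Target GC fraction.
#' @param primer_length Primer length in bp.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An `amplicon_set`.
#' @export
demo_amplicons <- function(n = 4, length = 200, gc = 0.45, primer_length = 20,
                           seed = 1) {
  n <- check_count(n, "n")
  lens <- rep_len(as.integer(length), n)
  with_seed_if(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    rand_seq <- function(L) paste(sample(BASES, L, replace = TRUE, prob = p), collapse = "")
    amplicon_set(
      id = sprintf("amp%02d", seq_len(n)),
      sequence = vapply(lens, rand_seq, ""),
      forward_primer = vapply(rep(primer_length, n), rand_seq, ""),
      reverse_primer = vapply(rep(primer_length, n), rand_seq, "")
    )
  })
}

#' GC content of a DNA sequence
#'
#' @param sequence Character vector of non-empty A/C/G/T sequences.
#' @return Fraction of G+C bases, in `[0, 1]`.
#' @examples
#' gc_content("GCAT") # 0.5
#' @export
gc_content <- function(sequence) {
  check_dna(sequence, "sequence")
  vapply(strsplit(sequence, ""), function(ch) mean(ch %in% c("G", "C")), numeric(1))
}

# SantaLucia (1998) unified nearest-neighbour parameters.
# dH kcal/mol, dS cal/(mol K); keys are 5'->3' dinucleotides of one strand.
NN_DH <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
  GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
NN_DS <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, TG = -22.7,
  GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)

#' Primer melting temperature (nearest-neighbour model)
#'
#' Unified nearest-neighbour thermodynamics with terminal initiation
#' penalties and an entropic monovalent-salt correction
#' (`dS + 0.368 (N-1) ln[Na+]`). This is a standard model, not a re-creation
#' of any specific primer-design program, so quality verdicts based on it are
#' advisory.
#'
#' @param primer A/C/G/T primer sequences (vectorised).
#' @param na_molar Monovalent cation concentration in mol/L (default 0.05).
#' @param primer_molar Primer concentration in mol/L (default 250 nM).
#' @return Melting temperature(s) in degrees Celsius.
#' @export
primer_tm <- function(primer, na_molar = 0.05, primer_molar = 250e-9) {
  check_dna(primer, "primer")
  if (any(nchar(primer) < 2)) abort("Primers must be at least 2 nt long.")
  R <- 1.98720425864083 # cal/(mol K)
  vapply(primer, function(s) {
    ch <- strsplit(s, "")[[1]]
    nn <- paste0(ch[-length(ch)], ch[-1])
    dh <- sum(NN_DH[nn])
    ds <- sum(NN_DS[nn])
    for (term in c(ch[1], ch[length(ch)])) {
      if (term %in% c("G", "C")) {
        dh <- dh + 0.1; ds <- ds - 2.8
      } else {
        dh <- dh + 2.3; ds <- ds + 4.1
      }
    }
    ds <- ds + 0.368 * (length(ch) - 1) * log(na_molar)
    dh * 1000 / (ds + R * log(primer_molar / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' Primer quality checks
#'
#' Applies the amplicon-design rules used for pooled screens: primer length
#' 19-21 nt, melting temperature within a target window (default 59-61 C),
#' a 3' GC clamp of at least two G/C among the terminal five bases, and no
#' homopolymer run longer than three. Verdicts are advisory; the screen
#' pipeline does not consume them.
#'
#' @param primer A single A/C/G/T primer sequence.
#' @param tm_range Acceptable melting-temperature window in Celsius.
#' @param length_range Acceptable primer length window in nt.
#' @param min_gc_clamp Minimum number of G/C among the last five 3' bases.
#' @param max_homopolymer Maximum allowed homopolymer run.
#' @param ... Passed to [primer_tm()].
#' @return A one-row tibble of class `primer_qc` with the measured values,
#'   one logical verdict per rule, `pass` (all rules), and a `messages`
#'   list-column describing any failures.
#' @export
primer_qc <- function(primer, tm_range = c(59, 61), length_range = c(19, 21),
                      min_gc_clamp = 2, max_homopolymer = 3, ...) {
  check_dna(primer, "primer")
  if (length(primer) != 1) abort("`primer` must be a single sequence.")
  len <- nchar(primer)
  tm <- primer_tm(primer, ...)
  tail5 <- strsplit(substr(primer, max(1, len - 4), len), "")[[1]]
  gc_clamp <- sum(tail5 %in% c("G", "C"))
  hp <- max_homopolymer(primer)
  length_ok <- len >= length_range[1] && len <= length_range[2]
  tm_ok <- tm >= tm_range[1] && tm <= tm_range[2]
  gc_clamp_ok <- gc_clamp >= min_gc_clamp
  homopolymer_ok <- hp <= max_homopolymer
  messages <- c(
    if (!length_ok) sprintf("length %d outside [%d, %d]", len, length_range[1], length_range[2]),
    if (!tm_ok) sprintf("Tm %.1f C outside [%.0f, %.0f]", tm, tm_range[1], tm_range[2]),
    if (!gc_clamp_ok) sprintf("only %d G/C in the 3'-terminal five bases", gc_clamp),
    if (!homopolymer_ok) sprintf("homopolymer run of %d exceeds %d", hp, max_homopolymer)
  )
  out <- tibble(
    primer = primer, length = len, tm = tm, gc_clamp = gc_clamp,
    max_homopolymer = hp,
    length_ok = length_ok, tm_ok = tm_ok, gc_clamp_ok = gc_clamp_ok,
    homopolymer_ok = homopolymer_ok,
    pass = length_ok && tm_ok && gc_clamp_ok && homopolymer_ok,
    messages = list(messages %||% character(0))
  )
  structure(out, class = c("primer_qc", class(out)))
}

#' Generate a pool barcode set
#'
#' Greedy randomised construction of `n` barcodes of a given length with all
#' pairwise Hamming distances at least `min_hamming` and homopolymer runs of
#' at most three. Deterministic for a given seed.
#'
#' @param n Number of barcodes.
#' @param length Barcode length in nt (default 10).
#' @param min_hamming Minimum pairwise Hamming distance (default 3).
#' @param seed Integer seed.
#' @param max_attempts Attempt budget before declaring the request infeasible.
#' @return Character vector of `n` barcodes.
#' @export
build_barcode_set <- function(n, length = 10, min_hamming = 3, seed = 1,
                              max_attempts = max(5000, 500 * n)) {
  n <- check_count(n, "n")
  length <- check_count(length, "length")
  min_hamming <- check_count(min_hamming, "min_hamming")
  if (min_hamming > length) abort("`min_hamming` cannot exceed the barcode length.")
  if (log(n) > length * log(4)) {
    abort(sprintf("Cannot build %s distinct barcodes of length %d.",
      format(n, scientific = FALSE), length), class = "poolscreen_capacity_error")
  }
  with_seed_if(seed, {
    accepted <- matrix(character(0), nrow = 0, ncol = length)
    attempts <- 0L
    while (nrow(accepted) < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        abort(sprintf(
          "Could not build %d barcodes (length %d, min Hamming %d) within %d attempts.",
          n, length, min_hamming, max_attempts
        ), class = "poolscreen_capacity_error")
      }
      cand <- sample(BASES, length, replace = TRUE)
      if (max(rle(cand)$lengths) > 3) next
      if (nrow(accepted) > 0) {
        dists <- rowSums(accepted != matrix(cand, nrow(accepted), length, byrow = TRUE))
        if (min(dists) < min_hamming) next
      }
      accepted <- rbind(accepted, cand)
    }
    apply(accepted, 1, paste, collapse = "")
  })
}

#' Barcode table for a pooling scheme
#'
#' Assigns one barcode to every pool of the scheme.
#'
#' @param scheme A `pooling_scheme`.
#' @inheritParams build_barcode_set
#' @return Tibble with columns `pool`, `barcode`.
#' @export
barcode_table <- function(scheme, length = 10, min_hamming = 3, seed = 1) {
  pools <- pool_ids(scheme)
  tibble(pool = pools, barcode = build_barcode_set(length(pools),
    length = length, min_hamming = min_hamming, seed = seed))
}

#' Write / read a barcode table as TSV
#'
#' @param barcodes Tibble with columns `pool`, `barcode`.
#' @param path File path.
#' @export
write_barcodes <- function(barcodes, path) {
  readr::write_tsv(barcodes[, c("pool", "barcode")], path)
  invisible(path)
}

#' @rdname write_barcodes
#' @export
read_barcodes <- function(path) {
  read_tsv_quiet(path, col_types = "cc")
}
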