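#' Demultiplex barcoded reads to pools
#'
#' A read is assigned to a pool when its prefix matches exactly one barcode
#' within `max_mismatch` substitutions; reads matching no barcode, or more
#' than one, are left unassigned. Matching is exact by default: the pooled
#' design tolerates losing a few reads far better than assigning a read to
#' the wrong pool.
#'
#' @param reads Tibble with columns `read_id`, `sequence`, `quality`
#'   (see [read_fastq()]).
#' @param barcodes Tibble with columns `pool`, `barcode`, all the same length.
#' @param max_mismatch Maximum barcode mismatches tolerated (default 0).
#' @return The `reads` tibble with added `pool` (NA when unassigned) and
#'   `original_length`; assigned reads have the barcode stripped from
#'   `sequence` and `quality`. Per-pool assignment counts are attached as
#'   attribute `summary` (also via [demux_summary()]).
#' @export
demultiplex <- function(reads, barcodes, max_mismatch = 0) {
  if (!nrow(barcodes)) abort("`barcodes` is empty.")
  bl <- unique(nchar(barcodes$barcode))
  if (length(bl) != 1) abort("Barcodes must all have the same length.")
  reads <- as_tibble(reads)
  n <- nrow(reads)
  prefix <- substr(reads$sequence, 1, bl)
  pool <- rep(NA_character_, n)
  if (n > 0) {
    ok_len <- nchar(reads$sequence) >= bl
    mm <- matrix(Inf, n, nrow(barcodes))
    if (any(ok_len)) {
      pm <- matrix(unlist(strsplit(prefix[ok_len], "")), nrow = bl)
      for (j in seq_len(nrow(barcodes))) {
        mm[ok_len, j] <- colSums(pm != strsplit(barcodes$barcode[j], "")[[1]])
      }
    }
    hits <- mm <= max_mismatch
    n_hit <- rowSums(hits)
    one <- n_hit == 1
    pool[one] <- barcodes$pool[apply(hits[one, , drop = FALSE], 1, which)]
  }
  out <- reads |>
    mutate(
      original_length = nchar(.data$sequence),
      pool = pool,
      sequence = ifelse(is.na(pool), .data$sequence,
        substring(.data$sequence, bl + 1)),
      quality = ifelse(is.na(pool), .data$quality,
        substring(.data$quality, bl + 1))
    )
  summary <- out |>
    mutate(pool = dplyr::coalesce(.data$pool, "unassigned")) |>
    count(.data$pool, name = "n_reads")
  structure(out, summary = summary, class = c("demux_reads", class(out)))
}

#' Per-pool read assignment summary
#'
#' @param x Output of [demultiplex()].
#' @return Tibble with columns `pool`, `n_reads` (including `"unassigned"`).
#' @export
demux_summary <- function(x) attr(x, "summary")

#' Trim the two-step PCR layout from demultiplexed reads
#'
#' Locates the universal tag at the read start, then one of the forward
#' primers (each within `max_mismatch` substitutions), strips both, and
#' removes any trailing reverse-primer/trP1 adapter (full match, or a partial
#' 3' overlap of at least 8 nt on truncated reads). Reads lacking the tag or
#' a primer, and reads whose remaining insert is shorter than `min_insert`
#' (notably ~50 bp primer-dimer artifacts, whose insert is empty), are
#' rejected; rejection is an outcome recorded in `status`, not an error.
#'
#' @param reads Output of [demultiplex()] (barcode already stripped).
#' @param refs An `amplicon_set`.
#' @param max_mismatch Mismatches tolerated in the tag and primer match.
#' @param min_insert Minimum insert length retained (default 30 bp).
#' @return Tibble of class `trimmed_reads`: `read_id`, `pool`, `status`
#'   (`"ok"` or a rejection reason), `amplicon_hint` (the matched forward
#'   primer's amplicon), `insert`, `insert_quality`, `original_length`.
#' @export
trim_reads <- function(reads, refs, max_mismatch = 1, min_insert = 30) {
  tag <- attr(refs, "universal_tag")
  tl <- nchar(tag)
  n <- nrow(reads)
  status <- rep("ok", n)
  status[is.na(reads$pool)] <- "unassigned"
  seqs <- reads$sequence
  quals <- reads$quality
  live <- status == "ok"

  # universal tag at position 1
  has_tag <- rep(FALSE, n)
  long_enough <- nchar(seqs) >= tl
  chk <- live & long_enough
  if (any(chk)) {
    has_tag[chk] <- str_mismatch(substr(seqs[chk], 1, tl), tag) <= max_mismatch
  }
  status[live & !has_tag] <- "no_tag"
  live <- status == "ok"

  # forward primer immediately after the tag
  amp_hint <- rep(NA_character_, n)
  best_mm <- rep(Inf, n)
  for (i in seq_len(nrow(refs))) {
    fp <- refs$forward_primer[i]
    pl <- nchar(fp)
    chk <- live & nchar(seqs) >= tl + pl
    if (!any(chk)) next
    mm <- str_mismatch(substr(seqs[chk], tl + 1, tl + pl), fp)
    better <- mm <= max_mismatch & mm < best_mm[chk]
    idx <- which(chk)[better]
    amp_hint[idx] <- refs$id[i]
    best_mm[idx] <- mm[better]
  }
  status[live & is.na(amp_hint)] <- "no_primer"
  live <- status == "ok"

  insert <- rep(NA_character_, n)
  insert_q <- rep(NA_character_, n)
  fpl <- setNames(nchar(refs$forward_primer), refs$id)
  adapters <- setNames(revcomp(refs$reverse_primer), refs$id)
  for (amp in refs$id) {
    sel <- which(live & amp_hint == amp)
    if (!length(sel)) next
    from <- tl + fpl[[amp]] + 1
    rem <- substring(seqs[sel], from)
    remq <- substring(quals[sel], from)
    ad <- adapters[[amp]]
    cut <- regexpr(ad, rem, fixed = TRUE)
    end <- ifelse(cut > 0, cut - 1L, nchar(rem))
    # truncated reads may retain only a 3' sliver of the adapter
    no_full <- which(cut < 0)
    if (length(no_full)) {
      for (ol in seq(min(nchar(ad) - 1L, 30L), 8L)) {
        if (!length(no_full)) break
        hit <- endsWith(rem[no_full], substr(ad, 1, ol))
        end[no_full[hit]] <- nchar(rem[no_full[hit]]) - ol
        no_full <- no_full[!hit]
      }
    }
    insert[sel] <- substr(rem, 1, end)
    insert_q[sel] <- substr(remq, 1, end)
  }
  too_short <- live & nchar(insert) < min_insert
  status[too_short] <- "short_insert"

  out <- tibble(
    read_id = reads$read_id, pool = reads$pool, status = status,
    amplicon_hint = amp_hint,
    insert = ifelse(status == "ok", insert, NA_character_),
    insert_quality = ifelse(status == "ok", insert_q, NA_character_),
    original_length = reads$original_length %||% nchar(reads$sequence)
  )
  structure(out, class = c("trimmed_reads", class(out)))
}

#' Align trimmed inserts to the amplicon references
#'
#' Local alignment of every accepted insert against every reference, scored
#' as match +1, mismatch -`mismatch` cost, gap -`insertion`/-`deletion` cost
#' (the classic read-mapper scheme with mismatch cost 2 and gap cost 3;
#' insertion and deletion costs must be equal). Local semantics let a read's
#' unalignable portion (adapter slivers, chimeric prefixes) be clipped, so
#' the aligned-length fraction is a meaningful acceptance gate. The
#' best-scoring reference wins; exact ties are broken by a seeded uniform
#' choice (non-specific matches map randomly). An alignment is accepted only
#' if at least `min_length_fraction` of the read aligns and the
#' aligned-column identity is at least `min_similarity`.
#'
#' @param trimmed Output of [trim_reads()].
#' @param refs An `amplicon_set`.
#' @param costs Named vector `c(mismatch = 2, insertion = 3, deletion = 3)`.
#' @param min_length_fraction Minimum fraction of the read aligned.
#' @param min_similarity Minimum identity over aligned columns.
#' @param seed Seed for random tie-breaking.
#' @return Tibble of class `amplicon_alignments` with one row per accepted
#'   insert attempt: `read_id`, `pool`, `amplicon`, `ref_start`, `read_start`,
#'   `aligned_pattern`, `aligned_subject`, `similarity`, `aligned_fraction`,
#'   `accepted`, `insert_quality`.
#' @export
align_to_amplicons <- function(trimmed, refs,
                               costs = c(mismatch = 2, insertion = 3, deletion = 3),
                               min_length_fraction = 0.8,
                               min_similarity = 0.8,
                               seed = NULL) {
  if (!nrow(refs)) abort("`refs` is empty.")
  if (costs[["insertion"]] != costs[["deletion"]]) {
    abort("Linear gap scoring requires equal insertion and deletion costs.")
  }
  ok <- trimmed[trimmed$status == "ok", ]
  empty <- tibble(
    read_id = character(0), pool = character(0), amplicon = character(0),
    ref_start = integer(0), read_start = integer(0),
    aligned_pattern = character(0), aligned_subject = character(0),
    similarity = numeric(0), aligned_fraction = numeric(0),
    accepted = logical(0), insert_quality = character(0)
  )
  if (!nrow(ok)) {
    return(structure(empty, class = c("amplicon_alignments", class(empty))))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -costs[["mismatch"]], baseOnly = TRUE
  )
  patterns <- Biostrings::DNAStringSet(ok$insert)
  alns <- lapply(seq_len(nrow(refs)), function(i) {
    Biostrings::pairwiseAlignment(
      pattern = patterns,
      subject = Biostrings::DNAString(refs$sequence[i]),
      type = "local",
      substitutionMatrix = mat,
      gapOpening = 0, gapExtension = costs[["insertion"]]
    )
  })
  scores <- vapply(alns, Biostrings::score, numeric(nrow(ok)))
  scores <- matrix(scores, nrow = nrow(ok))
  pick <- with_seed_if(seed, apply(scores, 1, function(s) {
    best <- which(s == max(s))
    if (length(best) == 1) best else best[sample.int(length(best), 1)]
  }))
  rows <- purrr::map_dfr(seq_len(nrow(refs)), function(r) {
    idx <- which(pick == r)
    if (!length(idx)) return(NULL)
    a <- alns[[r]][idx]
    ap <- as.character(Biostrings::pattern(a))
    as <- as.character(Biostrings::subject(a))
    pr <- Biostrings::pattern(a)
    aligned_len <- Biostrings::end(pr) - Biostrings::start(pr) + 1L
    tibble(
      read_id = ok$read_id[idx], pool = ok$pool[idx],
      amplicon = refs$id[r],
      ref_start = Biostrings::start(Biostrings::subject(a)),
      read_start = Biostrings::start(pr),
      aligned_pattern = ap, aligned_subject = as,
      similarity = Biostrings::nmatch(a) / nchar(ap),
      aligned_fraction = aligned_len / nchar(ok$insert[idx]),
      insert_quality = ok$insert_quality[idx]
    )
  })
  rows <- rows[order(match(rows$read_id, ok$read_id)), ]
  rows$accepted <- rows$aligned_fraction >= min_length_fraction &
    rows$similarity >= min_similarity
  structure(rows, class = c("amplicon_alignments", class(rows)))
}

#' Quality-filtered pileup of aligned reads
#'
#' Builds a per-pool allele-count table from accepted alignments. An aligned
#' base contributes to its reference position only if its own quality is at
#' least `central_q`, the mean quality within `radius` bases on the read is
#' at least `neighborhood_q`, and the read carries at most
#' `max_gap_mismatch` combined gaps and mismatches within that window.
#' Insertions and deletions are tallied at their left-flanking reference
#' position, gated by the same window checks.
#'
#' @param alignments Output of [align_to_amplicons()].
#' @param refs An `amplicon_set`.
#' @param central_q Minimum quality of the contributing base (default 20).
#' @param neighborhood_q Minimum mean quality in the window (default 15).
#' @param radius Window radius on the read in bases (default 5).
#' @param max_gap_mismatch Maximum gaps+mismatches in the window (default 5).
#' @return An `allele_counts` tibble covering every reference position
#'   (zero-filled) for every pool present in `alignments`.
#' @export
pileup <- function(alignments, refs, central_q = 20, neighborhood_q = 15,
                   radius = 5, max_gap_mismatch = 5) {
  acc <- alignments[alignments$accepted, ]
  pos_tab <- ref_position_table(refs)
  pools <- unique(acc$pool)
  grid <- tidyr::expand_grid(
    pool = if (length(pools)) pools else character(0),
    pos_tab[, c("amplicon", "position", "ref")]
  )
  tallies <- vector("list", nrow(acc))
  for (i in seq_len(nrow(acc))) {
    p <- strsplit(acc$aligned_pattern[i], "")[[1]]
    s <- strsplit(acc$aligned_subject[i], "")[[1]]
    qual <- phred_to_int(acc$insert_quality[i])[[1]]
    ref_pos <- acc$ref_start[i] + cumsum(s != "-") - 1L
    read_pos <- acc$read_start[i] + cumsum(p != "-") - 1L
    read_pos[p == "-"] <- pmax(read_pos[p == "-"], acc$read_start[i]) # deletion flank
    bad <- (p != s) # mismatch or gap column
    bad_per_read <- tabulate(pmin(read_pos[bad], length(qual)), nbins = length(qual))
    wq <- window_mean(qual, radius)
    wb <- window_sum(bad_per_read, radius)
    rp <- pmin(read_pos, length(qual))
    col_ok <- wq[rp] >= neighborhood_q & wb[rp] <= max_gap_mismatch
    is_base <- p != "-" & s != "-"
    is_ins <- s == "-" & p != "-"
    is_del <- p == "-" & s != "-"
    keep_base <- is_base & col_ok & qual[rp] >= central_q
    keep_ins <- is_ins & col_ok
    keep_del <- is_del & col_ok
    # insertions sit before the current reference position: left flank
    ins_pos <- ref_pos[keep_ins]
    allele <- c(p[keep_base], rep("ins", sum(keep_ins)), rep("del", sum(keep_del)))
    position <- c(ref_pos[keep_base], ins_pos, ref_pos[keep_del])
    ok <- position >= 1
    if (!any(ok)) next
    tallies[[i]] <- tibble(
      pool = acc$pool[i], amplicon = acc$amplicon[i],
      position = position[ok], allele = allele[ok]
    )
  }
  tallied <- bind_rows(tallies)
  if (nrow(tallied)) {
    wide <- tallied |>
      count(.data$pool, .data$amplicon, .data$position, .data$allele) |>
      tidyr::pivot_wider(names_from = "allele", values_from = "n", values_fill = 0L)
  } else {
    wide <- tibble(pool = character(0), amplicon = character(0), position = integer(0))
  }
  for (col in c(BASES, "ins", "del")) {
    if (!col %in% names(wide)) wide[[col]] <- 0L
  }
  out <- grid |>
    left_join(wide, by = c("pool", "amplicon", "position")) |>
    mutate(across(all_of(c(BASES, "ins", "del")), ~ dplyr::coalesce(.x, 0L))) |>
    select("pool", "amplicon", "position", "ref",
      all_of(BASES), "ins", "del") |>
    arrange(.data$pool, .data$amplicon, .data$position)
  structure(out, class = c("allele_counts", class(out)))
}
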