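#' Simulate a barcoded pooled-amplicon FASTQ run
#'
#' Generates reads laid out as `barcode + universal tag + forward primer +
#' target + revcomp(reverse primer) + revcomp(trP1)`. For each pool and
#' amplicon, the read count is drawn from the coverage model; each real read
#' samples a template individual from the pool (heterozygous carriers
#' transmit their mutant allele to half their templates), then per-base
#' substitution and homopolymer-indel errors are applied to the target
#' segment. A `junk_read_fraction` of reads are ~50 bp primer-dimer artifacts
#' that carry a valid barcode but no target. A fraction of reads is
#' 3'-truncated (incomplete extensions), producing the 3' coverage drop-off.
#' Output is deterministic for a given seed.
#'
#' @param scheme A `pooling_scheme`.
#' @param truth A `sim_truth`.
#' @param refs An `amplicon_set`.
#' @param barcodes Tibble with columns `pool`, `barcode` covering every pool.
#' @param coverage A [coverage_model()]; `mean_coverage` sets the expected
#'   reads per pool and amplicon.
#' @param error An [error_model()].
#' @param fastq Output FASTQ path.
#' @param seed Integer seed.
#' @param quality_mean,quality_sd Per-base Phred quality distribution of real
#'   reads (junk reads are drawn 12 points lower).
#' @param truncation_prob Probability that a read is 3'-truncated.
#' @return Invisibly, a list with `fastq` (the path), `reads` (tibble of read
#'   counts per pool and amplicon) and `truth`.
#' @export
simulate_reads <- function(scheme, truth, refs, barcodes,
                           coverage = coverage_model(),
                           error = error_model(),
                           fastq,
                           seed = NULL,
                           quality_mean = 30, quality_sd = 3,
                           truncation_prob = coverage$end_dropoff_fraction) {
  pools <- pool_ids(scheme)
  missing <- setdiff(pools, barcodes$pool)
  if (length(missing)) {
    abort(sprintf("No barcode for pool(s): %s", paste(missing, collapse = ", ")))
  }
  bc_of <- setNames(barcodes$barcode, barcodes$pool)
  tag <- attr(refs, "universal_tag")
  trp1 <- attr(refs, "trp1_adapter")
  rc_trp1 <- revcomp(trp1)
  rc_rev <- setNames(revcomp(refs$reverse_primer), refs$id)
  fwd <- setNames(refs$forward_primer, refs$id)
  targets <- setNames(refs$sequence, refs$id)

  run <- function() {
    rates <- draw_run_rates(error, sampled = TRUE)
    # per-base total substitution rate and conditional alt distribution
    tot_rate <- vapply(BASES, function(b) {
      sum(rates[paste0(b, ">", setdiff(BASES, b))])
    }, numeric(1))
    alt_probs <- lapply(setNames(BASES, BASES), function(b) {
      alts <- setdiff(BASES, b)
      p <- rates[paste0(b, ">", alts)]
      if (sum(p) == 0) p <- rep(1, 3)
      setNames(p / sum(p), alts)
    })
    grid <- tidyr::expand_grid(pool = pools, amplicon = refs$id)
    grid$n_reads <- as.integer(round(draw_depths(coverage, nrow(grid), TRUE)))
    all_seq <- character(0)
    all_qual <- character(0)
    members_by_pool <- lapply(setNames(pools, pools), function(p) pool_members(scheme, p))
    for (g in seq_len(nrow(grid))) {
      pool <- grid$pool[g]
      amp <- grid$amplicon[g]
      n_tot <- grid$n_reads[g]
      if (n_tot == 0) next
      n_junk <- rbinom(1, n_tot, coverage$junk_read_fraction)
      n_real <- n_tot - n_junk
      tgt <- targets[[amp]]
      L <- nchar(tgt)
      reads <- rep(tgt, n_real)
      if (n_real > 0) {
        members <- members_by_pool[[pool]]
        muts <- truth$mutations[truth$mutations$amplicon == amp &
          truth$mutations$sample_id %in% members$sample_id, ]
        if (nrow(muts)) {
          idx <- sample.int(nrow(members), n_real, replace = TRUE)
          tmpl <- members$sample_id[idx]
          for (k in seq_len(nrow(muts))) {
            sel <- tmpl == muts$sample_id[k]
            if (muts$zygosity[k] == "HET") sel <- sel & runif(n_real) < 0.5
            if (any(sel)) {
              substr(reads[sel], muts$position[k], muts$position[k]) <- muts$alt[k]
            }
          }
        }
        # substitution errors on the target segment
        base_w <- tot_rate[strsplit(tgt, "")[[1]]]
        lam <- sum(base_w)
        n_err <- rpois(n_real, lam)
        for (i in which(n_err > 0)) {
          ppos <- sample.int(L, min(n_err[i], L), prob = base_w)
          for (pp in ppos) {
            b <- substr(reads[i], pp, pp)
            ap <- alt_probs[[b]]
            substr(reads[i], pp, pp) <- sample(names(ap), 1, prob = ap)
          }
        }
        # homopolymer indel artifacts (duplicate or drop one base of a run)
        hp_pos <- which(homopolymer_mask(tgt, error$homopolymer_min_run))
        if (length(hp_pos)) {
          ind_lam <- 2 * length(hp_pos) * error$homopolymer_factor *
            error$mean_substitution_rate
          n_ind <- rpois(n_real, ind_lam)
          for (i in which(n_ind > 0)) {
            ch <- strsplit(reads[i], "")[[1]]
            for (k in seq_len(n_ind[i])) {
              pp <- hp_pos[sample.int(length(hp_pos), 1)]
              pp <- min(pp, length(ch))
              if (runif(1) < 0.5) {
                ch <- append(ch, ch[pp], after = pp) # insertion
              } else if (length(ch) > 1) {
                ch <- ch[-pp] # deletion
              }
            }
            reads[i] <- paste(ch, collapse = "")
          }
        }
      }
      # recycle0: paste0() must not promote an empty read vector to one read
      full <- if (n_real > 0) {
        paste0(bc_of[[pool]], tag, fwd[[amp]], reads, rc_rev[[amp]], rc_trp1)
      } else {
        character(0)
      }
      # 3'-truncated incomplete extensions
      trunc <- runif(n_real) < truncation_prob
      if (any(trunc)) {
        keep <- pmax(
          nchar(bc_of[[pool]]) + nchar(tag) + nchar(fwd[[amp]]) + 10L,
          floor(nchar(full[trunc]) * runif(sum(trunc), 0.6, 0.95))
        )
        full[trunc] <- substr(full[trunc], 1, keep)
      }
      junk <- character(0)
      if (n_junk > 0) {
        stub <- paste0(bc_of[[pool]], tag, fwd[[amp]], rc_rev[[amp]], rc_trp1)
        jlen <- pmin(pmax(round(rnorm(n_junk, 50, 5)), 35), nchar(stub))
        junk <- substr(rep(stub, n_junk), 1, jlen)
      }
      seqs <- c(full, junk)
      qmeans <- c(rep(quality_mean, n_real), rep(quality_mean - 12, n_junk))
      quals <- vapply(seq_along(seqs), function(i) {
        q <- round(rnorm(nchar(seqs[i]), qmeans[i], quality_sd))
        int_to_phred(list(pmin(pmax(q, 2L), 41L)))
      }, "")
      all_seq <- c(all_seq, seqs)
      all_qual <- c(all_qual, quals)
    }
    ord <- sample.int(length(all_seq))
    all_seq <- all_seq[ord]
    all_qual <- all_qual[ord]
    ids <- sprintf("sim%07d", seq_along(all_seq))
    rec <- character(4 * length(all_seq))
    rec[seq(1, length(rec), 4)] <- paste0("@", ids)
    rec[seq(2, length(rec), 4)] <- all_seq
    rec[seq(3, length(rec), 4)] <- "+"
    rec[seq(4, length(rec), 4)] <- all_qual
    writeLines(rec, fastq)
    list(fastq = fastq, reads = grid, truth = truth)
  }
  invisible(with_seed_if(seed, run()))
}

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ path (Sanger-scaled qualities).
#' @return Tibble with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  tibble(
    read_id = sub("\\s.*", "", names(x)),
    sequence = as.character(x),
    quality = as.character(Biostrings::quality(x))
  )
}
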