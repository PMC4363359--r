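#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join semi_join bind_rows distinct n row_number
#'   across all_of case_when slice_max count rename relocate pull if_else
#' @importFrom stats rbinom rpois rlnorm rnorm runif median sd setNames
#' @importFrom utils head tail
NULL

BASES <- c("A", "C", "G", "T")

# the 12 ordered substitution types "X>Y"
substitution_types <- function() {
  g <- expand.grid(ref = BASES, alt = BASES, stringsAsFactors = FALSE)
  g <- g[g$ref != g$alt, ]
  paste0(g$ref, ">", g$alt)
}

check_dna <- function(x, arg = "sequence", allow_empty = FALSE) {
  if (!is.character(x) || anyNA(x)) {
    abort(sprintf("`%s` must be a character vector of DNA sequences.", arg))
  }
  if (!allow_empty && any(!nzchar(x))) {
    abort(sprintf("`%s` contains an empty sequence.", arg))
  }
  if (any(grepl("[^ACGT]", x))) {
    abort(sprintf("`%s` contains characters outside {A, C, G, T}.", arg))
  }
  invisible(x)
}

check_count <- function(x, arg) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 1 || x != round(x)) {
    abort(sprintf("`%s` must be a single positive integer.", arg))
  }
  as.integer(x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# longest homopolymer run length of each sequence
max_homopolymer <- function(x) {
  vapply(strsplit(x, ""), function(ch) max(rle(ch)$lengths), integer(1))
}

# per-base table of one or more reference sequences, with homopolymer context
# (positions lying inside a run of length >= min_run)
ref_position_table <- function(refs, min_run = 3L) {
  purrr::map_dfr(seq_len(nrow(refs)), function(i) {
    ch <- strsplit(refs$sequence[i], "")[[1]]
    r <- rle(ch)
    in_run <- rep(r$lengths >= min_run, r$lengths)
    tibble(
      amplicon = refs$id[i],
      position = seq_along(ch),
      ref = ch,
      length = length(ch),
      homopolymer = in_run
    )
  })
}

# positions inside or immediately adjacent to a homopolymer run >= min_run
homopolymer_mask <- function(sequence, min_run = 3L) {
  ch <- strsplit(sequence, "")[[1]]
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_run
  mask <- logical(length(ch))
  for (j in which(keep)) {
    lo <- max(1L, starts[j] - 1L)
    hi <- min(length(ch), ends[j] + 1L)
    mask[lo:hi] <- TRUE
  }
  mask
}

# count character mismatches between equal-length strings; `y` is a scalar
str_mismatch <- function(x, y) {
  if (!length(x)) return(integer(0))
  m <- matrix(unlist(strsplit(x, "")), nrow = nchar(y))
  as.integer(colSums(m != strsplit(y, "")[[1]]))
}

phred_to_int <- function(q) {
  lapply(q, function(s) as.integer(charToRaw(s)) - 33L)
}

int_to_phred <- function(q) {
  vapply(q, function(v) rawToChar(as.raw(pmin(pmax(v, 0L), 60L) + 33L)), "")
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# trailing-window sum/mean helpers for read-level quality filters; windows are
# truncated at the read ends rather than padded
window_sum <- function(x, radius) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - radius, 1L)
  hi <- pmin(seq_len(n) + radius, n)
  cs[hi + 1L] - cs[lo]
}

window_mean <- function(x, radius) {
  n <- length(x)
  lo <- pmax(seq_len(n) - radius, 1L)
  hi <- pmin(seq_len(n) + radius, n)
  window_sum(x, radius) / (hi - lo + 1)
}

# provenance header written at the top of every pipeline artifact
prov_header <- function(stage, seed = NULL, params = NULL) {
  lines <- c(
    sprintf("# poolscreen %s", as.character(utils::packageVersion("poolscreen"))),
    sprintf("# stage=%s", stage)
  )
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed=%s", seed))
  if (!is.null(params)) {
    lines <- c(lines, sprintf("# %s=%s", names(params), unname(unlist(params))))
  }
  lines
}

write_tsv_prov <- function(x, path, stage, seed = NULL, params = NULL) {
  writeLines(prov_header(stage, seed, params), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE, ...)
}
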