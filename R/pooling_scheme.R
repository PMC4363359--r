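#' Build a tridimensional pooling scheme
#'
#' Assigns every well of a plate stack to three DNA pools: one per plate
#' (dimension A), one per plate column (dimension B) and one per plate row
#' (dimension C). With eight 96-well plates (8 rows x 12 columns) this yields
#' the classic 28-pool layout over 768 individuals: pools A1-A8 of 96
#' members, B1-B12 of 64 members and C1-C8 of 96 members. Because each
#' individual sits in exactly one pool per dimension, a rare variant flagged
#' in three intersecting pools identifies its source individual.
#'
#' @param n_plates,n_rows,n_cols Positive integers giving the stack geometry.
#' @param occupied Optional tibble with columns `plate`, `row`, `column`
#'   restricting the scheme to occupied wells (a screen need not fill every
#'   plate). Default: all wells occupied.
#' @return A tibble of class `pooling_scheme` with one row per occupied well
#'   and columns `sample_id`, `plate`, `row`, `column`, `pool_A`, `pool_B`,
#'   `pool_C`. Scheme geometry is carried in attributes `n_plates`, `n_rows`,
#'   `n_cols`.
#' @examples
#' scheme <- build_scheme(8, 8, 12)
#' nrow(scheme)        # 768 individuals
#' length(pool_ids(scheme))  # 28 pools
#' @export
build_scheme <- function(n_plates, n_rows, n_cols, occupied = NULL) {
  n_plates <- check_count(n_plates, "n_plates")
  n_rows <- check_count(n_rows, "n_rows")
  n_cols <- check_count(n_cols, "n_cols")
  grid <- tidyr::expand_grid(
    plate = seq_len(n_plates),
    row = seq_len(n_rows),
    column = seq_len(n_cols)
  )
  if (!is.null(occupied)) {
    occupied <- as_tibble(occupied)[, c("plate", "row", "column")]
    bad <- occupied$plate > n_plates | occupied$row > n_rows |
      occupied$column > n_cols | occupied$plate < 1 | occupied$row < 1 |
      occupied$column < 1
    if (any(bad)) abort("`occupied` contains wells outside the scheme geometry.")
    grid <- dplyr::semi_join(grid, occupied, by = c("plate", "row", "column"))
  }
  scheme <- grid |>
    mutate(
      sample_id = sprintf("S%04d", row_number()),
      pool_A = paste0("A", .data$plate),
      pool_B = paste0("B", .data$column),
      pool_C = paste0("C", .data$row)
    ) |>
    select("sample_id", "plate", "row", "column", "pool_A", "pool_B", "pool_C")
  structure(scheme,
    n_plates = n_plates, n_rows = n_rows, n_cols = n_cols,
    class = c("pooling_scheme", class(scheme))
  )
}

scheme_dims <- function(scheme) {
  c(
    n_plates = attr(scheme, "n_plates"),
    n_rows = attr(scheme, "n_rows"),
    n_cols = attr(scheme, "n_cols")
  )
}

#' Pool identifiers of a scheme
#'
#' @param scheme A `pooling_scheme`.
#' @return Character vector of pool ids in dimension order
#'   (`A1..`, `B1..`, `C1..`).
#' @export
pool_ids <- function(scheme) {
  d <- scheme_dims(scheme)
  c(
    paste0("A", seq_len(d[["n_plates"]])),
    paste0("B", seq_len(d[["n_cols"]])),
    paste0("C", seq_len(d[["n_rows"]]))
  )
}

#' Pool sizes (number of occupied member wells per pool)
#'
#' @param scheme A `pooling_scheme`.
#' @return Tibble with columns `pool`, `dimension`, `size`. Pools with no
#'   occupied wells are included with size 0.
#' @export
pool_sizes <- function(scheme) {
  long <- tidyr::pivot_longer(as_tibble(scheme),
    cols = c("pool_A", "pool_B", "pool_C"),
    names_to = NULL, values_to = "pool"
  )
  counts <- count(long, .data$pool, name = "size")
  tibble(pool = pool_ids(scheme)) |>
    left_join(counts, by = "pool") |>
    mutate(
      size = dplyr::coalesce(.data$size, 0L),
      dimension = substr(.data$pool, 1, 1)
    ) |>
    select("pool", "dimension", "size")
}

#' Member wells of a pool
#'
#' @param scheme A `pooling_scheme`.
#' @param pool A single pool id such as `"B7"`.
#' @return Tibble of member wells (`sample_id`, `plate`, `row`, `column`).
#' @export
pool_members <- function(scheme, pool) {
  parsed <- parse_pool_ids(scheme, pool)
  tab <- as_tibble(scheme)
  col <- c(A = "plate", B = "column", C = "row")[[parsed$dimension]]
  tab[tab[[col]] == parsed$index, c("sample_id", "plate", "row", "column")]
}

parse_pool_ids <- function(scheme, pools) {
  ok <- grepl("^[ABC][0-9]+$", pools)
  if (!all(ok)) {
    abort(sprintf("Invalid pool id(s): %s", paste(pools[!ok], collapse = ", ")))
  }
  dimension <- substr(pools, 1, 1)
  index <- as.integer(substring(pools, 2))
  d <- scheme_dims(scheme)
  limit <- c(A = d[["n_plates"]], B = d[["n_cols"]], C = d[["n_rows"]])[dimension]
  if (any(index < 1 | index > limit)) {
    abort("Pool id(s) out of range for this scheme's geometry.")
  }
  tibble(pool = pools, dimension = dimension, index = index)
}

#' Pools containing an individual
#'
#' Vectorised over wells: for each well, returns its plate (A), column (B)
#' and row (C) pool.
#'
#' @param scheme A `pooling_scheme`.
#' @param plate,row,column Integer vectors identifying the wells.
#' @return Tibble with columns `pool_A`, `pool_B`, `pool_C`.
#' @examples
#' scheme <- build_scheme(8, 8, 12)
#' pools_of_individual(scheme, plate = 3, row = 2, column = 5)  # A3 B5 C2
#' @export
pools_of_individual <- function(scheme, plate, row, column) {
  d <- scheme_dims(scheme)
  if (any(plate < 1 | plate > d[["n_plates"]] |
    row < 1 | row > d[["n_rows"]] |
    column < 1 | column > d[["n_cols"]])) {
    abort("Well address out of range for this scheme.")
  }
  tibble(
    pool_A = paste0("A", as.integer(plate)),
    pool_B = paste0("B", as.integer(column)),
    pool_C = paste0("C", as.integer(row))
  )
}

#' Deconvolve a flagged pool set to candidate individuals
#'
#' Inverts a set of flagged pools back to the wells compatible with all of
#' them. Within each dimension, flagged pools are unioned (two mutants from
#' the same run may flag two plate pools); the per-dimension sets are then
#' intersected. Resolution depends on how many dimensions are represented:
#' all three dimensions gives `"INDIVIDUAL"` (the mutation is pinned to a
#' well, or to a small ambiguous set when several pools per dimension were
#' flagged), exactly two gives `"SUBSET"` (the fallback in which the whole
#' one-dimensional intersection is re-sequenced), fewer gives `"NONE"` with
#' no candidates.
#'
#' @param scheme A `pooling_scheme`.
#' @param flagged Character vector of pool ids, e.g. `c("A3", "B5", "C2")`.
#' @return List with elements `candidates` (tibble of wells), `resolution`
#'   (`"INDIVIDUAL"`, `"SUBSET"` or `"NONE"`), `ambiguous` (TRUE when more
#'   than one candidate results) and `n_candidates`.
#' @examples
#' scheme <- build_scheme(8, 8, 12)
#' deconvolve(scheme, c("A3", "B5", "C2"))$candidates  # well (3, 2, 5)
#' @export
deconvolve <- function(scheme, flagged) {
  flagged <- unique(flagged)
  tab <- as_tibble(scheme)
  if (length(flagged) == 0) {
    return(list(
      candidates = tab[0, c("sample_id", "plate", "row", "column")],
      resolution = "NONE", ambiguous = FALSE, n_candidates = 0L
    ))
  }
  parsed <- parse_pool_ids(scheme, flagged)
  dims <- unique(parsed$dimension)
  if (length(dims) <= 1) {
    return(list(
      candidates = tab[0, c("sample_id", "plate", "row", "column")],
      resolution = "NONE", ambiguous = FALSE, n_candidates = 0L
    ))
  }
  keep <- rep(TRUE, nrow(tab))
  for (dm in dims) {
    idx <- parsed$index[parsed$dimension == dm]
    col <- c(A = "plate", B = "column", C = "row")[[dm]]
    keep <- keep & tab[[col]] %in% idx
  }
  cand <- tab[keep, c("sample_id", "plate", "row", "column")]
  resolution <- if (length(dims) == 3) "INDIVIDUAL" else "SUBSET"
  list(
    candidates = cand,
    resolution = resolution,
    ambiguous = nrow(cand) > 1,
    n_candidates = nrow(cand)
  )
}

#' Write / read a pooling scheme as TSV
#'
#' The file has columns `sample_id`, `plate`, `row`, `column`, `pool_A`,
#' `pool_B`, `pool_C` plus `#`-prefixed provenance header lines recording
#' the geometry.
#'
#' @param scheme A `pooling_scheme`.
#' @param path File path.
#' @return `write_scheme()` returns the path invisibly; `read_scheme()`
#'   returns a `pooling_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  d <- scheme_dims(scheme)
  write_tsv_prov(as_tibble(scheme), path, "design-pools", params = as.list(d))
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  tab <- read_tsv_quiet(path, col_types = "ciiiccc")
  header <- grep("^#", readLines(path, n = 20), value = TRUE)
  get_dim <- function(key, fallback) {
    hit <- grep(paste0("^# ", key, "="), header, value = TRUE)
    if (length(hit)) as.integer(sub(".*=", "", hit[1])) else fallback
  }
  structure(tab,
    n_plates = get_dim("n_plates", max(tab$plate)),
    n_rows = get_dim("n_rows", max(tab$row)),
    n_cols = get_dim("n_cols", max(tab$column)),
    class = c("pooling_scheme", class(tab))
  )
}

#' @export
print.pooling_scheme <- function(x, ...) {
  d <- scheme_dims(x)
  cat(sprintf(
    "Tridimensional pooling scheme: %d plates x %d rows x %d cols (%d wells, %d pools)\n",
    d[["n_plates"]], d[["n_rows"]], d[["n_cols"]], nrow(x),
    d[["n_plates"]] + d[["n_rows"]] + d[["n_cols"]]
  ))
  NextMethod()
}
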