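# Coordinate conventions: every interval in this package is 1-based and
# fully closed, matching the printed spans of the literature this package
# analyses (a span "118-140" is 23 residues long: 140 - 118 + 1).

#' Length of a 1-based fully-closed interval
#'
#' @param start,end Integer vectors of interval endpoints, `1 <= start <= end`.
#' @return Integer vector of residue counts, `end - start + 1`.
#' @export
#' @examples
#' interval_length(118, 140) # 23
interval_length <- function(start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start) | is.na(end))) abort("interval endpoints must be non-missing")
  if (any(start < 1L)) abort("interval start must be >= 1")
  if (any(end < start)) abort("interval end must be >= start")
  end - start + 1L
}

#' Project a residue interval of a gapped row onto alignment columns
#'
#' Maps an interval expressed in ungapped residue coordinates of one row of
#' an alignment onto the smallest column interval whose non-gap positions
#' cover exactly those residues. For a gapless row this is the identity.
#'
#' @param row A single gapped sequence (string).
#' @param start,end Residue interval (1-based, closed) on the ungapped row.
#' @return A one-row tibble with columns `start` and `end` in column space.
#' @export
#' @examples
#' project_interval_to_columns("A-CD", 2, 3) # columns 3..4
project_interval_to_columns <- function(row, start, end) {
  stopifnot(length(row) == 1L)
  interval_length(start, end) # validates
  cc <- chars(row)
  non_gap <- cc != GAP
  n_res <- sum(non_gap)
  if (end > n_res) {
    abort(sprintf("interval end %d beyond ungapped length %d", end, n_res))
  }
  residue_index <- cumsum(non_gap)
  residue_index[!non_gap] <- NA_integer_
  tibble(
    start = which(!is.na(residue_index) & residue_index == start)[1],
    end = which(!is.na(residue_index) & residue_index == end)[1]
  )
}

# inverse helper: ungapped residue position of each alignment column for a
# gapped row (NA at gap columns)
residue_positions <- function(row) {
  cc <- chars(row)
  non_gap <- cc != GAP
  idx <- cumsum(non_gap)
  idx[!non_gap] <- NA_integer_
  idx
}
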