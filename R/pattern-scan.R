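#' Scan protein sequences for matches to a Prosite-dialect pattern
#'
#' Matches a parsed (or textual) pattern against one or more ungapped
#' protein sequences. Variable-repeat wildcards are matched shortest-first
#' at each anchor position. `X` (unknown residue) in a sequence matches
#' wildcard elements only, never a residue-set element: an unknown residue
#' cannot certify set membership.
#'
#' @param seqs A tibble with columns `id`/`residues`, a named character
#'   vector, or a single string.
#' @param pattern A `prosite_pattern` or pattern text.
#' @param mode `"leftmost"` (default) returns a greedy left-to-right
#'   non-overlapping cover, taking the shortest match at each anchor --
#'   the natural mode for counting zinc fingers, which never overlap.
#'   `"all"` returns every `(start, end)` pair satisfying the pattern,
#'   including overlaps.
#' @param label Pattern label recorded in the result (defaults to the
#'   pattern's source text).
#' @return A tibble with columns `seq_id`, `start`, `end`, `pattern_label`,
#'   `match` (the matched substring); zero rows when nothing matches.
#' @seealso [find_tetrad()], [parse_pattern()]
#' @export
#' @examples
#' scan_pattern("ACDECA", "C-x(2)-C")
scan_pattern <- function(seqs, pattern, mode = c("leftmost", "all"),
                         label = NULL) {
  mode <- match.arg(mode)
  pattern <- as_pattern(pattern)
  if (is.null(label)) label <- attr(pattern, "source")
  seqs <- as_protein_tbl(seqs)

  res <- lapply(seq_len(nrow(seqs)), function(i) {
    hits <- scan_one(seqs$residues[[i]], pattern, mode)
    if (nrow(hits) == 0L) return(NULL)
    tibble(seq_id = seqs$id[[i]], start = hits$start, end = hits$end,
           pattern_label = label,
           match = substring(seqs$residues[[i]], hits$start, hits$end))
  })
  res <- dplyr::bind_rows(res)
  if (nrow(res) == 0L) {
    res <- tibble(seq_id = character(), start = integer(), end = integer(),
                  pattern_label = character(), match = character())
  }
  res
}

scan_one <- function(residues, pattern, mode) {
  cc <- chars(residues)
  L <- length(cc)
  min_span <- attr(pattern, "min_span")
  n_el <- nrow(pattern)
  kinds <- pattern$kind
  allowed <- lapply(seq_len(n_el), function(i) {
    if (kinds[i] == "set") c(pattern$major[[i]], pattern$exceptional[[i]]) else NULL
  })
  lo <- pattern$min_rep
  hi <- pattern$max_rep

  # all ends (ascending) of matches anchored at `pos`; in shortest mode the
  # recursion stops at the first (shortest) completion
  match_ends <- function(pos, shortest) {
    ends <- integer()
    rec <- function(el, p) {
      if (el > n_el) {
        ends[[length(ends) + 1L]] <<- p - 1L
        return(shortest)
      }
      if (kinds[el] == "set") {
        if (p > L || !(cc[p] %in% allowed[[el]])) return(FALSE)
        return(rec(el + 1L, p + 1L))
      }
      for (take in lo[el]:hi[el]) {  # shortest-first
        if (p + take - 1L > L) break
        if (rec(el + 1L, p + take)) return(TRUE)
      }
      FALSE
    }
    rec(1L, pos)
    sort(unique(ends))
  }

  # candidate anchors: prefilter on the first element when it is a set
  cand <- if (kinds[1] == "set") which(cc %in% allowed[[1]]) else seq_len(L)
  cand <- cand[cand <= L - min_span + 1L]

  starts <- integer(); ends <- integer()
  if (mode == "all") {
    for (s in cand) {
      e <- match_ends(s, shortest = FALSE)
      if (length(e)) {
        starts <- c(starts, rep.int(s, length(e)))
        ends <- c(ends, e)
      }
    }
  } else {
    last_end <- 0L
    for (s in cand) {
      if (s <= last_end) next
      e <- match_ends(s, shortest = TRUE)
      if (length(e)) {
        starts <- c(starts, s); ends <- c(ends, e[1])
        last_end <- e[1]
      }
    }
  }
  tibble(start = starts, end = ends)
}

#' Find a tetrad of non-overlapping motif matches
#'
#' Searches a sorted match table for a run of four consecutive,
#' non-overlapping matches whose inter-motif linkers are each at most
#' `max_linker` residues -- the configuration of the conserved C2H2
#' zinc-finger tetrad. The default `max_linker = 20` comfortably covers the
#' observed inter-motif gaps of 5, 5 and 15 residues.
#'
#' @param matches A tibble of matches as returned by [scan_pattern()]
#'   (columns `start`, `end`; a single sequence's matches).
#' @param max_linker Maximum allowed gap (residues) between consecutive
#'   motifs in the tetrad.
#' @param prefer `"first"` (default) returns the N-terminal-most valid
#'   window of four; `"last"` returns the C-terminal-most, which is the
#'   convention used for domain-architecture assembly since the tetrad of
#'   this family sits at the C-terminal end.
#' @return A four-row tibble (the tetrad, columns as in `matches` plus
#'   `motif` labelled I--IV), or a zero-row tibble when no valid tetrad
#'   exists.
#' @export
find_tetrad <- function(matches, max_linker = 20, prefer = c("first", "last")) {
  prefer <- match.arg(prefer)
  empty <- dplyr::mutate(matches[0, , drop = FALSE], motif = character())
  if (nrow(matches) < 4L) return(empty)
  if ("seq_id" %in% names(matches) && length(unique(matches$seq_id)) > 1L) {
    abort("find_tetrad() expects matches from a single sequence")
  }
  m <- dplyr::arrange(matches, .data$start, .data$end)
  gaps <- m$start[-1] - m$end[-nrow(m)] - 1L
  ok_step <- gaps >= 0L & gaps <= max_linker
  windows <- which(vapply(seq_len(nrow(m) - 3L),
                          function(i) all(ok_step[i:(i + 2L)]), TRUE))
  if (length(windows) == 0L) return(empty)
  i <- if (prefer == "first") windows[1] else windows[length(windows)]
  out <- m[i:(i + 3L), , drop = FALSE]
  out$motif <- c("I", "II", "III", "IV")
  out
}
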