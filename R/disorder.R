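#' Build a per-residue disorder track
#'
#' Validates a per-residue disorder-prediction table (the shape produced by
#' per-residue disorder predictors: one row per position with a score in
#' \[0, 1\] and/or an ordered/disordered state call). Disorder prediction
#' itself is upstream of this package -- the predictors are trained
#' classifiers -- so this module consumes their output only.
#'
#' @param df A data frame with columns `position`, `residue`, and `score`
#'   and/or `state` (`state` may be logical, `0/1`, or
#'   `"ordered"/"disordered"`).
#' @param threshold Score threshold applied when `state` is absent
#'   (default 0.5, the conventional midpoint; the published 5%-false-
#'   positive-rate threshold is a calibration of the upstream predictor and
#'   not recomputable here).
#' @param id Sequence id recorded on the track (default `"seq1"` or the
#'   `seq_id` column when present).
#' @return A tibble of class `disorder_track` with columns `seq_id`,
#'   `position`, `residue`, `score`, `state` (logical: `TRUE` =
#'   disordered); attribute `threshold`.
#' @export
disorder_track <- function(df, threshold = 0.5, id = NULL) {
  df <- as_tibble(df)
  if (nrow(df) == 0L) abort("empty disorder table")
  if (!"position" %in% names(df)) abort("disorder table needs a `position` column")
  if (is.null(id)) id <- if ("seq_id" %in% names(df)) df$seq_id[[1]] else "seq1"
  df <- dplyr::arrange(df, .data$position)
  pos <- as.integer(df$position)
  expected <- seq_len(length(pos))
  if (!identical(pos, expected)) {
    gap_at <- expected[which(pos != expected)[1]]
    abort(sprintf("position gap at %d: positions must be contiguous from 1", gap_at))
  }
  has_score <- "score" %in% names(df)
  has_state <- "state" %in% names(df)
  if (!has_score && !has_state) abort("disorder table needs `score` and/or `state`")
  score <- if (has_score) as.numeric(df$score) else rep(NA_real_, nrow(df))
  if (has_score && any(score < 0 | score > 1, na.rm = TRUE)) {
    abort("disorder scores must lie in [0, 1]")
  }
  state <- if (has_state) parse_state(df$state) else score >= threshold
  res <- if ("residue" %in% names(df)) toupper(as.character(df$residue))
         else rep(NA_character_, nrow(df))
  out <- tibble(seq_id = id, position = pos, residue = res,
                score = score, state = state)
  structure(out, threshold = threshold,
            class = c("disorder_track", class(out)))
}

parse_state <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  x <- tolower(as.character(x))
  if (all(x %in% c("ordered", "disordered"))) return(x == "disordered")
  if (all(x %in% c("o", "d", ".", "*"))) return(x %in% c("d", "*"))
  abort("unrecognised `state` encoding in disorder table")
}

#' Read a per-residue disorder table (TSV)
#'
#' Tab-delimited with a header row; lines starting with `#` are ignored.
#' Expected columns: `position`, `residue`, `score` and/or `state`
#' (optionally `seq_id`).
#'
#' @param path Path to the TSV file.
#' @inheritParams disorder_track
#' @return A `disorder_track` tibble; see [disorder_track()].
#' @export
read_disorder_track <- function(path, threshold = 0.5, id = NULL) {
  if (!file.exists(path)) abort(sprintf("disorder table not found: %s", path))
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  disorder_track(df, threshold = threshold, id = id)
}

#' Call disordered regions from a disorder track
#'
#' Returns the maximal runs of disordered state of length at least
#' `min_len`, as 1-based closed intervals.
#'
#' @param track A `disorder_track` (or compatible tibble with `seq_id`,
#'   `position`, `state`).
#' @param min_len Minimum region length in residues (default 5; short
#'   isolated calls are typically low-confidence).
#' @return A tibble of region annotations: `seq_id`, `start`, `end`,
#'   `kind = "disordered"`, `detail` (mean score over the region, as text).
#' @export
call_disordered_regions <- function(track, min_len = 5) {
  stopifnot(all(c("seq_id", "position", "state") %in% names(track)))
  out <- lapply(split(as_tibble(track), track$seq_id), function(tr) {
    tr <- dplyr::arrange(tr, .data$position)
    r <- rle(tr$state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_len
    if (!any(keep)) return(NULL)
    tibble(seq_id = tr$seq_id[[1]],
           start = tr$position[starts[keep]],
           end = tr$position[ends[keep]],
           kind = "disordered",
           detail = sprintf("mean_score=%.3f", vapply(which(keep), function(i) {
             mean(tr$score[starts[i]:ends[i]], na.rm = TRUE)
           }, 1)))
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) {
    out <- tibble(seq_id = character(), start = integer(), end = integer(),
                  kind = character(), detail = character())
  }
  out
}

#' Detect compositionally biased ("X-rich") residue patches
#'
#' Slides a window along the sequence and, for each residue type, merges
#' all windows in which that residue's frequency reaches `min_frac` into
#' maximal patches. Disordered extensions are frequently dominated by
#' single-residue patches (Gln-rich, Gly-rich, ...), and patches of
#' different residues may overlap; all are reported.
#'
#' @param seq A single protein sequence (string, or one-row tibble with
#'   `id`/`residues`).
#' @param window Window width in residues (default 20; must be >= 5).
#' @param min_frac Minimum within-window frequency of the dominant residue
#'   (default 0.35). Defaults are exposed because reported patches span a
#'   wide length range (about 21--322 aa) and no canonical thresholds
#'   exist.
#' @return A tibble: `seq_id`, `start`, `end`, `kind = "x-rich"`, `detail`
#'   (dominant residue), `residue`, `frequency` (of the dominant residue
#'   within the patch). Sequences shorter than `window` yield an empty
#'   result with a warning.
#' @export
#' @examples
#' find_bias_patches(strrep("Q", 30), window = 20, min_frac = 0.35)
find_bias_patches <- function(seq, window = 20, min_frac = 0.35) {
  if (window < 5) abort("`window` must be >= 5")
  if (min_frac <= 0 || min_frac > 1) abort("`min_frac` must be in (0, 1]")
  seq_tbl <- as_protein_tbl(seq, "seq")
  if (nrow(seq_tbl) != 1L) abort("`seq` must be a single sequence")
  id <- seq_tbl$id[[1]]
  cc <- chars(seq_tbl$residues[[1]])
  L <- length(cc)
  empty <- tibble(seq_id = character(), start = integer(), end = integer(),
                  kind = character(), detail = character(),
                  residue = character(), frequency = numeric())
  if (L < window) {
    warn(sprintf("sequence '%s' (%d aa) shorter than window (%d); no patches called",
                 id, L, window))
    return(empty)
  }
  need <- ceiling(min_frac * window - 1e-9)
  out <- list()
  for (res in intersect(unique(cc), AA20)) {
    ind <- as.integer(cc == res)
    counts <- cumsum(ind)
    win_counts <- counts[window:L] - c(0, counts)[seq_len(L - window + 1L)]
    hit_starts <- which(win_counts >= need)
    if (length(hit_starts) == 0L) next
    covered <- rep(FALSE, L)
    for (s in hit_starts) covered[s:(s + window - 1L)] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      s <- starts[k]; e <- ends[k]
      # trim patch boundaries to occurrences of the dominant residue
      occ <- which(ind[s:e] == 1L) + s - 1L
      if (length(occ) == 0L) next
      s <- occ[1]; e <- occ[length(occ)]
      if (e - s + 1L < window) next  # minimum patch length = window
      out[[length(out) + 1L]] <- tibble(
        seq_id = id, start = s, end = e, kind = "x-rich", detail = res,
        residue = res, frequency = mean(cc[s:e] == res))
    }
  }
  if (length(out) == 0L) return(empty)
  dplyr::arrange(dplyr::bind_rows(out), .data$start, .data$residue)
}

#' Write region annotations as BED-like TSV
#'
#' Columns `seq_id`, `start`, `end`, `kind`, `detail`, tab-delimited. The
#' coordinates are 1-based and fully closed, stated in the file header.
#'
#' @param annotations Annotation tibble (`seq_id`, `start`, `end`, `kind`,
#'   `detail`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates are 1-based, fully closed intervals", con)
  writeLines(paste(c("seq_id", "start", "end", "kind", "detail"), collapse = "\t"), con)
  if (nrow(annotations) > 0) {
    lines <- apply(annotations[, c("seq_id", "start", "end", "kind", "detail")],
                   1L, paste, collapse = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}
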