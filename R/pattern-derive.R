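#' Derive a consensus Prosite-dialect pattern from aligned motif instances
#'
#' Summarises an alignment of motif instances into a pattern string using
#' the lowercase-exceptional-residue convention: per column, residues whose
#' frequency reaches `f_major` are written uppercase ("major"), residues
#' observed below `f_major` are written lowercase ("exceptional"), and a
#' column whose top residue frequency falls below `f_wild` becomes a
#' wildcard. Consecutive wildcard columns consolidate to `x(n)`, or to
#' `x(n,m)` where instance gap patterns make the covered lengths vary.
#' Columns where a single residue dominates completely emit the bare letter.
#'
#' Frequencies are computed over the total instance count (gap rows count
#' toward the denominator), so a residue contributed by a single-instance
#' insertion column classifies as part of a variable-length wildcard region
#' and the derived pattern stays consistent with all of its own instances.
#' Within a bracket, members are ordered by descending frequency, ties
#' broken by first appearance in instance order.
#'
#' @param instances An alignment of motif instances (tibble with
#'   `id`/`residues`, named character vector, or character vector), at least
#'   two rows.
#' @param f_major Frequency at or above which a residue is a major
#'   (uppercase) member. Default 0.2.
#' @param f_wild If the most frequent residue of a column is below this
#'   frequency the column is written as a wildcard. Default 0.5.
#' @return The derived pattern as a string (parseable by [parse_pattern()]).
#' @export
#' @examples
#' derive_pattern(c("CAAC", "CTTC", "CAGC"))  # "C-[AT]-x-C"
derive_pattern <- function(instances, f_major = 0.2, f_wild = 0.5) {
  if (f_major <= 0) abort("`f_major` must be > 0")
  aln <- check_alignment(as_protein_tbl(instances, "instances"), "instances")
  if (nrow(aln) < 2L) abort("need at least two aligned instances")
  m <- alignment_matrix(aln)
  n <- nrow(m)

  col_class <- character(ncol(m))
  col_set <- vector("list", ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    res <- col[col != GAP]
    if (length(res) == 0L) { col_class[j] <- "wild"; next }
    # frequency over total instances; members ordered by first appearance
    first_seen <- !duplicated(res)
    members <- res[first_seen]
    freq <- as.vector(table(factor(res, levels = members))) / n
    ord <- order(-freq, seq_along(members))
    members <- members[ord]; freq <- freq[ord]
    if (freq[1] < f_wild) { col_class[j] <- "wild"; next }
    col_class[j] <- "set"
    col_set[[j]] <- list(major = members[freq >= f_major],
                         exceptional = members[freq < f_major])
  }

  toks <- character(); j <- 1L
  while (j <= ncol(m)) {
    if (col_class[j] == "wild") {
      k <- j
      while (k < ncol(m) && col_class[k + 1L] == "wild") k <- k + 1L
      # per-instance covered length across the wildcard run
      block <- m[, j:k, drop = FALSE]
      covered <- rowSums(block != GAP)
      lo <- min(covered); hi <- max(covered)
      if (lo < 1L) lo <- max(lo, 1L)  # a run must consume >= 1 position
      tok <- if (lo == hi && lo == 1L) "x"
             else if (lo == hi) sprintf("x(%d)", lo)
             else sprintf("x(%d,%d)", lo, hi)
      toks <- c(toks, tok)
      j <- k + 1L
    } else {
      s <- col_set[[j]]
      tok <- if (length(s$major) == 1L && length(s$exceptional) == 0L) s$major
             else paste0("[", paste0(c(s$major, tolower(s$exceptional)), collapse = ""), "]")
      toks <- c(toks, tok)
      j <- j + 1L
    }
  }
  paste(toks, collapse = "-")
}

#' Frequency / information matrix of aligned motif instances
#'
#' Computes, per alignment column, residue frequencies over the 20 standard
#' amino acids (renormalised over non-gap residues) plus the gap fraction,
#' and the information content in bits:
#' \deqn{I_j = \log_2 20 - H_j - e_n,}
#' where \eqn{H_j} is the column's Shannon entropy in bits and
#' \eqn{e_n = 19 / (2 \ln 2 \cdot n)} is the small-sample correction
#' (applied by default, mirroring common sequence-logo practice; disable
#' with `small_sample_correction = FALSE`). Information is clamped at 0.
#' A column consisting entirely of gaps gets zero frequencies, zero
#' information, and `all_gap = TRUE`.
#'
#' @param instances Alignment of motif instances (any form accepted by
#'   [read_alignment()]-style tibbles or character vectors).
#' @param small_sample_correction Logical, default `TRUE`.
#' @return A tibble of class `logo_matrix` with columns `column`, one
#'   frequency column per amino acid (`A` ... `Y`), `gap`, `information`,
#'   `n_residues`, `all_gap`; attribute `n` is the instance count.
#' @export
logo_matrix <- function(instances, small_sample_correction = TRUE) {
  aln <- check_alignment(as_protein_tbl(instances, "instances"), "instances")
  m <- alignment_matrix(aln)
  n_inst <- nrow(m)
  rows <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    res <- col[col %in% AA20]
    n <- length(res)
    freq <- if (n > 0) as.vector(table(factor(res, levels = AA20))) / n
            else rep(0, 20)
    info <- 0
    if (n > 0) {
      p <- freq[freq > 0]
      H <- -sum(p * log2(p))
      info <- log2(20) - H
      if (small_sample_correction) info <- info - 19 / (2 * log(2) * n)
      info <- max(info, 0)
    }
    out <- c(list(column = j), as.list(setNames(freq, AA20)),
             list(gap = sum(col == GAP) / n_inst,
                  information = info, n_residues = n, all_gap = n == 0L))
    as_tibble(out)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, n = n_inst, class = c("logo_matrix", class(out)))
}

#' @describeIn logo_matrix Stacked-bar rendering of per-column residue
#'   contributions scaled by information content.
#' @param object A `logo_matrix`.
#' @param ... Unused.
#' @export
autoplot.logo_matrix <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object)[, c("column", AA20, "information")],
                              cols = dplyr::all_of(AA20),
                              names_to = "residue", values_to = "frequency")
  long <- dplyr::filter(long, .data$frequency > 0)
  long$height <- long$frequency * long$information
  ggplot2::ggplot(long, ggplot2::aes(x = .data$column, y = .data$height,
                                     fill = .data$residue)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.1) +
    ggplot2::labs(x = "alignment column", y = "information (bits)",
                  fill = "residue") +
    ggplot2::theme_minimal()
}
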