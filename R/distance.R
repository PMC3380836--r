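#' p-distance between two aligned sequences with pairwise deletion
#'
#' The p-distance is the proportion of differing sites among comparable
#' positions. Comparable positions are those where both rows carry one of
#' the 20 standard residues: gaps and `X` (unknown) are excluded per pair
#' ("pairwise deletion"), since an unknown residue can be scored neither
#' as match nor mismatch.
#'
#' @param row_a,row_b Gapped sequences of equal length (strings).
#' @param columns Optional integer vector restricting the computation to a
#'   column subset.
#' @return A list with `distance` (in \[0, 1\], `NA` when no site is
#'   comparable) and `sites` (comparable-site count).
#' @export
#' @examples
#' p_distance("ACDE", "ACDF")   # 0.25 over 4 sites
#' p_distance("AC-EF", "ACDEF") # 0 over 4 sites (pairwise deletion)
p_distance <- function(row_a, row_b, columns = NULL) {
  a <- chars(row_a)
  b <- chars(row_b)
  if (length(a) != length(b)) {
    abort(sprintf("row lengths differ (%d vs %d)", length(a), length(b)))
  }
  if (!is.null(columns)) {
    if (any(columns < 1L | columns > length(a))) abort("`columns` out of bounds")
    a <- a[columns]; b <- b[columns]
  }
  comp <- a %in% AA20 & b %in% AA20
  sites <- sum(comp)
  list(distance = if (sites == 0L) NA_real_ else mean(a[comp] != b[comp]),
       sites = sites)
}

#' Pairwise p-distance matrix of an alignment
#'
#' Computes all unordered pairwise p-distances (pairwise deletion, see
#' [p_distance()]) over an optional column subset, together with
#' comparable-site counts and the overall mean distance (mean of the
#' defined off-diagonal entries).
#'
#' @param aln Alignment (tibble with `id`/`residues`, or character vector);
#'   at least two rows.
#' @param columns Optional column subset.
#' @return An object of class `p_dist`: list with `distance` and `sites`
#'   matrices (taxa in rows/columns), `taxa`, `overall_mean`, `columns`.
#'   Methods: [tidy()], `as.matrix()`, `as.dist()`, `print()`.
#' @export
distance_matrix <- function(aln, columns = NULL) {
  aln <- check_alignment(as_protein_tbl(aln, "aln"), "aln")
  if (nrow(aln) < 2L) abort("need at least two sequences")
  m <- alignment_matrix(aln)
  if (!is.null(columns)) {
    if (any(columns < 1L | columns > ncol(m))) abort("`columns` out of bounds")
    m <- m[, columns, drop = FALSE]
  }
  n <- nrow(m)
  ok <- matrix(m %in% AA20, nrow = n)
  D <- matrix(0, n, n, dimnames = list(aln$id, aln$id))
  S <- matrix(0L, n, n, dimnames = list(aln$id, aln$id))
  diag(S) <- rowSums(ok)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      s <- sum(comp)
      d <- if (s == 0L) NA_real_ else sum(m[i, comp] != m[j, comp]) / s
      D[i, j] <- D[j, i] <- d
      S[i, j] <- S[j, i] <- s
    }
  }
  vals <- D[upper.tri(D)]
  structure(list(distance = D, sites = S, taxa = aln$id,
                 overall_mean = mean(vals, na.rm = TRUE),
                 columns = columns),
            class = "p_dist")
}

#' @export
as.matrix.p_dist <- function(x, ...) x$distance

#' @importFrom stats as.dist
#' @export
as.dist.p_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$distance, diag = diag, upper = upper)
}

#' @export
print.p_dist <- function(x, ...) {
  cat(sprintf("<p_dist> %d taxa, overall mean distance %.4f\n",
              length(x$taxa), x$overall_mean))
  print(round(x$distance, 4))
  invisible(x)
}

#' @export
tidy.p_dist <- function(x, ...) {
  D <- x$distance; S <- x$sites
  idx <- which(upper.tri(D), arr.ind = TRUE)
  tibble(item1 = x$taxa[idx[, 1]], item2 = x$taxa[idx[, 2]],
         distance = D[idx], sites = S[idx])
}

#' Bootstrap variance of one pairwise p-distance
#'
#' Resamples alignment columns with replacement, recomputes the p-distance
#' of the chosen pair per replicate, and returns the unbiased sample
#' variance across replicates. Replicates in which the resampled pair has
#' no comparable site are excluded and counted. Deterministic for a fixed
#' seed.
#'
#' @param aln Alignment (as in [distance_matrix()]).
#' @param pair Character vector of two sequence ids (or two row indices).
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed (required, for reproducibility).
#' @param columns Optional column subset resampled from.
#' @return List with `variance`, `n_used`, `n_excluded`, `replicates`.
#' @export
bootstrap_variance <- function(aln, pair, replicates = 1000, seed, columns = NULL) {
  if (missing(seed)) abort("`seed` is required for bootstrap_variance()")
  if (replicates < 2) abort("`replicates` must be >= 2")
  aln <- check_alignment(as_protein_tbl(aln, "aln"), "aln")
  idx <- if (is.numeric(pair)) as.integer(pair) else match(pair, aln$id)
  if (length(idx) != 2L || anyNA(idx)) abort("`pair` must name two rows of the alignment")
  a <- chars(aln$residues[[idx[1]]])
  b <- chars(aln$residues[[idx[2]]])
  if (!is.null(columns)) { a <- a[columns]; b <- b[columns] }
  L <- length(a)
  comp <- a %in% AA20 & b %in% AA20
  mism <- comp & a != b
  set.seed(seed)
  cols <- matrix(sample.int(L, L * replicates, replace = TRUE), nrow = L)
  sites <- colSums(matrix(comp[cols], nrow = L))
  diffs <- colSums(matrix(mism[cols], nrow = L))
  defined <- sites > 0L
  d <- diffs[defined] / sites[defined]
  list(variance = var(d), n_used = sum(defined),
       n_excluded = sum(!defined), replicates = replicates)
}
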