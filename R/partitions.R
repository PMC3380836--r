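#' Partition alignment columns into structured vs disordered sets
#'
#' A column is assigned to the disordered set when more than `rule_frac`
#' of its non-gap residues fall inside a `kind = "disordered"` annotation
#' of their own row; all remaining columns are structured. The two sets
#' are disjoint and together cover every column.
#'
#' @param aln Alignment (tibble with `id`/`residues` or character vector).
#' @param annotations Region annotations (`seq_id`, `start`, `end`,
#'   `kind`), with coordinates in each row's own ungapped residue space.
#' @param rule_frac Fraction threshold (default 0.5; the translation of
#'   per-sequence disorder calls into alignment partitions admits several
#'   conventions, so the threshold is exposed).
#' @return A tibble with columns `column` and `partition`
#'   (`"structured"`/`"disordered"`).
#' @export
partition_columns <- function(aln, annotations, rule_frac = 0.5) {
  aln <- check_alignment(as_protein_tbl(aln, "aln"), "aln")
  ann <- dplyr::filter(as_tibble(annotations), .data$kind == "disordered")
  unknown <- setdiff(unique(ann$seq_id), aln$id)
  if (length(unknown)) {
    abort(sprintf("annotation(s) reference unknown row(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  dis <- row_disorder_flags(aln, ann)        # rows x columns, NA at gaps
  n_nongap <- colSums(!is.na(dis))
  n_dis <- colSums(dis, na.rm = TRUE)
  disordered <- n_nongap > 0L & n_dis > rule_frac * n_nongap
  tibble(column = seq_along(disordered),
         partition = ifelse(disordered, "disordered", "structured"))
}

# logical matrix rows x columns: is this row's residue at this column
# inside one of its own disordered annotations? NA at gap columns.
row_disorder_flags <- function(aln, ann) {
  m <- alignment_matrix(aln)
  out <- matrix(NA, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    pos <- residue_positions(aln$residues[[i]])
    a <- ann[ann$seq_id == aln$id[[i]], , drop = FALSE]
    flag <- rep(FALSE, max(pos, 0L, na.rm = TRUE))
    if (nrow(a)) for (k in seq_len(nrow(a))) flag[a$start[k]:a$end[k]] <- TRUE
    out[i, !is.na(pos)] <- flag[pos[!is.na(pos)]]
  }
  out
}

#' Kruskal-Wallis rank test across labelled groups
#'
#' Computes the Kruskal-Wallis H statistic with midranks and tie
#' correction, and a p-value from the chi-square approximation with
#' `k - 1` degrees of freedom (optionally a seeded permutation p-value for
#' small samples). When every value is identical across groups, H is 0 by
#' convention (the tie-corrected statistic is otherwise 0/0).
#'
#' @param data A data frame with a value column and a group column, or a
#'   named list of numeric vectors (one per group).
#' @param value,group Column names (tidy-eval) when `data` is a data frame.
#' @param p_method `"chisq"` (default) or `"permutation"`.
#' @param n_perm Permutation count for `p_method = "permutation"`.
#' @param seed Seed for the permutation p-value.
#' @return An object of class `kw_test`: list with `statistic` (H), `df`,
#'   `p.value`, `tie_correction` (the factor \eqn{1 - \sum(t^3 - t)/(N^3 - N)}),
#'   `group_sizes`, `method`. Methods: [tidy()], [glance()], `print()`.
#' @export
#' @examples
#' kruskal_wallis(list(a = 1:3, b = 4:6, c = 7:9))$statistic # 7.2
kruskal_wallis <- function(data, value = NULL, group = NULL,
                           p_method = c("chisq", "permutation"),
                           n_perm = 2000, seed = NULL) {
  p_method <- match.arg(p_method)
  if (is.data.frame(data)) {
    value <- rlang::enquo(value); group <- rlang::enquo(group)
    x <- rlang::eval_tidy(value, data)
    g <- rlang::eval_tidy(group, data)
  } else if (is.list(data)) {
    if (is.null(names(data))) names(data) <- paste0("group", seq_along(data))
    x <- unlist(data, use.names = FALSE)
    g <- rep(names(data), lengths(data))
  } else {
    abort("`data` must be a data frame or a named list of numeric vectors")
  }
  keep <- !is.na(x)
  x <- x[keep]; g <- as.character(g[keep])
  sizes <- table(g)
  if (length(sizes) < 2L) abort("need at least two groups")
  if (any(sizes == 0L)) abort("every group must be non-empty")
  N <- length(x)
  if (N < 3L) abort("need at least three observations in total")
  k <- length(sizes)
  t_counts <- table(x)
  tie_c <- 1 - sum(t_counts^3 - t_counts) / (N^3 - N)

  if (length(unique(x)) == 1L) {
    H <- 0; p <- 1
  } else {
    kt <- stats::kruskal.test(x, factor(g))
    H <- unname(kt$statistic)
    p <- kt$p.value
  }

  if (p_method == "permutation") {
    if (!is.null(seed)) set.seed(seed)
    r <- rank(x)
    h_of <- function(gg) {
      if (tie_c == 0) return(0)
      rs <- tapply(r, gg, sum)
      ns <- tapply(r, gg, length)
      (12 / (N * (N + 1)) * sum(rs^2 / ns) - 3 * (N + 1)) / tie_c
    }
    perms <- replicate(n_perm, h_of(sample(g)))
    p <- (1 + sum(perms >= H - 1e-12)) / (n_perm + 1)
  }

  structure(list(statistic = H, df = k - 1L, p.value = p,
                 tie_correction = tie_c,
                 group_sizes = as.integer(sizes),
                 groups = names(sizes),
                 method = p_method),
            class = "kw_test")
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g (%s)\n",
              x$statistic, x$df, x$p.value, x$method))
  cat("groups:", paste(sprintf("%s (n=%d)", x$groups, x$group_sizes),
                       collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.kw_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
         tie_correction = x$tie_correction, method = x$method)
}

#' @export
glance.kw_test <- function(x, ...) tidy(x)

#' Compare divergence across full-length / structured / disordered partitions
#'
#' Computes pairwise p-distances (pairwise deletion) on the full column
#' set, the structured-only columns, and the disordered-only columns,
#' tests the three distance collections with a Kruskal-Wallis rank test,
#' and emits a per-partition five-number box-plot summary. Pairwise
#' distances are not independent observations; the rank test is applied
#' to them as the conventional summary of partitioned divergence and its
#' p-value should be read with that caveat (see the package vignette).
#'
#' @param aln Alignment with at least three rows.
#' @param annotations Disorder annotations (see [partition_columns()]).
#' @param rule_frac Column-vote threshold for [partition_columns()].
#' @param method `"columns"` (default) partitions alignment columns by
#'   vote; `"per-row-mask"` instead restricts each pair's comparable sites
#'   to positions where both rows are inside (disordered) or outside
#'   (structured) their own annotations.
#' @param p_method,seed Passed to [kruskal_wallis()].
#' @return An object of class `partition_divergence`: list with
#'   `distances` (long tibble: `partition`, `item1`, `item2`, `distance`,
#'   `sites`), `summary` (per-partition `min`, `q1`, `median`, `q3`,
#'   `max`, `n_pairs`), `kw` (a `kw_test`), `partitions` (column index
#'   sets), `empty_partitions`. Methods: [tidy()], [glance()],
#'   [autoplot()], `print()`.
#' @export
compare_partitions <- function(aln, annotations, rule_frac = 0.5,
                               method = c("columns", "per-row-mask"),
                               p_method = c("chisq", "permutation"),
                               seed = NULL) {
  method <- match.arg(method)
  p_method <- match.arg(p_method)
  aln <- check_alignment(as_protein_tbl(aln, "aln"), "aln")
  if (nrow(aln) < 3L) abort("need at least three sequences")
  ncols <- nchar(aln$residues[[1]])

  if (method == "columns") {
    parts <- partition_columns(aln, annotations, rule_frac)
    col_sets <- list(
      `full-length` = seq_len(ncols),
      structured = parts$column[parts$partition == "structured"],
      disordered = parts$column[parts$partition == "disordered"]
    )
    dists <- lapply(col_sets, function(cols) {
      if (length(cols) == 0L) return(NULL)
      tidy(distance_matrix(aln, columns = cols))
    })
  } else {
    dis <- row_disorder_flags(
      aln, dplyr::filter(as_tibble(annotations), .data$kind == "disordered"))
    m <- alignment_matrix(aln)
    ok <- matrix(m %in% AA20, nrow = nrow(m))
    pair_dists <- function(mask_fun) {
      idx <- utils::combn(nrow(m), 2)
      dplyr::bind_rows(lapply(seq_len(ncol(idx)), function(p) {
        i <- idx[1, p]; j <- idx[2, p]
        comp <- ok[i, ] & ok[j, ] & mask_fun(i, j)
        s <- sum(comp)
        tibble(item1 = aln$id[i], item2 = aln$id[j],
               distance = if (s == 0L) NA_real_ else
                 sum(m[i, comp] != m[j, comp]) / s,
               sites = s)
      }))
    }
    dists <- list(
      `full-length` = pair_dists(function(i, j) TRUE),
      structured = pair_dists(function(i, j) !isTRUE_mat(dis, i) & !isTRUE_mat(dis, j)),
      disordered = pair_dists(function(i, j) isTRUE_mat(dis, i) & isTRUE_mat(dis, j))
    )
    col_sets <- NULL
  }

  empty <- names(dists)[vapply(dists, is.null, TRUE)]
  dists <- dists[!vapply(dists, is.null, TRUE)]
  long <- dplyr::bind_rows(dists, .id = "partition")
  defined <- dplyr::filter(long, !is.na(.data$distance))

  summary_tbl <- dplyr::summarise(
    dplyr::group_by(defined, .data$partition),
    min = min(.data$distance),
    q1 = quantile(.data$distance, 0.25, names = FALSE),
    median = quantile(.data$distance, 0.5, names = FALSE),
    q3 = quantile(.data$distance, 0.75, names = FALSE),
    max = max(.data$distance),
    n_pairs = dplyr::n(),
    .groups = "drop"
  )

  groups <- split(defined$distance, defined$partition)
  kw <- if (length(groups) >= 2L) {
    kruskal_wallis(groups, p_method = p_method, seed = seed)
  } else NULL
  if (length(empty)) {
    warn(sprintf("empty partition(s): %s", paste(empty, collapse = ", ")))
  }

  structure(list(distances = long, summary = summary_tbl, kw = kw,
                 partitions = col_sets, empty_partitions = empty,
                 method = method, rule_frac = rule_frac),
            class = "partition_divergence")
}

# row-wise helper for the per-row-mask variant
isTRUE_mat <- function(dis, i) {
  v <- dis[i, ]
  v[is.na(v)] <- FALSE
  v
}

#' @export
print.partition_divergence <- function(x, ...) {
  cat("<partition_divergence> (", x$method, " partitioning)\n", sep = "")
  print(x$summary)
  if (!is.null(x$kw)) print(x$kw)
  if (length(x$empty_partitions)) {
    cat("empty partitions:", paste(x$empty_partitions, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.partition_divergence <- function(x, ...) x$distances

#' @export
glance.partition_divergence <- function(x, ...) {
  med <- setNames(x$summary$median, x$summary$partition)
  tibble(
    n_pairs = sum(x$summary$n_pairs),
    median_full = unname(med["full-length"]),
    median_structured = unname(med["structured"]),
    median_disordered = unname(med["disordered"]),
    statistic = if (is.null(x$kw)) NA_real_ else x$kw$statistic,
    df = if (is.null(x$kw)) NA_integer_ else x$kw$df,
    p.value = if (is.null(x$kw)) NA_real_ else x$kw$p.value
  )
}

#' @describeIn compare_partitions Box plot of pairwise distances per
#'   partition (the conventional view of partitioned divergence).
#' @param object A `partition_divergence`.
#' @param ... Unused.
#' @export
autoplot.partition_divergence <- function(object, ...) {
  d <- dplyr::filter(object$distances, !is.na(.data$distance))
  d$partition <- factor(d$partition,
                        levels = c("structured", "disordered", "full-length"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$partition, y = .data$distance)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "pairwise p-distance") +
    ggplot2::theme_minimal()
}
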