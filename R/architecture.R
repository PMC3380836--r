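#' Assemble domain architectures: N-extension / C2H2 tetrad core / C-extension
#'
#' For each protein, scans for the C2H2 motif pattern, locates the
#' zinc-finger tetrad, and partitions the sequence into an N-terminal
#' extension, the conserved core (motif I start through motif IV end,
#' inclusive of the inter-motif linkers, treated as one conserved domain),
#' and a C-terminal extension. When more than four motifs are present the
#' C-terminal-most valid tetrad is chosen, since the tetrad of this family
#' sits at the C-terminal end. Supplied region annotations (disordered
#' regions, biased patches) are attached and classified by where they lie.
#'
#' @param seqs Protein sequences (tibble with `id`/`residues`, named
#'   character vector, or single string).
#' @param pattern C2H2 pattern (text or `prosite_pattern`); default the
#'   generic C2H2 pattern PS00028 from [ovol_patterns()].
#' @param annotations Optional region annotation tibble (`seq_id`, `start`,
#'   `end`, `kind`, ...), e.g. from [call_disordered_regions()] or
#'   [find_bias_patches()].
#' @param max_linker Maximum inter-motif linker length passed to
#'   [find_tetrad()].
#' @return A tibble of class `ovol_architecture`, one row per protein:
#'   `seq_id`, `length`, `core_start`, `core_end`, `n_extension_len`,
#'   `c_extension_len`, `side` (`"N-only"`, `"C-only"`, `"both"`,
#'   `"none"`), list-columns `tetrad` (four-row match tibble) and
#'   `id_regions` (annotations with a `location` column: `n-extension`,
#'   `core`, or `c-extension`). Always
#'   `n_extension_len + core length + c_extension_len = length`.
#' @export
build_architecture <- function(seqs, pattern = ovol_patterns()[["ps00028"]],
                               annotations = NULL, max_linker = 20) {
  pattern <- as_pattern(pattern)
  seqs <- as_protein_tbl(seqs)
  rows <- lapply(seq_len(nrow(seqs)), function(i) {
    id <- seqs$id[[i]]
    total <- nchar(seqs$residues[[i]])
    matches <- scan_pattern(seqs[i, ], pattern, mode = "leftmost")
    tet <- find_tetrad(matches, max_linker = max_linker, prefer = "last")
    if (nrow(tet) < 4L) {
      abort(sprintf("no C2H2 tetrad found in '%s' (%d motif match(es))",
                    id, nrow(matches)),
            class = "ovolution_no_tetrad",
            matches = matches)
    }
    core_start <- tet$start[1]
    core_end <- tet$end[4]
    n_ext <- core_start - 1L
    c_ext <- total - core_end
    ann <- if (is.null(annotations)) {
      tibble(seq_id = character(), start = integer(), end = integer(),
             kind = character(), location = character())
    } else {
      a <- dplyr::filter(as_tibble(annotations), .data$seq_id == id)
      a$location <- dplyr::case_when(
        a$end < core_start ~ "n-extension",
        a$start > core_end ~ "c-extension",
        TRUE ~ "core"
      )
      a
    }
    tibble(seq_id = id, length = total,
           core_start = core_start, core_end = core_end,
           n_extension_len = n_ext, c_extension_len = c_ext,
           side = extension_side(n_ext, c_ext),
           tetrad = list(tet), id_regions = list(ann))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("ovol_architecture", class(out)))
}

extension_side <- function(n_ext, c_ext) {
  dplyr::case_when(
    n_ext > 0 & c_ext > 0 ~ "both",
    n_ext > 0 ~ "N-only",
    c_ext > 0 ~ "C-only",
    TRUE ~ "none"
  )
}

#' Summarise a set of domain architectures
#'
#' One row per protein with lineage label, lengths, extension-side
#' classification, and the count and dominant residues of attached
#' biased/disordered patches; the min--max total-length range is attached
#' as attribute `length_range` and shown by `print()`.
#'
#' @param archs An `ovol_architecture` tibble from [build_architecture()].
#' @return A tibble: `seq_id`, `length`, `n_extension_len`,
#'   `c_extension_len`, `side`, `n_id_regions`, `dominant_residues`
#'   (comma-separated `detail` values of attached x-rich patches);
#'   attribute `length_range = c(min, max)`.
#' @export
summarize_architectures <- function(archs) {
  stopifnot(nrow(archs) >= 1L)
  out <- dplyr::mutate(
    as_tibble(archs)[, c("seq_id", "length", "n_extension_len",
                         "c_extension_len", "side")],
    n_id_regions = vapply(archs$id_regions, nrow, 1L),
    dominant_residues = vapply(archs$id_regions, function(a) {
      if (nrow(a) == 0L || !"detail" %in% names(a)) return("")
      paste(unique(a$detail[a$kind == "x-rich"]), collapse = ",")
    }, "")
  )
  structure(out, length_range = range(archs$length),
            class = c("architecture_summary", class(out)))
}

#' @export
print.architecture_summary <- function(x, ...) {
  rng <- attr(x, "length_range")
  NextMethod()
  cat(sprintf("# total length range: %d-%d aa\n", rng[1], rng[2]))
  invisible(x)
}

#' @describeIn build_architecture Domain-layout plot: one horizontal track
#'   per protein with the tetrad core, individual motifs and extensions.
#' @param object An `ovol_architecture`.
#' @param ... Unused.
#' @export
autoplot.ovol_architecture <- function(object, ...) {
  arch <- as_tibble(object)
  arch$y <- seq_len(nrow(arch))
  motifs <- dplyr::bind_rows(lapply(seq_len(nrow(arch)), function(i) {
    m <- arch$tetrad[[i]]
    m$y <- arch$y[i]
    m
  }))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = arch,
      ggplot2::aes(x = 1, xend = .data$length, y = .data$y, yend = .data$y),
      colour = "grey60") +
    ggplot2::geom_rect(data = arch,
      ggplot2::aes(xmin = .data$core_start, xmax = .data$core_end,
                   ymin = .data$y - 0.25, ymax = .data$y + 0.25),
      fill = "gold", colour = "grey30") +
    ggplot2::geom_rect(data = motifs,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = .data$y - 0.25, ymax = .data$y + 0.25),
      fill = "firebrick", alpha = 0.8) +
    ggplot2::scale_y_continuous(breaks = arch$y, labels = arch$seq_id) +
    ggplot2::labs(x = "residue", y = NULL) +
    ggplot2::theme_minimal()
}
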