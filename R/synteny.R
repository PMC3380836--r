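#' Read a gene-order table
#'
#' Tab-delimited with header, `#` comments ignored. Columns: `genome`,
#' `contig`, `rank` (gene order along the contig), `gene_id`, `family_id`
#' (paralogous genes share a family), `strand` (`+`/`-`), `is_focal`
#' (logical or 0/1 marking the focal gene of the locus, at most one per
#' genome/contig).
#'
#' @param path Path to the TSV.
#' @return A tibble with the columns above.
#' @export
read_gene_order <- function(path) {
  if (!file.exists(path)) abort(sprintf("gene-order table not found: %s", path))
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("genome", "contig", "rank", "gene_id", "family_id", "strand", "is_focal")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(sprintf("gene-order table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  df$is_focal <- parse_state(df$is_focal)
  df
}

#' Read a gene-to-family map
#'
#' Two tab-delimited columns `gene_id`, `family_id`. Genes absent from the
#' map default to their own singleton family.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `gene_id`, `family_id`.
#' @export
read_family_map <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("gene_id", "family_id") %in% names(df))) {
    abort("family map needs columns `gene_id` and `family_id`")
  }
  if (anyDuplicated(df$gene_id)) abort("family map assigns a gene to multiple families")
  df
}

#' Build a locus card: a focal gene plus its ordered flanking markers
#'
#' @param gene_order A gene-order tibble (see [read_gene_order()]),
#'   possibly covering several genomes.
#' @param genome Genome to extract.
#' @param contig Optional contig (needed when the genome has several loci).
#' @return An object of class `locus_card`: list with `genome`, `contig`,
#'   `focal_id` (`NA` when the locus has lost its focal gene) and
#'   `markers`, a tibble of flanking genes with `gene_id`, `family_id`,
#'   `strand`, `side` (`left`/`right` of the focal position; `NA` when no
#'   focal gene is present) and `rank_distance`.
#' @export
locus_card <- function(gene_order, genome, contig = NULL) {
  g <- dplyr::filter(as_tibble(gene_order), .data$genome == !!genome)
  if (!is.null(contig)) g <- dplyr::filter(g, .data$contig == !!contig)
  if (nrow(g) == 0L) abort(sprintf("no rows for genome '%s'", genome))
  if (length(unique(g$contig)) > 1L) {
    abort(sprintf("genome '%s' spans several contigs; supply `contig`", genome))
  }
  g <- dplyr::arrange(g, .data$rank)
  focal <- which(g$is_focal)
  if (length(focal) > 1L) abort("a locus card can hold at most one focal gene")
  focal_rank <- if (length(focal)) g$rank[focal] else NA_integer_
  markers <- g[!g$is_focal, c("gene_id", "family_id", "strand", "rank")]
  markers$side <- if (is.na(focal_rank)) NA_character_ else
    ifelse(markers$rank < focal_rank, "left", "right")
  markers$rank_distance <- if (is.na(focal_rank)) NA_integer_ else
    abs(markers$rank - focal_rank)
  structure(list(genome = genome, contig = g$contig[[1]],
                 focal_id = if (length(focal)) g$gene_id[focal] else NA_character_,
                 markers = markers[, c("gene_id", "family_id", "strand",
                                       "side", "rank_distance")]),
            class = "locus_card")
}

#' @export
print.locus_card <- function(x, ...) {
  cat(sprintf("<locus_card> %s / %s, focal: %s, %d markers\n",
              x$genome, x$contig,
              ifelse(is.na(x$focal_id), "(absent)", x$focal_id),
              nrow(x$markers)))
  invisible(x)
}

# markers within the rank window; cards without a focal gene contribute all
# markers (no anchor to measure rank distance from)
card_window <- function(card, window, fam = NULL) {
  m <- card$markers
  if (!all(is.na(m$rank_distance))) m <- m[m$rank_distance <= window, , drop = FALSE]
  if (!is.null(fam)) {
    hit <- match(m$gene_id, fam$gene_id)
    m$family_id <- ifelse(is.na(hit), m$family_id, fam$family_id[hit])
  }
  m
}

#' Shared flanking markers between two loci
#'
#' Intersects the marker gene ids of two locus cards (within a rank
#' window), and their family ids via the family map. Marker order and
#' strand are carried in the report but not scored: the classification
#' here argues from marker presence, not colinearity.
#'
#' @param a,b `locus_card` objects.
#' @param fam Optional family-map tibble (`gene_id`, `family_id`)
#'   overriding the cards' own family ids.
#' @param window Maximum rank distance from the focal position considered
#'   (default 8).
#' @return List with `genes` (shared gene ids), `families` (shared family
#'   ids), and `markers` (the two windowed marker tables).
#' @export
shared_markers <- function(a, b, fam = NULL, window = 8) {
  if (window < 1) abort("`window` must be >= 1")
  ma <- card_window(a, window, fam)
  mb <- card_window(b, window, fam)
  list(genes = intersect(ma$gene_id, mb$gene_id),
       families = intersect(ma$family_id, mb$family_id),
       markers = list(a = ma, b = mb))
}

#' Classify a pair of loci as orthologous, paralogous, or unrelated
#'
#' Orthologous loci share at least `min_ortho` identical marker genes.
#' Failing that, loci sharing at least `min_para` marker *families*
#' (homologous but non-identical flanking genes, e.g. the BANF1/BANF2 and
#' SNX32/SNX5 pairs that flank the two loci of a fragmental duplication)
#' are called `paralogous-duplication`. Anything else is `unrelated`.
#' Verdicts are invariant to swapping the left/right side labels, since
#' loci appear in either orientation across genomes.
#'
#' @inheritParams shared_markers
#' @param min_ortho Minimum shared identical markers for orthology
#'   (default 3, a conserved triad).
#' @param min_para Minimum shared marker families for a duplication call
#'   (default 2).
#' @return A one-row tibble: `genome_a`, `genome_b`, `focal_a`, `focal_b`,
#'   `shared_gene_count`, `shared_family_count`, `verdict`, plus
#'   list-columns `shared_genes`, `shared_families`.
#' @export
classify_locus_pair <- function(a, b, fam = NULL, min_ortho = 3, min_para = 2,
                                window = 8) {
  if (min_ortho < 1 || min_para < 1) abort("thresholds must be >= 1")
  sh <- shared_markers(a, b, fam = fam, window = window)
  n_genes <- length(sh$genes)
  n_fam <- length(sh$families)
  verdict <- if (n_genes >= min_ortho) "orthologous"
             else if (n_fam >= min_para) "paralogous-duplication"
             else "unrelated"
  tibble(genome_a = a$genome, genome_b = b$genome,
         focal_a = a$focal_id, focal_b = b$focal_id,
         shared_gene_count = n_genes, shared_family_count = n_fam,
         verdict = verdict,
         shared_genes = list(sh$genes), shared_families = list(sh$families))
}

#' Detect a duplication-then-loss scenario
#'
#' The post-duplication pattern in which a gene survives only at the
#' duplicated locus: the original locus (focal gene lost) still shares its
#' flanking markers with a reference genome's focal-bearing locus, and the
#' original and duplicated loci are tied together by at least one
#' paralogous marker-family pair (two different genes of one family, one
#' at each locus). When both conditions hold the verdict is
#' `duplicate-retained-original-lost`; otherwise `unrelated`.
#'
#' @param original `locus_card` whose focal gene is absent.
#' @param duplicated `locus_card` carrying the focal gene.
#' @param reference Focal-bearing `locus_card` from a reference genome
#'   (the lineage that retained the original locus).
#' @inheritParams classify_locus_pair
#' @return A one-row tibble: genomes, `shared_with_reference` (marker
#'   count), `paralogous_family_pairs` (list-column), `verdict`.
#' @export
detect_duplication_loss <- function(original, duplicated, reference,
                                    fam = NULL, min_ortho = 3, window = 8) {
  if (!is.na(original$focal_id)) {
    abort("`original` must be a locus card without a focal gene")
  }
  if (is.na(duplicated$focal_id)) {
    abort("both cards lack a focal gene; `duplicated` must carry the focal gene")
  }
  sh_ref <- shared_markers(original, reference, fam = fam, window = window)
  mo <- card_window(original, window, fam)
  md <- card_window(duplicated, window, fam)
  # paralogous pair: same family, different gene ids, one at each locus
  pairs <- dplyr::inner_join(
    mo[, c("gene_id", "family_id")], md[, c("gene_id", "family_id")],
    by = "family_id", suffix = c("_original", "_duplicated"),
    relationship = "many-to-many")
  pairs <- dplyr::filter(pairs, .data$gene_id_original != .data$gene_id_duplicated)
  verdict <- if (length(sh_ref$genes) >= min_ortho && nrow(pairs) >= 1L) {
    "duplicate-retained-original-lost"
  } else "unrelated"
  tibble(genome_original = original$genome,
         genome_duplicated = duplicated$genome,
         genome_reference = reference$genome,
         focal_duplicated = duplicated$focal_id,
         shared_with_reference = length(sh_ref$genes),
         paralogous_family_pairs = list(pairs),
         verdict = verdict)
}
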