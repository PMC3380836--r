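#' Published C2H2 pattern strings for the OVOL family
#'
#' The generic Prosite C2H2 pattern (PS00028) together with the
#' OVOL-specific per-motif patterns and the overall OVOL consensus, in the
#' lowercase-exceptional-residue convention. These strings are inputs to
#' the pattern engine, not derived quantities.
#'
#' @return A named character vector: `ps00028`, `motif_i` ... `motif_iv`,
#'   `overall`.
#' @export
#' @examples
#' parse_pattern(ovol_patterns()[["overall"]])
ovol_patterns <- function() {
  c(
    ps00028  = "C-x(2,4)-C-x(3)-[LIVMFYWC]-x(8)-H-x(3,5)-H",
    motif_i  = "C-x(2)-C-x(3)-[FW]-x(8)-H-x(3)-H",
    motif_ii = "C-x(2)-C-x(3)-[F]-x(8)-H-x(3)-H",
    motif_iii = "C-x(2)-C-x(3)-[F]-x(8)-H-x(4)-H",
    motif_iv = "C-x(2)-C-x(3)-[Fsgat]-x(8)-H-x(4)-H",
    overall  = "C-x(2)-C-x(3)-[FWsgat]-x(8)-H-x(3,4)-H"
  )
}

#' Literature-reported coordinates of OVOL reference proteins
#'
#' Printed feature coordinates of the human OVOL1 protein (267 aa) and the
#' fly OVO-B isoform (1351 aa): the four C2H2 zinc-finger motifs of each,
#' and the compositionally biased disordered regions of OVO-B. Coordinates
#' are 1-based, fully closed. `reported_len` is the length *as printed*;
#' note that the reported 39 aa of the His-rich region is internally
#' inconsistent with its span (645--665 holds 21 residues), so consumers
#' should compare `reported_len` against `end - start + 1` before relying
#' on it.
#'
#' @return A tibble: `protein`, `feature`, `kind` (`motif`/`x-rich`),
#'   `detail` (dominant residue for x-rich features), `start`, `end`,
#'   `reported_len`, `protein_len`.
#' @export
ovol_reported_features <- function() {
  tibble::tribble(
    ~protein, ~feature, ~kind, ~detail, ~start, ~end, ~reported_len, ~protein_len,
    "human_OVOL1", "motif_I",   "motif", "",  118L,  140L, 23L,  267L,
    "human_OVOL1", "motif_II",  "motif", "",  146L,  168L, 23L,  267L,
    "human_OVOL1", "motif_III", "motif", "",  174L,  197L, 24L,  267L,
    "human_OVOL1", "motif_IV",  "motif", "",  213L,  236L, 24L,  267L,
    "drosophila_OVO_B", "motif_I",   "motif", "", 1197L, 1219L, 23L, 1351L,
    "drosophila_OVO_B", "motif_II",  "motif", "", 1225L, 1247L, 23L, 1351L,
    "drosophila_OVO_B", "motif_III", "motif", "", 1253L, 1276L, 24L, 1351L,
    "drosophila_OVO_B", "motif_IV",  "motif", "", 1292L, 1315L, 24L, 1351L,
    "drosophila_OVO_B", "glu_rich", "x-rich", "E",  196L,  239L,  44L, 1351L,
    "drosophila_OVO_B", "pro_rich", "x-rich", "P",  309L,  342L,  34L, 1351L,
    "drosophila_OVO_B", "gly_rich", "x-rich", "G",  448L,  618L, 171L, 1351L,
    "drosophila_OVO_B", "asn_rich", "x-rich", "N",  620L,  660L,  41L, 1351L,
    "drosophila_OVO_B", "his_rich", "x-rich", "H",  645L,  665L,  39L, 1351L,
    "drosophila_OVO_B", "gln_rich", "x-rich", "Q",  837L, 1158L, 322L, 1351L,
    "drosophila_OVO_B", "ala_rich", "x-rich", "A", 1001L, 1059L,  59L, 1351L,
    "drosophila_OVO_B", "ser_rich", "x-rich", "S", 1025L, 1045L,  21L, 1351L
  )
}

#' Synthetic stand-ins for the OVOL reference proteins
#'
#' Constructs a synthetic protein whose C2H2 tetrad occupies *exactly* the
#' literature-reported motif spans of the chosen reference protein (see
#' [ovol_reported_features()]) and matches the generic C2H2 pattern
#' PS00028. These are synthetic sequences, not database downloads: the
#' real residues outside the printed coordinates are unpublished, so the
#' filler is drawn from an alphabet without cysteine or histidine (which
#' guarantees the motif match set is exactly the intended tetrad), and for
#' OVO-B the reported compositionally biased regions are emulated by
#' patches of their dominant residue. Use them to exercise coordinate
#' arithmetic, scanning, tetrad detection and architecture assembly
#' against the printed feature geometry.
#'
#' @param which `"human_OVOL1"` (267 aa) or `"drosophila_OVO_B"` (1351 aa).
#' @param seed Integer seed controlling the filler residues.
#' @param bias_strength Dominant-residue frequency inside the emulated
#'   biased patches of OVO-B (default 0.6).
#' @return A one-row tibble with `id` (prefixed `synthetic_`),
#'   `description`, `residues`.
#' @export
synthetic_reference_protein <- function(which = c("human_OVOL1", "drosophila_OVO_B"),
                                        seed = 1, bias_strength = 0.6) {
  which <- match.arg(which)
  set.seed(seed)
  feats <- ovol_reported_features()
  feats <- feats[feats$protein == which, , drop = FALSE]
  total <- feats$protein_len[[1]]
  filler <- setdiff(AA20, c("C", "H"))
  cc <- sample(filler, total, replace = TRUE)

  # emulate the reported biased regions (before motif placement, so motifs
  # always win where coordinates would collide)
  xr <- feats[feats$kind == "x-rich", , drop = FALSE]
  if (nrow(xr)) {
    for (k in seq_len(nrow(xr))) {
      span <- xr$start[k]:xr$end[k]
      dominant <- stats::runif(length(span)) < bias_strength
      cc[span[dominant]] <- xr$detail[k]
    }
  }

  # place PS00028-compatible motifs at the printed spans: the only pattern
  # geometry consistent with 23-24 aa spans is C-x(4)-C-x(3)-F-x(8)-H-x(3|4)-H
  mo <- feats[feats$kind == "motif", , drop = FALSE]
  for (k in seq_len(nrow(mo))) {
    s <- mo$start[k]; e <- mo$end[k]
    len <- e - s + 1L
    stopifnot(len %in% c(23L, 24L))
    cc[s:e] <- sample(filler, len, replace = TRUE)
    cc[s] <- "C"; cc[s + 5L] <- "C"; cc[s + 9L] <- "F"
    cc[s + 18L] <- "H"; cc[e] <- "H"
  }
  tibble(id = paste0("synthetic_", which),
         description = sprintf("synthetic stand-in; tetrad at printed spans of %s", which),
         residues = paste(cc, collapse = ""))
}
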