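#' Configuration for the synthetic protein-family generator
#'
#' Defines the conditions of a simulated zinc-finger family: a slowly
#' evolving conserved core of four C2H2 motifs, plus fast-evolving,
#' compositionally biased intrinsically disordered (ID) N/C-terminal
#' extensions of variable length. Defaults reflect the family this
#' package models: `p_id` far above `p_core` (disordered segments evolve
#' much faster than the structured core), extensions of 100--1000 aa
#' (the observed range), predominantly N-terminal.
#'
#' @param taxa Number of taxa; ignored when `tree` is given. A star tree
#'   is used, i.e. every lineage diverges independently from the ancestor.
#' @param tree Optional guide tree (`phylo` or Newick string); one round
#'   of per-site substitution is applied along each edge.
#' @param p_core Per-site substitution probability per branch at core
#'   sites (default 0.02).
#' @param p_id Per-site substitution probability per branch at ID sites
#'   (default 0.4). Must satisfy `0 <= p_core < p_id <= 1`.
#' @param id_length Length range (min, max aa) of each ID extension
#'   (default `c(100, 1000)`).
#' @param extension_side Extension side per lineage: `"N"`, `"C"`,
#'   `"both"` or `"none"`; recycled over taxa. Default `"N"`.
#' @param bias_prob Probability that an ID segment is dominated by one
#'   residue type (default 0.5).
#' @param bias_strength Dominant-residue frequency within a biased
#'   segment (default 0.5).
#' @param indel_rate Per-site probability per branch that an indel event
#'   starts at an ID site (split evenly between insertion and deletion;
#'   default 0.02). Indel lengths are geometric with mean `indel_mean`
#'   (default 3). Core sites never gain indels.
#' @param mutate_anchors If `TRUE`, the Cys/His anchor residues mutate at
#'   `p_core` like any core site (for robustness testing); by default they
#'   are invariant so that detection failures indicate pipeline bugs
#'   rather than simulation luck.
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_family()]
#' @export
simulation_config <- function(taxa = 6, tree = NULL, p_core = 0.02, p_id = 0.4,
                              id_length = c(100, 1000), extension_side = "N",
                              bias_prob = 0.5, bias_strength = 0.5,
                              indel_rate = 0.02, indel_mean = 3,
                              mutate_anchors = FALSE) {
  probs <- c(p_core = p_core, p_id = p_id, bias_prob = bias_prob,
             bias_strength = bias_strength, indel_rate = indel_rate)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must lie in [0, 1]")
  if (!(p_core < p_id)) abort("require 0 <= p_core < p_id <= 1")
  if (length(id_length) != 2L || id_length[1] > id_length[2] || id_length[1] < 1) {
    abort("`id_length` must be c(min, max) with 1 <= min <= max")
  }
  if (!all(extension_side %in% c("N", "C", "both", "none"))) {
    abort('`extension_side` values must be "N", "C", "both" or "none"')
  }
  if (indel_mean < 1) abort("`indel_mean` must be >= 1")
  structure(list(taxa = taxa, tree = tree, p_core = p_core, p_id = p_id,
                 id_length = id_length, extension_side = extension_side,
                 bias_prob = bias_prob, bias_strength = bias_strength,
                 indel_rate = indel_rate, indel_mean = indel_mean,
                 mutate_anchors = mutate_anchors),
            class = "sim_config")
}

# core template in the geometry of the overall OVOL C2H2 pattern:
# motifs I/II are 21 aa (H-x(3)-H), III/IV are 22 aa (H-x(4)-H), linkers
# 5/5/15 aa. Returns chars + per-site class ("anchor"/"setpos"/"core")
# and the motif intervals within the core.
core_template <- function() {
  filler <- setdiff(AA20, c("C", "H"))
  motif <- function(len) {
    cc <- sample(filler, len, replace = TRUE)
    cls <- rep("core", len)
    cc[c(1L, 4L)] <- "C"; cls[c(1L, 4L)] <- "anchor"
    cc[8L] <- "F"; cls[8L] <- "setpos"
    cc[17L] <- "H"; cc[len] <- "H"; cls[c(17L, len)] <- "anchor"
    list(cc = cc, cls = cls)
  }
  lens <- c(21L, 21L, 22L, 22L)
  linkers <- c(5L, 5L, 15L)
  cc <- character(); cls <- character()
  starts <- integer(4); ends <- integer(4)
  for (i in 1:4) {
    m <- motif(lens[i])
    starts[i] <- length(cc) + 1L
    cc <- c(cc, m$cc); cls <- c(cls, m$cls)
    ends[i] <- length(cc)
    if (i < 4L) {
      cc <- c(cc, sample(filler, linkers[i], replace = TRUE))
      cls <- c(cls, rep("core", linkers[i]))
    }
  }
  list(cc = cc, cls = cls, motif_start = starts, motif_end = ends)
}

# the residue set at the pattern-constrained ("setpos") position; the
# generator guarantees every taxon's core keeps matching the overall
# pattern, so substitutions there stay within this set
SETPOS_ALLOWED <- c("F", "W", "S", "G", "A", "T")

# residue sampler for one ID segment
make_segment_sampler <- function(cfg) {
  biased <- stats::runif(1) < cfg$bias_prob
  dominant <- if (biased) sample(AA20, 1) else NA_character_
  function(n) {
    if (!biased) return(sample(AA20, n, replace = TRUE))
    dom <- stats::runif(n) < cfg$bias_strength
    out <- sample(setdiff(AA20, dominant), n, replace = TRUE)
    out[dom] <- dominant
    out
  }
}

evolve_branch <- function(state, cfg, samplers) {
  n <- length(state$char)
  p <- numeric(n)
  p[state$cls == "core"] <- cfg$p_core
  p[state$cls == "setpos"] <- cfg$p_core
  p[state$cls == "id"] <- cfg$p_id
  p[state$cls == "anchor"] <- if (cfg$mutate_anchors) cfg$p_core else 0
  hit <- which(stats::runif(n) < p)
  for (i in hit) {
    pool <- if (state$cls[i] == "setpos") setdiff(SETPOS_ALLOWED, state$char[i])
            else setdiff(AA20, state$char[i])
    state$char[i] <- sample(pool, 1)
  }

  id_idx <- which(state$cls == "id")
  if (length(id_idx) && cfg$indel_rate > 0) {
    # deletions: runs of consecutive ID entries
    del_start <- id_idx[stats::runif(length(id_idx)) < cfg$indel_rate / 2]
    drop <- logical(n)
    for (s in del_start) {
      len <- 1L + stats::rgeom(1, prob = 1 / cfg$indel_mean)
      run <- s
      while (length(run) < len && run[length(run)] + 1L <= n &&
             state$cls[run[length(run)] + 1L] == "id") {
        run <- c(run, run[length(run)] + 1L)
      }
      drop[run] <- TRUE
    }
    # insertions: new ID columns after the chosen site
    ins_after <- id_idx[stats::runif(length(id_idx)) < cfg$indel_rate / 2]
    ins_after <- ins_after[!drop[ins_after]]
    inserts <- lapply(ins_after, function(i) {
      len <- 1L + stats::rgeom(1, prob = 1 / cfg$indel_mean)
      next_key <- if (i < n) state$key[i + 1L] else state$key[i] + 1
      list(key = sort(stats::runif(len, state$key[i], next_key)),
           char = samplers[[state$seg[i]]](len),
           cls = rep("id", len),
           seg = rep(state$seg[i], len),
           after = i)
    })
    keep <- !drop
    pieces_key <- list(); pieces_char <- list()
    pieces_cls <- list(); pieces_seg <- list()
    prev <- 0L
    for (b in seq_along(inserts)) {
      i <- inserts[[b]]$after
      sel <- which(keep & seq_len(n) > prev & seq_len(n) <= i)
      pieces_key[[length(pieces_key) + 1L]] <- state$key[sel]
      pieces_char[[length(pieces_char) + 1L]] <- state$char[sel]
      pieces_cls[[length(pieces_cls) + 1L]] <- state$cls[sel]
      pieces_seg[[length(pieces_seg) + 1L]] <- state$seg[sel]
      pieces_key[[length(pieces_key) + 1L]] <- inserts[[b]]$key
      pieces_char[[length(pieces_char) + 1L]] <- inserts[[b]]$char
      pieces_cls[[length(pieces_cls) + 1L]] <- inserts[[b]]$cls
      pieces_seg[[length(pieces_seg) + 1L]] <- inserts[[b]]$seg
      prev <- i
    }
    sel <- which(keep & seq_len(n) > prev)
    pieces_key[[length(pieces_key) + 1L]] <- state$key[sel]
    pieces_char[[length(pieces_char) + 1L]] <- state$char[sel]
    pieces_cls[[length(pieces_cls) + 1L]] <- state$cls[sel]
    pieces_seg[[length(pieces_seg) + 1L]] <- state$seg[sel]
    state <- list(key = unlist(pieces_key), char = unlist(pieces_char),
                  cls = unlist(pieces_cls), seg = unlist(pieces_seg))
  }
  state
}

#' Simulate an OVOL-like protein family with truth annotations
#'
#' Generates an ancestral protein -- four C2H2 motifs (in the geometry of
#' the overall OVOL consensus pattern) joined by short linkers, flanked by
#' intrinsically disordered extensions on the configured sides -- and
#' evolves it along a guide tree: core sites substitute at `p_core`
#' (Cys/His anchors invariant by default; the pattern-constrained
#' position substitutes within its allowed residue set, so every taxon's
#' core keeps matching the consensus pattern), ID sites substitute at
#' `p_id` and gain geometric-length indels. ID segments are ancestral and
#' evolve so fast that they are effectively lineage-specific; lineages
#' whose configured side excludes a segment lose it outright.
#' Substitutions draw the replacement uniformly from the other residues
#' (no empirical exchange matrix: the downstream statistics are
#' distance-based, not model-based). Deterministic for a fixed seed.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed (required).
#' @return An object of class `ovol_family_sim`: list with
#'   `records` (ungapped tibble: `id`, `description`, `residues`),
#'   `alignment` (the true alignment, gapped tibble),
#'   `truth` (list of tibbles: `motifs`, `core`, `id_regions` -- all in
#'   each taxon's own ungapped coordinates), `tree` (`phylo`),
#'   `config`, `seed`.
#' @export
#' @examples
#' sim <- simulate_family(simulation_config(taxa = 4, id_length = c(60, 80)), seed = 11)
#' sim$records
simulate_family <- function(config = simulation_config(), seed) {
  if (missing(seed)) abort("`seed` is required for simulate_family()")
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)

  tree <- if (is.null(config$tree)) {
    star_tree(config$taxa)
  } else if (inherits(config$tree, "phylo")) {
    config$tree
  } else {
    ape::read.tree(text = config$tree)
  }
  taxa <- tree$tip.label
  n_taxa <- length(taxa)
  sides <- rep_len(config$extension_side, n_taxa)

  tpl <- core_template()
  core_len <- length(tpl$cc)
  need_n <- any(sides %in% c("N", "both"))
  need_c <- any(sides %in% c("C", "both"))
  len_n <- if (need_n) sample(config$id_length[1]:config$id_length[2], 1) else 0L
  len_c <- if (need_c) sample(config$id_length[1]:config$id_length[2], 1) else 0L
  samplers <- list(N = make_segment_sampler(config),
                   core = NULL,
                   C = make_segment_sampler(config))

  root <- list(
    key = c(seq_len(len_n) - len_n - 1, seq_len(core_len),
            core_len + seq_len(len_c)),
    char = c(if (len_n) samplers$N(len_n), tpl$cc,
             if (len_c) samplers$C(len_c)),
    cls = c(rep("id", len_n), tpl$cls, rep("id", len_c)),
    seg = c(rep("N", len_n), rep("core", core_len), rep("C", len_c))
  )

  # evolve down the tree (preorder over edges)
  tree_cw <- stats::reorder(tree, "cladewise")  # parents precede children
  n_nodes <- max(tree_cw$edge)
  states <- vector("list", n_nodes)
  root_node <- n_taxa + 1L
  states[[root_node]] <- root
  for (e in seq_len(nrow(tree_cw$edge))) {
    parent <- tree_cw$edge[e, 1]; child <- tree_cw$edge[e, 2]
    states[[child]] <- evolve_branch(states[[parent]], config, samplers)
  }

  # per-lineage side filtering
  tips <- lapply(seq_len(n_taxa), function(t) {
    st <- states[[t]]
    keep <- switch(sides[t],
                   "N" = st$seg != "C",
                   "C" = st$seg != "N",
                   "both" = rep(TRUE, length(st$seg)),
                   "none" = st$seg == "core")
    lapply(st, `[`, keep)
  })
  names(tips) <- taxa

  all_keys <- sort(unique(unlist(lapply(tips, `[[`, "key"))))
  aln_rows <- vapply(tips, function(st) {
    row <- rep(GAP, length(all_keys))
    row[match(st$key, all_keys)] <- st$char
    paste(row, collapse = "")
  }, "")

  motifs <- list(); cores <- list(); id_regions <- list()
  for (t in seq_len(n_taxa)) {
    st <- tips[[t]]
    pos_of_key <- function(k) match(k, st$key)
    m_start <- vapply(tpl$motif_start, pos_of_key, 1L)
    m_end <- vapply(tpl$motif_end, pos_of_key, 1L)
    motifs[[t]] <- tibble(seq_id = taxa[t], motif = c("I", "II", "III", "IV"),
                          start = m_start, end = m_end)
    cores[[t]] <- tibble(seq_id = taxa[t], start = m_start[1], end = m_end[4])
    r <- rle(st$seg)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    idk <- which(r$values %in% c("N", "C"))
    if (length(idk)) {
      id_regions[[t]] <- tibble(seq_id = taxa[t],
                                start = starts[idk], end = ends[idk],
                                kind = "disordered",
                                detail = paste0(r$values[idk], "-extension"))
    }
  }

  records <- tibble(id = taxa, description = "",
                    residues = unname(vapply(tips, function(st) paste(st$char, collapse = ""), "")))
  structure(list(
    records = records,
    alignment = tibble(id = taxa, description = "", residues = unname(aln_rows)),
    truth = list(motifs = dplyr::bind_rows(motifs),
                 core = dplyr::bind_rows(cores),
                 id_regions = dplyr::bind_rows(id_regions),
                 sides = tibble(seq_id = taxa, side = sides)),
    tree = tree, config = config, seed = seed),
    class = "ovol_family_sim")
}

star_tree <- function(n) {
  stopifnot(n >= 2)
  tree <- ape::stree(n, type = "star")
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree
}

#' @export
print.ovol_family_sim <- function(x, ...) {
  cat(sprintf("<ovol_family_sim> %d taxa, seed %d\n", nrow(x$records), x$seed))
  cat(sprintf("  lengths: %s\n", paste(nchar(x$records$residues), collapse = ", ")))
  invisible(x)
}

#' Emit per-residue disorder tracks from simulation truth
#'
#' Produces disorder-prediction-shaped tracks for every simulated taxon:
#' score 0.9 (plus optional Gaussian noise, clamped to \[0, 1\]) inside the
#' true ID regions, 0.1 elsewhere; state by the 0.5 threshold. With
#' `noise_sd = 0` the called regions reproduce the truth exactly.
#'
#' @param sim An `ovol_family_sim` from [simulate_family()].
#' @param noise_sd Standard deviation of the score noise (default 0).
#' @param seed Optional seed for the noise.
#' @return A `disorder_track`-shaped tibble covering all taxa
#'   (`seq_id`, `position`, `residue`, `score`, `state`).
#' @export
emit_disorder_tracks <- function(sim, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(sim, "ovol_family_sim"))
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nrow(sim$records)), function(i) {
    id <- sim$records$id[[i]]
    cc <- chars(sim$records$residues[[i]])
    score <- rep(0.1, length(cc))
    reg <- sim$truth$id_regions
    reg <- reg[reg$seq_id == id, , drop = FALSE]
    if (nrow(reg)) for (k in seq_len(nrow(reg))) score[reg$start[k]:reg$end[k]] <- 0.9
    if (noise_sd > 0) score <- pmin(1, pmax(0, score + stats::rnorm(length(cc), 0, noise_sd)))
    tibble(seq_id = id, position = seq_along(cc), residue = cc,
           score = score, state = score >= 0.5)
  })
  dplyr::bind_rows(out)
}

#' Write per-taxon disorder tracks as TSV files
#'
#' @param tracks A track tibble from [emit_disorder_tracks()].
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_disorder_tracks <- function(tracks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(split(tracks, tracks$seq_id), function(tr) {
    p <- file.path(dir, paste0(tr$seq_id[[1]], ".disorder.tsv"))
    readr::write_tsv(tr, p)
    p
  }, "")
  invisible(paths)
}
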