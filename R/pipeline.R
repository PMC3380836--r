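#' Run the full comparative-analysis pipeline
#'
#' Strings the package's stages together: motif scanning and tetrad
#' detection, architecture assembly, disorder-region calling and bias
#' patches, column partitioning, partitioned p-distances with the
#' Kruskal-Wallis comparison, and a neighbor-joining tree; writes the
#' per-stage TSV artifacts, a machine-readable JSON summary, and a
#' MANIFEST marking which stages completed. Inputs may be supplied as
#' files; with no input a synthetic family is simulated (seeded), so the
#' pipeline always has something to run end-to-end.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; required (it drives the simulation and any
#'   stochastic stage).
#' @param fasta Optional path to an ungapped protein FASTA.
#' @param alignment Optional path to an aligned FASTA. Required for the
#'   divergence stages when `fasta` is given; the simulator provides its
#'   own truth alignment.
#' @param disorder_dir Optional directory of per-sequence disorder TSVs
#'   (named `<seq_id>.disorder.tsv`); the simulator provides truth-derived
#'   tracks when absent.
#' @param pattern Pattern text used for scanning (default the overall
#'   OVOL consensus from [ovol_patterns()]).
#' @param sim_config A [simulation_config()] used when no `fasta` is given.
#' @param rule_frac,max_linker,min_region_len Stage thresholds (see
#'   [partition_columns()], [find_tetrad()], [call_disordered_regions()]).
#' @param quiet Suppress progress messages (they go to standard error).
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(out_dir, seed, fasta = NULL, alignment = NULL,
                         disorder_dir = NULL,
                         pattern = ovol_patterns()[["overall"]],
                         sim_config = simulation_config(),
                         rule_frac = 0.5, max_linker = 20,
                         min_region_len = 5, quiet = FALSE) {
  if (missing(seed)) abort("`seed` is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[pipeline] ", sprintf(...))
  done <- character()
  manifest <- file.path(out_dir, "MANIFEST")
  note_stage <- function(stage) {
    done <<- c(done, stage)
    writeLines(c("# completed pipeline stages", done), manifest)
  }
  run_stage <- function(stage, expr) {
    say("stage: %s", stage)
    tryCatch(force(expr), error = function(e) {
      writeLines(c("# completed pipeline stages", done,
                   sprintf("# FAILED at stage: %s", stage)), manifest)
      abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
            parent = e)
    })
  }

  config_summary <- list(
    seed = seed, pattern = pattern, rule_frac = rule_frac,
    max_linker = max_linker, min_region_len = min_region_len,
    simulated = is.null(fasta),
    package_version = as.character(utils::packageVersion("ovolution"))
  )
  config_summary$config_hash <- rlang::hash(config_summary)
  say("seed %d, config hash %s", seed, config_summary$config_hash)

  inputs <- run_stage("input", {
    if (is.null(fasta)) {
      sim <- simulate_family(sim_config, seed = seed)
      write_fasta(sim$records, file.path(out_dir, "records.fasta"))
      write_fasta(sim$alignment, file.path(out_dir, "alignment.fasta"))
      tracks <- emit_disorder_tracks(sim)
      list(records = sim$records, aln = sim$alignment, tracks = tracks)
    } else {
      if (!file.exists(fasta)) abort(sprintf("input FASTA not found: %s", fasta))
      records <- read_fasta(fasta)
      aln <- if (!is.null(alignment)) read_alignment(alignment) else NULL
      tracks <- if (!is.null(disorder_dir)) {
        dplyr::bind_rows(lapply(list.files(disorder_dir, "\\.disorder\\.tsv$",
                                           full.names = TRUE), function(p) {
          as_tibble(read_disorder_track(p,
            id = sub("\\.disorder\\.tsv$", "", basename(p))))
        }))
      } else NULL
      list(records = records, aln = aln, tracks = tracks)
    }
  })
  note_stage("input")

  matches <- run_stage("scan", {
    m <- scan_pattern(inputs$records, pattern)
    readr::write_tsv(m, file.path(out_dir, "matches.tsv"))
    m
  })
  note_stage("scan")

  annotations <- run_stage("disorder", {
    ann <- if (!is.null(inputs$tracks)) {
      call_disordered_regions(inputs$tracks, min_len = min_region_len)
    } else {
      tibble(seq_id = character(), start = integer(), end = integer(),
             kind = character(), detail = character())
    }
    bias <- dplyr::bind_rows(lapply(seq_len(nrow(inputs$records)), function(i) {
      suppressWarnings(find_bias_patches(inputs$records[i, ]))
    }))
    all_ann <- dplyr::bind_rows(ann, bias[, intersect(names(bias),
                c("seq_id", "start", "end", "kind", "detail"))])
    write_annotations(all_ann, file.path(out_dir, "annotations.tsv"))
    all_ann
  })
  note_stage("disorder")

  arch <- run_stage("architecture", {
    a <- build_architecture(inputs$records, pattern = pattern,
                            annotations = annotations, max_linker = max_linker)
    readr::write_tsv(summarize_architectures(a),
                     file.path(out_dir, "architecture.tsv"))
    a
  })
  note_stage("architecture")

  divergence <- run_stage("divergence", {
    if (is.null(inputs$aln)) {
      say("no alignment supplied; skipping divergence stages")
      NULL
    } else {
      cmp <- compare_partitions(inputs$aln, annotations, rule_frac = rule_frac)
      readr::write_tsv(cmp$summary, file.path(out_dir, "partition_summary.tsv"))
      readr::write_tsv(cmp$distances, file.path(out_dir, "distances.tsv"))
      dm <- distance_matrix(inputs$aln)
      utils::write.table(round(dm$distance, 6),
                         file.path(out_dir, "distance_matrix.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
      tree <- if (nrow(inputs$aln) >= 3 && !anyNA(dm$distance)) {
        tr <- suppressWarnings(nj_tree(dm))
        ape::write.tree(tr, file.path(out_dir, "nj_tree.nwk"))
        tr
      } else NULL
      list(cmp = cmp, dm = dm, tree = tree)
    }
  })
  note_stage("divergence")

  summary <- run_stage("report", {
    s <- list(
      config = config_summary,
      n_sequences = nrow(inputs$records),
      n_motif_matches = nrow(matches),
      architectures = as.data.frame(summarize_architectures(arch)),
      partition_medians = if (!is.null(divergence)) {
        setNames(as.list(divergence$cmp$summary$median),
                 divergence$cmp$summary$partition)
      } else NULL,
      kruskal_wallis = if (!is.null(divergence) && !is.null(divergence$cmp$kw)) {
        as.data.frame(tidy(divergence$cmp$kw))
      } else NULL,
      overall_mean_distance = if (!is.null(divergence)) divergence$dm$overall_mean else NULL
    )
    jsonlite::write_json(s, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    s
  })
  note_stage("report")
  say("done: %s", out_dir)
  invisible(summary)
}
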