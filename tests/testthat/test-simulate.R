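test_that("zero-rate limit: cores identical, tetrads detected in every taxon", {
  cfg <- simulation_config(taxa = 4, p_core = 0, p_id = 1e-9,
                           id_length = c(60, 120), indel_rate = 0)
  sim <- simulate_family(cfg, seed = 11)
  cores <- substr(sim$records$residues,
                  sim$truth$core$start, sim$truth$core$end)
  expect_equal(length(unique(cores)), 1L)
  for (i in seq_len(4)) {
    hits <- scan_pattern(sim$records[i, ], ovol_patterns()[["overall"]])
    expect_equal(nrow(find_tetrad(hits, prefer = "last")), 4L)
  }
})

test_that("simulation is byte-identical for a fixed seed and config", {
  cfg <- simulation_config(taxa = 5, id_length = c(50, 150))
  s1 <- simulate_family(cfg, seed = 42)
  s2 <- simulate_family(cfg, seed = 42)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$alignment, s2$alignment)
  expect_identical(s1$truth, s2$truth)

  s3 <- simulate_family(cfg, seed = 43)
  expect_false(identical(s1$records$residues, s3$records$residues))
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(p_core = 0.5, p_id = 0.1), "p_core < p_id")
  expect_error(simulation_config(p_core = -0.1), "\\[0, 1\\]")
  expect_error(simulation_config(id_length = c(10, 5)), "id_length")
  expect_error(simulation_config(extension_side = "NE"), "extension_side")
  expect_error(simulate_family(simulation_config()), "seed")
})

test_that("every simulated core still matches the consensus pattern (anchors conserved)", {
  for (s in 1:5) {
    sim <- simulate_family(simulation_config(taxa = 6, id_length = c(100, 300)),
                           seed = s)
    for (i in seq_len(nrow(sim$records))) {
      id <- sim$records$id[[i]]
      truth_m <- dplyr::filter(sim$truth$motifs, seq_id == id)
      hits <- scan_pattern(sim$records[i, ], ovol_patterns()[["overall"]],
                           mode = "all")
      for (k in 1:4) {
        expect_true(any(hits$start == truth_m$start[k] & hits$end == truth_m$end[k]),
                    info = sprintf("seed %d taxon %s motif %d", s, id, k))
      }
    }
  }
})

test_that("truth alignment rows ungap to the emitted records", {
  sim <- simulate_family(simulation_config(taxa = 5, id_length = c(50, 150)),
                         seed = 7)
  expect_equal(ungap(sim$alignment$residues), sim$records$residues)
  expect_equal(sim$alignment$id, sim$records$id)
})

test_that("extension sides honour the per-lineage configuration", {
  cfg <- simulation_config(taxa = 4, id_length = c(40, 60),
                           extension_side = c("N", "C", "both", "none"))
  sim <- simulate_family(cfg, seed = 5)
  reg <- sim$truth$id_regions
  core <- sim$truth$core
  for (i in 1:4) {
    id <- sim$records$id[[i]]
    r <- reg[reg$seq_id == id, ]
    side <- cfg$extension_side[i]
    has_n <- any(r$end < core$start[core$seq_id == id])
    has_c <- any(r$start > core$end[core$seq_id == id])
    expect_equal(has_n, side %in% c("N", "both"), info = side)
    expect_equal(has_c, side %in% c("C", "both"), info = side)
  }
})

test_that("mean core divergence tracks the configured substitution probability", {
  # star tree: two lineages each one branch from the ancestor; at free core
  # sites P(differ) = 1 - ((1-p)^2 + p^2/19)
  p <- 0.1
  cfg <- simulation_config(taxa = 6, p_core = p, p_id = 0.4,
                           id_length = c(100, 200))
  ds <- numeric(0)
  for (s in 1:10) {
    sim <- simulate_family(cfg, seed = s)
    core_rows <- substr(sim$records$residues, sim$truth$core$start,
                        sim$truth$core$end)
    names(core_rows) <- sim$records$id
    ds <- c(ds, tidy(distance_matrix(core_rows))$distance)
  }
  expected_free <- 1 - ((1 - p)^2 + p^2 / 19)
  # 16 of the 111 core sites are invariant anchors, 4 are set-constrained;
  # observed divergence should fall below the free-site expectation but
  # clearly above half of it
  expect_lt(mean(ds), expected_free)
  expect_gt(mean(ds), 0.5 * expected_free)
})

test_that("disorder tracks emitted from truth round-trip through region calling", {
  sim <- simulate_family(simulation_config(taxa = 4, id_length = c(50, 100)),
                         seed = 9)
  tracks <- emit_disorder_tracks(sim, noise_sd = 0)
  called <- call_disordered_regions(tracks, min_len = 5)
  truth <- dplyr::arrange(sim$truth$id_regions, seq_id, start)
  called <- dplyr::arrange(called, seq_id, start)
  expect_equal(called$seq_id, truth$seq_id)
  expect_equal(called$start, truth$start)
  expect_equal(called$end, truth$end)

  t1 <- emit_disorder_tracks(sim, noise_sd = 0.05, seed = 1)
  t2 <- emit_disorder_tracks(sim, noise_sd = 0.05, seed = 1)
  expect_identical(t1, t2)
})

test_that("disorder track TSVs are written per taxon and read back", {
  sim <- simulate_family(simulation_config(taxa = 3, id_length = c(40, 60)),
                         seed = 2)
  dir <- withr::local_tempdir()
  paths <- write_disorder_tracks(emit_disorder_tracks(sim), dir)
  expect_equal(length(paths), 3L)
  tr <- read_disorder_track(paths[[1]], id = sim$records$id[[1]])
  expect_equal(nrow(tr), nchar(sim$records$residues[[1]]))
})
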