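test_that("an all-conserved rigid domain yields no regions", {
  b <- synth_domain_bundle(seed = 51, n_residues = 80, n_sequences = 50,
                           coupling = tibble::tibble(
                             start = integer(), end = integer(),
                             high_H = logical(), high_B = logical(),
                             unmodeled = logical()),
                           truth_draws = 100)
  prof <- profile_domain(b$structure, "A", b$msa, "reference")
  expect_equal(nrow(prof$regions), 0L)
})

test_that("planted dual-evidence segments are recovered with exact bounds", {
  coupling <- tibble::tibble(start = c(20L, 60L), end = c(27L, 70L),
                             high_H = TRUE, high_B = TRUE, unmodeled = FALSE)
  b <- synth_domain_bundle(seed = 52, n_residues = 100, n_sequences = 80,
                           coupling = coupling, truth_draws = 100)
  prof <- profile_domain(b$structure, "A", b$msa, "reference")
  expect_equal(nrow(prof$regions), 2L)
  expect_equal(prof$regions$start, coupling$start)
  expect_equal(prof$regions$end, coupling$end)
  expect_true(all(grepl("high_entropy", prof$regions$evidence)))
  expect_true(all(grepl("high_bfactor", prof$regions$evidence)))
})

test_that("the two-loop emulation yields the BorA/FluA evidence pattern", {
  b <- synth_domain_bundle(seed = 53, n_residues = 150, n_sequences = 100,
                           truth_draws = 100)
  labels <- tibble::tibble(
    start = b$truth$regions$start, end = b$truth$regions$end,
    label = c("β7–α2", "α3–β11")
  )
  prof <- profile_domain(b$structure, "A", b$msa, "reference",
                         config = dh_config(region_labels = labels))
  expect_equal(nrow(prof$regions), 2L)
  expect_equal(prof$regions$evidence, b$truth$regions$evidence)
  expect_equal(prof$regions$label, labels$label)
  expect_true(all(prof$regions$mean_H > 3))
  # the unmodeled loop carries no z; the flexible loop carries z >= 2
  expect_true(is.na(prof$regions$mean_z[2]))
  expect_true(prof$regions$mean_z[1] >= 2)
})

test_that("stricter thresholds only shrink the called region set", {
  b <- synth_domain_bundle(seed = 54, n_residues = 120, n_sequences = 80,
                           truth_draws = 100)
  ep <- entropy_profile(b$msa)
  cm <- map_to_reference(b$msa, "reference", b$structure, "A")
  track <- residue_entropy_track(ep, cm, b$structure, "A")
  flex <- bfactor_profile(b$structure, "A")
  residues_of <- function(reg) {
    if (nrow(reg) == 0) return(integer(0))
    unlist(mapply(seq, reg$start, reg$end, SIMPLIFY = FALSE))
  }
  loose <- call_variable_regions(track, flex, h_percentile = 0.5,
                                 z_threshold = 0.5)
  strict <- call_variable_regions(track, flex, h_percentile = 0.9,
                                  z_threshold = 2.0)
  expect_true(all(residues_of(strict) %in% residues_of(loose)))
})

test_that("disjoint numbering raises an index-mismatch error", {
  b <- synth_domain_bundle(seed = 55, n_residues = 60, n_sequences = 40,
                           truth_draws = 100)
  ep <- entropy_profile(b$msa)
  cm <- map_to_reference(b$msa, "reference", b$structure, "A")
  track <- residue_entropy_track(ep, cm)
  track$resno <- track$resno + 1000L
  flex <- bfactor_profile(b$structure, "A")
  expect_error(call_variable_regions(track, flex),
               class = "dhprof_index_mismatch")
})

test_that("profile_domain without conservation falls back to flexibility evidence", {
  b <- synth_domain_bundle(seed = 56, n_residues = 100, n_sequences = 40,
                           truth_draws = 100)
  prof <- profile_domain(b$structure, "A",
                         config = dh_config(use_conservation = FALSE))
  expect_null(prof$entropy)
  expect_true(all(prof$regions$evidence %in% c("high_bfactor", "unmodeled")))
  expect_true(nrow(prof$regions) >= 2L)
})

test_that("secondary structure uses records first, dihedral rule otherwise", {
  s <- synth_structure(n_residues = 30, seed = 57,
                       helix = tibble::tibble(start = 5, end = 12),
                       sheet = tibble::tibble(start = 20, end = 24))
  ss <- secondary_structure(s, "A")
  expect_equal(unique(ss$ss[ss$resno %in% 5:12]), "H")
  expect_equal(unique(ss$ss[ss$resno %in% 20:24]), "E")
  expect_equal(unique(ss$ss[ss$resno %in% c(1:4, 13:19, 25:30)]), "C")
  # records survive a PDB round trip
  f <- tempfile(fileext = ".pdb")
  write_pdb(s, f)
  s2 <- read_structure(f)
  expect_equal(s2$helix$start, 5L)
  expect_equal(s2$sheet$end, 24L)
  # CA-only trace without records -> all coil from the dihedral fallback
  s3 <- synth_structure(n_residues = 10, seed = 58)
  expect_equal(unique(secondary_structure(s3, "A")$ss), "C")
})

test_that("a profile report is deterministic within a session", {
  b <- synth_domain_bundle(seed = 59, n_residues = 80, n_sequences = 40,
                           truth_draws = 100)
  p1 <- profile_domain(b$structure, "A", b$msa, "reference")
  p2 <- profile_domain(b$structure, "A", b$msa, "reference")
  expect_identical(write_profile_json(p1), write_profile_json(p2))
})
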