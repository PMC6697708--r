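test_that("motif scanning finds wildcard matches at the right positions", {
  expect_equal(scan_motifs("AHPLLG", "HPLL")$pos, 2L)
  expect_equal(scan_motifs("LALGR", "LxLxR")$pos, 1L)
  expect_equal(nrow(scan_motifs(strrep("A", 30), "GYxYGPxF")), 0L)
  expect_error(scan_motifs("ACDE", "Hz*"), class = "dhprof_argument")
  # overlapping matches are all reported
  expect_equal(scan_motifs("AAAA", "AA")$pos, 1:3)
})

test_that("motif scanning equals a naive sliding-window oracle", {
  set.seed(31)
  for (i in 1:20) {
    s <- random_aa(60, letters = c("A", "G", "H", "P", "L", "R"))
    for (p in c("HxxxGxxxxP", "LxLxR", "HPLL", "LPFxW")) {
      expect_equal(scan_motifs(s, p)$pos, motif_oracle(s, p))
    }
  }
})

test_that("motif positions carry author residue numbers from the sequence map", {
  s <- synth_structure(n_residues = 20, seed = 32,
                       sequence = paste0("AAAH", "PLLA", strrep("A", 12)))
  hits <- scan_motifs(chain_sequence(s, "A"), "HPLL")
  expect_equal(hits$resno, 4L)
})

test_that("a planted dyad is found at its exact distance", {
  seqs <- paste0(strrep("A", 4), "H", strrep("A", 15), "D", strrep("A", 9))
  s <- synth_structure(n_residues = 30, seed = 33, sequence = seqs,
                       dyad = list(his = 5, asp = 21, distance = 2.8))
  g <- find_catalytic_dyad(s, "A")
  expect_equal(g$his$resno, 5L)
  expect_equal(g$asp$resno, 21L)
  expect_equal(g$dyad_distance, 2.8, tolerance = 1e-9)
  expect_true(g$dyad_found)
})

test_that("the motif-anchored His is preferred over a closer motif-less pair", {
  # His5 (in HxxxGxxxxP) pairs with Asp at 3.5 A; His20 with Asp at 2.8 A
  seqs <- paste0("AAAA", "HAAAGAAAAP", "AAAAA", "HAAAA", "DAAAA", "DAAAA",
                 strrep("A", 6))
  s <- synth_structure(n_residues = 40, seed = 34, sequence = seqs)
  at <- s$atoms
  place <- function(at, resno, name, v) {
    i <- which(at$resno == resno & at$atom == name)
    at$x[i] <- v[1]; at$y[i] <- v[2]; at$z[i] <- v[3]; at
  }
  at <- place(at, 5, "NE2", c(100, 0, 0));  at <- place(at, 5, "ND1", c(98, 0, 0))
  at <- place(at, 25, "OD1", c(103.5, 0, 0)); at <- place(at, 25, "OD2", c(105, 0, 0))
  at <- place(at, 20, "NE2", c(200, 0, 0)); at <- place(at, 20, "ND1", c(198, 0, 0))
  at <- place(at, 30, "OD1", c(202.8, 0, 0)); at <- place(at, 30, "OD2", c(204, 0, 0))
  s$atoms <- at
  g <- find_catalytic_dyad(s, "A")
  expect_equal(g$his$resno, 5L)
  expect_equal(g$asp$resno, 25L)
  expect_equal(g$dyad_distance, 3.5, tolerance = 1e-9)
  # absent His is an error
  s0 <- synth_structure(n_residues = 10, seed = 35)
  expect_error(find_catalytic_dyad(s0, "A"), class = "dhprof_nodyad")
})

test_that("without a motif the dyad equals the brute-force enumeration", {
  safe <- setdiff(aa20, c("W", "H", "D"))
  set.seed(36)
  for (i in 1:10) {
    letters1 <- sample(safe, 60, replace = TRUE)
    letters1[sample(60, 3)] <- "H"
    letters1[sample(setdiff(1:60, which(letters1 == "H")), 3)] <- "D"
    s <- synth_structure(n_residues = 60, seed = 360 + i,
                         sequence = paste(letters1, collapse = ""))
    g <- find_catalytic_dyad(s, "A", his_motif = "WWWWW")
    orc <- dyad_oracle(s)
    expect_equal(g$his$resno, orc$his)
    expect_equal(g$asp$resno, orc$asp)
    expect_equal(g$dyad_distance, orc$d, tolerance = 1e-9)
  }
})

test_that("the conserved Arg comes from the last LxLxR match at the planted distance", {
  seqs <- paste0("AAA", "H", "D", strrep("A", 6), "LALAR",
                 strrep("A", 4), "LGLGR", strrep("A", 5))
  stopifnot(nchar(seqs) == 30)  # LxLxR at 12 and 21; last Arg is residue 25
  s <- synth_structure(n_residues = 30, seed = 37, sequence = seqs,
                       arg_his = list(arg = 25, his = 4, distance = 17.8))
  g <- find_catalytic_dyad(s, "A", his_motif = "H")
  g <- conserved_arg_distance(s, "A", g)
  expect_equal(g$conserved_arg$resno, 25L)  # last match, not the first
  expect_equal(g$arg_his_ca_distance, 17.8, tolerance = 1e-9)
  # no motif -> warning, Arg absent
  s2 <- synth_structure(n_residues = 20, seed = 38,
                        sequence = paste0("AAAH", "D", strrep("A", 15)))
  g2 <- find_catalytic_dyad(s2, "A", his_motif = "H")
  expect_warning(g2 <- conserved_arg_distance(s2, "A", g2), "conserved Arg")
  expect_null(g2$conserved_arg)
})

test_that("ligand reach measures the planted two-atom distance", {
  s <- synth_structure(n_residues = 10, seed = 39,
                       ligand = list(resname = "PNS", atom_a = "P",
                                     atom_b = "C3", distance = 16.4))
  expect_equal(ligand_reach(s, "PNS", "P", "C3"), 16.4, tolerance = 1e-9)
  expect_equal(ligand_reach(s, "PNS", "C3", "P"), 16.4, tolerance = 1e-9)
  expect_error(ligand_reach(s, "XYZ", "P", "C3"), class = "dhprof_notfound")
  expect_error(ligand_reach(s, "PNS", "P", "O9"), class = "dhprof_notfound")
})

test_that("active-site distances are invariant under rigid transformation", {
  b <- synth_domain_bundle(seed = 40, n_residues = 100, n_sequences = 40,
                           truth_draws = 100)
  s <- b$structure
  g <- conserved_arg_distance(s, "A", find_catalytic_dyad(s, "A"))
  d0 <- c(g$dyad_distance, g$arg_his_ca_distance,
          ligand_reach(s, "PNS", "P", "C3"))
  set.seed(41)
  for (i in 1:3) {
    s2 <- transform_structure(s, random_rotation(), runif(3, -50, 50))
    g2 <- conserved_arg_distance(s2, "A", find_catalytic_dyad(s2, "A"))
    d2 <- c(g2$dyad_distance, g2$arg_his_ca_distance,
            ligand_reach(s2, "PNS", "P", "C3"))
    expect_equal(d2, d0, tolerance = 1e-9)
  }
})
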