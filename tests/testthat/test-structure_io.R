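test_that("a toy PDB parses into chains, residues and a ligand store", {
  path <- write_toy_pdb(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    pdb_atom_line(3, "CA", "HIS", "A", 3, 7.6, 0, 0),
    pdb_atom_line(4, "P2", "CAO", "A", 401, 0, 0, 0, record = "HETATM"),
    pdb_atom_line(5, "O", "HOH", "A", 501, 9, 9, 9, record = "HETATM"),
    "END"
  ))
  s <- read_structure(path)
  expect_s3_class(s, "dh_structure")
  expect_equal(unique(s$atoms$chain), "A")
  expect_equal(nrow(s$atoms), 3L)
  expect_equal(s$atoms$resname, c("ALA", "GLY", "HIS"))
  expect_equal(s$ligands$resname, "CAO")   # water dropped, ligand kept
  expect_equal(s$atoms$b_factor, rep(20, 3))
})

test_that("altloc collapse keeps the highest-occupancy copy, ties to 'A'", {
  path <- write_toy_pdb(c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 1, 0, 0, occ = 0.6, altloc = "A"),
    pdb_atom_line(2, "CA", "GLY", "A", 1, 2, 0, 0, occ = 0.4, altloc = "B"),
    pdb_atom_line(3, "CA", "ALA", "A", 2, 3, 0, 0, occ = 0.5, altloc = "B"),
    pdb_atom_line(4, "CA", "ALA", "A", 2, 4, 0, 0, occ = 0.5, altloc = "A"),
    "END"
  ))
  s <- read_structure(path)
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(s$atoms$x[s$atoms$resno == 1], 1)      # occ 0.6 wins
  expect_equal(s$atoms$x[s$atoms$resno == 2], 4)      # tie -> altloc A
})

test_that("REMARK 465 declarations become unmodeled residues (11-residue loop)", {
  hdr <- c("REMARK 465 MISSING RESIDUES", "REMARK 465   M RES C SSSEQI",
           sprintf("REMARK 465     ALA A   %3d", 240:250))
  body <- c(
    vapply(235:239, function(i)
      pdb_atom_line(i, "CA", "ALA", "A", i, i, 0, 0), character(1)),
    vapply(251:255, function(i)
      pdb_atom_line(i, "CA", "ALA", "A", i, i, 0, 0), character(1)),
    "END")
  s <- read_structure(write_toy_pdb(c(hdr, body)))
  expect_equal(nrow(s$missing), 11L)
  segs <- unmodeled_segments(s, "A")
  expect_equal(segs$start, 240L)
  expect_equal(segs$end, 250L)
  expect_equal(segs$length, 11L)
})

test_that("chain_sequence maps modeled residues and handles MSE and gaps", {
  path <- write_toy_pdb(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    pdb_atom_line(3, "CA", "HIS", "A", 3, 7.6, 0, 0),
    pdb_atom_line(4, "CA", "MSE", "A", 4, 11.4, 0, 0),
    pdb_atom_line(5, "CA", "VAL", "A", 8, 15.2, 0, 0),
    "END"
  ))
  s <- read_structure(path)
  sm <- chain_sequence(s, "A")
  expect_equal(sm$seq, "AGHXV")
  expect_equal(chain_sequence(s, "A", mse_as_met = TRUE)$seq, "AGHMV")
  expect_equal(sm$map$resno, c(1L, 2L, 3L, 4L, 8L))
  expect_error(chain_sequence(s, "Z"), class = "dhprof_notfound")
})

test_that("unmodeled segments = declared + inferred gaps, matching a set oracle", {
  # fully modeled -> empty
  full <- synth_structure(n_residues = 20, seed = 1)
  expect_equal(nrow(unmodeled_segments(full, "A")), 0L)
  # modeled 1-10 and 14-20, nothing declared -> inferred (11,13,3)
  path <- write_toy_pdb(c(
    vapply(c(1:10, 14:20), function(i)
      pdb_atom_line(i, "CA", "ALA", "A", i, i, 0, 0), character(1)), "END"))
  s <- read_structure(path)
  segs <- unmodeled_segments(s, "A")
  expect_equal(as.integer(unlist(segs)), c(11L, 13L, 3L))
  # property: summed lengths equal a brute-force set-difference oracle
  for (seed in 1:5) {
    set.seed(seed)
    n <- 60L
    k <- sample(2:5, 1)
    starts <- sort(sample(5:(n - 10), k))
    ranges <- tibble::tibble(start = starts, end = pmin(starts + sample(0:4, k, TRUE), n))
    ranges <- ranges[!duplicated(ranges$start), ]
    ranges <- ranges[c(TRUE, diff(ranges$start) > 6), ]  # keep disjoint
    st <- synth_structure(n_residues = n, seed = seed, unmodeled = ranges)
    segs <- unmodeled_segments(st, "A")
    oracle <- setdiff(seq_len(n), unique(st$atoms$resno))
    oracle <- oracle[oracle > min(st$atoms$resno) | oracle %in% st$missing$resno]
    expect_equal(sum(segs$length), length(oracle))
  }
})

test_that("write_pdb/read_structure round-trips atoms, coordinates and B-factors", {
  s <- synth_structure(n_residues = 25, seed = 7,
                       unmodeled = tibble::tibble(start = 10, end = 12),
                       elevated = tibble::tibble(start = 18, end = 20, value = 55))
  f <- tempfile(fileext = ".pdb")
  expect_no_warning(write_pdb(s, f))
  s2 <- expect_no_warning(read_structure(f))
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_equal(s2$atoms$x, s$atoms$x, tolerance = 1e-3)
  expect_equal(s2$atoms$b_factor, s$atoms$b_factor, tolerance = 5e-3)
  expect_equal(s2$missing$resno, s$missing$resno)
  # idempotence: parsing the same file twice yields identical models
  s3 <- read_structure(f)
  s3$id <- s2$id
  expect_identical(s2[-1], s3[-1])
})

test_that("a minimal mmCIF file parses through the same surface", {
  cif <- c(
    "data_toy",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA . ALA A 1 1 ? 0.000 0.000 0.000 1.00 20.00 1 ALA A CA 1",
    "ATOM 2 C CA . GLY A 1 2 ? 3.800 0.000 0.000 1.00 25.00 2 GLY A CA 1",
    "ATOM 3 C CA . HIS A 1 3 ? 7.600 0.000 0.000 1.00 30.00 3 HIS A CA 1"
  )
  path <- tempfile(fileext = ".cif")
  writeLines(cif, path)
  s <- read_structure(path)
  expect_equal(s$source_format, "mmCIF")
  expect_equal(chain_sequence(s, "A")$seq, "AGH")
  expect_equal(s$atoms$b_factor, c(20, 25, 30))
})

test_that("unreadable and unknown-format inputs raise classed errors", {
  expect_error(read_structure("nope.pdb"), class = "dhprof_notfound")
  f <- tempfile(fileext = ".xyz")
  writeLines("junk", f)
  expect_error(read_structure(f), class = "dhprof_format")
})
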