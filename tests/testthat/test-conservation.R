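toy_msa <- function(rows) dh_msa(sprintf("s%02d", seq_along(rows)), rows)

test_that("column occupancy counts non-gap fractions", {
  m <- toy_msa(c("A-C", "A-C", "AAC", "A-C", "A-C",
                 "AAC", "A-C", "AAC", "AAC", "A-C"))
  occ <- column_occupancy(m)
  expect_equal(occ$occupancy, c(1, 0.4, 1))
  m2 <- toy_msa(c("A-", "C-"))
  expect_equal(column_occupancy(m2)$occupancy[2], 0)
  # counting oracle on a random gapped MSA
  set.seed(11)
  rows <- vapply(1:20, function(i) {
    s <- strsplit(random_aa(15), "")[[1]]
    s[runif(15) < 0.3] <- "-"
    paste(s, collapse = "")
  }, character(1))
  m3 <- toy_msa(rows)
  mat <- do.call(rbind, strsplit(rows, ""))
  expect_equal(column_occupancy(m3)$occupancy, colMeans(mat != "-"))
})

test_that("occupancy refinement keeps the inclusive >= 10% boundary", {
  # 20 sequences: col1 full, col2 two non-gaps (0.10, kept), col3 one (removed)
  rows <- c("AAA", "AA-", rep("A--", 18))
  m <- toy_msa(rows)
  ref <- refine_msa(m, 0.10)
  expect_equal(attr(ref, "columns"), c(1L, 2L))
  # no gaps -> everything retained
  m2 <- toy_msa(c("ACD", "ACD", "ACD"))
  expect_equal(attr(refine_msa(m2, 0.10), "columns"), 1:3)
  expect_error(refine_msa(toy_msa(c("--", "--")), 0.5), class = "dhprof_empty")
  expect_error(refine_msa(m, 0), class = "dhprof_argument")
})

test_that("refinement is monotone in the occupancy threshold", {
  set.seed(12)
  rows <- vapply(1:30, function(i) {
    s <- strsplit(random_aa(40), "")[[1]]
    s[runif(40) < runif(1, 0, 0.9)] <- "-"
    paste(s, collapse = "")
  }, character(1))
  m <- toy_msa(rows)
  kept <- lapply(c(0.05, 0.1, 0.3, 0.6), function(th) {
    tryCatch(attr(refine_msa(m, th), "columns"), error = function(e) integer(0))
  })
  for (k in seq_len(length(kept) - 1)) {
    expect_true(all(kept[[k + 1]] %in% kept[[k]]))
  }
})

test_that("Shannon entropy matches closed forms and the direct oracle", {
  expect_equal(shannon_entropy(rep("A", 50)), 0, tolerance = 1e-12)
  expect_equal(shannon_entropy(rep(aa20, 5)), log2(20), tolerance = 1e-9)
  expect_equal(shannon_entropy(c(rep("A", 10), rep("V", 10))), 1.0,
               tolerance = 1e-12)
  # gaps and nonstandard letters are excluded from the counts
  expect_equal(shannon_entropy(c(rep("A", 5), rep("-", 5), "X", "B")), 0)
  expect_error(shannon_entropy(rep("-", 4)), class = "dhprof_undefined")
  # natural-log option
  expect_equal(shannon_entropy(c("A", "V"), base = exp(1)), log(2),
               tolerance = 1e-12)
  set.seed(13)
  for (i in 1:30) {
    col <- sample(aa20, sample(5:80, 1), replace = TRUE)
    expect_equal(shannon_entropy(col), entropy_oracle(col), tolerance = 1e-12)
  }
})

test_that("entropy_profile prunes, preserves indices and bounds H", {
  m <- toy_msa(c("AAC-", "AAC-", "AVCA", "AVC-", "AVC-"))
  ep <- entropy_profile(m, min_occupancy = 0.25)
  expect_equal(ep$column, 1:3)          # col 4 occupancy 0.2 pruned
  expect_equal(ep$entropy[1], 0)
  expect_equal(ep$entropy[2], shannon_entropy(c("A", "A", "V", "V", "V")))
  expect_true(all(ep$entropy >= 0 & ep$entropy <= log2(20)))
  expect_equal(sum(ep$freqs[[2]]), 1)
  # fully conserved alignment -> all zero
  ep0 <- entropy_profile(toy_msa(rep("ACDE", 4)))
  expect_equal(ep0$entropy, rep(0, 4))
})

test_that("permuting sequence order changes no occupancy or entropy", {
  gen <- synth_msa(n_sequences = 40, n_columns = 25, seed = 14,
                   variable_columns = 5:10, gap_prob = 0.2, truth_draws = 100)
  m <- gen$msa
  perm <- dh_msa(m$id[40:1], m$seq[40:1])
  expect_equal(tidy(entropy_profile(m)), tidy(entropy_profile(perm)))
})

test_that("empirical column entropy approaches the generator's simulated truth", {
  gen <- synth_msa(n_sequences = 500, n_columns = 30, seed = 15,
                   variable_columns = 1:15, alpha = 1)
  ep <- entropy_profile(gen$msa, min_occupancy = 0.1)
  joined <- merge(tidy(ep), gen$truth, by = "column")
  varc <- joined[joined$type == "variable", ]
  expect_true(all(abs(varc$entropy - varc$expected_entropy) < 0.15))
  cons <- joined[joined$type == "conserved", ]
  expect_equal(cons$entropy, rep(0, nrow(cons)))
})

test_that("map_to_reference handles exact, gapped and missing-residue cases", {
  s <- synth_structure(n_residues = 30, seed = 16)
  sq <- chain_sequence(s, "A")$seq
  # exact match, no gaps in the reference row
  m <- dh_msa(c("reference", "other"), c(sq, random_aa(30)))
  cm <- map_to_reference(m, "reference", s, "A")
  expect_equal(cm$column, 1:30)
  expect_equal(cm$resno, 1:30)
  # 5 leading gap columns shift the first mapped column to 6
  m2 <- dh_msa(c("reference", "other"),
               c(paste0("-----", sq), paste0(random_aa(5), random_aa(30))))
  cm2 <- map_to_reference(m2, "reference", s, "A")
  expect_equal(cm2$column[1], 6L)
  expect_equal(cm2$resno, 1:30)
  # chain missing modeled residues mid-domain: those columns unmapped
  s3 <- synth_structure(n_residues = 30, seed = 16,
                        unmodeled = tibble::tibble(start = 11, end = 15))
  cm3 <- map_to_reference(m, "reference", s3, "A")
  expect_false(any(cm3$column %in% 11:15))
  expect_equal(cm3$resno, c(1:10, 16:30))
  # wrong sequence -> reference-mismatch error
  expect_error(map_to_reference(dh_msa(c("reference"), random_aa(30)),
                                "reference", s, "A"),
               class = "dhprof_reference_mismatch")
})

test_that("unmodeled residues inherit interpolated column entropies", {
  b <- synth_domain_bundle(seed = 17, n_residues = 80, n_sequences = 60,
                           truth_draws = 100)
  ep <- entropy_profile(b$msa)
  cm <- map_to_reference(b$msa, "reference", b$structure, "A")
  track <- residue_entropy_track(ep, cm, b$structure, "A")
  expect_equal(nrow(track), 80L)
  unmod <- b$truth$coupling[b$truth$coupling$unmodeled, ]
  idx <- track$resno >= unmod$start & track$resno <= unmod$end
  expect_true(all(!track$modeled[idx]))
  expect_equal(track$column[idx], track$resno[idx])  # gapless reference row
  expect_true(all(track$entropy[idx] > 3))           # high-H coupled region
})

test_that("alignment files in FASTA, Clustal and Stockholm all load", {
  rows <- c(A = "ACD-E", B = "ACDFE", C = "AC--E")
  fa <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(rows), "\n", rows), fa)
  st <- tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", paste(names(rows), rows), "//"), st)
  cl <- tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (toy)", "", "",
               paste(format(names(rows), width = 10), rows)), cl)
  m_fa <- read_msa(fa)
  m_st <- read_msa(st)
  m_cl <- read_msa(cl)
  expect_equal(m_fa$seq, unname(rows))
  expect_equal(m_st$seq, unname(rows))
  expect_equal(m_cl$seq, unname(rows))
  expect_error(read_msa(tempfile()), class = "dhprof_notfound")
})
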