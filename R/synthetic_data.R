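# Deterministic generators for toy structures, alignments and coupled
# domain bundles.  Fixtures are statistical, not physical: the C-alpha trace
# is an idealized 3.8 A persistent random walk and side chains are stubs, so
# the pipeline's inputs (coordinates, B-factors, gaps, alignments) are
# realistic in distribution while every planted quantity stays exactly known.

#' Generate a synthetic single-chain structure
#'
#' Builds an idealized C-alpha trace (3.8 Å virtual bonds along a smooth
#' persistent random walk) with His/Asp side-chain stub atoms
#' (Nδ1/Nε2, Oδ1/Oδ2) wherever the sequence has His or Asp, a planted
#' B-factor profile, planted unmodeled segments (removed from the
#' coordinates and declared as missing residues), and optionally exact
#' active-site geometry and a two-atom ligand.
#'
#' @param n_residues Chain length (author numbering 1..n).
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @param sequence Optional one-letter sequence (length `n_residues`);
#'   random (His/Asp/Arg-free) letters otherwise.
#' @param chain_id,id Chain and structure identifiers.
#' @param bfactor_mean,bfactor_sd Background B-factor distribution (Å²).
#' @param elevated Optional tibble (`start`, `end`, `value`) of residue
#'   ranges whose B-factors are set near `value`.
#' @param unmodeled Optional tibble (`start`, `end`) of residue ranges to
#'   remove and declare missing.
#' @param dyad Optional list `(his, asp, distance)`: plants the His Nε2 and
#'   Asp Oδ1 so their separation is exactly `distance` Å.
#' @param arg_his Optional list `(arg, his, distance)`: rescales the Arg
#'   C-alpha position so its distance to the His C-alpha is exactly
#'   `distance` Å.
#' @param ligand Optional list `(resname, atom_a, atom_b, distance)`: adds a
#'   two-atom HETATM ligand with the given atom separation.
#' @param helix,sheet Optional tibbles (`start`, `end`) written as
#'   HELIX/SHEET records.
#' @return A `dh_structure`.
#' @export
synth_structure <- function(n_residues = 220L, seed = 1L, sequence = NULL,
                            chain_id = "A", id = "synthetic",
                            bfactor_mean = 20, bfactor_sd = 2,
                            elevated = NULL, unmodeled = NULL,
                            dyad = NULL, arg_his = NULL, ligand = NULL,
                            helix = NULL, sheet = NULL) {
  check_ranges <- function(r, what) {
    if (is.null(r) || nrow(r) == 0L) return(invisible())
    if (any(r$start < 1L | r$end > n_residues | r$start > r$end)) {
      dh_abort(paste0(what, " ranges must lie within [1, n_residues]"), "spec")
    }
  }
  check_ranges(elevated, "elevated")
  check_ranges(unmodeled, "unmodeled")
  with_local_seed(seed, {
    if (is.null(sequence)) {
      safe <- setdiff(.aa_letters, c("H", "D", "R"))
      sequence <- paste(sample(safe, n_residues, replace = TRUE), collapse = "")
    }
    letters1 <- strsplit(sequence, "")[[1]]
    if (length(letters1) != n_residues) {
      dh_abort("sequence length must equal n_residues", "spec")
    }
    coords <- ca_trace(n_residues)
    b <- pmax(rnorm(n_residues, bfactor_mean, bfactor_sd), 0.01)
    if (!is.null(elevated)) {
      for (i in seq_len(nrow(elevated))) {
        idx <- elevated$start[i]:elevated$end[i]
        b[idx] <- pmax(rnorm(length(idx), elevated$value[i], bfactor_sd), 0.01)
      }
    }
    resname <- aa_one_to_three(letters1)
    atoms <- tibble::tibble(
      chain = chain_id, resno = seq_len(n_residues), icode = "",
      resname = resname, atom = "CA", element = "C",
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      occupancy = 1, b_factor = b, altloc = ""
    )
    atoms <- dplyr::bind_rows(atoms, sidechain_stubs(atoms, coords))
    if (!is.null(dyad)) {
      atoms <- plant_dyad(atoms, dyad)
    }
    if (!is.null(arg_his)) {
      atoms <- plant_arg_distance(atoms, arg_his)
    }
    missing <- empty_missing()
    if (!is.null(unmodeled) && nrow(unmodeled) > 0L) {
      gone <- unlist(purrr::map2(unmodeled$start, unmodeled$end, seq))
      missing <- tibble::tibble(
        chain = chain_id, resno = as.integer(gone), icode = "",
        resname = resname[gone]
      )
      atoms <- dplyr::filter(atoms, !.data$resno %in% gone)
    }
    ligands <- tibble::tibble(
      chain = character(), resno = integer(), icode = character(),
      resname = character(), atom = character(), element = character(),
      x = numeric(), y = numeric(), z = numeric(),
      occupancy = numeric(), b_factor = numeric(), altloc = character()
    )
    if (!is.null(ligand)) {
      origin <- colMeans(coords) + c(30, 0, 0)   # clear of the chain
      dirv <- rand_unit()
      ligands <- tibble::tibble(
        chain = chain_id, resno = 900L, icode = "",
        resname = ligand$resname,
        atom = c(ligand$atom_a, ligand$atom_b),
        element = substr(c(ligand$atom_a, ligand$atom_b), 1, 1),
        x = c(origin[1], origin[1] + ligand$distance * dirv[1]),
        y = c(origin[2], origin[2] + ligand$distance * dirv[2]),
        z = c(origin[3], origin[3] + ligand$distance * dirv[3]),
        occupancy = 1, b_factor = 30, altloc = ""
      )
    }
    ss_tbl <- function(r) {
      if (is.null(r) || nrow(r) == 0L) {
        tibble::tibble(chain = character(), start = integer(), end = integer())
      } else {
        tibble::tibble(chain = chain_id, start = as.integer(r$start),
                       end = as.integer(r$end))
      }
    }
    structure(
      list(id = id, source_format = "PDB", atoms = atoms, ligands = ligands,
           missing = missing, helix = ss_tbl(helix), sheet = ss_tbl(sheet)),
      class = "dh_structure"
    )
  })
}

# persistent random walk with fixed 3.8 A virtual bonds
ca_trace <- function(n) {
  coords <- matrix(0, n, 3)
  d <- rand_unit()
  for (i in 2:n) {
    d <- d + 0.4 * rand_unit()
    d <- d / vec_norm(d)
    coords[i, ] <- coords[i - 1L, ] + 3.8 * d
  }
  coords
}

rand_unit <- function() {
  v <- rnorm(3)
  v / vec_norm(v)
}

# stub imidazole N / carboxylate O atoms for every His and Asp
sidechain_stubs <- function(atoms, coords) {
  out <- list()
  n <- nrow(coords)
  for (i in which(atoms$resname %in% c("HIS", "ASP"))) {
    nxt <- coords[min(i + 1L, n), ] - coords[i, ]
    if (vec_norm(nxt) < 1e-9) nxt <- c(1, 0, 0)
    p <- c(nxt[2], -nxt[1], 0)
    if (vec_norm(p) < 1e-6) p <- c(1, 0, 0)
    p <- p / vec_norm(p)
    base <- coords[i, ] + 2.0 * p
    nm <- if (atoms$resname[i] == "HIS") c("ND1", "NE2") else c("OD1", "OD2")
    out[[length(out) + 1L]] <- tibble::tibble(
      chain = atoms$chain[i], resno = atoms$resno[i], icode = "",
      resname = atoms$resname[i], atom = nm,
      element = substr(nm, 1, 1),
      x = c(base[1], base[1] + 1.1 * nxt[1] / vec_norm(nxt)),
      y = c(base[2], base[2] + 1.1 * nxt[2] / vec_norm(nxt)),
      z = c(base[3], base[3] + 1.1 * nxt[3] / vec_norm(nxt)),
      occupancy = 1, b_factor = atoms$b_factor[i], altloc = ""
    )
  }
  dplyr::bind_rows(out)
}

plant_dyad <- function(atoms, dyad) {
  ca_h <- as.numeric(atoms[atoms$resno == dyad$his & atoms$atom == "CA",
                           c("x", "y", "z")])
  u <- rand_unit()
  ne2 <- ca_h + 2.0 * u
  od1 <- ne2 + dyad$distance * rand_unit()
  od2 <- od1 + 1.0 * (od1 - ne2) / vec_norm(od1 - ne2)
  nd1 <- ne2 + 2.2 * (od1 - ne2) / vec_norm(od1 - ne2) * -1
  set_atom <- function(atoms, resno, name, v) {
    i <- which(atoms$resno == resno & atoms$atom == name)
    if (length(i) == 0L) {
      dh_abort(paste0("cannot plant dyad: residue ", resno,
                      " lacks atom ", name), "spec")
    }
    atoms$x[i] <- v[1]; atoms$y[i] <- v[2]; atoms$z[i] <- v[3]
    atoms
  }
  atoms <- set_atom(atoms, dyad$his, "NE2", ne2)
  atoms <- set_atom(atoms, dyad$his, "ND1", nd1)
  atoms <- set_atom(atoms, dyad$asp, "OD1", od1)
  set_atom(atoms, dyad$asp, "OD2", od2)
}

plant_arg_distance <- function(atoms, arg_his) {
  ia <- which(atoms$resno == arg_his$arg & atoms$atom == "CA")
  ih <- which(atoms$resno == arg_his$his & atoms$atom == "CA")
  ca_a <- as.numeric(atoms[ia, c("x", "y", "z")])
  ca_h <- as.numeric(atoms[ih, c("x", "y", "z")])
  v <- ca_a - ca_h
  if (vec_norm(v) < 1e-9) v <- rand_unit()
  new_ca <- ca_h + arg_his$distance * v / vec_norm(v)
  atoms$x[ia] <- new_ca[1]; atoms$y[ia] <- new_ca[2]; atoms$z[ia] <- new_ca[3]
  atoms
}

#' Generate a rigidly related structure pair with known ground truth
#'
#' Builds a reference structure A and a copy B obtained by a (random or
#' supplied) proper rotation and translation, per-atom Gaussian coordinate
#' noise, and optional planted displacements of selected residues.  `noise`
#' is the RMS 3-D displacement per atom (per-coordinate sd `noise/sqrt(3)`),
#' so the post-fit core RMSD of an undisplaced pair is close to `noise`.
#'
#' @param n_residues Chain length.
#' @param seed Integer seed.
#' @param noise RMS displacement per atom in Å (default 0).
#' @param displaced Integer vector of residue numbers to displace, or a
#'   fraction in (0,1) drawn deterministically from the seed.
#' @param displacement Displacement magnitude in Å (default 6).
#' @param rotation,translation Optional 3×3 proper rotation / length-3
#'   translation; random when `NULL`.
#' @param ... Passed to [synth_structure()] for structure A.
#' @return List with `a`, `b` (`dh_structure`), and `truth`: list
#'   (`rotation`, `translation`, `noise`, `displaced` residue numbers,
#'   `displacement`).
#' @export
synth_structure_pair <- function(n_residues = 200L, seed = 1L, noise = 0,
                                 displaced = integer(0), displacement = 6,
                                 rotation = NULL, translation = NULL, ...) {
  a <- synth_structure(n_residues = n_residues, seed = seed, id = "synthA", ...)
  with_local_seed(seed + 1L, {
    if (is.null(rotation)) rotation <- rand_rotation()
    if (is.null(translation)) translation <- runif(3, -20, 20)
    if (length(displaced) == 1L && displaced > 0 && displaced < 1) {
      displaced <- sort(sample.int(n_residues, round(displaced * n_residues)))
    }
    displaced <- as.integer(displaced)
    atoms_b <- a$atoms
    xyz <- as.matrix(atoms_b[, c("x", "y", "z")])
    for (rn in displaced) {
      idx <- which(atoms_b$resno == rn)
      off <- displacement * rand_unit()
      xyz[idx, ] <- sweep(xyz[idx, , drop = FALSE], 2, off, "+")
    }
    if (noise > 0) {
      xyz <- xyz + matrix(rnorm(length(xyz), 0, noise / sqrt(3)), ncol = 3)
    }
    xyz <- sweep(xyz %*% t(rotation), 2, translation, "+")
    atoms_b$x <- xyz[, 1]; atoms_b$y <- xyz[, 2]; atoms_b$z <- xyz[, 3]
    b <- a
    b$id <- "synthB"
    b$atoms <- atoms_b
    list(a = a, b = b,
         truth = list(rotation = rotation, translation = translation,
                      noise = noise, displaced = displaced,
                      displacement = displacement))
  })
}

# uniform random proper rotation via normalized quaternion
rand_rotation <- function() {
  q <- rnorm(4)
  q <- q / vec_norm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Generate a synthetic MSA with controlled column compositions
#'
#' Each column has its own generating distribution: either a conserved
#' letter with substitution probability `sub_prob` (the remaining mass spread
#' uniformly over the other 19 letters), or a multinomial drawn once from a
#' symmetric Dirichlet with concentration `alpha` ("variable" columns).
#' Sequences are sampled column-independently; gaps are applied per column
#' with probability `gap_prob` (the reference row, when given, is never
#' gapped).  The expected plug-in entropy of every column is estimated by
#' direct simulation (`truth_draws` draws) and stored as ground truth, so
#' tests never share code with the entropy implementation under test.
#'
#' @param n_sequences Number of rows (default 330, a ClusterCAD-scale
#'   dehydratase alignment).
#' @param n_columns Number of columns (ignored when `reference_seq` is
#'   given).
#' @param seed Integer seed.
#' @param reference_seq Optional ungapped reference sequence forming row 1
#'   (id `"reference"`); conserved letters default to it.
#' @param variable_columns Column indices generated from the Dirichlet.
#' @param alpha Symmetric Dirichlet concentration for variable columns
#'   (default 20: compositions close to uniform, entropy near `log2(20)`).
#' @param sub_prob Substitution probability of conserved columns (default 0).
#' @param gap_prob Per-column gap probability, scalar or length
#'   `n_columns`.
#' @param truth_draws Monte-Carlo draws for the stored expected entropy.
#' @return List with `msa` (a `dh_msa`) and `truth`: tibble (`column`,
#'   `type`, `p` list-column, `expected_entropy` bits, `gap_prob`).
#' @export
synth_msa <- function(n_sequences = 330L, n_columns = 220L, seed = 1L,
                      reference_seq = NULL, variable_columns = integer(0),
                      alpha = 20, sub_prob = 0, gap_prob = 0,
                      truth_draws = 1e5L) {
  with_local_seed(seed, {
    if (!is.null(reference_seq)) {
      ref <- strsplit(toupper(reference_seq), "")[[1]]
      n_columns <- length(ref)
    } else {
      ref <- sample(.aa_letters, n_columns, replace = TRUE)
    }
    gap_prob <- rep_len(gap_prob, n_columns)
    if (any(gap_prob < 0 | gap_prob > 1)) {
      dh_abort("gap_prob must be in [0, 1]", "spec")
    }
    if (length(variable_columns) &&
        any(variable_columns < 1L | variable_columns > n_columns)) {
      dh_abort("variable_columns out of range", "spec")
    }
    ps <- vector("list", n_columns)
    type <- rep("conserved", n_columns)
    for (j in seq_len(n_columns)) {
      if (j %in% variable_columns) {
        type[j] <- "variable"
        g <- rgamma(20, shape = alpha)
        ps[[j]] <- setNames(g / sum(g), .aa_letters)
      } else {
        p <- rep(sub_prob / 19, 20)
        p[match(ref[j], .aa_letters)] <- 1 - sub_prob
        if (!ref[j] %in% .aa_letters) p <- rep(1 / 20, 20)  # 'X' reference
        ps[[j]] <- setNames(p, .aa_letters)
      }
    }
    m <- matrix("", n_sequences, n_columns)
    has_ref <- !is.null(reference_seq)
    if (has_ref) m[1, ] <- ref
    for (j in seq_len(n_columns)) {
      rows <- if (has_ref) seq(2L, n_sequences) else seq_len(n_sequences)
      m[rows, j] <- sample(.aa_letters, length(rows), replace = TRUE,
                           prob = ps[[j]])
      if (gap_prob[j] > 0) {
        gapped <- rows[runif(length(rows)) < gap_prob[j]]
        m[gapped, j] <- "-"
      }
    }
    ids <- c(if (has_ref) "reference",
             sprintf("seq%03d", seq_len(n_sequences - has_ref)))
    truth_h <- vapply(seq_len(n_columns), function(j) {
      if (type[j] == "conserved" && sub_prob == 0) return(0)
      draws <- sample.int(20, truth_draws, replace = TRUE, prob = ps[[j]])
      f <- tabulate(draws, nbins = 20) / truth_draws
      f <- f[f > 0]
      -sum(f * log2(f))
    }, numeric(1))
    list(
      msa = dh_msa(ids, apply(m, 1, paste, collapse = "")),
      truth = tibble::tibble(
        column = seq_len(n_columns), type = type, p = ps,
        expected_entropy = truth_h, gap_prob = gap_prob
      )
    )
  })
}

#' Generate a coupled structure + MSA domain bundle
#'
#' Produces a pipeline-ready fixture emulating the dehydratase two-loop
#' pattern: a reference structure whose chain sequence equals the ungapped
#' reference row of a synthetic MSA, with coupled regions that are
#' simultaneously high-entropy in the alignment and flexible (elevated
#' B-factors) or unmodeled in the structure.  Planted active-site geometry
#' (His/Asp dyad, conserved Arg, two-atom PPant-like ligand) makes the full
#' [profile_domain()] pipeline runnable on the fixture.
#'
#' @param seed Integer seed.
#' @param n_residues Domain length (default 220).
#' @param n_sequences MSA depth (default 330).
#' @param coupling Tibble (`start`, `end`, `high_H`, `high_B`, `unmodeled`)
#'   of coupled regions; the default plants one unmodeled high-entropy
#'   11-residue loop and one flexible high-entropy 8-residue loop.
#' @param alpha,sub_prob,gap_prob MSA composition parameters (see
#'   [synth_msa()]; defaults 20 / 0.05 / 0.05).
#' @param bfactor_mean,bfactor_sd,elevated_b B-factor background and planted
#'   elevation (defaults 20 / 2 / 80 Å²).
#' @param plant_active_site Plant dyad, Arg and ligand geometry
#'   (default TRUE).
#' @param dyad_distance,arg_his_distance,ppant_c3_distance Planted
#'   active-site distances in Å (defaults 2.8, 17.8, 16.4).
#' @param truth_draws Monte-Carlo draws for the stored expected entropies.
#' @return List with `structure`, `msa`, `reference_id`, `truth`: list
#'   (`regions` tibble with expected evidence, `msa` truth tibble,
#'   `active_site` list, `coupling`).
#' @export
synth_domain_bundle <- function(seed = 1L, n_residues = 220L,
                                n_sequences = 330L, coupling = NULL,
                                alpha = 20, sub_prob = 0.05, gap_prob = 0.05,
                                bfactor_mean = 20, bfactor_sd = 2,
                                elevated_b = 80, plant_active_site = TRUE,
                                dyad_distance = 2.8, arg_his_distance = 17.8,
                                ppant_c3_distance = 16.4, truth_draws = 1e5L) {
  if (is.null(coupling)) {
    s1 <- round(0.55 * n_residues)
    s2 <- round(0.32 * n_residues)
    coupling <- tibble::tibble(
      start = c(s2, s1), end = c(s2 + 7L, s1 + 10L),
      high_H = TRUE, high_B = c(TRUE, FALSE), unmodeled = c(FALSE, TRUE)
    )
  }
  if (any(coupling$start < 1L | coupling$end > n_residues |
            coupling$start > coupling$end)) {
    dh_abort("coupling ranges must lie within [1, n_residues]", "spec")
  }
  if (any(coupling$unmodeled & coupling$high_B)) {
    dh_abort("a region cannot be both unmodeled and high-B (no atoms carry B)",
             "spec")
  }

  seq1 <- with_local_seed(seed + 2L, {
    safe <- setdiff(.aa_letters, c("H", "D", "R"))
    letters1 <- sample(safe, n_residues, replace = TRUE)
    if (plant_active_site) {
      put <- function(letters1, pos, motif) {
        mc <- strsplit(motif, "")[[1]]
        fill <- mc != "x"
        letters1[pos + which(fill) - 1L] <- mc[fill]
        letters1
      }
      his_pos <- max(2L, round(0.15 * n_residues))
      letters1 <- put(letters1, his_pos, "HxxxGxxxxP")
      letters1 <- put(letters1, n_residues - 5L, "LxLxR")
      asp_pos <- max(coupling$start[nrow(coupling)] - 5L, his_pos + 11L)
      letters1[asp_pos] <- "D"
    }
    letters1
  })

  elev <- coupling |> dplyr::filter(.data$high_B) |>
    dplyr::mutate(value = elevated_b) |> dplyr::select("start", "end", "value")
  unmod <- coupling |> dplyr::filter(.data$unmodeled) |>
    dplyr::select("start", "end")
  his_pos <- if (plant_active_site) max(2L, round(0.15 * n_residues)) else NULL
  asp_pos <- if (plant_active_site) {
    max(coupling$start[nrow(coupling)] - 5L, his_pos + 11L)
  } else NULL
  arg_pos <- if (plant_active_site) n_residues - 1L else NULL

  str <- synth_structure(
    n_residues = n_residues, seed = seed,
    sequence = paste(seq1, collapse = ""),
    id = "bundle", bfactor_mean = bfactor_mean, bfactor_sd = bfactor_sd,
    elevated = if (nrow(elev)) elev else NULL,
    unmodeled = if (nrow(unmod)) unmod else NULL,
    dyad = if (plant_active_site)
      list(his = his_pos, asp = asp_pos, distance = dyad_distance),
    arg_his = if (plant_active_site)
      list(arg = arg_pos, his = his_pos, distance = arg_his_distance),
    ligand = if (plant_active_site)
      list(resname = "PNS", atom_a = "P", atom_b = "C3",
           distance = ppant_c3_distance)
  )

  var_cols <- coupling |> dplyr::filter(.data$high_H)
  var_idx <- if (nrow(var_cols)) {
    unlist(purrr::map2(var_cols$start, var_cols$end, seq))
  } else integer(0)
  gen <- synth_msa(
    n_sequences = n_sequences, seed = seed + 3L,
    reference_seq = paste(seq1, collapse = ""),
    variable_columns = var_idx, alpha = alpha,
    sub_prob = sub_prob, gap_prob = gap_prob, truth_draws = truth_draws
  )

  truth_regions <- coupling |>
    dplyr::mutate(evidence = purrr::pmap_chr(
      list(.data$high_H, .data$high_B, .data$unmodeled),
      function(h, b, u) paste(c(if (h) "high_entropy", if (b) "high_bfactor",
                                if (u) "unmodeled"), collapse = ",")
    )) |>
    dplyr::select("start", "end", "evidence")

  list(
    structure = str, msa = gen$msa, reference_id = "reference",
    truth = list(
      regions = truth_regions, msa = gen$truth,
      active_site = if (plant_active_site) {
        list(his = his_pos, asp = asp_pos, arg = arg_pos,
             dyad_distance = dyad_distance,
             arg_his_distance = arg_his_distance,
             ppant_c3_distance = ppant_c3_distance)
      },
      coupling = coupling
    )
  )
}
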