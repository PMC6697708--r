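#' Scan a sequence for wildcard motifs
#'
#' Finds every (possibly overlapping) exact match of motif patterns written
#' in the conventional one-letter shorthand with `x` as a single-residue
#' wildcard — e.g. the dehydratase motifs `HxxxGxxxxP`, `GYxYGPxF`, `LPFxW`,
#' `HPLL` and `LxLxR`.
#'
#' @param x A `dh_seqmap` from [chain_sequence()] or a plain amino-acid
#'   string.
#' @param patterns Character vector of motif strings (20 standard letters
#'   plus `x`).
#' @return Tibble sorted by position: `pattern`, `pos` (1-based position in
#'   the modeled sequence), `resno` (author number of the first matched
#'   residue; `NA` for a plain string), `matched`.
#' @examples
#' scan_motifs("AHPLLG", "HPLL")
#' @export
scan_motifs <- function(x, patterns) {
  seqmap <- NULL
  if (inherits(x, "dh_seqmap")) {
    seqmap <- x
    x <- x$seq
  }
  x <- as_aa_string(x, "x")
  bad <- grepl(paste0("[^", paste(.aa_letters, collapse = ""), "x]"), patterns)
  if (any(bad)) {
    dh_abort(paste0("invalid motif pattern(s): ",
                    paste(patterns[bad], collapse = ", "),
                    " (use one-letter codes and 'x')"), "argument")
  }
  out <- purrr::map(patterns, function(p) {
    rx <- paste0("(?=(", gsub("x", ".", p, fixed = TRUE), "))")
    m <- gregexpr(rx, x, perl = TRUE)[[1]]
    if (m[1] == -1L) {
      return(tibble::tibble(pattern = character(), pos = integer(),
                            matched = character()))
    }
    tibble::tibble(
      pattern = p,
      pos = as.integer(m),
      matched = substring(x, m, m + nchar(p) - 1L)
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$pos, .data$pattern)
  out$resno <- if (!is.null(seqmap)) seqmap$map$resno[out$pos] else NA_integer_
  out[, c("pattern", "pos", "resno", "matched")]
}

atom_xyz <- function(structure, chain_id, resno, atom_names) {
  structure$atoms |>
    dplyr::filter(.data$chain == chain_id, .data$resno == !!resno,
                  .data$atom %in% atom_names) |>
    dplyr::select("atom", "x", "y", "z")
}

#' Locate the His/Asp catalytic dyad
#'
#' The dehydratase catalytic histidine sits at the start of the
#' `HxxxGxxxxP` motif; its partner aspartate is found geometrically as the
#' Asp whose carboxylate oxygen (Oδ1/Oδ2) lies nearest any imidazole
#' nitrogen (Nδ1/Nε2) of the candidate His.  When the motif is absent every
#' His is considered.  The pair is accepted when the minimum N–O distance is
#' at most `max_dyad_distance`; the measured distance is always reported.
#'
#' @param structure A `dh_structure`.
#' @param chain_id Chain identifier.
#' @param his_motif Motif anchoring the catalytic His (default
#'   `"HxxxGxxxxP"`).
#' @param max_dyad_distance Acceptance cutoff in Å (default 4.0; observed
#'   dyads average under 3.8 Å).
#' @return A `dh_activesite`: list with `chain`, `his` (tibble row), `asp`,
#'   `dyad_distance` (Å), `dyad_found`, plus `conserved_arg` /
#'   `arg_his_ca_distance` / `ligand_reach` slots filled by
#'   [conserved_arg_distance()] and [ligand_reach()].
#' @export
find_catalytic_dyad <- function(structure, chain_id, his_motif = "HxxxGxxxxP",
                                max_dyad_distance = 4.0) {
  seqmap <- chain_sequence(structure, chain_id)
  res <- seqmap$map
  his_all <- res$resno[res$resname == "HIS"]
  if (length(his_all) == 0L) {
    dh_abort(paste0("no histidine in chain '", chain_id, "'"), "nodyad")
  }
  hits <- scan_motifs(seqmap, his_motif)
  cand <- if (nrow(hits) > 0L) unique(hits$resno) else his_all
  asp_all <- res$resno[res$resname == "ASP"]
  best <- NULL
  for (h in cand) {
    hn <- atom_xyz(structure, chain_id, h, c("ND1", "NE2"))
    if (nrow(hn) == 0L) next
    for (a in asp_all) {
      ao <- atom_xyz(structure, chain_id, a, c("OD1", "OD2"))
      if (nrow(ao) == 0L) next
      d <- min(apply(as.matrix(hn[, c("x", "y", "z")]), 1, function(hc) {
        apply(as.matrix(ao[, c("x", "y", "z")]), 1,
              function(oc) vec_norm(hc - oc))
      }))
      if (is.null(best) || d < best$d) best <- list(his = h, asp = a, d = d)
    }
  }
  if (is.null(best)) {
    dh_abort("no His imidazole-N / Asp carboxylate-O atom pairs present",
             "nodyad")
  }
  structure(
    list(
      chain = chain_id,
      his = tibble::tibble(resno = best$his, resname = "HIS"),
      asp = tibble::tibble(resno = best$asp, resname = "ASP"),
      dyad_distance = best$d,
      dyad_found = best$d <= max_dyad_distance,
      conserved_arg = NULL,
      arg_his_ca_distance = NA_real_,
      ligand_reach = NA_real_
    ),
    class = "dh_activesite"
  )
}

#' Distance from the catalytic His to the conserved PPant-side Arg
#'
#' The invariant arginine at the C-terminal end of β14 (proposed to dock the
#' ACP/PPant arm) is identified as the Arg of the last `LxLxR` motif match
#' in the chain; the reported quantity is its Cα–Cα distance to the
#' catalytic His.  Across type I DH structures this distance averages
#' 17.8 Å.
#'
#' @param structure A `dh_structure`.
#' @param chain_id Chain identifier.
#' @param geometry A `dh_activesite` from [find_catalytic_dyad()].
#' @param arg_motif Motif whose final position is the conserved Arg
#'   (default `"LxLxR"`).
#' @return The updated `dh_activesite`.  When no motif match exists a
#'   warning is raised and `conserved_arg` stays `NULL`.
#' @export
conserved_arg_distance <- function(structure, chain_id, geometry,
                                   arg_motif = "LxLxR") {
  stopifnot(inherits(geometry, "dh_activesite"))
  seqmap <- chain_sequence(structure, chain_id)
  hits <- scan_motifs(seqmap, arg_motif)
  if (nrow(hits) == 0L) {
    warn(paste0("no ", arg_motif, " motif in chain '", chain_id,
                "'; conserved Arg not assigned"))
    return(geometry)
  }
  last <- hits[nrow(hits), ]
  arg_pos <- last$pos + nchar(arg_motif) - 1L
  arg_resno <- seqmap$map$resno[arg_pos]
  ca_h <- atom_xyz(structure, chain_id, geometry$his$resno, "CA")
  ca_r <- atom_xyz(structure, chain_id, arg_resno, "CA")
  if (nrow(ca_h) == 0L || nrow(ca_r) == 0L) {
    dh_abort("missing C-alpha atom on His or Arg", "notfound")
  }
  geometry$conserved_arg <- tibble::tibble(
    resno = arg_resno, resname = seqmap$map$resname[arg_pos]
  )
  geometry$arg_his_ca_distance <-
    vec_norm(as.numeric(ca_h[1, c("x", "y", "z")]) -
               as.numeric(ca_r[1, c("x", "y", "z")]))
  geometry
}

#' Distance between two named atoms of a bound ligand
#'
#' Measures the Euclidean distance between two atoms of a HETATM ligand —
#' e.g. the phosphopantetheine phosphate to the C-3 position of a bound
#' acyl thioester, the span that places the reactive carbon in the catalytic
#' region (about 16.4 Å in PPant-bound DH co-crystal structures).
#'
#' @param structure A `dh_structure`.
#' @param het_code Three-letter HET code of the ligand.
#' @param atom_a,atom_b Atom names within that ligand.
#' @return Distance in Å.
#' @export
ligand_reach <- function(structure, het_code, atom_a, atom_b) {
  lig <- structure$ligands |> dplyr::filter(.data$resname == het_code)
  if (nrow(lig) == 0L) {
    dh_abort(paste0("ligand '", het_code, "' not found"), "notfound")
  }
  get_atom <- function(nm) {
    row <- lig |> dplyr::filter(.data$atom == nm)
    if (nrow(row) == 0L) {
      dh_abort(paste0("atom '", nm, "' not found in ligand '", het_code, "'"),
               "notfound")
    }
    as.numeric(row[1, c("x", "y", "z")])
  }
  vec_norm(get_atom(atom_a) - get_atom(atom_b))
}

#' @export
print.dh_activesite <- function(x, ...) {
  cat("<dh_activesite> chain ", x$chain,
      ": His", x$his$resno, " / Asp", x$asp$resno,
      sprintf(" dyad %.2f A", x$dyad_distance),
      if (!x$dyad_found) " (beyond cutoff)", "\n", sep = "")
  if (!is.null(x$conserved_arg)) {
    cat(sprintf("  conserved Arg%d, Arg-His Ca %.2f A\n",
                x$conserved_arg$resno, x$arg_his_ca_distance))
  }
  invisible(x)
}

#' @export
tidy.dh_activesite <- function(x, ...) {
  tibble::tibble(
    chain = x$chain,
    his_resno = x$his$resno,
    asp_resno = x$asp$resno,
    dyad_distance = x$dyad_distance,
    dyad_found = x$dyad_found,
    arg_resno = if (is.null(x$conserved_arg)) NA_integer_ else x$conserved_arg$resno,
    arg_his_ca_distance = x$arg_his_ca_distance,
    ligand_reach = x$ligand_reach
  )
}
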