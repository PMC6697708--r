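#' Call variable substrate-binding regions
#'
#' Integrates sequence variability and structural flexibility into region
#' calls: a residue is flagged when its mapped-column Shannon entropy is at
#' or above the `h_percentile` quantile of the track AND it is either
#' flexible (`z >= z_threshold`) or unmodeled (missing density counts as the
#' strongest disorder evidence).  Flagged residues are merged into maximal
#' segments allowing numbering gaps of at most `merge_gap`; segments shorter
#' than `min_length` are dropped.  In dehydratase domains this reproduces
#' the characteristic pattern of two variable loops (α3–β11 and β7–α2)
#' flanking an otherwise conserved, rigid double-hotdog core.
#'
#' @param entropy_track Per-residue entropy tibble from
#'   [residue_entropy_track()] (columns `resno`, `entropy`, `modeled`).
#' @param flex A `dh_flexprofile` for the same chain/numbering.
#' @param h_percentile Entropy percentile cutoff in `[0, 1)` (default 0.75).
#' @param h_floor Absolute entropy floor in bits (default 1.0): a residue is
#'   never called high-entropy below it.  This keeps the percentile cutoff
#'   meaningful on uniformly conserved domains, where the track is nearly
#'   constant and any percentile would otherwise flag a quarter of the chain.
#' @param z_threshold B-factor z-score threshold (default 1.0).
#' @param min_length Minimum region length in residues (default 3).
#' @param merge_gap Maximum numbering gap bridged when merging (default 1).
#' @param labels Optional tibble (`start`, `end`, `label`) assigning
#'   canonical names (e.g. `"α3–β11"`) to called regions by maximal overlap.
#' @return Tibble of `RegionAnnotation` rows: `chain`, `start`, `end`,
#'   `length`, `label`, `evidence` (comma-joined subset of `high_entropy`,
#'   `high_bfactor`, `unmodeled`), `mean_H`, `mean_z`.  Sorted and
#'   non-overlapping.
#' @export
call_variable_regions <- function(entropy_track, flex,
                                  h_percentile = 0.75, z_threshold = 1.0,
                                  min_length = 3L, merge_gap = 1L,
                                  labels = NULL, h_floor = 1.0) {
  stopifnot(inherits(flex, "dh_flexprofile"))
  flex_tbl <- tibble::as_tibble(flex)[, c("resno", "z", "modeled")]
  track <- tibble::as_tibble(entropy_track)
  if (!all(c("resno", "entropy") %in% names(track))) {
    dh_abort("entropy_track needs columns resno and entropy", "argument")
  }
  joined <- dplyr::inner_join(track[, c("resno", "entropy")], flex_tbl,
                              by = "resno")
  if (nrow(joined) == 0L) {
    dh_abort("entropy track and flexibility profile share no residue numbers",
             "index_mismatch")
  }
  h_cut <- max(quantile(joined$entropy, h_percentile, na.rm = TRUE,
                        names = FALSE),
               h_floor)
  joined <- joined |>
    dplyr::mutate(
      high_h = !is.na(.data$entropy) & .data$entropy >= h_cut,
      high_z = .data$modeled & !is.na(.data$z) & .data$z >= z_threshold,
      flagged = .data$high_h & (.data$high_z | !.data$modeled)
    )
  hot <- sort(unique(joined$resno[joined$flagged]))
  regions <- merge_with_gap(hot, merge_gap)
  regions <- regions[regions$length >= min_length, , drop = FALSE]
  chain_id <- attr(flex, "chain_id")
  if (nrow(regions) == 0L) {
    return(tibble::tibble(chain = character(), start = integer(),
                          end = integer(), length = integer(),
                          label = character(), evidence = character(),
                          mean_H = numeric(), mean_z = numeric()))
  }
  ann <- purrr::pmap(regions, function(start, end, length) {
    mem <- joined |> dplyr::filter(.data$resno >= start, .data$resno <= end,
                                   .data$flagged)
    ev <- c(
      "high_entropy",
      if (any(mem$high_z)) "high_bfactor",
      if (any(!mem$modeled)) "unmodeled"
    )
    tibble::tibble(
      chain = chain_id, start = start, end = end, length = length,
      label = NA_character_,
      evidence = paste(ev, collapse = ","),
      mean_H = mean(mem$entropy, na.rm = TRUE),
      mean_z = if (any(mem$modeled)) mean(mem$z[mem$modeled]) else NA_real_
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$start)
  if (!is.null(labels)) {
    ann$label <- purrr::map2_chr(ann$start, ann$end, function(s, e) {
      ov <- pmin(labels$end, e) - pmax(labels$start, s) + 1L
      if (any(ov > 0)) labels$label[which.max(ov)] else NA_character_
    })
  }
  ann
}

# merge sorted residue numbers into segments bridging gaps <= merge_gap
merge_with_gap <- function(x, merge_gap) {
  x <- sort(unique(as.integer(x)))
  if (length(x) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(), length = integer()))
  }
  brk <- c(0L, which(diff(x) > merge_gap + 1L), length(x))
  tibble::tibble(start = x[head(brk, -1L) + 1L], end = x[brk[-1L]]) |>
    dplyr::mutate(length = .data$end - .data$start + 1L)
}

#' Per-residue secondary structure of a chain
#'
#' Uses `HELIX`/`SHEET` records when the file declares them; otherwise falls
#' back to a backbone-dihedral rule (helix: phi in \[-100, -30\] and psi in
#' \[-80, -5\] degrees for runs of at least 4; strand: phi in \[-180, -40\]
#' and psi in \[90, 180\] or \[-180, -170\] for runs of at least 3).  Chains
#' without full backbone atoms (e.g. C-alpha traces) and no records come
#' back all-coil.
#'
#' @param structure A `dh_structure`.
#' @param chain_id Chain identifier.
#' @return Tibble `resno`, `ss` (`"H"`, `"E"` or `"C"`).
#' @export
secondary_structure <- function(structure, chain_id) {
  check_chain(structure, chain_id)
  res <- modeled_residues(structure, chain_id)
  ss <- rep("C", nrow(res))
  hel <- structure$helix |> dplyr::filter(.data$chain == chain_id)
  she <- structure$sheet |> dplyr::filter(.data$chain == chain_id)
  if (nrow(hel) + nrow(she) > 0L) {
    for (i in seq_len(nrow(hel))) {
      ss[res$resno >= hel$start[i] & res$resno <= hel$end[i]] <- "H"
    }
    for (i in seq_len(nrow(she))) {
      ss[res$resno >= she$start[i] & res$resno <= she$end[i]] <- "E"
    }
    return(tibble::tibble(resno = res$resno, ss = ss))
  }
  tors <- backbone_phipsi(structure, chain_id, res$resno)
  is_h <- !is.na(tors$phi) & !is.na(tors$psi) &
    tors$phi >= -100 & tors$phi <= -30 & tors$psi >= -80 & tors$psi <= -5
  is_e <- !is.na(tors$phi) & !is.na(tors$psi) &
    tors$phi >= -180 & tors$phi <= -40 &
    ((tors$psi >= 90 & tors$psi <= 180) | (tors$psi >= -180 & tors$psi <= -170))
  mark_runs <- function(flag, min_run, code) {
    r <- rle(flag)
    pos <- 1L
    for (k in seq_along(r$lengths)) {
      if (r$values[k] && r$lengths[k] >= min_run) {
        ss[pos:(pos + r$lengths[k] - 1L)] <<- code
      }
      pos <- pos + r$lengths[k]
    }
  }
  mark_runs(is_h, 4L, "H")
  mark_runs(is_e, 3L, "E")
  tibble::tibble(resno = res$resno, ss = ss)
}

backbone_phipsi <- function(structure, chain_id, resnos) {
  get1 <- function(rn, nm) {
    v <- atom_xyz(structure, chain_id, rn, nm)
    if (nrow(v) == 0L) return(NULL)
    as.numeric(v[1, c("x", "y", "z")])
  }
  dihedral <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
            b2[1] * b3[2] - b2[2] * b3[1])
    m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
            n1[1] * b2[2] - n1[2] * b2[1]) / vec_norm(b2)
    atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  }
  phi <- psi <- rep(NA_real_, length(resnos))
  for (i in seq_along(resnos)) {
    rn <- resnos[i]
    n0 <- get1(rn, "N"); ca0 <- get1(rn, "CA"); c0 <- get1(rn, "C")
    cp <- get1(rn - 1L, "C"); nn <- get1(rn + 1L, "N")
    if (!is.null(cp) && !is.null(n0) && !is.null(ca0) && !is.null(c0)) {
      phi[i] <- dihedral(cp, n0, ca0, c0)
    }
    if (!is.null(n0) && !is.null(ca0) && !is.null(c0) && !is.null(nn)) {
      psi[i] <- dihedral(n0, ca0, c0, nn)
    }
  }
  tibble::tibble(resno = resnos, phi = phi, psi = psi)
}

#' Run the full domain-profiling pipeline on one chain
#'
#' Orchestrates flexibility profiling, conservation mapping, active-site
#' geometry and region calling into a single report object.  Deterministic
#' given inputs and configuration.
#'
#' @param structure A `dh_structure`.
#' @param chain_id Chain identifier.
#' @param msa Optional `dh_msa`; `NULL` (or `use_conservation = FALSE` in
#'   the config) restricts region evidence to flexibility alone.
#' @param reference_id MSA row matching the chain (required with `msa`).
#' @param config Parameter list from [dh_config()].
#' @return A `dh_domain_profile`: list with `structure_id`, `chain`,
#'   `flexibility`, `entropy`, `colmap`, `entropy_track`, `active_site`,
#'   `regions`, `config`.
#' @export
profile_domain <- function(structure, chain_id, msa = NULL,
                           reference_id = NULL, config = dh_config()) {
  config <- dh_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      dh_abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
               "stage", parent = e)
    })
  }
  flex <- stage("flexibility",
                bfactor_profile(structure, chain_id,
                                atom_selection = config$atom_selection))
  ent <- colmap <- track <- NULL
  use_cons <- isTRUE(config$use_conservation) && !is.null(msa)
  if (use_cons) {
    if (is.null(reference_id)) {
      dh_abort("reference_id is required when an MSA is supplied", "argument")
    }
    ent <- stage("conservation",
                 entropy_profile(msa, min_occupancy = config$min_occupancy,
                                 base = config$entropy_base))
    colmap <- stage("mapping",
                    map_to_reference(msa, reference_id, structure, chain_id,
                                     min_identity = config$min_ref_identity))
    track <- stage("mapping",
                   residue_entropy_track(ent, colmap, structure, chain_id))
  }
  site <- NULL
  if (isTRUE(config$do_active_site)) {
    site <- stage("active_site", {
      g <- find_catalytic_dyad(structure, chain_id,
                               his_motif = config$his_motif,
                               max_dyad_distance = config$max_dyad_distance)
      suppressWarnings(
        conserved_arg_distance(structure, chain_id, g,
                               arg_motif = config$arg_motif)
      )
    })
  }
  regions <- stage("region_calling", {
    if (use_cons) {
      call_variable_regions(track, flex,
                            h_percentile = config$h_percentile,
                            z_threshold = config$z_threshold,
                            min_length = config$min_length,
                            merge_gap = config$merge_gap,
                            labels = config$region_labels,
                            h_floor = config$h_floor)
    } else {
      segs <- flexible_segments(flex, z_threshold = config$z_threshold,
                                min_length = config$min_length)
      segs |>
        dplyr::mutate(label = NA_character_, mean_H = NA_real_,
                      mean_z = NA_real_) |>
        dplyr::select("chain", "start", "end", "length", "label",
                      evidence = "evidence", "mean_H", "mean_z")
    }
  })
  structure(
    list(structure_id = structure$id, chain = chain_id,
         flexibility = flex, entropy = ent, colmap = colmap,
         entropy_track = track, active_site = site, regions = regions,
         config = config),
    class = "dh_domain_profile"
  )
}

#' @export
print.dh_domain_profile <- function(x, ...) {
  cat("<dh_domain_profile> ", x$structure_id, " chain ", x$chain, "\n", sep = "")
  cat("  regions called: ", nrow(x$regions), "\n", sep = "")
  if (nrow(x$regions) > 0L) print(x$regions)
  invisible(x)
}

#' @export
tidy.dh_domain_profile <- function(x, ...) x$regions

#' @export
glance.dh_domain_profile <- function(x, ...) {
  tibble::tibble(
    structure_id = x$structure_id, chain = x$chain,
    n_regions = nrow(x$regions),
    n_residues = nrow(x$flexibility),
    n_unmodeled = sum(!x$flexibility$modeled),
    dyad_distance = if (is.null(x$active_site)) NA_real_ else
      x$active_site$dyad_distance,
    arg_his_ca_distance = if (is.null(x$active_site)) NA_real_ else
      x$active_site$arg_his_ca_distance,
    mean_entropy = if (is.null(x$entropy)) NA_real_ else mean(x$entropy$entropy)
  )
}
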