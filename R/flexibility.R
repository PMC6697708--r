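#' Per-residue B-factor flexibility profile
#'
#' Averages isotropic B-factors over the selected atoms of each modeled
#' residue and z-scores them within the chain (crystal forms differ in
#' absolute B, so normalization is per chain).  Declared-missing and
#' numbering-gap residues appear as unmodeled rows with no B value — in
#' crystallographic practice missing density is the strongest disorder
#' signal, so downstream callers treat them as maximally flexible.
#'
#' @param structure A `dh_structure`.
#' @param chain_id Chain identifier.
#' @param atom_selection `"CA"`, `"backbone"` (N, CA, C, O) or `"all"`.
#' @return A `dh_flexprofile` tibble with one row per residue (`chain`,
#'   `resno`, `icode`, `resname`, `mean_b`, `z`, `modeled`) and attributes
#'   `chain_id`, `mean_b`, `sd_b`, `atom_selection`.  A constant-B chain
#'   yields all-zero z-scores with a warning.
#' @examples
#' s <- synth_structure(n_residues = 30, seed = 1)
#' bfactor_profile(s, "A")
#' @export
bfactor_profile <- function(structure, chain_id,
                            atom_selection = c("CA", "backbone", "all")) {
  atom_selection <- match.arg(atom_selection)
  check_chain(structure, chain_id)
  sel <- structure$atoms |> dplyr::filter(.data$chain == chain_id)
  sel <- switch(atom_selection,
    CA = dplyr::filter(sel, .data$atom == "CA"),
    backbone = dplyr::filter(sel, .data$atom %in% c("N", "CA", "C", "O")),
    all = sel
  )
  per_res <- sel |>
    dplyr::summarise(mean_b = mean(.data$b_factor),
                     .by = c("chain", "resno", "icode", "resname"))
  if (nrow(per_res) < 2L) {
    dh_abort("chain needs at least 2 modeled residues with selected atoms",
             "insufficient")
  }
  mu <- mean(per_res$mean_b)
  sdv <- sqrt(mean((per_res$mean_b - mu)^2))  # population sd
  if (sdv == 0) {
    warn("constant B-factors in chain; all z-scores set to 0")
    per_res$z <- 0
  } else {
    per_res$z <- (per_res$mean_b - mu) / sdv
  }
  per_res$modeled <- TRUE

  unmod <- unmodeled_residue_rows(structure, chain_id)
  out <- dplyr::bind_rows(per_res, unmod) |>
    dplyr::arrange(.data$resno, .data$icode)
  tibble::new_tibble(out, class = "dh_flexprofile",
                     chain_id = chain_id, mean_b = mu, sd_b = sdv,
                     atom_selection = atom_selection)
}

unmodeled_residue_rows <- function(structure, chain_id) {
  segs <- suppressWarnings(unmodeled_segments(structure, chain_id))
  if (nrow(segs) == 0L) {
    return(tibble::tibble(chain = character(), resno = integer(),
                          icode = character(), resname = character(),
                          mean_b = numeric(), z = numeric(),
                          modeled = logical()))
  }
  resno <- unlist(purrr::map2(segs$start, segs$end, seq))
  declared <- structure$missing |> dplyr::filter(.data$chain == chain_id)
  tibble::tibble(
    chain = chain_id, resno = as.integer(resno), icode = "",
    resname = declared$resname[match(resno, declared$resno)],
    mean_b = NA_real_, z = NA_real_, modeled = FALSE
  )
}

#' Flexible and unmodeled segments of a flexibility profile
#'
#' Maximal runs of at least `min_length` consecutive modeled residues with
#' z-score at or above `z_threshold` (tagged `high_bfactor`), plus the
#' chain's unmodeled segments (tagged `unmodeled`).
#'
#' @param profile A `dh_flexprofile` from [bfactor_profile()].
#' @param z_threshold Z-score threshold (dimensionless, default 1.0).
#' @param min_length Minimum run length in residues (default 3).
#' @return Tibble of segments: `chain`, `start`, `end`, `length`, `evidence`.
#'   Sorted; segments sharing a tag never overlap.
#' @export
flexible_segments <- function(profile, z_threshold = 1.0, min_length = 3L) {
  stopifnot(inherits(profile, "dh_flexprofile"))
  chain_id <- attr(profile, "chain_id")
  hot <- profile$resno[profile$modeled & !is.na(profile$z) &
                         profile$z >= z_threshold]
  # runs must be consecutive in numbering AND uninterrupted by other residues
  high <- runs_from_numbers(hot)
  if (nrow(high) > 0L) {
    n_inside <- purrr::map2_int(high$start, high$end, function(s, e) {
      sum(profile$resno >= s & profile$resno <= e)
    })
    high <- high[high$length == n_inside & high$length >= min_length, ,
                 drop = FALSE]
  }
  unmod <- runs_from_numbers(profile$resno[!profile$modeled])
  out <- dplyr::bind_rows(
    dplyr::mutate(high, evidence = "high_bfactor"),
    dplyr::mutate(unmod, evidence = "unmodeled")
  )
  out |>
    dplyr::mutate(chain = chain_id, .before = 1) |>
    dplyr::arrange(.data$start, .data$evidence)
}

#' @export
tidy.dh_flexprofile <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.dh_flexprofile <- function(x, ...) {
  tibble::tibble(
    chain = attr(x, "chain_id"), n_residues = nrow(x),
    n_modeled = sum(x$modeled), mean_b = attr(x, "mean_b"),
    sd_b = attr(x, "sd_b"), atom_selection = attr(x, "atom_selection")
  )
}
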