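#' Read a protein coordinate file into a tidy structure model
#'
#' Parses a PDB or mmCIF file into a uniform model: one tibble of polymer
#' atoms, one of ligand (HETATM, non-water) atoms, declared-missing residues
#' (PDB `REMARK 465`), and any `HELIX`/`SHEET` secondary-structure records.
#' Alternate locations are collapsed to a single copy per atom: the highest
#' occupancy wins, ties go to the alphabetically first altloc tag.
#'
#' Parsing is delegated to \pkg{bio3d} (`read.pdb()` / `read.cif()`);
#' missing-residue records are extracted here since bio3d does not expose
#' them.  Waters (HOH/WAT/DOD) are dropped.  Residues within each chain are
#' sorted by author residue number and insertion code.
#'
#' @param path Path to a coordinate file.
#' @param format `"auto"` (by extension: `.pdb`/`.ent` vs `.cif`/`.mmcif`),
#'   `"pdb"` or `"cif"`.
#' @param id Structure identifier; defaults to the file base name.
#' @return An object of class `dh_structure`: a list with elements `id`,
#'   `source_format`, `atoms`, `ligands`, `missing`, `helix`, `sheet`.
#'   `atoms` has columns `chain`, `resno`, `icode`, `resname`, `atom`,
#'   `element`, `x`, `y`, `z`, `occupancy`, `b_factor`, `altloc`.
#' @examples
#' pdb <- system.file("extdata", "toy_dh.pdb", package = "dhprof")
#' s <- read_structure(pdb)
#' s$missing
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    dh_abort(paste0("coordinate file not found: ", path), "notfound")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      pdb = , ent = "pdb",
      cif = , mmcif = "cif",
      dh_abort(paste0("cannot infer coordinate format from extension '.", ext,
                      "'; pass format explicitly"), "format")
    )
  }
  parsed <- tryCatch(
    {
      txt <- utils::capture.output(
        obj <- if (format == "pdb") {
          suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE))
        } else {
          suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
        }
      )
      obj
    },
    error = function(e) {
      dh_abort(paste0("failed to parse ", format, " file '", path, "': ",
                      conditionMessage(e)), "parse")
    }
  )
  at <- tibble::as_tibble(parsed$atom)
  at <- tibble::tibble(
    record = at$type,
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    icode = dplyr::coalesce(as.character(at$insert), ""),
    resname = as.character(at$resid),
    atom = as.character(at$elety),
    element = dplyr::coalesce(as.character(at$elesy), ""),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    occupancy = dplyr::coalesce(as.numeric(at$o), 1),
    b_factor = dplyr::coalesce(as.numeric(at$b), 0),
    altloc = dplyr::coalesce(as.character(at$alt), "")
  )
  at <- dplyr::filter(at, !.data$resname %in% c("HOH", "WAT", "DOD"))

  # altloc collapse: highest occupancy, tie -> first altloc letter
  at <- at |>
    dplyr::arrange(.data$chain, .data$resno, .data$icode, .data$atom,
                   dplyr::desc(.data$occupancy), .data$altloc) |>
    dplyr::distinct(.data$record, .data$chain, .data$resno, .data$icode,
                    .data$atom, .keep_all = TRUE)

  atoms <- at |>
    dplyr::filter(.data$record == "ATOM") |>
    dplyr::select(-"record") |>
    dplyr::arrange(.data$chain, .data$resno, .data$icode)
  ligands <- at |>
    dplyr::filter(.data$record == "HETATM") |>
    dplyr::select(-"record") |>
    dplyr::arrange(.data$chain, .data$resno, .data$icode)

  missing <- if (format == "pdb") {
    parse_remark465(readLines(path, warn = FALSE))
  } else {
    empty_missing()
  }

  hel <- ss_records_tbl(parsed$helix)
  she <- ss_records_tbl(parsed$sheet)

  structure(
    list(
      id = id %||% tools::file_path_sans_ext(basename(path)),
      source_format = if (format == "pdb") "PDB" else "mmCIF",
      atoms = atoms,
      ligands = ligands,
      missing = missing,
      helix = hel,
      sheet = she
    ),
    class = "dh_structure"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_missing <- function() {
  tibble::tibble(chain = character(), resno = integer(),
                 icode = character(), resname = character())
}

ss_records_tbl <- function(rec) {
  if (is.null(rec) || length(rec$start) == 0L) {
    return(tibble::tibble(chain = character(), start = integer(), end = integer()))
  }
  tibble::tibble(
    chain = as.character(rec$chain),
    start = as.integer(rec$start),
    end = as.integer(rec$end)
  )
}

# REMARK 465 entry lines: "REMARK 465     GLY A   240" (optional model column,
# optional insertion code glued to the residue number)
parse_remark465 <- function(lines) {
  cand <- grep("^REMARK 465", lines, value = TRUE)
  out <- empty_missing()
  for (ln in cand) {
    body <- trimws(sub("^REMARK 465", "", ln))
    toks <- strsplit(body, "\\s+")[[1]]
    if (length(toks) == 4L && grepl("^[0-9]+$", toks[1])) toks <- toks[-1]
    if (length(toks) != 3L) next
    if (!grepl("^[A-Z0-9]{1,3}$", toks[1]) || nchar(toks[2]) != 1L) next
    m <- regmatches(toks[3], regexec("^(-?[0-9]+)([A-Za-z]?)$", toks[3]))[[1]]
    if (length(m) == 0L) next
    out <- dplyr::bind_rows(out, tibble::tibble(
      chain = toks[2], resno = as.integer(m[2]), icode = m[3], resname = toks[1]
    ))
  }
  dplyr::arrange(out, .data$chain, .data$resno, .data$icode)
}

#' @export
print.dh_structure <- function(x, ...) {
  nres <- nrow(dplyr::distinct(x$atoms, .data$chain, .data$resno, .data$icode))
  cat("<dh_structure> ", x$id, " [", x$source_format, "]\n", sep = "")
  cat("  chains: ", paste(unique(x$atoms$chain), collapse = ", "),
      " | modeled residues: ", nres,
      " | atoms: ", nrow(x$atoms),
      " | ligand atoms: ", nrow(x$ligands),
      " | declared missing: ", nrow(x$missing), "\n", sep = "")
  invisible(x)
}

modeled_residues <- function(structure, chain_id) {
  structure$atoms |>
    dplyr::filter(.data$chain == chain_id) |>
    dplyr::distinct(.data$chain, .data$resno, .data$icode, .data$resname)
}

check_chain <- function(structure, chain_id) {
  if (!chain_id %in% structure$atoms$chain) {
    dh_abort(paste0("chain '", chain_id, "' not found in structure '",
                    structure$id, "'"), "notfound")
  }
}

#' One-letter sequence of the modeled residues of a chain
#'
#' Returns the amino-acid sequence of the modeled residues (those with at
#' least one atom) in chain order, plus a positional map back to author
#' residue numbering.  Nonstandard residues become `'X'`; selenomethionine
#' (`MSE`) can optionally be aliased to `'M'`.
#'
#' @param structure A `dh_structure`.
#' @param chain_id Chain identifier.
#' @param mse_as_met Alias MSE to `'M'` instead of `'X'`.
#' @return A `dh_seqmap`: list with `seq` (single string) and `map`, a tibble
#'   with one row per sequence position (`pos`, `chain`, `resno`, `icode`,
#'   `resname`).
#' @export
chain_sequence <- function(structure, chain_id, mse_as_met = FALSE) {
  check_chain(structure, chain_id)
  res <- modeled_residues(structure, chain_id)
  if (nrow(res) == 0L) {
    dh_abort(paste0("chain '", chain_id, "' has no modeled residues"), "notfound")
  }
  letters1 <- aa_three_to_one(res$resname, mse_as_met = mse_as_met)
  structure(
    list(
      seq = paste(letters1, collapse = ""),
      map = tibble::tibble(
        pos = seq_len(nrow(res)),
        chain = res$chain, resno = res$resno,
        icode = res$icode, resname = res$resname
      )
    ),
    class = "dh_seqmap"
  )
}

#' @export
print.dh_seqmap <- function(x, ...) {
  cat("<dh_seqmap> ", nrow(x$map), " residues, chain ",
      x$map$chain[1], "\n", sep = "")
  cat(strtrim(x$seq, 60), if (nchar(x$seq) > 60) "...", "\n", sep = "")
  invisible(x)
}

#' Unmodeled (missing) segments of a chain
#'
#' Returns the union of declared-missing residues (PDB `REMARK 465`) and
#' segments inferred from gaps in author numbering between consecutive
#' modeled residues, as sorted non-overlapping runs.  Inference assumes
#' monotone author numbering; a non-monotone chain disables inference (with a
#' warning) and only declared residues are reported.
#'
#' @inheritParams chain_sequence
#' @return Tibble with columns `start`, `end`, `length` (author numbering,
#'   inclusive).  Empty when the chain is fully modeled.
#' @export
unmodeled_segments <- function(structure, chain_id) {
  check_chain(structure, chain_id)
  declared <- structure$missing |>
    dplyr::filter(.data$chain == chain_id) |>
    dplyr::pull("resno")
  modeled <- modeled_residues(structure, chain_id)$resno
  miss <- declared
  if (is.unsorted(modeled, strictly = FALSE)) {
    warn(paste0("chain '", chain_id, "' has non-monotone author numbering; ",
                "numbering-gap inference disabled"))
  } else if (length(modeled) >= 2L) {
    full <- seq(min(modeled), max(modeled))
    miss <- union(miss, setdiff(full, modeled))
  }
  miss <- setdiff(miss, modeled)
  runs_from_numbers(miss)
}

#' Write a structure to a minimal PDB file
#'
#' Emits `REMARK 465`, `HELIX`, `SHEET`, `ATOM`/`HETATM`, `TER` and `END`
#' records — the dialect needed to round-trip the package's own models and
#' synthetic fixtures, not a general-purpose PDB writer.
#'
#' @param structure A `dh_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  lines <- character()
  if (nrow(structure$missing) > 0L) {
    lines <- c(lines,
               "REMARK 465 MISSING RESIDUES",
               "REMARK 465   M RES C SSSEQI",
               sprintf("REMARK 465     %3s %1s %5d%1s",
                       structure$missing$resname, structure$missing$chain,
                       structure$missing$resno, structure$missing$icode))
  }
  if (nrow(structure$helix) > 0L) {
    h <- structure$helix
    lines <- c(lines, sprintf(
      "HELIX  %3d %3d %3s %1s %4d  %3s %1s %4d  1%30s%6d",
      seq_len(nrow(h)), seq_len(nrow(h)), "ALA", h$chain, h$start,
      "ALA", h$chain, h$end, "", h$end - h$start + 1L))
  }
  if (nrow(structure$sheet) > 0L) {
    s <- structure$sheet
    lines <- c(lines, sprintf(
      "SHEET  %3d   S%2d %3s %1s%4d  %3s %1s%4d  0",
      seq_len(nrow(s)), nrow(s), "ALA", s$chain, s$start,
      "ALA", s$chain, s$end))
  }
  serial <- 0L
  fmt_atom <- function(df, record) {
    vapply(seq_len(nrow(df)), function(i) {
      serial <<- serial + 1L
      nm <- df$atom[i]
      nm4 <- if (nchar(nm) >= 4L) substr(nm, 1, 4) else sprintf(" %-3s", nm)
      sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
              record, serial, nm4, substr(df$altloc[i], 1, 1),
              df$resname[i], df$chain[i], df$resno[i],
              substr(df$icode[i], 1, 1),
              df$x[i], df$y[i], df$z[i],
              df$occupancy[i], df$b_factor[i],
              df$element[i])
    }, character(1))
  }
  for (ch in unique(structure$atoms$chain)) {
    sub <- dplyr::filter(structure$atoms, .data$chain == ch)
    lines <- c(lines, fmt_atom(sub, "ATOM"), "TER")
  }
  if (nrow(structure$ligands) > 0L) {
    lines <- c(lines, fmt_atom(structure$ligands, "HETATM"))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}
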