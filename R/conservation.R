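#' Construct an MSA object from ids and gapped sequences
#'
#' @param ids Character vector of sequence identifiers.
#' @param seqs Character vector of equal-length gapped sequences.  `'.'` gap
#'   characters are normalized to `'-'`; letters are upper-cased.
#' @return A `dh_msa` tibble with columns `id`, `seq` and attribute
#'   `n_columns`.
#' @export
dh_msa <- function(ids, seqs) {
  if (length(ids) != length(seqs) || length(ids) == 0L) {
    dh_abort("ids and seqs must be non-empty vectors of equal length", "argument")
  }
  seqs <- toupper(gsub(".", "-", seqs, fixed = TRUE))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    dh_abort("ragged alignment: sequences differ in gapped length", "format")
  }
  tibble::new_tibble(
    tibble::tibble(id = as.character(ids), seq = seqs),
    class = "dh_msa", n_columns = widths[1]
  )
}

#' Read a multiple sequence alignment
#'
#' Reads gapped FASTA, Clustal or Stockholm alignments via
#' `Biostrings::readAAMultipleAlignment()`.
#'
#' @param path Alignment file path.
#' @param format `"auto"` (sniffed from the first line), `"fasta"`,
#'   `"clustal"` or `"stockholm"`.
#' @return A `dh_msa` tibble.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "clustal", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    dh_abort(paste0("alignment file not found: ", path), "notfound")
  }
  if (format == "auto") {
    first <- readLines(path, n = 5L, warn = FALSE)
    first <- first[nzchar(trimws(first))][1]
    format <- if (startsWith(first, ">")) {
      "fasta"
    } else if (grepl("^CLUSTAL", first, ignore.case = TRUE)) {
      "clustal"
    } else if (startsWith(first, "# STOCKHOLM")) {
      "stockholm"
    } else {
      dh_abort(paste0("cannot sniff alignment format of ", path), "format")
    }
  }
  aln <- tryCatch(
    Biostrings::readAAMultipleAlignment(path, format = format),
    error = function(e) {
      dh_abort(paste0("failed to parse ", format, " alignment '", path, "': ",
                      conditionMessage(e)), "parse")
    }
  )
  seqs <- as.character(Biostrings::unmasked(aln))
  dh_msa(names(seqs), unname(seqs))
}

msa_matrix <- function(msa) {
  stopifnot(inherits(msa, "dh_msa"))
  do.call(rbind, strsplit(msa$seq, ""))
}

#' Per-column occupancy of an MSA
#'
#' Occupancy of column j is the fraction of sequences with a non-gap
#' character there.
#'
#' @param msa A `dh_msa`.
#' @return Tibble with columns `column` (1-based) and `occupancy`.
#' @export
column_occupancy <- function(msa) {
  m <- msa_matrix(msa)
  tibble::tibble(
    column = seq_len(ncol(m)),
    occupancy = colMeans(m != "-")
  )
}

#' Drop low-occupancy MSA columns
#'
#' Retains, in order, every column whose occupancy is at least
#' `min_occupancy` (inclusive boundary: a column at exactly the threshold is
#' kept).  This is the standard refinement applied before per-column
#' conservation scoring so that sparse insert columns do not dominate.
#'
#' @param msa A `dh_msa`.
#' @param min_occupancy Occupancy threshold in `(0, 1]`, default 0.10.
#' @return A `dh_msa` whose attribute `columns` gives the retained original
#'   (1-based) column indices.
#' @export
refine_msa <- function(msa, min_occupancy = 0.10) {
  if (!is.numeric(min_occupancy) || min_occupancy <= 0 || min_occupancy > 1) {
    dh_abort("min_occupancy must be in (0, 1]", "argument")
  }
  occ <- column_occupancy(msa)
  keep <- occ$column[occ$occupancy >= min_occupancy]
  if (length(keep) == 0L) {
    dh_abort("no columns meet the occupancy threshold", "empty")
  }
  m <- msa_matrix(msa)[, keep, drop = FALSE]
  out <- dh_msa(msa$id, apply(m, 1, paste, collapse = ""))
  attr(out, "columns") <- keep
  out
}

#' Shannon entropy of one alignment column
#'
#' `H = -sum(p_i * log2(p_i))` over the 20 standard amino acids, with
#' frequencies taken from the non-gap standard-residue counts of the column.
#' Gaps and ambiguous letters (B, J, Z, X, U, O) are excluded from the
#' counts: they occupy the column but have no unambiguous frequency bin.
#'
#' @param column Character vector of single residues (one per sequence), or a
#'   single string.
#' @param base Logarithm base, 2 for bits (default) or `exp(1)` for nats.
#' @return Entropy (`0 <= H <= log(20)/log(base)`).
#' @examples
#' shannon_entropy(rep("A", 50))          # 0
#' shannon_entropy(c(rep("A", 10), rep("V", 10)))  # 1 bit
#' @export
shannon_entropy <- function(column, base = 2) {
  if (length(column) == 1L && nchar(column[1]) > 1L) {
    column <- strsplit(column, "")[[1]]
  }
  column <- toupper(column)
  counts <- table(factor(column[column %in% .aa_letters], levels = .aa_letters))
  n <- sum(counts)
  if (n == 0L) {
    if (all(column %in% c("-", "."))) {
      dh_abort("entropy undefined for an all-gap column", "undefined")
    }
    return(0)
  }
  p <- as.numeric(counts) / n
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

#' Occupancy-refined per-column entropy profile
#'
#' Applies [refine_msa()] then computes occupancy, Shannon entropy and the
#' 20-way residue frequency vector for every retained column, reported
#' against original column indices.
#'
#' @param msa A `dh_msa`.
#' @param min_occupancy Occupancy threshold (default 0.10, inclusive).
#' @param base Entropy logarithm base (default 2 = bits).
#' @return A `dh_entropy` tibble: `column` (original index), `occupancy`,
#'   `entropy`, `freqs` (list-column of named length-20 frequency vectors);
#'   attributes `min_occupancy` and `base`.
#' @export
entropy_profile <- function(msa, min_occupancy = 0.10, base = 2) {
  refined <- refine_msa(msa, min_occupancy)
  keep <- attr(refined, "columns")
  m <- msa_matrix(refined)
  out <- purrr::map(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    std <- col[col %in% .aa_letters]
    counts <- table(factor(std, levels = .aa_letters))
    p <- if (sum(counts) > 0) as.numeric(counts) / sum(counts) else
      rep(0, length(.aa_letters))
    tibble::tibble(
      column = keep[j],
      occupancy = mean(col != "-"),
      entropy = shannon_entropy(col, base = base),
      freqs = list(setNames(p, .aa_letters))
    )
  }) |>
    dplyr::bind_rows()
  tibble::new_tibble(out, class = "dh_entropy",
                     min_occupancy = min_occupancy, base = base)
}

#' @export
tidy.dh_entropy <- function(x, ...) {
  tibble::as_tibble(x)[, c("column", "occupancy", "entropy")]
}

#' @export
glance.dh_entropy <- function(x, ...) {
  tibble::tibble(
    n_columns = nrow(x), min_occupancy = attr(x, "min_occupancy"),
    base = attr(x, "base"), mean_entropy = mean(x$entropy),
    max_entropy = max(x$entropy)
  )
}

#' Map MSA columns onto a reference structure chain
#'
#' Aligns the ungapped reference row of the MSA against the modeled-residue
#' sequence of a chain and maps every MSA column where the reference row is
#' non-gap to an author residue number.  Leading/trailing mismatching
#' alignment runs are trimmed; internal substitutions stay mapped.  An
#' overall identity below `min_identity` aborts — it almost always means the
#' wrong chain or sequence was supplied.
#'
#' @param msa A `dh_msa` containing `reference_id`.
#' @param reference_id Sequence id of the reference row.
#' @param structure A `dh_structure`.
#' @param chain_id Chain identifier of the reference chain.
#' @param min_identity Minimum aligned-pairs identity (default 0.9).
#' @param ... Passed to [global_align()].
#' @return A `dh_colmap` tibble: `column` (1-based MSA column), `chain`,
#'   `resno`, `icode`; attribute `reference_id`.  Injective both ways.
#' @export
map_to_reference <- function(msa, reference_id, structure, chain_id,
                             min_identity = 0.9, ...) {
  row <- msa$seq[msa$id == reference_id]
  if (length(row) != 1L) {
    dh_abort(paste0("reference id '", reference_id, "' not found once in MSA"),
             "notfound")
  }
  ref_chars <- strsplit(row, "")[[1]]
  nongap_cols <- which(ref_chars != "-")
  ref_ungapped <- paste(ref_chars[nongap_cols], collapse = "")
  seqmap <- chain_sequence(structure, chain_id)
  aln <- global_align(ref_ungapped, seqmap$seq, ...)
  if (is.na(aln$identity) || aln$identity < min_identity) {
    dh_abort(sprintf(
      "reference row and chain sequence identity %.3f below %.2f: wrong chain or sequence?",
      aln$identity, min_identity), "reference_mismatch")
  }
  pairs <- aln$pairs
  # trim mismatching tails
  first <- match(TRUE, pairs$match)
  last <- nrow(pairs) + 1L - match(TRUE, rev(pairs$match))
  pairs <- pairs[seq(first, last), , drop = FALSE]
  pairs <- canonicalize_gaps(pairs, ref_ungapped, seqmap)
  out <- tibble::tibble(
    column = nongap_cols[pairs$index_a],
    chain = chain_id,
    resno = seqmap$map$resno[pairs$index_b],
    icode = seqmap$map$icode[pairs$index_b]
  )
  tibble::new_tibble(out, class = "dh_colmap", reference_id = reference_id)
}

# Alignment gaps bordered by coincidentally identical letters can be placed
# at several score-equivalent positions; the aligner picks one arbitrarily,
# which may disagree with the chain's author numbering (a residue just after
# a deletion ends up mapped across the gap).  Re-anchor short
# offset-inconsistent pair runs to the offset of a flanking run whenever the
# reassigned reference letters still match and injectivity is preserved.
canonicalize_gaps <- function(pairs, ref_ungapped, seqmap) {
  if (nrow(pairs) < 3L) return(pairs)
  ra <- strsplit(ref_ungapped, "")[[1]]
  cb <- strsplit(seqmap$seq, "")[[1]]
  resno_b <- seqmap$map$resno[pairs$index_b]
  aoff <- pairs$index_a - resno_b
  r <- rle(aoff)
  if (length(r$lengths) == 1L) return(pairs)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  orig <- pairs
  for (k in seq_along(r$lengths)) {
    if (r$lengths[k] > 2L) next
    targets <- c(if (k < length(r$lengths)) r$values[k + 1L],
                 if (k > 1L) r$values[k - 1L])
    idx <- starts[k]:ends[k]
    for (tgt in targets) {
      new_a <- resno_b[idx] + tgt
      ok <- all(new_a >= 1L & new_a <= length(ra)) &&
        all(ra[new_a] == cb[pairs$index_b[idx]]) &&
        !any(new_a %in% pairs$index_a[-idx])
      if (ok) {
        pairs$index_a[idx] <- new_a
        break
      }
    }
  }
  # keep only order-consistent reassignments
  if (is.unsorted(pairs$index_a, strictly = TRUE)) orig else pairs
}

#' Per-residue entropy track on the reference chain
#'
#' Joins an entropy profile with a column-to-residue map to yield one
#' entropy value per mapped residue.  When a structure is supplied, residues
#' that are unmodeled inherit the entropy of their interpolated column: if
#' flanking mapped residues bracket the gap with a column offset equal to the
#' residue-number offset (i.e. the reference MSA row is gapless across the
#' stretch), the intervening columns are assigned positionally; otherwise the
#' residues carry `NA` entropy.
#'
#' @param profile A `dh_entropy`.
#' @param colmap A `dh_colmap` from [map_to_reference()].
#' @param structure,chain_id Optional structure/chain whose unmodeled
#'   residues should be filled in.
#' @return Tibble `chain`, `resno`, `column`, `entropy`, `occupancy`,
#'   `modeled`.
#' @export
residue_entropy_track <- function(profile, colmap,
                                  structure = NULL, chain_id = NULL) {
  track <- colmap |>
    tibble::as_tibble() |>
    dplyr::inner_join(
      tibble::as_tibble(profile)[, c("column", "entropy", "occupancy")],
      by = "column"
    ) |>
    dplyr::mutate(modeled = TRUE) |>
    dplyr::select("chain", "resno", "column", "entropy", "occupancy", "modeled")
  if (is.null(structure)) {
    return(dplyr::arrange(track, .data$resno))
  }
  segs <- suppressWarnings(unmodeled_segments(structure, chain_id))
  extra <- purrr::pmap(segs, function(start, end, length) {
    lo <- track |> dplyr::filter(.data$resno < start) |> dplyr::slice_max(.data$resno, n = 1)
    hi <- track |> dplyr::filter(.data$resno > end) |> dplyr::slice_min(.data$resno, n = 1)
    resno <- seq(start, end)
    col <- rep(NA_integer_, length)
    if (nrow(lo) == 1L && nrow(hi) == 1L &&
        (hi$column - lo$column) == (hi$resno - lo$resno)) {
      col <- lo$column + (resno - lo$resno)
    }
    ent <- occ <- rep(NA_real_, length)
    known <- match(col, profile$column)
    ent[!is.na(known)] <- profile$entropy[known[!is.na(known)]]
    occ[!is.na(known)] <- profile$occupancy[known[!is.na(known)]]
    tibble::tibble(chain = chain_id, resno = as.integer(resno), column = col,
                   entropy = ent, occupancy = occ, modeled = FALSE)
  }) |>
    dplyr::bind_rows()
  dplyr::bind_rows(track, extra) |> dplyr::arrange(.data$resno)
}
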