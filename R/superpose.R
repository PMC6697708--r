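#' Least-squares rigid superposition of paired point sets (Kabsch)
#'
#' Computes the proper rotation `R` and translation `t` minimizing the RMSD
#' of `R %*% b + t` onto `a` over paired rows, by SVD of the cross-covariance
#' matrix with reflection correction (determinant forced to +1).
#'
#' @param coords_a,coords_b Numeric `N x 3` matrices (Å), paired row-for-row,
#'   `N >= 3`.
#' @return A `dh_superposition`: list with `rotation` (3×3, det +1),
#'   `translation` (length 3), `rmsd` (Å), `n_pairs`, `cycles` (single-row
#'   trace tibble), and `degenerate` (`TRUE` when the points are collinear or
#'   coincident, in which case the rotation is not uniquely determined).
#' @examples
#' a <- matrix(rnorm(30), ncol = 3)
#' fit <- kabsch(a, a)
#' fit$rmsd
#' @export
kabsch <- function(coords_a, coords_b) {
  coords_a <- as_coords(coords_a, "coords_a")
  coords_b <- as_coords(coords_b, "coords_b")
  if (nrow(coords_a) != nrow(coords_b)) {
    dh_abort("coordinate sets must be paired row-for-row", "argument")
  }
  n <- nrow(coords_a)
  if (n < 3L) {
    dh_abort("superposition needs at least 3 paired points", "insufficient")
  }
  ca <- colMeans(coords_a)
  cb <- colMeans(coords_b)
  a0 <- sweep(coords_a, 2, ca)
  b0 <- sweep(coords_b, 2, cb)
  h <- crossprod(b0, a0)           # 3x3 cross-covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- ca - as.vector(rot %*% cb)
  moved <- sweep(b0 %*% t(rot), 2, ca, "+")
  rmsd <- sqrt(mean(rowSums((coords_a - moved)^2)))
  degenerate <- sv$d[2] <= 1e-8 * max(sv$d[1], 1e-12)
  new_superposition(rot, trans, rmsd, n,
                    cycles = tibble::tibble(cycle = 1L, n_pairs = n,
                                            rmsd = rmsd, n_rejected = 0L),
                    degenerate = degenerate)
}

as_coords <- function(x, arg) {
  x <- as.matrix(x)
  if (ncol(x) != 3L || !is.numeric(x) || any(!is.finite(x))) {
    dh_abort(paste0(arg, " must be a finite numeric N x 3 matrix"), "argument")
  }
  x
}

new_superposition <- function(rotation, translation, rmsd, n_pairs, cycles,
                              degenerate = FALSE, pairs = NULL) {
  structure(
    list(rotation = rotation, translation = as.vector(translation),
         rmsd = rmsd, n_pairs = n_pairs, cycles = cycles,
         degenerate = degenerate, pairs = pairs),
    class = "dh_superposition"
  )
}

#' Apply a superposition transform to coordinates
#'
#' @param fit A `dh_superposition`.
#' @param coords `N x 3` matrix of coordinates in the mobile frame.
#' @return Transformed `N x 3` matrix, `R %*% x + t` per row.
#' @export
apply_transform <- function(fit, coords) {
  coords <- as_coords(coords, "coords")
  sweep(coords %*% t(fit$rotation), 2, fit$translation, "+")
}

#' @export
print.dh_superposition <- function(x, ...) {
  cat("<dh_superposition> rmsd ", sprintf("%.4f", x$rmsd), " A over ",
      x$n_pairs, " pairs (", nrow(x$cycles), " cycle",
      if (nrow(x$cycles) != 1L) "s", ")",
      if (isTRUE(x$degenerate)) " [degenerate]", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.dh_superposition <- function(x, ...) x$cycles

#' @export
glance.dh_superposition <- function(x, ...) {
  tibble::tibble(
    rmsd = x$rmsd, n_pairs = x$n_pairs, n_cycles = nrow(x$cycles),
    n_rejected = sum(x$cycles$n_rejected), degenerate = isTRUE(x$degenerate)
  )
}

#' Sequence-guided iterative C-alpha superposition
#'
#' Aligns the modeled-residue sequences of two chains ([global_align()]),
#' takes C-alpha pairs from non-gap alignment columns, and iterates Kabsch
#' fitting with batch outlier rejection: after each fit, every pair deviating
#' by more than `cutoff` is dropped and the fit repeated, until no pair is
#' rejected or `max_cycles` fits have run.  This is the usual protocol behind
#' "RMSD of x Å within N residues" figures in structure papers.
#'
#' @param structure_a,structure_b `dh_structure` objects.
#' @param chain_a,chain_b Chain identifiers.
#' @param cutoff Post-fit deviation cutoff in Å (default 2.0).
#' @param max_cycles Maximum number of fit cycles (default 5).
#' @param ... Alignment parameters passed to [global_align()].
#' @return A `dh_superposition` whose `cycles` tibble traces
#'   `(cycle, n_pairs, rmsd, n_rejected)` and whose `pairs` tibble lists every
#'   aligned C-alpha pair (`resno_a`, `resno_b`, `deviation` under the final
#'   transform, `retained`).
#' @export
iterative_superpose <- function(structure_a, chain_a, structure_b, chain_b,
                                cutoff = 2.0, max_cycles = 5L, ...) {
  sa <- chain_sequence(structure_a, chain_a)
  sb <- chain_sequence(structure_b, chain_b)
  aln <- global_align(sa, sb, ...)
  if (nrow(aln$pairs) < 3L) {
    dh_abort("fewer than 3 aligned residue pairs", "degenerate")
  }
  ca_a <- ca_coords(structure_a, chain_a)
  ca_b <- ca_coords(structure_b, chain_b)
  pos_a <- match(aln$pairs$index_a, ca_a$pos)
  pos_b <- match(aln$pairs$index_b, ca_b$pos)
  ok <- !is.na(pos_a) & !is.na(pos_b)
  xa <- as.matrix(ca_a[pos_a[ok], c("x", "y", "z")])
  xb <- as.matrix(ca_b[pos_b[ok], c("x", "y", "z")])
  resno_a <- ca_a$resno[pos_a[ok]]
  resno_b <- ca_b$resno[pos_b[ok]]
  n <- sum(ok)
  if (n < 3L) dh_abort("fewer than 3 aligned C-alpha pairs", "degenerate")

  retained <- rep(TRUE, n)
  trace <- list()
  fit <- NULL
  for (cyc in seq_len(max_cycles)) {
    if (sum(retained) < 3L) {
      dh_abort("fewer than 3 C-alpha pairs survive outlier rejection",
               "degenerate")
    }
    fit <- kabsch(xa[retained, , drop = FALSE], xb[retained, , drop = FALSE])
    dev <- sqrt(rowSums((xa - apply_transform(fit, xb))^2))
    reject <- retained & dev > cutoff
    trace[[cyc]] <- tibble::tibble(
      cycle = cyc, n_pairs = sum(retained), rmsd = fit$rmsd,
      n_rejected = sum(reject)
    )
    if (!any(reject) || cyc == max_cycles) break
    retained <- retained & !reject
  }
  dev <- sqrt(rowSums((xa - apply_transform(fit, xb))^2))
  new_superposition(
    fit$rotation, fit$translation,
    rmsd = fit$rmsd,
    n_pairs = sum(retained),
    cycles = dplyr::bind_rows(trace),
    degenerate = fit$degenerate,
    pairs = tibble::tibble(resno_a = resno_a, resno_b = resno_b,
                           deviation = dev, retained = retained)
  )
}

ca_coords <- function(structure, chain_id) {
  seqmap <- chain_sequence(structure, chain_id)
  cas <- structure$atoms |>
    dplyr::filter(.data$chain == chain_id, .data$atom == "CA") |>
    dplyr::distinct(.data$resno, .data$icode, .keep_all = TRUE)
  seqmap$map |>
    dplyr::inner_join(cas |> dplyr::select("resno", "icode", "x", "y", "z"),
                      by = c("resno", "icode"))
}
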