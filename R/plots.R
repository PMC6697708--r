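# autoplot methods: quick-look figures for the main result types

#' Plot an entropy profile
#'
#' Per-column Shannon entropy against (original) MSA column index.
#'
#' @param object A `dh_entropy` from [entropy_profile()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.dh_entropy <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$entropy)) +
    ggplot2::geom_col(width = 1, fill = "grey35") +
    ggplot2::labs(x = "MSA column", y = "Shannon entropy (bits)") +
    ggplot2::theme_minimal()
}

#' Plot a flexibility profile
#'
#' Per-residue B-factor z-score; unmodeled residues are marked as rug ticks
#' at the bottom (they carry no B value but signal maximal disorder).
#'
#' @param object A `dh_flexprofile` from [bfactor_profile()].
#' @param z_threshold Optional horizontal reference line.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.dh_flexprofile <- function(object, z_threshold = 1.0, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(dplyr::filter(df, .data$modeled),
                       ggplot2::aes(x = .data$resno, y = .data$z)) +
    ggplot2::geom_line(colour = "grey35") +
    ggplot2::geom_hline(yintercept = z_threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "Residue", y = "B-factor z-score") +
    ggplot2::theme_minimal()
  unmod <- dplyr::filter(df, !.data$modeled)
  if (nrow(unmod) > 0L) {
    p <- p + ggplot2::geom_rug(data = unmod, ggplot2::aes(x = .data$resno),
                               inherit.aes = FALSE, colour = "firebrick")
  }
  p
}

#' Plot a domain profile
#'
#' Stacked entropy and flexibility tracks with called variable regions
#' shaded — the package's one-figure summary of the conservation/flexibility
#' co-location analysis.
#'
#' @param object A `dh_domain_profile` from [profile_domain()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.dh_domain_profile <- function(object, ...) {
  flex <- tibble::as_tibble(object$flexibility)
  tracks <- dplyr::bind_rows(
    tibble::tibble(resno = flex$resno, value = flex$z,
                   track = "B-factor z-score"),
    if (!is.null(object$entropy_track)) {
      tibble::tibble(resno = object$entropy_track$resno,
                     value = object$entropy_track$entropy,
                     track = "Shannon entropy (bits)")
    }
  )
  p <- ggplot2::ggplot(tracks, ggplot2::aes(x = .data$resno, y = .data$value)) +
    ggplot2::geom_line(colour = "grey35", na.rm = TRUE) +
    ggplot2::facet_wrap(~track, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Residue", y = NULL,
                  title = paste0(object$structure_id, " chain ", object$chain)) +
    ggplot2::theme_minimal()
  if (nrow(object$regions) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = object$regions,
      ggplot2::aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "firebrick", alpha = 0.15
    )
  }
  p
}
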