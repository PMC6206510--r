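#' Per-landmark genotype displacement field
#'
#' Regresses each landmark coordinate on the dosage across subjects (simple
#' per-coordinate OLS) and returns, per landmark, the 3-vector of slopes —
#' the displacement per allele — and its magnitude. The field's squared
#' magnitudes are the "energy" used to quantify how localized an effect is.
#'
#' @param shapes `n x L x 3` array (typically adjusted, aligned shapes;
#'   cohorts may be pooled).
#' @param dosage Numeric n-vector.
#' @return Tibble: `landmark`, `bx`, `by`, `bz`, `magnitude`.
#' @export
effect_field <- function(shapes, dosage) {
  flat <- flatten_configs(shapes)
  d <- dosage - mean(dosage)
  ssd <- sum(d^2)
  assert_that(ssd > 0, "constant dosage")
  b <- crossprod(flat, d) / ssd          # 3L slopes
  L <- ncol(flat) / 3
  B <- matrix(b, L, 3, byrow = TRUE)
  tibble::tibble(landmark = seq_len(L), bx = B[, 1], by = B[, 2], bz = B[, 3],
                 magnitude = sqrt(rowSums(B^2)))
}

#' Fraction of a displacement field's energy inside a landmark set
#'
#' @param field Tibble from [effect_field()].
#' @param landmarks Integer vector (e.g. a module's landmarks).
#' @return Scalar in `[0, 1]`: sum of squared slopes inside / total.
#' @export
field_energy_concentration <- function(field, landmarks) {
  e <- field$bx^2 + field$by^2 + field$bz^2
  sum(e[landmarks]) / sum(e)
}

#' Plot a module tree on the template face
#'
#' Frontal (x–y) projection of the template landmarks colored by module
#' membership at one tree level.
#'
#' @param object A `module_tree`.
#' @param template A `template_face` supplying landmark coordinates.
#' @param level Tree level to display (default: deepest).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot module_tree
#' @export
autoplot.module_tree <- function(object, template, level = NULL, ...) {
  if (is.null(level)) level <- max(object$level)
  rows <- object[object$level == level, ]
  df <- dplyr::bind_rows(lapply(seq_len(nrow(rows)), function(i)
    tibble::tibble(module = factor(rows$module_id[i]),
                   landmark = rows$landmarks[[i]])))
  df$x <- template$coordinates[df$landmark, 1]
  df$y <- template$coordinates[df$landmark, 2]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$module)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Facial modules, level %d", level),
                  x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot meta-analysis p-values by module
#'
#' One point per SNP x module, -log10 meta p, faceted by discovery
#' rotation; the dashed line marks the study-wide threshold if present.
#'
#' @param object A `meta_result` tibble from [round_robin_meta()].
#' @param threshold Optional significance cutoff to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot meta_result
#' @export
autoplot.meta_result <- function(object, threshold = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$module_id,
                                        y = -log10(.data$p_meta),
                                        colour = .data$snp)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~rotation) +
    ggplot2::labs(x = "module", y = expression(-log[10](italic(p)[meta]))) +
    ggplot2::theme_minimal()
  if (!is.null(threshold))
    p <- p + ggplot2::geom_hline(yintercept = -log10(threshold), linetype = "dashed")
  p
}

#' Heat-map style plot of a displacement field on the face
#'
#' Frontal projection with point size/colour by displacement magnitude per
#' allele — the package's analogue of an effect heat map.
#'
#' @param field Tibble from [effect_field()].
#' @param template A `template_face`.
#' @return A ggplot object.
#' @export
plot_effect_field <- function(field, template) {
  df <- field
  df$x <- template$coordinates[df$landmark, 1]
  df$y <- template$coordinates[df$landmark, 2]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$magnitude,
                                   size = .data$magnitude)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c(name = "mm/allele") +
    ggplot2::scale_size_continuous(guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}
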