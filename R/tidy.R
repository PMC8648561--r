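# broom-style tidiers and ggplot2 autoplot methods for the tabular results.

#' Tidy an FSC curve into a tibble
#'
#' @param x an `fsc_curve`.
#' @param ... unused.
#' @return tibble with shell_radius, fsc, n_voxels, half_bit_threshold.
#' @export
tidy.fsc_curve <- function(x, ...) {
  tibble::tibble(shell_radius = x$shell_radii, fsc = x$fsc,
                 n_voxels = x$n_voxels_per_shell,
                 half_bit_threshold = x$half_bit_threshold)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
tidy.default <- function(x, ...) {
  stop("no tidy method for this object", call. = FALSE)
}

#' Tidy an SSIM comparison
#'
#' @param x an `ssim_comparison`.
#' @param ... unused.
#' @return the per-pair tibble.
#' @export
tidy.ssim_comparison <- function(x, ...) x$pairs

#' One-row summary of an SSIM comparison
#'
#' @param x an `ssim_comparison`.
#' @param ... unused.
#' @return tibble with the ANOVA F and p and the grand median SSIM.
#' @export
glance.ssim_comparison <- function(x, ...) {
  tibble::tibble(median_ssim = stats::median(x$pairs$ssim),
                 F = x$anova$F, p = x$anova$p)
}

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Tidy a morphometry report
#'
#' @param x a `morphometry_report`.
#' @param ... unused.
#' @return the per-VOI records tibble.
#' @export
tidy.morphometry_report <- function(x, ...) x$records

#' Per-measure test summary of a morphometry report
#'
#' @param x a `morphometry_report`.
#' @param ... unused.
#' @return the ANOVA tibble.
#' @export
glance.morphometry_report <- function(x, ...) x$anova

#' Tidy a biopsy estimate
#'
#' @param x a `biopsy_estimate`.
#' @param ... unused.
#' @return one-row tibble.
#' @export
tidy.biopsy_estimate <- function(x, ...) {
  tibble::tibble(count_in_biopsy = x$count_in_biopsy,
                 parenchyma_vol_biopsy = x$parenchyma_vol_biopsy,
                 parenchyma_vol_total = x$parenchyma_vol_total,
                 n_total = x$n_total, se = x$se)
}

#' Plot an FSC curve with its 1/2-bit threshold
#'
#' @param object an `fsc_curve`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.fsc_curve <- function(object, ...) {
  df <- tidy.fsc_curve(object)
  ggplot2::ggplot(df, ggplot2::aes(x = shell_radius)) +
    ggplot2::geom_line(ggplot2::aes(y = fsc), linewidth = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = half_bit_threshold),
                       linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "spatial frequency (cycles/voxel)",
                  y = "Fourier shell correlation",
                  title = "FSC with 1/2-bit threshold") +
    ggplot2::theme_minimal()
}

#' Plot per-group morphometry distributions
#'
#' @param object a `morphometry_report`.
#' @param measure which measure to plot.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.morphometry_report <- function(object,
                                        measure = "surface_area_to_volume",
                                        ...) {
  df <- object$records
  df$.measure <- df[[measure]]
  ggplot2::ggplot(df, ggplot2::aes(x = group, y = .measure)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = measure) +
    ggplot2::theme_minimal()
}

#' Plot a grey-level slice of a volume
#'
#' @param vol a [volume3d()].
#' @param slice z index (default: middle slice).
#' @return a ggplot raster of the slice.
#' @export
plot_slice <- function(vol, slice = NULL) {
  x <- physical_values(vol)
  if (is.null(slice)) slice <- ceiling(dim(x)[3] / 2)
  m <- x[, , slice]
  df <- expand.grid(x = seq_len(nrow(m)), y = seq_len(ncol(m)))
  df$value <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x, y, fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
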