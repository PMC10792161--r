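# ggplot2 visualisation of slabs, masks and cohort summaries.

slab_raster_df <- function(img) {
  tibble(
    row = rep(seq_len(nrow(img)) - 1L, times = ncol(img)),
    col = rep(seq_len(ncol(img)) - 1L, each = nrow(img)),
    intensity = as.vector(img)
  )
}

#' Plot an en-face slab
#'
#' Grayscale raster of the slab with an optional ROI outline.
#'
#' @param object An [en_face_slab()].
#' @param roi Optional [make_roi()] result to outline.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.en_face_slab <- function(object, roi = NULL, ...) {
  df <- slab_raster_df(object$image)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), name = "I") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s slab", object$slab_kind),
                  x = "col (px)", y = "row (px)") +
    ggplot2::theme_minimal()
  if (!is.null(roi)) {
    t <- seq(0, 2 * pi, length.out = 181)
    circ <- tibble(col = roi$center_px[2] + roi$radius_px * cos(t),
                   row = roi$center_px[1] + roi$radius_px * sin(t))
    p <- p + ggplot2::geom_path(data = circ,
                                ggplot2::aes(x = .data$col, y = .data$row),
                                inherit.aes = FALSE, color = "yellow")
  }
  p
}

#' Plot a binarization result over its source slab
#'
#' Overlays the foreground mask (and optionally the skeleton centerlines)
#' on the grayscale slab.
#'
#' @param slab An [en_face_slab()].
#' @param mask An `octa_binary_mask`.
#' @param skeleton Optional `octa_skeleton`.
#' @param roi Optional ROI outline.
#' @return A ggplot object.
#' @export
plot_binarization <- function(slab, mask, skeleton = NULL, roi = NULL) {
  p <- autoplot.en_face_slab(slab, roi = roi)
  fg <- which(mask$mask, arr.ind = TRUE)
  if (nrow(fg) > 0) {
    p <- p + ggplot2::geom_tile(
      data = tibble(row = fg[, 1] - 1L, col = fg[, 2] - 1L),
      ggplot2::aes(x = .data$col, y = .data$row),
      inherit.aes = FALSE, fill = "red", alpha = 0.35)
  }
  if (!is.null(skeleton)) {
    sk <- which(skeleton$mask, arr.ind = TRUE)
    if (nrow(sk) > 0) {
      p <- p + ggplot2::geom_tile(
        data = tibble(row = sk[, 1] - 1L, col = sk[, 2] - 1L),
        ggplot2::aes(x = .data$col, y = .data$row),
        inherit.aes = FALSE, fill = "cyan")
    }
  }
  p + ggplot2::labs(title = sprintf("%s binarization (%s)", slab$slab_kind,
                                    mask$provenance$method))
}

#' Plot a cohort summary
#'
#' Study vs fellow means with ±1 SD ranges, one facet per metric, annotated
#' with the paired-test p-value.
#'
#' @param object An `octa_cohort_summary` from [summarize_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.octa_cohort_summary <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble(label = object$label, eye = "study",
           mean = object$study_mean, sd = object$study_sd),
    tibble(label = object$label, eye = "fellow",
           mean = object$fellow_mean, sd = object$fellow_sd)
  )
  labs <- tibble(label = object$label,
                 txt = sprintf("p = %s", object$p_formatted))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$eye, y = .data$mean,
                                     color = .data$eye)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::geom_text(data = labs,
                       ggplot2::aes(x = 1.5, y = Inf, label = .data$txt),
                       inherit.aes = FALSE, vjust = 1.5, size = 3) +
    ggplot2::facet_wrap(~label, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean ± SD",
                  title = "Paired study-vs-fellow-eye comparison") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
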