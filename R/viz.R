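# Heat-map rendering of matrices, profiles and differential profiles.

#' Render a 2D-SIFt heat map
#'
#' Rows are the 7 feature types in canonical order (vdW at the bottom);
#' columns are residues x 9 interaction types with block separators and
#' residue labels (generic numbers when available). Gray intensity is
#' proportional to the cell value; `diff_red_blue` renders positive cells red
#' and negative cells blue (agonist-minus-antagonist style); a
#' `display_threshold` hides cells below the given value (profiles are
#' typically drawn with the interactions found in more than 30% of the
#' complexes).
#'
#' @param x a `sift2d_matrix`, `sift2d_profile` or `sift2d_diff`.
#' @param path output image file (.png, .pdf or .svg).
#' @param color_mode "grayscale_counts" or "diff_red_blue" (the default
#'   follows the object class).
#' @param display_threshold minimum absolute cell value displayed.
#' @param width,height device size in inches.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(x, path, color_mode = NULL, display_threshold = 0,
                           width = NULL, height = 3.2) {
  if (is.null(color_mode)) {
    color_mode <- if (inherits(x, "sift2d_diff")) "diff_red_blue"
                  else "grayscale_counts"
  }
  color_mode <- match.arg(color_mode, c("grayscale_counts", "diff_red_blue"))
  labels <- block_labels(x)
  nblk <- length(x$blocks)
  df <- do.call(rbind, lapply(seq_len(nblk), function(i) {
    b <- x$blocks[[i]]
    data.frame(block = i,
               feature = factor(rep(FEATURE_TYPES, 9L),
                                levels = rev(FEATURE_TYPES)),
               interaction = rep(INTERACTION_TYPES, each = 7L),
               col = (i - 1L) * 9L + rep(seq_len(9L), each = 7L),
               value = as.numeric(b))
  }))
  df$value[abs(df$value) < display_threshold] <- 0
  if (nrow(df) == 0L || all(df$value == 0)) {
    warning("rendering an all-zero matrix: the heat map is empty",
            call. = FALSE)
  }
  if (is.null(width)) width <- max(3, 0.6 + 0.28 * 9 * nblk)
  vmax <- max(abs(df$value), 1e-9)
  g <- ggplot2::ggplot(df, ggplot2::aes(x = col, y = feature)) +
    ggplot2::geom_tile(ggplot2::aes(fill = value), color = "grey85",
                       linewidth = 0.1)
  g <- if (color_mode == "grayscale_counts") {
    g + ggplot2::scale_fill_gradient(low = "white", high = "black",
                                     limits = c(0, vmax), name = "count")
  } else {
    g + ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                      high = "#b2182b",
                                      limits = c(-vmax, vmax), name = "a - b")
  }
  g <- g +
    ggplot2::geom_vline(xintercept = 9 * seq_len(nblk) + 0.5,
                        linewidth = 0.5, color = "grey30") +
    ggplot2::scale_x_continuous(
      breaks = 9 * (seq_len(nblk) - 1L) + 5,
      labels = labels,
      sec.axis = ggplot2::dup_axis(breaks = seq_len(9 * nblk),
                                   labels = rep(INTERACTION_TYPES, nblk))) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = if (!is.null(x$complex_id)) x$complex_id) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x.top = ggplot2::element_text(size = 4),
                   panel.grid = ggplot2::element_blank())
  ggplot2::ggsave(path, g, width = min(width, 45), height = height,
                  dpi = 150, limitsize = FALSE)
  invisible(path)
}

utils::globalVariables(c("col", "feature", "value"))
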