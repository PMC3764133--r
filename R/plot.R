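#' Lower-triangular r-squared heatmap
#'
#' SNPs in position order on both axes, colour scale fixed to [0, 1], only
#' the lower triangle drawn.
#'
#' @param object An [ld_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ld_matrix
#' @export
autoplot.ld_matrix <- function(object, ...) {
  ids <- object$variant_ids
  long <- tidy(object)
  long <- dplyr::mutate(long,
    snp1 = factor(.data$snp1, levels = ids),
    snp2 = factor(.data$snp2, levels = ids)
  )
  # tidy() returns the upper triangle (i < j); plot it as a lower triangle
  # with snp2 on x and snp1 on y.
  ggplot2::ggplot(long, ggplot2::aes(x = .data$snp2, y = .data$snp1,
                                     fill = .data$r2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "red",
                                 limits = c(0, 1), name = expression(r^2)) +
    ggplot2::scale_y_discrete(limits = rev(ids[-length(ids)])) +
    ggplot2::scale_x_discrete(limits = ids[-1]) +
    ggplot2::labs(title = sprintf("%s pairwise LD (%s)", object$population,
                                  object$method),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Save an r-squared heatmap to an image file
#'
#' @param ld An [ld_matrix()].
#' @param out_path Output image path (extension selects the device).
#' @param width,height,dpi Passed to [ggplot2::ggsave()].
#' @return The path, invisibly.
#' @export
plot_heatmap <- function(ld, out_path, width = 6, height = 5, dpi = 150) {
  p <- autoplot(ld)
  ggplot2::ggsave(out_path, p, width = width, height = height, dpi = dpi)
  invisible(out_path)
}

#' Plot LD profiles around a focal SNP
#'
#' One r-squared-versus-position series per population with a vertical
#' marker at the focal SNP position. Supply either a single [ld_profile()]
#' tibble or several row-bound together; all rows must share one focal SNP.
#'
#' @param profiles An `ld_profile` tibble (rows from one or more
#'   populations).
#' @param out_path Optional image path; when given the plot is saved there.
#' @return A ggplot object (invisibly when `out_path` is given).
#' @export
plot_ld_profile <- function(profiles, out_path = NULL) {
  focal <- unique(profiles$focal_id)
  if (length(focal) != 1L) {
    abort("profiles mix different focal SNPs; plot them separately")
  }
  focal_pos <- unique(profiles$pos[profiles$id == focal])
  p <- ggplot2::ggplot(profiles,
                       ggplot2::aes(x = .data$pos / 1e6, y = .data$r2,
                                    colour = .data$population)) +
    ggplot2::geom_vline(xintercept = focal_pos / 1e6, linetype = "dashed") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Position (Mb)", y = expression(r^2),
                  title = sprintf("LD around %s", focal),
                  colour = "Population") +
    ggplot2::theme_minimal()
  if (!is.null(out_path)) {
    ggplot2::ggsave(out_path, p, width = 7, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}

#' @rdname plot_ld_profile
#' @param object An `ld_profile` tibble.
#' @param ... Unused.
#' @method autoplot ld_profile
#' @export
autoplot.ld_profile <- function(object, ...) plot_ld_profile(object)
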