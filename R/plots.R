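## ggplot2 displays for the package's result types.

#' Plot a nearest-summit distance histogram
#'
#' Bars per distance bin with the proximal threshold marked; the classic
#' display in which co-binding appears as a sharp leftmost peak.
#'
#' @param object A `cobind_histogram` from [distance_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cobind_histogram
#' @export
autoplot.cobind_histogram <- function(object, ...) {
  thr <- attr(object, "proximal_threshold")
  lbl <- paste(attr(object, "query_label") %||% "query", "vs",
               attr(object, "ref_label") %||% "reference")
  ggplot2::ggplot(as_tibble(object)) +
    ggplot2::geom_col(
      ggplot2::aes(x = (.data$bin_left + .data$bin_right) / 2,
                   y = .data$count),
      width = object$bin_right[1] - object$bin_left[1], fill = "grey35"
    ) +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "distance to nearest reference summit (bp)",
                  y = "query peaks", title = lbl,
                  subtitle = paste0("proximal threshold ", thr, " bp")) +
    ggplot2::theme_minimal()
}

#' @method autoplot cobind
#' @export
autoplot.cobind <- function(object, ...) {
  autoplot(object$histogram, ...)
}

#' Plot a TSS-anchored metagene fold-change profile
#'
#' @param object A `metagene_profile` from [fold_change_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metagene_profile
#' @export
autoplot.metagene_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$position, y = .data$fold_change)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "position relative to TSS (bp)",
      y = "fold change over upstream baseline",
      subtitle = paste0("n = ", attr(object, "n_sites"), " sites")
    ) +
    ggplot2::theme_minimal()
}
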