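# broom-style accessors and plotting for pipeline results.

#' @export
print.vdj_run <- function(x, ...) {
  n <- nrow(x$annotations)
  cat("<vdj_run> ", n, " reads annotated (", x$n_too_short,
      " below the length prefilter)\n", sep = "")
  if (n > 0) {
    cat(sprintf("  non-regular fraction: %.1f%%\n",
                100 * x$summary$non_regular_fraction))
    cls <- x$summary$classes
    cls <- cls[cls$n > 0, ]
    cat("  classes:",
        paste(sprintf("%s=%d", cls$class, cls$n), collapse = " "), "\n")
  }
  invisible(x)
}

#' Tidy per-read annotations of a pipeline run
#'
#' @param x A `vdj_run` object.
#' @param ... Unused.
#' @return The annotation tibble, one row per processed read.
#' @export
tidy.vdj_run <- function(x, ...) {
  x$annotations
}

#' One-row summary of a pipeline run
#'
#' @param x A `vdj_run` object.
#' @param ... Unused.
#' @return A one-row tibble: read counts, regular/non-regular fractions, and
#'   CDR3 yield.
#' @export
glance.vdj_run <- function(x, ...) {
  a <- x$annotations
  tibble(
    n_reads = nrow(a),
    n_too_short = x$n_too_short,
    regular_fraction = mean(a$class == "REGULAR"),
    non_regular_fraction = x$summary$non_regular_fraction,
    n_cdr3 = if (is.null(x$cdr3)) 0L else nrow(x$cdr3),
    multi_v_fraction = mean(grepl(",", a$v_calls))
  )
}

#' Plot the regularity-class composition of a run
#'
#' @param object A `vdj_run` object.
#' @param ... Unused.
#' @return A ggplot bar chart of read counts per regularity class.
#' @export
autoplot.vdj_run <- function(object, ...) {
  cls <- object$summary$classes
  cls$class <- factor(cls$class, levels = REGULARITY_CLASSES)
  ggplot2::ggplot(cls, ggplot2::aes(x = .data$class, y = .data$n,
                                    fill = .data$class == "REGULAR")) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8",
                                          `FALSE` = "#bdbdbd")) +
    ggplot2::labs(x = NULL, y = "reads",
                  title = "Recombination classes",
                  subtitle = sprintf("non-regular: %.1f%%",
                                     100 * object$summary$non_regular_fraction)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
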