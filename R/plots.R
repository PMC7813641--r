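# ggplot2 helpers for the main result types.

#' Plot a GC profile
#' @param object A [gc_profile()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gc_profile
#' @export
autoplot.gc_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$start, y = .data$gc)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_hline(yintercept = mean(object$gc, na.rm = TRUE),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::labs(
      x = "position (bp)", y = "GC fraction",
      title = paste0("GC profile: ", attr(object, "genome_id") %||% ""),
      subtitle = sprintf("window %d bp, step %d bp",
                         attr(object, "window"), attr(object, "step"))
    ) +
    ggplot2::ylim(0, 1)
}

#' @rdname autoplot.gc_profile
#' @param profile A [gc_profile()] tibble.
#' @export
plot_gc_profile <- function(profile, ...) autoplot.gc_profile(profile, ...)

#' Plot a dotplot point set
#' @param points A [dotplot()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_dotplot <- function(points, ...) {
  ggplot2::ggplot(points, ggplot2::aes(x = .data$i, y = .data$j)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "sequence A (bp)", y = "sequence B (bp)")
}

#' Plot SIR family counts per genome
#' @param object A [build_sir_tables()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sir_table
#' @export
autoplot.sir_table <- function(object, ...) {
  ggplot2::ggplot(object$counts,
                  ggplot2::aes(x = .data$hexamer, y = .data$n,
                               fill = .data$genome_id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "stem hexamer family", y = "count", fill = "genome")
}

#' @rdname autoplot.sir_table
#' @param sir_table A [build_sir_tables()] result.
#' @export
plot_sir_counts <- function(sir_table, ...) autoplot.sir_table(sir_table, ...)
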