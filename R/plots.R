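# ggplot2 views of the main result types.

#' Plot per-library size distributions of unique signatures
#'
#' @param sizedist Tibble from [size_distribution()].
#' @param percent Plot percentages instead of counts.
#' @return A ggplot.
#' @export
plot_size_distribution <- function(sizedist, percent = FALSE) {
  y <- if (percent) "pct" else "n_signatures"
  ggplot2::ggplot(sizedist,
                  ggplot2::aes(x = factor(.data$length),
                               y = .data[[y]],
                               fill = factor(.data$length))) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$library)) +
    ggplot2::labs(x = "signature length (nt)",
                  y = if (percent) "% of unique signatures"
                      else "unique signatures") +
    ggplot2::theme_minimal()
}

#' Plot a siRNA cluster as per-strand alignment positions
#'
#' Each distinct signature is a point at its alignment start, above the axis
#' for plus-strand and below for minus-strand placements, mirroring the
#' conventional two-strand cluster view.
#'
#' @param cluster One cluster row from [cluster_alignments()].
#' @return A ggplot.
#' @export
plot_cluster <- function(cluster) {
  aln <- cluster$alignments[[1]] %>%
    mutate(y = if_else(.data$strand == "+", 1, -1))
  ggplot2::ggplot(aln, ggplot2::aes(x = .data$start, y = .data$y,
                                    colour = .data$strand)) +
    ggplot2::geom_point(shape = 18, size = 3) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`+` = "#c0392b", `-` = "#2980b9")) +
    ggplot2::labs(x = sprintf("%s position", cluster$chrom), y = NULL,
                  title = sprintf("%s: %d signatures over %d bases",
                                  cluster$cluster_id, cluster$n_signatures,
                                  cluster$footprint)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot TE family size-class profiles
#'
#' @param profiles Tibble from [family_size_profiles()].
#' @param what `"unique"` (distinct signatures) or `"reads"`.
#' @return A ggplot.
#' @export
plot_family_profiles <- function(profiles, what = c("unique", "reads")) {
  what <- match.arg(what)
  y <- if (what == "unique") "n_unique" else "n_reads"
  ggplot2::ggplot(filter(profiles, .data$family != "all"),
                  ggplot2::aes(x = factor(.data$length), y = .data[[y]])) +
    ggplot2::geom_col(fill = "#27ae60") +
    ggplot2::facet_wrap(ggplot2::vars(.data$family), scales = "free_y") +
    ggplot2::labs(x = "length (nt)",
                  y = if (what == "unique") "distinct signatures"
                      else "summed reads") +
    ggplot2::theme_minimal()
}

#' @describeIn phase_register Register histogram of a phasing result.
#' @param object A `phasing_result`.
#' @method autoplot phasing_result
#' @export
autoplot.phasing_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$register, y = .data$n_positions)) +
    ggplot2::geom_col(fill = "#8e44ad") +
    ggplot2::labs(x = sprintf("register (mod %d)", object$period),
                  y = "distinct 5' positions",
                  subtitle = if (!object$insufficient)
                    sprintf("score %.2f, p = %.3g", object$score,
                            object$p_value) else "insufficient positions") +
    ggplot2::theme_minimal()
}
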