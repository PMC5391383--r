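# ggplot2 displays for the main result types. Colours for secondary
# structure follow the usual convention for these evolution plots: coil
# white, beta-strand purple, beta-bridge black, turn grey, 3-10 helix
# yellow, alpha-helix blue.

ss_fill_scale <- function() {
  ggplot2::scale_fill_manual(
    values = c(
      H = "#2166AC", G = "#FFD700", E = "#762A83",
      B = "#000000", T = "#BDBDBD", C = "#FFFFFF"
    ),
    breaks = c("H", "G", "E", "B", "T", "C"),
    labels = c(
      "alpha-helix", "3-10 helix", "beta-strand",
      "beta-bridge", "turn", "coil/other"
    ),
    drop = FALSE, name = NULL
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Secondary-structure evolution plot
#'
#' Time (frames) against residue, coloured by secondary-structure class --
#' the per-frame evolution view of an ensemble.
#'
#' @param object An `ss_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ss_matrix
#' @export
autoplot.ss_matrix <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = time_ps / 1000, y = res_seq, fill = code)) +
    ggplot2::geom_raster() +
    ss_fill_scale() +
    ggplot2::labs(x = "time (ns)", y = "residue") +
    ggplot2::theme_minimal()
}

#' Per-residue occupancy profile plot
#'
#' Stacked per-residue fractions of simulation time spent in each
#' secondary-structure class.
#'
#' @param occ An occupancy tibble from [occupancy()].
#' @return A ggplot object.
#' @export
plot_occupancy <- function(occ) {
  occ$code <- factor(occ$code, levels = c("H", "G", "E", "B", "T", "C"))
  ggplot2::ggplot(occ, ggplot2::aes(x = res_seq, y = fraction, fill = code)) +
    ggplot2::geom_col(colour = "grey40", linewidth = 0.1) +
    ss_fill_scale() +
    ggplot2::labs(x = "residue", y = "fraction of frames") +
    ggplot2::theme_minimal()
}

#' Cluster population plot
#'
#' @param object A `tail_clustering`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tail_clustering
#' @export
autoplot.tail_clustering <- function(object, ...) {
  d <- tibble::tibble(
    cluster = factor(seq_along(object$sizes)),
    n = object$sizes
  )
  ggplot2::ggplot(d, ggplot2::aes(x = cluster, y = n)) +
    ggplot2::geom_col(fill = "#2166AC") +
    ggplot2::labs(x = "cluster (by population)", y = "frames") +
    ggplot2::theme_minimal()
}

#' Reach distribution comparison plot
#'
#' Box-and-whisker comparison of tail reach distributions (boxes at the
#' quartiles, the convention used for tail-length distributions).
#'
#' @param ... Named reach series tibbles (from [reach_series()]).
#' @param whiskers Whisker convention, `"tukey"` or `"minmax"`.
#' @return A ggplot object.
#' @export
plot_reach_compare <- function(..., whiskers = c("tukey", "minmax")) {
  whiskers <- match.arg(whiskers)
  series <- list(...)
  if (is.null(names(series)) || any(names(series) == "")) {
    names(series) <- paste0("series_", seq_along(series))
  }
  d <- dplyr::bind_rows(
    lapply(series, function(s) tibble::tibble(reach = s$reach)),
    .id = "isoform"
  )
  coef <- if (whiskers == "tukey") 1.5 else Inf
  ggplot2::ggplot(d, ggplot2::aes(x = isoform, y = reach)) +
    ggplot2::geom_boxplot(coef = coef, fill = "grey85") +
    ggplot2::labs(x = NULL, y = "maximum tail reach (Å)") +
    ggplot2::theme_minimal()
}

#' Site-reachability matrix plot
#'
#' Anchors against sites, tiles coloured by relation and marked when the
#' site lies inside the anchor's reach shell.
#'
#' @param classified Tibble from [classify_reachable_sites()].
#' @return A ggplot object.
#' @export
plot_reachability <- function(classified) {
  ggplot2::ggplot(
    classified,
    ggplot2::aes(x = site_id, y = anchor_id, fill = relation, alpha = reachable)
  ) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.2)) +
    ggplot2::labs(x = "site", y = "anchor") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
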