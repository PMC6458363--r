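#' Plot an NMDS ordination
#'
#' @param object An `rz_nmds` fit.
#' @param meta Optional metadata tibble joined on `sample_id`.
#' @param colour Metadata column mapped to point colour (default
#'   `"plant_state"` when present).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.rz_nmds <- function(object, meta = NULL, colour = "plant_state",
                             ...) {
  pts <- object$points
  if (!is.null(meta)) pts <- left_join(pts, meta, by = "sample_id")
  p <- ggplot2::ggplot(pts, ggplot2::aes(.data$NMDS1, .data$NMDS2))
  if (!is.null(meta) && colour %in% names(pts)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(caption = sprintf("stress = %.3f", object$stress)) +
    ggplot2::theme_minimal()
}

#' Plot a Mantel correlogram
#'
#' Filled points mark classes with progressively corrected p < 0.05.
#'
#' @param object An `rz_mantel` fit.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.rz_mantel <- function(object, ...) {
  tb <- mutate(object$table, significant = .data$p_corr < 0.05)
  ggplot2::ggplot(tb, ggplot2::aes(.data$d_center, .data$r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(fill = .data$significant),
                        shape = 21, size = 2.5) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black",
                                          `FALSE` = "white")) +
    ggplot2::labs(x = "distance class centre (m)", y = "Mantel r") +
    ggplot2::theme_minimal()
}

#' Plot a co-abundance network
#'
#' Fruchterman-Reingold layout; edge colour encodes association sign.
#'
#' @param object A `coabundance_network`.
#' @param sign `"positive"`, `"negative"` or `"both"` (default).
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.coabundance_network <- function(object,
                                         sign = c("both", "positive",
                                                  "negative"),
                                         seed = 1, ...) {
  sign <- match.arg(sign)
  e <- object$edges
  if (sign != "both") e <- filter(e, .data$sign == !!sign)
  g <- igraph::graph_from_data_frame(
    e, directed = FALSE, vertices = data.frame(name = object$nodes))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(otu_id = object$nodes, x = xy[, 1], y = xy[, 2])
  seg <- left_join(e, rename(nodes, xa = "x", ya = "y"),
                   by = c(otu_a = "otu_id"))
  seg <- left_join(seg, rename(nodes, xb = "x", yb = "y"),
                   by = c(otu_b = "otu_id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, colour = .data$sign),
      alpha = 0.7) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(.data$x, .data$y), size = 1.5) +
    ggplot2::scale_colour_manual(values = c(positive = "#2166ac",
                                            negative = "#b2182b")) +
    ggplot2::theme_void()
}

#' Plot preference scores by state
#'
#' Scores for every (OTU, state) pair, with the screening threshold drawn;
#' degenerate pairs are omitted.
#'
#' @param object A `preference_tbl`.
#' @param z_min Threshold line (default 3).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.preference_tbl <- function(object, z_min = 3, ...) {
  tb <- filter(as_tibble(object), !.data$degenerate)
  ggplot2::ggplot(tb, ggplot2::aes(.data$state, .data$preference)) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = z_min, linetype = 2,
                        colour = "#b2182b") +
    ggplot2::labs(x = NULL, y = "preference (z)") +
    ggplot2::theme_minimal()
}

#' Plot rarefaction or accumulation curves
#'
#' @param curves Output of [rarefaction_curve()] or
#'   [accumulation_curve()].
#' @return A ggplot.
#' @export
plot_rarefaction <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(.data$depth, .data$richness,
                                       group = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "reads subsampled", y = "expected OTU richness") +
    ggplot2::theme_minimal()
}

#' @rdname plot_rarefaction
#' @export
plot_accumulation <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(.data$n_samples, .data$richness)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$richness - .data$sd,
                                      ymax = .data$richness + .data$sd),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "samples", y = "cumulative OTUs") +
    ggplot2::theme_minimal()
}
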