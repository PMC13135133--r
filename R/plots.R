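#' Plot the signed association network
#'
#' Force-directed layout of the regional network with edges coloured by
#' association sign (negative = red, positive = blue, both = green) and
#' node size scaled by degree.
#'
#' @param net A `pin_network`.
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_network <- function(net, seed = 1) {
  stopifnot(inherits(net, "pin_network"))
  set.seed(seed)
  xy <- igraph::layout_with_fr(net$graph)
  nodes <- net$nodes %>%
    mutate(x = xy[, 1], y = xy[, 2])
  edges <- net$edges %>%
    left_join(nodes %>% select("species_id", xi = "x", yi = "y"),
      by = c(species_i = "species_id")) %>%
    left_join(nodes %>% select("species_id", xj = "x", yj = "y"),
      by = c(species_j = "species_id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xi, y = .data$yi, xend = .data$xj,
        yend = .data$yj, colour = .data$sign),
      alpha = 0.6
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$degree)
    ) +
    ggplot2::scale_colour_manual(values = c(
      negative = "#c0392b", positive = "#2980b9", both = "#27ae60")) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "association", size = "degree")
}

#' Biplot of a trait PCA
#'
#' Species scores on the first two components with trait loading arrows,
#' optionally coloured by network group.
#'
#' @param object A `pin_pca`.
#' @param groups Optional tibble `species_id`, `group` (or `role`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pin_pca <- function(object, groups = NULL, ...) {
  sc <- object$scores
  if (!is.null(groups)) {
    grp_col <- intersect(c("group", "role", "block"), names(groups))[1]
    sc <- sc %>% left_join(
      groups %>% select("species_id", group = all_of(grp_col)),
      by = "species_id")
  } else {
    sc$group <- "species"
  }
  mult <- max(abs(c(sc$PC1, sc$PC2))) * 0.8
  ld <- object$loadings
  vf <- object$variance$variance_fraction
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.7) +
    ggplot2::geom_segment(
      data = ld,
      ggplot2::aes(x = 0, y = 0, xend = .data$PC1 * mult,
        yend = .data$PC2 * mult),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      inherit.aes = FALSE
    ) +
    ggplot2::geom_text(
      data = ld,
      ggplot2::aes(x = .data$PC1 * mult * 1.08,
        y = .data$PC2 * mult * 1.08, label = .data$trait),
      inherit.aes = FALSE, size = 3
    ) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * vf[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * vf[2])
    ) +
    ggplot2::theme_minimal()
}

#' Distinctiveness-scarcity biplot
#'
#' Per-species mean functional distinctiveness against mean scarcity,
#' optionally coloured by network group.
#'
#' @param rarity A `pin_rarity`.
#' @param groups Optional tibble `species_id`, `group` (or `role`).
#' @return A ggplot object.
#' @export
plot_rarity <- function(rarity, groups = NULL) {
  stopifnot(inherits(rarity, "pin_rarity"))
  dat <- rarity$per_species
  if (!is.null(groups)) {
    grp_col <- intersect(c("group", "role", "block"), names(groups))[1]
    dat <- dat %>% left_join(
      groups %>% select("species_id", group = all_of(grp_col)),
      by = "species_id")
  } else {
    dat$group <- "species"
  }
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$mean_scarcity, y = .data$mean_distinctiveness,
    colour = .data$group
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "mean scarcity", y = "mean distinctiveness") +
    ggplot2::theme_minimal()
}
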