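#' Build the signed regional association network
#'
#' Nodes are the species involved in at least one significant regional
#' association; edges are the significant pairs, signed `positive`,
#' `negative`, or `both` (a pair significant in both tails keeps a single
#' edge flagged `both`). Connectance is reported against two denominators:
#' all co-occurring pairs (the potential associations of the whole survey),
#' and the co-occurring pairs among associated species only — the printed
#' value depends strongly on which is meant, so both are kept.
#'
#' @param associations Calls from [screen_associations()].
#' @param pairs Co-occurring pairs from [cooccurring_pairs()].
#' @return A `pin_network`: list with `graph` (igraph, `sign` edge
#'   attribute), `nodes` (tibble with per-species degree), `edges` (tibble)
#'   and `metrics` (connectance variants, global clustering coefficient,
#'   counts).
#' @export
build_network <- function(associations, pairs) {
  edges <- associations %>%
    filter(.data$sign != "none") %>%
    select("species_i", "species_j", "sign")
  nodes <- sort(unique(c(edges$species_i, edges$species_j)))
  g <- igraph::graph_from_data_frame(
    edges %>% rename(from = "species_i", to = "species_j"),
    directed = FALSE,
    vertices = if (length(nodes)) data.frame(name = nodes) else NULL
  )
  n_cooc <- nrow(pairs)
  cooc_assoc <- pairs %>%
    filter(.data$species_i %in% nodes & .data$species_j %in% nodes)
  deg <- if (length(nodes)) igraph::degree(g) else numeric(0)
  clustering <- if (nrow(edges) > 0) {
    tr <- igraph::transitivity(g, type = "global")
    if (is.nan(tr)) 0 else tr
  } else {
    0
  }
  metrics <- list(
    n_nodes = length(nodes),
    n_edges = nrow(edges),
    n_positive = sum(edges$sign == "positive"),
    n_negative = sum(edges$sign == "negative"),
    n_both = sum(edges$sign == "both"),
    connectance_cooccurring = if (n_cooc > 0) nrow(edges) / n_cooc else 0,
    connectance_associated = if (nrow(cooc_assoc) > 0) {
      nrow(edges) / nrow(cooc_assoc)
    } else {
      0
    },
    clustering = clustering
  )
  structure(
    list(
      graph = g,
      nodes = tibble(species_id = nodes, degree = as.numeric(deg[nodes])),
      edges = edges,
      metrics = metrics
    ),
    class = "pin_network"
  )
}

#' @export
print.pin_network <- function(x, ...) {
  m <- x$metrics
  cat("<pin_network> ", m$n_nodes, " species, ", m$n_edges, " associations (",
    m$n_positive, " +, ", m$n_negative, " -, ", m$n_both, " both)\n",
    "  connectance (co-occurring pairs): ",
    signif(m$connectance_cooccurring, 3),
    " | (associated species): ", signif(m$connectance_associated, 3),
    "\n  global clustering: ", signif(m$clustering, 3), "\n", sep = "")
  invisible(x)
}

#' Erdos-Renyi null tests for clustering and degrees
#'
#' Compares the observed global clustering coefficient and per-species
#' degrees with an ensemble of G(n, m) random graphs having the same number
#' of nodes and links. Empirical upper-tail p-values use the
#' `(1 + exceedances) / (n_replicates + 1)` convention; node degrees are
#' referred to the pooled null degree distribution (all nodes of a G(n, m)
#' graph are exchangeable) and hubs are the species whose BH-corrected
#' degree p-value is at most 0.05.
#'
#' @param net A `pin_network`.
#' @param n_replicates Number of null graphs (999 in the classical setup).
#' @param seed Integer seed for the ensemble.
#' @return List with `p_clustering`, `null_clustering` (numeric vector),
#'   `degree_tests` (tibble: `species_id`, `degree`, `p`, `q`, `hub`) and
#'   `n_replicates`.
#' @export
er_null_tests <- function(net, n_replicates = 999, seed = 1) {
  stopifnot(inherits(net, "pin_network"))
  n <- net$metrics$n_nodes
  m <- net$metrics$n_edges
  if (m < 1) abort("Network has no edges", class = "pinnet_domain_error")
  null_clust <- numeric(n_replicates)
  null_deg <- vector("list", n_replicates)
  set.seed(seed)
  for (r in seq_len(n_replicates)) {
    gr <- igraph::sample_gnm(n, m)
    tr <- igraph::transitivity(gr, type = "global")
    null_clust[r] <- if (is.nan(tr)) 0 else tr
    null_deg[[r]] <- igraph::degree(gr)
  }
  pooled <- unlist(null_deg)
  p_clust <- (1 + sum(null_clust >= net$metrics$clustering)) /
    (n_replicates + 1)
  deg <- net$nodes$degree
  n_pool <- length(pooled)
  p_deg <- vapply(deg, function(d) {
    (1 + sum(pooled >= d)) / (n_pool + 1)
  }, numeric(1))
  q_deg <- bh_adjust(p_deg)
  list(
    p_clustering = p_clust,
    null_clustering = null_clust,
    degree_tests = tibble(
      species_id = net$nodes$species_id,
      degree = deg, p = p_deg, q = q_deg, hub = q_deg <= 0.05
    ),
    n_replicates = n_replicates
  )
}

#' Per-group abundance models against the abiotic context
#'
#' One quasi-Poisson GLM (log link) per network group: a baseline model with
#' the plot's total contact count as sole predictor, and a full model adding
#' abiotic covariates. Overdispersion is estimated by Pearson chi-square
#' over residual degrees of freedom; explanatory power is the adjusted
#' deviance R-squared `1 - (D_res/(n-p)) / (D_null/(n-1))`, and the gain
#' from the abiotic covariates is the difference between the two models.
#'
#' @param group_abundance Tibble with `plot_id`, `block` (group label) and
#'   `abundance` (summed occupied-pinpoint counts of the group's species in
#'   the plot).
#' @param totals Plot totals from [plot_totals()] (`plot_id`,
#'   `n_individuals`).
#' @param environment Environment tibble (`plot_id` + covariate columns).
#' @param covariates Character vector of abiotic covariate names.
#' @return Tibble: one row per group with `block`, `r2_baseline`, `r2_full`,
#'   `delta_r2`, `dispersion_full`, `coefficients` (list column of the full
#'   model's coefficient tibble).
#' @export
group_abundance_models <- function(group_abundance, totals, environment,
                                   covariates) {
  dat <- group_abundance %>%
    inner_join(totals, by = "plot_id") %>%
    inner_join(environment, by = "plot_id")
  if (nrow(dat) == 0) {
    abort("Plot sets of abundances and environment do not overlap",
      class = "pinnet_domain_error")
  }
  missing_cov <- setdiff(covariates, names(dat))
  if (length(missing_cov) > 0) {
    abort(paste0("Covariate(s) not in environment table: ",
      paste(missing_cov, collapse = ", ")), class = "pinnet_format_error")
  }
  groups <- sort(unique(dat$block))
  out <- lapply(groups, function(b) {
    sub <- dat %>% filter(.data$block == b)
    base <- glm(abundance ~ n_individuals, data = sub, family = quasipoisson())
    full_f <- as.formula(paste("abundance ~ n_individuals +",
      paste(covariates, collapse = " + ")))
    full <- glm(full_f, data = sub, family = quasipoisson())
    disp <- sum(residuals(full, type = "pearson")^2) / full$df.residual
    cf <- summary(full)$coefficients
    tibble(
      block = b,
      n_plots = nrow(sub),
      r2_baseline = adjusted_deviance_r2(base),
      r2_full = adjusted_deviance_r2(full),
      dispersion_full = disp,
      coefficients = list(tibble(
        term = rownames(cf), estimate = cf[, 1], std_error = cf[, 2],
        p_value = cf[, 4]
      ))
    )
  })
  bind_rows(out) %>%
    mutate(delta_r2 = .data$r2_full - .data$r2_baseline) %>%
    select("block", "n_plots", "r2_baseline", "r2_full", "delta_r2",
      "dispersion_full", "coefficients")
}

#' Adjusted deviance R-squared of a GLM
#'
#' `1 - (D_res / (n - p)) / (D_null / (n - 1))`; equals 0 for an
#' intercept-only model and penalises added parameters.
#'
#' @param fit A fitted `glm`.
#' @return A single number (can be negative for models worse than chance).
#' @export
adjusted_deviance_r2 <- function(fit) {
  n <- length(fit$y)
  p <- length(coef(fit))
  if (p <= 1 || n <= p) return(0)
  if (!is.finite(fit$null.deviance) || fit$null.deviance <= 0) return(0)
  1 - (fit$deviance / (n - p)) / (fit$null.deviance / (n - 1))
}

#' Export a network as edge list / GraphML
#'
#' @param net A `pin_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(net, path) {
  readr::write_tsv(net$edges, path)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}
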