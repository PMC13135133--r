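#' Pipeline run configuration
#'
#' All thresholds the analysis prints are configuration, not constants:
#' significance level, combination variant, null-model replicates, SBM
#' search range and restarts, and the seeds of every stochastic stage.
#'
#' @param alpha Significance level for screening and FDR steps.
#' @param variant Combination method: `"gamma2"`, `"gamma3"` or `"exact"`.
#' @param exact_cap Grid cap for the exact convolution.
#' @param null_reps Erdos-Renyi null replicates (classical value 999).
#' @param sbm_kmax Largest number of SBM blocks searched.
#' @param sbm_restarts Random restarts per SBM fit.
#' @param covariates Abiotic covariates offered to the environment models.
#' @param seed Master seed for the stochastic stages.
#' @return A `run_config` list.
#' @export
run_config <- function(alpha = 0.05, variant = "gamma2", exact_cap = 1e6,
                       null_reps = 999, sbm_kmax = 6, sbm_restarts = 5,
                       covariates = c("pH", "N_pct", "ETP", "GDD"),
                       seed = 1) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(
    alpha = alpha, variant = variant, exact_cap = exact_cap,
    null_reps = null_reps, sbm_kmax = sbm_kmax,
    sbm_restarts = sbm_restarts, covariates = covariates, seed = seed
  ), class = "run_config")
}

#' Run the whole association pipeline
#'
#' Executes the stages in order — local exact tests, evidence combination
#' with detectability pre-filter, regional calls and contributing plots,
#' signed network with Erdos-Renyi nulls, SBM roles, and (when the tables
#' are supplied) trait and environment analyses — and writes each stage's
#' TSV/JSON outputs plus a manifest into `out_dir`. Stages needing a
#' missing input are skipped with a warning; re-running with the same
#' inputs and config reproduces all outputs exactly.
#'
#' @param survey A `pin_survey`.
#' @param environment Optional plot-level environment tibble.
#' @param traits Optional species trait tibble.
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @return Invisibly, a list with every stage result (`tests`,
#'   `associations`, `network`, `null_tests`, `sbm`, `pca`, `rarity`,
#'   `richness_model`, `group_models`, `summary`).
#' @export
run_pipeline <- function(survey, environment = NULL, traits = NULL,
                         config = run_config(), out_dir = NULL) {
  stopifnot(inherits(survey, "pin_survey"), inherits(config, "run_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(x, file) {
    if (!is.null(out_dir)) readr::write_tsv(x, file.path(out_dir, file))
  }

  pairs <- cooccurring_pairs(survey)
  tests <- pair_plot_tests(survey)
  emit(tests, "pair_plot_tests.tsv")

  assoc <- screen_associations(tests, alpha = config$alpha,
    variant = config$variant, exact_cap = config$exact_cap)
  scr <- attr(assoc, "summary")
  assoc <- contributing_plots(assoc, tests, alpha = config$alpha)
  emit(
    assoc %>% mutate(
      contributing_plots_plus = vapply(.data$contributing_plots_plus,
        function(x) paste(x, collapse = ";"), character(1)),
      contributing_plots_minus = vapply(.data$contributing_plots_minus,
        function(x) paste(x, collapse = ";"), character(1))
    ),
    "associations.tsv"
  )

  net <- build_network(assoc, pairs)
  null_tests <- NULL
  sbm <- NULL
  if (net$metrics$n_edges >= 1) {
    null_tests <- er_null_tests(net, n_replicates = config$null_reps,
      seed = config$seed)
    emit(null_tests$degree_tests, "degree_tests.tsv")
    if (!is.null(out_dir)) write_edgelist(net, file.path(out_dir, "edges.tsv"))
    kmax <- min(config$sbm_kmax, net$metrics$n_nodes)
    sbm <- fit_sbm(net, K_range = seq_len(kmax),
      n_restarts = config$sbm_restarts, seed = config$seed)
    emit(sbm$memberships, "sbm_memberships.tsv")
  } else {
    warn("Empty association network: network and SBM stages skipped")
  }

  pca <- NULL; rarity <- NULL
  if (!is.null(traits)) {
    pca <- trait_pca(traits)
    rarity <- functional_rarity(traits, species_counts(survey))
    emit(rarity$per_species, "functional_rarity.tsv")
  }

  richness <- NULL; group_models <- NULL
  if (!is.null(environment)) {
    covs <- intersect(config$covariates, names(environment))
    totals <- plot_totals(survey)
    n_asso <- local_association_counts(assoc,
      plot_ids = survey$plots$plot_id)
    dat <- n_asso %>%
      inner_join(totals, by = "plot_id") %>%
      inner_join(environment, by = "plot_id")
    if (length(covs) > 0 && nrow(dat) > length(covs) + 3) {
      richness <- association_richness_model(dat, covariates = covs)
      emit(richness$coefficients, "richness_coefficients.tsv")
      emit(richness$partition, "richness_partition.tsv")
    } else {
      warn("Environment stage skipped: too few plots or no covariates")
    }
    if (!is.null(sbm)) {
      ga <- species_counts(survey) %>%
        inner_join(sbm$memberships, by = "species_id") %>%
        group_by(.data$plot_id, .data$block) %>%
        summarise(abundance = sum(.data$n), .groups = "drop")
      group_models <- tryCatch(
        group_abundance_models(ga, totals, environment, covs),
        error = function(e) {
          warn(paste0("Group abundance models skipped: ",
            conditionMessage(e)))
          NULL
        })
    }
  } else {
    warn("No environment table: abiotic stages skipped")
  }

  summary <- c(
    scr,
    list(
      n_plots = nrow(survey$plots),
      n_species = dplyr::n_distinct(survey$records$species_id),
      n_nodes = net$metrics$n_nodes,
      n_edges = net$metrics$n_edges,
      connectance_cooccurring = net$metrics$connectance_cooccurring,
      connectance_associated = net$metrics$connectance_associated,
      clustering = net$metrics$clustering,
      p_clustering = if (!is.null(null_tests)) null_tests$p_clustering
        else NA_real_,
      n_hubs = if (!is.null(null_tests)) sum(null_tests$degree_tests$hub)
        else 0L,
      sbm_K = if (!is.null(sbm)) sbm$K else NA_integer_,
      seed = config$seed
    )
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(list(
    tests = tests, associations = assoc, pairs = pairs, network = net,
    null_tests = null_tests, sbm = sbm, pca = pca, rarity = rarity,
    richness_model = richness, group_models = group_models,
    summary = summary
  ))
}
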