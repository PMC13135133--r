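make_assoc <- function(edges, sign = "negative") {
  tibble::tibble(
    species_i = edges[, 1], species_j = edges[, 2],
    n_plots = 2L, p_plus = NA_real_, p_minus = NA_real_,
    q_plus = NA_real_, q_minus = NA_real_,
    tested_plus = TRUE, tested_minus = TRUE,
    significant_plus = sign %in% c("positive", "both"),
    significant_minus = sign %in% c("negative", "both"),
    sign = sign
  )
}

all_pairs_of <- function(sp) {
  cmb <- t(combn(sp, 2))
  tibble::tibble(species_i = cmb[, 1], species_j = cmb[, 2],
    plot_ids = list("P1"), n_plots = 1L)
}

test_that("network metrics behave on canonical graphs", {
  # triangle: C = 1 (both denominators), clustering = 1
  tri <- make_assoc(cbind(c("a", "a", "b"), c("b", "c", "c")))
  net <- build_network(tri, all_pairs_of(c("a", "b", "c")))
  expect_equal(net$metrics$connectance_cooccurring, 1)
  expect_equal(net$metrics$connectance_associated, 1)
  expect_equal(net$metrics$clustering, 1)
  expect_equal(sum(net$nodes$degree), 2 * net$metrics$n_edges)

  # star on 5 nodes: no closed triads
  star <- make_assoc(cbind(rep("hub", 4), paste0("s", 1:4)))
  net <- build_network(star, all_pairs_of(c("hub", paste0("s", 1:4))))
  expect_equal(net$metrics$clustering, 0)
  expect_equal(sum(net$nodes$degree), 8)

  # empty network
  none <- make_assoc(cbind("a", "b"))[0, ]
  net0 <- build_network(none, all_pairs_of(c("a", "b")))
  expect_equal(net0$metrics$n_edges, 0)
  expect_equal(net0$metrics$connectance_cooccurring, 0)

  # sign = both kept as one flagged edge
  both <- make_assoc(cbind("a", "b"), sign = "both")
  netb <- build_network(both, all_pairs_of(c("a", "b")))
  expect_equal(netb$metrics$n_edges, 1)
  expect_equal(netb$metrics$n_both, 1)
})

test_that("ER null tests give valid empirical p-values and find hubs", {
  # a dense hub attached to a sparse background
  sp <- c("hub", paste0("s", 1:14))
  edges <- cbind(rep("hub", 14), paste0("s", 1:14))
  edges <- rbind(edges, cbind("s1", "s2"))
  net <- build_network(make_assoc(edges), all_pairs_of(sp))
  res <- er_null_tests(net, n_replicates = 199, seed = 42)
  expect_gte(res$p_clustering, 1 / 200)
  expect_lte(res$p_clustering, 1)
  expect_equal(length(res$null_clustering), 199)
  # the hub's degree (14 of 14 possible) must be flagged
  hub_row <- res$degree_tests[res$degree_tests$species_id == "hub", ]
  expect_true(hub_row$hub)
  # reproducibility: identical seed, identical ensemble
  res2 <- er_null_tests(net, n_replicates = 199, seed = 42)
  expect_identical(res$null_clustering, res2$null_clustering)
  expect_error(er_null_tests(build_network(make_assoc(cbind("a", "b"))[0, ],
    all_pairs_of(c("a", "b")))), class = "pinnet_domain_error")
})

test_that("group abundance models recover planted abiotic effects", {
  set.seed(8)
  n_plots <- 60
  env <- tibble::tibble(plot_id = sprintf("p%02d", 1:n_plots),
    pH = rnorm(n_plots, 5.5, 0.8), GDD = rnorm(n_plots, 1500, 300))
  totals <- tibble::tibble(plot_id = env$plot_id,
    n_individuals = rpois(n_plots, 300))
  mu_core <- exp(2 + 0.002 * totals$n_individuals - 0.9 * (env$pH - 5.5))
  mu_flat <- exp(2 + 0.002 * totals$n_individuals)
  ga <- dplyr::bind_rows(
    tibble::tibble(plot_id = env$plot_id, block = 1L,
      abundance = rpois(n_plots, mu_core)),
    tibble::tibble(plot_id = env$plot_id, block = 2L,
      abundance = rpois(n_plots, mu_flat))
  )
  fits <- group_abundance_models(ga, totals, env, covariates = c("pH", "GDD"))
  core <- fits[fits$block == 1, ]
  flat <- fits[fits$block == 2, ]
  expect_gt(core$delta_r2, 0.1)
  cf <- core$coefficients[[1]]
  expect_lt(cf$estimate[cf$term == "pH"], 0)
  # abiotically flat group gains little
  expect_lt(abs(flat$delta_r2), 0.1)
  # disjoint plot sets are a domain error
  expect_error(group_abundance_models(
    ga %>% dplyr::mutate(plot_id = paste0("x", plot_id)), totals, env,
    covariates = "pH"), class = "pinnet_domain_error")
})

test_that("adjusted deviance R2 follows its defining formula", {
  set.seed(2)
  d <- tibble::tibble(y = rpois(40, 5), x = rnorm(40))
  fit <- glm(y ~ x, data = d, family = quasipoisson())
  n <- 40; p <- 2
  expect_equal(adjusted_deviance_r2(fit),
    1 - (fit$deviance / (n - p)) / (fit$null.deviance / (n - 1)),
    tolerance = 1e-12)
  fit0 <- glm(y ~ 1, data = d, family = quasipoisson())
  expect_equal(adjusted_deviance_r2(fit0), 0)
})
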