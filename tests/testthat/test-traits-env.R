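fake_traits <- function(n = 40, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    species_id = sprintf("sp%03d", 1:n),
    SLA = rlnorm(n, log(18), 0.3),
    LDMC = rlnorm(n, log(250), 0.3),
    leaf_area = rlnorm(n, log(200), 0.5),
    vegetative_height = rlnorm(n, log(0.3), 0.4),
    seed_mass = rlnorm(n, log(1), 0.6)
  )
}

test_that("trait PCA captures correlated structure and scales variance", {
  tr <- fake_traits(60, seed = 2)
  tr$LDMC <- 1000 / tr$SLA # perfectly (negatively) correlated pair
  pca <- trait_pca(tr)
  expect_equal(sum(pca$variance$variance_fraction), 1, tolerance = 1e-9)
  # first axis is dominated by the correlated pair
  l1 <- dplyr::filter(tidy(pca), component == "PC1")
  lead <- l1$trait[order(-abs(l1$loading))][1:2]
  expect_setequal(lead, c("SLA", "LDMC"))
  # constant column is rejected by name
  tr$SLA <- 10
  expect_error(trait_pca(tr), "SLA", class = "pinnet_domain_error")
})

test_that("pairwise PERMANOVA separates distinct centroids and not identical ones", {
  set.seed(9)
  x <- rbind(
    matrix(rnorm(40, 0), ncol = 2),
    matrix(rnorm(40, 10), ncol = 2), # 10 within-SD units away
    matrix(rnorm(40, 0), ncol = 2)
  )
  g <- rep(c("a", "b", "c"), each = 20)
  res <- pairwise_permanova(x, g, n_perm = 199, seed = 1)
  ab <- res[res$group_1 == "a" & res$group_2 == "b", ]
  expect_equal(ab$p, 1 / 200, tolerance = 1e-12) # minimum attainable
  ac <- res[res$group_1 == "a" & res$group_2 == "c", ]
  expect_gt(ac$p, 0.05)
  # single-member groups are skipped with a warning
  expect_warning(
    pairwise_permanova(x[1:41, ], c(g[1:40], "z"), n_perm = 49, seed = 1),
    "single-member"
  )
})

test_that("distinctiveness and scarcity follow their closed forms", {
  # 2 species, equal abundance: a = 0.5, S = exp(-2 ln2 * 0.5) = 0.5
  tr <- tibble::tibble(species_id = c("a", "b"), SLA = c(10, 20))
  ab <- tibble::tibble(plot_id = "P1", species_id = c("a", "b"),
    n = c(5L, 5L))
  r <- functional_rarity(tr, ab)
  expect_equal(r$per_plot$scarcity, c(0.5, 0.5), tolerance = 1e-12)

  # three species with d12 = d13 = 0.5, d23 = 0, equal abundances:
  # D_1 = 0.5, D_2 = (0.5 + 0)/2 = 0.25. Trait values 0/1/1 z-scored and
  # rescaled by the max distance give exactly those distances.
  tr3 <- tibble::tibble(species_id = c("s1", "s2", "s3"), SLA = c(1, 2, 2))
  ab3 <- tibble::tibble(plot_id = "P1", species_id = c("s1", "s2", "s3"),
    n = c(1L, 1L, 1L))
  r3 <- functional_rarity(tr3, ab3)
  d <- setNames(r3$per_plot$distinctiveness, r3$per_plot$species_id)
  expect_equal(unname(d["s1"]), 1, tolerance = 1e-12) # d12=d13=1 rescaled
  expect_equal(unname(d["s2"]), 0.5, tolerance = 1e-12)

  # functionally identical species -> D = 0 everywhere
  trs <- tibble::tibble(species_id = c("x", "y"), SLA = c(3, 3),
    LDMC = c(200, 200))
  abs2 <- tibble::tibble(plot_id = "P1", species_id = c("x", "y"),
    n = c(2L, 8L))
  r0 <- functional_rarity(trs, abs2)
  expect_equal(r0$per_plot$distinctiveness, c(0, 0))

  # species alone in a plot: D undefined and flagged
  ab1 <- tibble::tibble(plot_id = "P2", species_id = "a", n = 3L)
  rr <- functional_rarity(tr, dplyr::bind_rows(ab, ab1))
  alone <- rr$per_plot[rr$per_plot$plot_id == "P2", ]
  expect_true(is.na(alone$distinctiveness))
  expect_true(alone$alone)

  # species absent everywhere excluded with warning
  tr_extra <- dplyr::bind_rows(tr,
    tibble::tibble(species_id = "ghost", SLA = 15))
  expect_warning(functional_rarity(tr_extra, ab), "absent")
})

test_that("distinctiveness is invariant to adding a zero-abundance species", {
  tr <- fake_traits(10, seed = 3)
  ab <- tibble::tibble(plot_id = "P1",
    species_id = tr$species_id[1:6], n = c(4L, 2L, 7L, 1L, 3L, 5L))
  base <- functional_rarity(tr[1:6, ], ab)
  # the 7th species exists in the trait table but occupies no plot
  expect_warning(ext <- functional_rarity(tr[1:7, ], ab), "absent")
  expect_equal(base$per_plot$distinctiveness, ext$per_plot$distinctiveness,
    tolerance = 1e-12)
})

test_that("rank tests match exact small-sample references", {
  # Wilcoxon rank-sum: n = 3 vs 3, no ties; exact p from enumeration of
  # the 20 equally likely group assignments
  x <- c(1.1, 2.3, 3.1); y <- c(4.2, 5.0, 6.7) # complete separation
  d <- tibble::tibble(v = c(x, y), g = rep(c("a", "b"), each = 3))
  res <- group_contrasts(d, "v", "g", test = "wilcoxon")
  exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value # 2/20
  expect_equal(exact, 0.1, tolerance = 1e-12)
  # the normal-approximation p stays close at this size
  expect_lt(abs(res$p - exact), 0.05)
  kr <- group_contrasts(d, "v", "g", test = "kruskal")
  expect_equal(nrow(kr), 1)
  expect_lt(kr$p, 0.1)
})

test_that("hierarchical partitioning sums to the full-model R2", {
  set.seed(4)
  n <- 80
  d <- tibble::tibble(
    x1 = rnorm(n), x2 = rnorm(n),
    y = rpois(n, exp(1 + 0.5 * x1 + 0.3 * x2))
  )
  hp <- hierarchical_partition(d, "y", c("x1", "x2"))
  full <- adjusted_deviance_r2(glm(y ~ x1 + x2, data = d,
    family = quasipoisson()))
  expect_equal(sum(hp$independent), full, tolerance = 1e-9)
  expect_gt(hp$independent[hp$term == "x1"], hp$independent[hp$term == "x2"])

  # single predictor: 100% share
  hp1 <- hierarchical_partition(d, "y", "x1")
  expect_equal(hp1$share_pct, 100, tolerance = 1e-9)

  # duplicated predictor: shares split equally by symmetry
  d$x1b <- d$x1
  hp2 <- hierarchical_partition(d, "y", c("x1", "x1b"))
  expect_equal(hp2$independent[1], hp2$independent[2], tolerance = 1e-9)

  expect_error(hierarchical_partition(d, "y", paste0("z", 1:9)),
    class = "pinnet_capacity_error")
})

test_that("association richness model recovers planted abiotic signal", {
  set.seed(12)
  n <- 100
  dat <- tibble::tibble(
    plot_id = sprintf("p%03d", 1:n),
    n_individuals = rpois(n, 250),
    pH = rnorm(n, 5.5, 0.7),
    N_pct = pmax(0.05, rnorm(n, 0.4, 0.12)),
    GDD = rnorm(n, 1500, 300)
  )
  mu <- exp(0.5 + 0.004 * dat$n_individuals - 0.6 * (dat$pH - 5.5) +
    2.5 * (dat$N_pct - 0.4))
  dat$n_asso <- rpois(n, mu)
  fit <- association_richness_model(dat, covariates = c("pH", "N_pct", "GDD"))
  expect_gt(glance(fit)$r2_selected, glance(fit)$r2_baseline)
  cf <- tidy(fit)
  expect_lt(cf$estimate[cf$term == "pH"], 0)
  expect_gt(cf$estimate[cf$term == "N_pct"], 0)
  expect_equal(sum(fit$partition$independent),
    fit$r2$adjusted_r2[fit$r2$model == "selected"], tolerance = 1e-9)

  # collinear covariates are refused with the pair named
  dat$pH2 <- dat$pH * 1.01 + 0.001
  expect_error(
    association_richness_model(dat, covariates = c("pH", "pH2")),
    class = "pinnet_collinearity_error"
  )
})

test_that("stepwise drops uninformative abiotic terms", {
  set.seed(13)
  n <- 90
  dat <- tibble::tibble(
    n_individuals = rpois(n, 250),
    pH = rnorm(n), GDD = rnorm(n),
    n_asso = rpois(n, exp(0.5 + 0.004 * n_individuals))
  )
  fit <- association_richness_model(dat, covariates = c("pH", "GDD"))
  # abiotic-independent response: adjusted R2 gain stays negligible
  expect_lt(glance(fit)$r2_selected - glance(fit)$r2_baseline, 0.05)
})
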