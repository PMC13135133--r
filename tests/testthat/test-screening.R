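test_that("BH adjustment matches the hand step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.5)),
    c(0.04, 0.04, 0.04 * 4 / 3, 0.5), tolerance = 1e-12)
  # rejections at alpha = 0.05: largest k with p_(k) <= k alpha / m is 2
  expect_equal(sum(bh_adjust(c(0.01, 0.02, 0.04, 0.5)) <= 0.05), 2)
  expect_equal(bh_adjust(1), 1)
  expect_equal(bh_adjust(rep(0.03, 5)), rep(0.03, 5))
  p <- runif(20)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("detectability pre-filter drops undetectable tails only", {
  # locally rare pair: segregation minimum ~0.97, aggregation tiny
  pv <- hypergeom_pvalues(1, 3, 3, 300)
  tests <- tibble::tibble(species_i = "a", species_j = "b", plot_id = "P1",
    n_ijs = 1L, n_is = 3L, n_js = 3L, N_s = 300L,
    p_plus = pv$p_plus, p_minus = pv$p_minus)
  pf <- prefilter_pairs(tests, alpha = 0.05)
  expect_false(pf$tested[pf$tail == "minus"])
  expect_true(pf$tested[pf$tail == "plus"])
  # empty input
  expect_equal(nrow(prefilter_pairs(tests[0, ])), 0)
})

test_that("regional calls assign signs per tail and respect q <= alpha", {
  combined <- tibble::tibble(
    species_i = c("a", "a", "c", "c"),
    species_j = c("b", "b", "d", "d"),
    tail = c("plus", "minus", "plus", "minus"),
    K = 3L, n_plots = 3L, T_obs = 1,
    p_combined = c(1e-6, 1e-5, 0.9, 0.8),
    method = "gamma2"
  )
  calls <- call_regional(combined, alpha = 0.05)
  ab <- calls[calls$species_i == "a", ]
  expect_equal(ab$sign, "both")
  cd <- calls[calls$species_i == "c", ]
  expect_equal(cd$sign, "none")
  expect_true(all(calls$q_plus >= calls$p_plus, na.rm = TRUE))
})

test_that("screening stage counts are internally consistent", {
  cfg <- synth_config(n_plots = 8, n_species = 15, seed = 3,
    planted = tibble::tibble(species_i = "sp001", species_j = "sp002",
      theta = 4))
  sv <- generate_survey(cfg)$survey
  tests <- pair_plot_tests(sv)
  assoc <- screen_associations(tests, alpha = 0.05)
  s <- attr(assoc, "summary")
  expect_equal(nrow(assoc), s$n_cooccurring_pairs)
  expect_equal(sum(assoc$tested_plus), s$n_tested_plus)
  expect_equal(sum(assoc$significant_minus), s$n_significant_minus)
  # significant pairs are a subset of tested pairs, per tail
  expect_true(all(!assoc$significant_plus | assoc$tested_plus))
  expect_true(all(!assoc$significant_minus | assoc$tested_minus))
  # determinism: identical inputs give identical calls
  assoc2 <- screen_associations(tests, alpha = 0.05)
  expect_identical(as.data.frame(assoc), as.data.frame(assoc2))
})

test_that("discrete step-up reduces to classical BH for uniform supports", {
  m <- 2000
  unif <- tibble::tibble(value = seq_len(m) / m, mass = rep(1 / m, m))
  set.seed(21)
  for (rep in 1:10) {
    p <- round(runif(8, 1 / m, 1) * m) / m # attainable values
    sup <- replicate(8, unif, simplify = FALSE)
    expect_equal(discrete_bh(p, sup, alpha = 0.1), bh_reject(p, 0.1))
  }
})

test_that("discrete step-up never rejects fewer than classical BH", {
  set.seed(31)
  for (rep in 1:20) {
    K <- sample(3:8, 1)
    sups <- lapply(seq_len(K), function(i) {
      m <- random_margins(40, 10)
      pvalue_support(m$n_i, m$n_j, m$N, sample(c("plus", "minus"), 1))
    })
    p <- vapply(sups, function(s) sample1(s$value), numeric(1))
    disc <- discrete_bh(p, sups, alpha = 0.05)
    clas <- bh_reject(p, 0.05)
    expect_true(all(disc | !clas))
  }
})

test_that("a single plot at its minimum attainable value can contribute", {
  s <- pvalue_support(6, 6, 40, "plus")
  p_min <- s$value[1]
  # critical constant: largest attainable t with F(t) <= alpha
  expect_true(discrete_bh(p_min, list(s), alpha = 0.05)[1])
})

test_that("contributing plots are a subset of co-occurrence plots", {
  cfg <- synth_config(n_plots = 10, n_species = 12, seed = 5,
    median_abundance = 25,
    planted = tibble::tibble(species_i = "sp001", species_j = "sp002",
      theta = 4))
  sv <- generate_survey(cfg)$survey
  tests <- pair_plot_tests(sv)
  assoc <- screen_associations(tests, alpha = 0.05)
  assoc <- contributing_plots(assoc, tests, alpha = 0.05)
  sig <- assoc[assoc$sign != "none", ]
  expect_gt(nrow(sig), 0)
  for (i in seq_len(nrow(sig))) {
    shared <- tests$plot_id[tests$species_i == sig$species_i[i] &
        tests$species_j == sig$species_j[i]]
    expect_true(all(sig$contributing_plots_plus[[i]] %in% shared))
  }
  # post-hoc contract: requesting a non-significant pair errors
  ns <- assoc[assoc$sign == "none", ][1, c("species_i", "species_j")]
  expect_error(contributing_plots(assoc, tests, pairs = ns),
    class = "pinnet_contract_error")
  # per-plot local association counts cover all plots when asked
  cnt <- local_association_counts(assoc, plot_ids = sv$plots$plot_id)
  expect_equal(nrow(cnt), nrow(sv$plots))
  expect_true(all(cnt$n_asso >= 0))
})
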