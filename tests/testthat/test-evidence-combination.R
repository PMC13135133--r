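test_that("null moments of the combination statistic are exact", {
  s <- pvalue_support(2, 2, 4, "plus")
  mom <- null_moments(list(s))
  # hand computation over the 3-point distribution of -ln p
  t_vals <- -log(c(1 / 6, 5 / 6, 1))
  w <- c(1 / 6, 4 / 6, 1 / 6)
  expect_equal(mom$mu, sum(w * t_vals), tolerance = 1e-12)
  expect_equal(mom$sigma2, sum(w * (t_vals - mom$mu)^2), tolerance = 1e-12)
  expect_equal(mom$mu, 0.42018, tolerance = 1e-4)
  expect_equal(mom$sigma2, 0.38068, tolerance = 1e-4)

  # two identical strata: moments double (cumulants add)
  mom2 <- null_moments(list(s, s))
  expect_equal(mom2$mu, 2 * mom$mu, tolerance = 1e-12)
  expect_equal(mom2$sigma2, 2 * mom$sigma2, tolerance = 1e-12)

  # continuous-uniform stand-in: -ln U ~ Exp(1), so mu -> 1, sigma2 -> 1
  m <- 20000
  grid <- tibble::tibble(value = seq_len(m) / m, mass = rep(1 / m, m))
  momu <- null_moments(list(grid))
  expect_equal(momu$mu, 1, tolerance = 5e-4)
  expect_equal(momu$sigma2, 1, tolerance = 5e-3)

  expect_error(null_moments(list()), class = "pinnet_domain_error")
})

test_that("exact convolution reproduces enumeration and its identities", {
  s <- pvalue_support(2, 2, 4, "plus")
  # K = 1: P(p <= v) = v at every attainable v
  for (v in s$value) {
    expect_equal(combine_exact(v, list(s))$p_combined, v, tolerance = 1e-12)
  }
  # two strata both at the minimum attainable value: only the
  # double-extreme joint outcome reaches T_obs -> product of masses
  res <- combine_exact(c(1 / 6, 1 / 6), list(s, s))
  expect_equal(res$p_combined, 1 / 36, tolerance = 1e-12)
  expect_equal(res$T_obs, 2 * log(6), tolerance = 1e-12)
  # all observed at 1 -> no evidence
  expect_equal(combine_exact(c(1, 1), list(s, s))$p_combined, 1)
  # capacity error for oversized grids
  big <- pvalue_support(40, 40, 100, "plus")
  expect_error(
    combine_exact(rep(0.5, 4), list(big, big, big, big), cap = 100),
    class = "pinnet_capacity_error"
  )
  expect_error(combine_exact(0, list(s)), class = "pinnet_domain_error")
})

test_that("exact convolution equals brute-force enumeration on random configs", {
  set.seed(123)
  for (rep in 1:40) {
    K <- sample(1:3, 1)
    sups <- lapply(seq_len(K), function(i) {
      m <- random_margins(N_max = 30, n_max = 8)
      pvalue_support(m$n_i, m$n_j, m$N, sample(c("plus", "minus"), 1))
    })
    p_obs <- vapply(sups, function(s) sample1(s$value), numeric(1))
    expect_equal(
      combine_exact(p_obs, sups)$p_combined,
      enum_combined_p(p_obs, sups),
      tolerance = 1e-12
    )
  }
})

test_that("gamma approximation tracks the exact null", {
  s <- pvalue_support(2, 2, 4, "plus")
  # single stratum: gamma2 within half an order of magnitude at attainable
  # values (the spec-level bound is |log10 ratio| <= 0.3 on this support)
  for (v in s$value) {
    g <- combine_gamma(v, list(s), "gamma2")$p_combined
    expect_lt(abs(log10(g / v)), 0.3)
  }
  # all observed at 1 -> T = 0 -> p = 1
  expect_equal(combine_gamma(c(1, 1), list(s, s), "gamma2")$p_combined, 1)
  # sigma2 = 0 (all strata degenerate) -> p = 1
  d <- pvalue_support(1, 10, 10, "plus")
  expect_equal(combine_gamma(1, list(d), "gamma2")$p_combined, 1)
  expect_equal(combine_gamma(1, list(d), "gamma2")$K, 0L)
})

test_that("degenerate strata contribute nothing to the combination", {
  s <- pvalue_support(3, 4, 12, "plus")
  d <- pvalue_support(1, 12, 12, "plus") # support {1}
  for (fun in list(
    function(p, sup) combine_exact(p, sup)$p_combined,
    function(p, sup) combine_gamma(p, sup, "gamma2")$p_combined,
    function(p, sup) combine_gamma(p, sup, "gamma3")$p_combined
  )) {
    with_d <- fun(c(s$value[1], 1, s$value[2]), list(s, d, s))
    without <- fun(c(s$value[1], s$value[2]), list(s, s))
    expect_equal(with_d, without, tolerance = 1e-12)
  }
})

test_that("minimum combined p dominates every observed combination", {
  set.seed(5)
  for (variant in c("gamma2", "gamma3", "exact")) {
    for (rep in 1:15) {
      K <- sample(1:3, 1)
      margins <- lapply(seq_len(K), function(i) random_margins(30, 8))
      tests <- dplyr::bind_rows(lapply(seq_along(margins), function(i) {
        m <- margins[[i]]
        k <- sample1(max(0, m$n_i + m$n_j - m$N):min(m$n_i, m$n_j))
        pv <- hypergeom_pvalues(k, m$n_i, m$n_j, m$N)
        tibble::tibble(species_i = "a", species_j = "b",
          plot_id = paste0("P", i), n_ijs = k, n_is = m$n_i, n_js = m$n_j,
          N_s = m$N, p_plus = pv$p_plus, p_minus = pv$p_minus)
      }))
      cmb <- combine_pairs(tests, variant = variant)
      mn <- min_combined_pvalues(tests, variant = variant)
      joined <- dplyr::inner_join(cmb, mn,
        by = c("species_i", "species_j", "tail"))
      expect_true(all(joined$p_min_combined <= joined$p_combined + 1e-12))
    }
  }
})

test_that("adding a plot with informative support never raises the minimum", {
  tests1 <- tibble::tibble(species_i = "a", species_j = "b",
    plot_id = "P1", n_ijs = 2L, n_is = 8L, n_js = 9L, N_s = 60L,
    p_plus = hypergeom_pvalues(2, 8, 9, 60)$p_plus,
    p_minus = hypergeom_pvalues(2, 8, 9, 60)$p_minus)
  tests2 <- dplyr::bind_rows(tests1, tibble::tibble(species_i = "a",
    species_j = "b", plot_id = "P2", n_ijs = 1L, n_is = 5L, n_js = 6L,
    N_s = 50L, p_plus = hypergeom_pvalues(1, 5, 6, 50)$p_plus,
    p_minus = hypergeom_pvalues(1, 5, 6, 50)$p_minus))
  for (variant in c("gamma2", "exact")) {
    m1 <- min_combined_pvalues(tests1, variant = variant)
    m2 <- min_combined_pvalues(tests2, variant = variant)
    expect_true(all(m2$p_min_combined <= m1$p_min_combined + 1e-12))
  }
})
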