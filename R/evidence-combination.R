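#' Combining discrete local p-values across plots
#'
#' A pair's local tests are independent strata (one per plot where the pair
#' co-occurs) with discrete, superuniform p-value distributions. Evidence is
#' pooled with Fisher's statistic `T = sum_s -ln p_s`, whose exact null is
#' the convolution of the per-stratum distributions of `-ln p` over their
#' attainable values. Two routes evaluate `P(T >= T_obs)`:
#'
#' * a moment-matched gamma approximation of the stratified discrete null
#'   (`gamma2` matching mean and variance, `gamma3` a shifted gamma also
#'   matching skewness), fast enough for tens of thousands of pairs;
#' * an exact discrete convolution (`exact`), tractable for small numbers of
#'   plots or compact supports, which serves as the authoritative reference.
#'
#' Strata whose whole support is {1} carry no evidence and are dropped
#' before moment computation and convolution (the truncation rule); the
#' gamma tail is clamped below at the exact minimum attainable combined
#' p-value so the approximation never undercuts what the discrete null can
#' produce.
#'
#' @name evidence_combination
NULL

# fast internal support of -ln p: list(t, mass), t >= 0, unordered
.neglog_support <- function(n_is, n_js, N_s, tail) {
  k <- seq.int(max(0, n_is + n_js - N_s), min(n_is, n_js))
  mass <- dhyper(k, n_is, N_s - n_is, n_js)
  p <- if (tail == "plus") {
    phyper(k - 1, n_is, N_s - n_is, n_js, lower.tail = FALSE)
  } else {
    phyper(k, n_is, N_s - n_is, n_js)
  }
  list(t = -log(pmin(p, 1)), mass = mass)
}

.is_degenerate <- function(sup) {
  length(sup$t) == 1L && sup$t[1] <= 1e-15
}

.as_neglog <- function(support) {
  # accepts a (value, mass) tibble or an internal (t, mass) list
  if (!is.null(support[["t"]])) return(support)
  list(t = -log(support[["value"]]), mass = support[["mass"]])
}

#' Exact null moments of the combination statistic
#'
#' Computes mean, variance and skewness of `T = sum_s -ln p_s` under the
#' stratified discrete null, exactly over the attainable values of each
#' stratum. Cumulants add across independent strata. Strata with support
#' {1} are dropped first.
#'
#' @param supports List of p-value supports, each a tibble with `value` and
#'   `mass` columns (see [pvalue_support()]).
#' @return List with `mu`, `sigma2`, `gamma1` (skewness of the sum) and
#'   `n_strata` (strata retained after truncation).
#' @examples
#' s <- pvalue_support(2, 2, 4, "plus")
#' null_moments(list(s)) # mu ~ 0.420, sigma2 ~ 0.381
#' @export
null_moments <- function(supports) {
  if (length(supports) == 0) {
    abort("Need at least one stratum", class = "pinnet_domain_error")
  }
  sups <- lapply(supports, .as_neglog)
  sups <- sups[!vapply(sups, .is_degenerate, logical(1))]
  mu <- 0; s2 <- 0; m3 <- 0
  for (sup in sups) {
    w <- sup$mass / sum(sup$mass)
    m <- sum(w * sup$t)
    d <- sup$t - m
    mu <- mu + m
    s2 <- s2 + sum(w * d^2)
    m3 <- m3 + sum(w * d^3)
  }
  list(
    mu = mu, sigma2 = s2,
    gamma1 = if (s2 > 0) m3 / s2^1.5 else 0,
    n_strata = length(sups)
  )
}

# exact minimum attainable combined p: all strata at their extreme point
.min_attainable_combined <- function(sups) {
  lp <- 0
  for (sup in sups) {
    i <- which.max(sup$t)
    lp <- lp + log(sup$mass[i])
  }
  exp(lp)
}

#' Gamma-approximate combined p-value
#'
#' Approximates the upper tail of the stratified discrete null of Fisher's
#' statistic. Strata with very coarse supports (at most `coarse_cap`
#' attainable values) are convolved exactly — a few-atom staircase is not
#' approximable by any smooth tail and costs nothing to enumerate — while
#' the remaining strata enter through a moment-matched gamma: `gamma2`
#' matches mean and variance (shape `mu^2/sigma^2`, scale `sigma^2/mu`),
#' `gamma3` is a shifted gamma also matching skewness (shape `4/gamma1^2`,
#' scale `sqrt(sigma2/shape)`, shift `mu - shape*scale`, tail evaluated at
#' `max(T - shift, 0)`). A discreteness correction adds half the observed
#' joint atom's null mass (the exact tail carries that atom fully, a
#' continuous tail only about half of it), and the result is floored at
#' the method's own value for the most extreme attainable data, so the
#' minimum achievable combined p-value is a true lower bound.
#'
#' @param p_values Observed per-stratum p-values in (0, 1].
#' @param supports Per-stratum p-value supports (same order), each a tibble
#'   with `value`/`mass` (or internal `t`/`mass`) columns.
#' @param variant `"gamma2"` or `"gamma3"`.
#' @param coarse_cap Supports with at most this many attainable values are
#'   convolved exactly (their joint grid is capped at 4096 atoms).
#' @return List with `T_obs`, `p_combined`, `K` (strata retained), `method`.
#' @export
combine_gamma <- function(p_values, supports, variant = c("gamma2", "gamma3"),
                          coarse_cap = 4) {
  variant <- match.arg(variant)
  stopifnot(length(p_values) == length(supports))
  if (any(p_values <= 0 | p_values > 1)) {
    abort("p-values must lie in (0, 1]", class = "pinnet_domain_error")
  }
  sups <- lapply(supports, .as_neglog)
  keep <- !vapply(sups, .is_degenerate, logical(1))
  sups <- sups[keep]
  p_values <- p_values[keep]
  T_obs <- sum(-log(p_values))
  if (length(sups) == 0) {
    return(list(T_obs = 0, p_combined = 1, K = 0L, method = variant))
  }
  sizes <- vapply(sups, function(s) length(s$t), integer(1))
  is_coarse <- .pick_coarse(sizes, coarse_cap, grid_cap = 4096)
  coarse <- sups[is_coarse]
  fine <- sups[!is_coarse]
  mom <- if (length(fine) > 0) null_moments(fine) else NULL
  grid <- .convolve_grid(coarse)
  p_min_each <- vapply(sups, function(s) exp(-max(s$t)), numeric(1))

  raw_obs <- .hybrid_tail(T_obs, p_values, sups, is_coarse, grid, mom,
    variant)
  raw_ext <- .hybrid_tail(sum(-log(p_min_each)), p_min_each, sups,
    is_coarse, grid, mom, variant)
  p <- max(raw_obs, raw_ext, .min_attainable_combined(sups))
  list(T_obs = T_obs, p_combined = min(max(p, 0), 1), K = length(sups),
    method = variant)
}

# choose which strata to convolve exactly, keeping the joint grid small
.pick_coarse <- function(sizes, coarse_cap, grid_cap) {
  is_coarse <- sizes <= coarse_cap
  o <- order(sizes)
  prod_sz <- 1
  for (i in o) {
    if (!is_coarse[i]) next
    if (prod_sz * sizes[i] > grid_cap) {
      is_coarse[i] <- FALSE
    } else {
      prod_sz <- prod_sz * sizes[i]
    }
  }
  is_coarse
}

.convolve_grid <- function(sups) {
  grid_t <- 0; grid_m <- 1
  for (sup in sups) {
    t_new <- as.vector(outer(grid_t, sup$t, `+`))
    m_new <- as.vector(outer(grid_m, sup$mass, `*`))
    o <- order(t_new)
    grid_t <- t_new[o]; grid_m <- m_new[o]
  }
  list(t = grid_t, mass = grid_m)
}

# P(T >= T_obs) with the coarse part enumerated and the fine part gamma
.hybrid_tail <- function(T_obs, p_values, sups, is_coarse, grid, mom,
                         variant) {
  tol <- 1e-9 * max(T_obs, 1)
  if (is.null(mom)) {
    return(sum(grid$mass[grid$t >= T_obs - tol]))
  }
  if (mom$sigma2 <= 0) {
    # fine strata carry no spread: their contribution is a point mass
    T_res <- T_obs - mom$mu
    return(sum(grid$mass[grid$t >= T_res - tol]))
  }
  tails <- vapply(grid$t, function(tg) {
    x <- T_obs - tg
    if (x <= 0) 1 else .gamma_tail(x, mom, variant)
  }, numeric(1))
  p <- sum(grid$mass * tails)
  # half the observed joint atom's mass: the exact tail includes that atom
  # fully, the smooth gamma tail only about half of it
  atom <- 0
  for (i in seq_along(sups)) {
    j <- which.min(abs(sups[[i]]$t - (-log(p_values[i]))))
    atom <- atom + log(sups[[i]]$mass[j])
  }
  p + 0.5 * exp(atom)
}

.gamma_tail <- function(T_obs, mom, variant) {
  if (variant == "gamma3" && abs(mom$gamma1) > 1e-8) {
    a <- 4 / mom$gamma1^2
    theta <- sqrt(mom$sigma2 / a)
    shift <- mom$mu - a * theta
    pgamma(max(T_obs - shift, 0), shape = a, scale = theta,
      lower.tail = FALSE)
  } else {
    a <- mom$mu^2 / mom$sigma2
    pgamma(T_obs, shape = a, scale = mom$sigma2 / mom$mu,
      lower.tail = FALSE)
  }
}

#' Exact combined p-value by discrete convolution
#'
#' Convolves the per-stratum distributions of `-ln p` over their attainable
#' values and returns `P(T >= T_obs)`. Atoms whose statistic values agree
#' within relative tolerance 1e-9 are merged as the grid grows; the grid is
#' capped (default 1e6 atoms) and a capacity error pointing at the gamma
#' variants is raised beyond it.
#'
#' @inheritParams combine_gamma
#' @param cap Maximum number of atoms kept in the convolution grid.
#' @return List with `T_obs`, `p_combined`, `K`, `method = "exact"`.
#' @export
combine_exact <- function(p_values, supports, cap = 1e6) {
  stopifnot(length(p_values) == length(supports))
  if (any(p_values <= 0 | p_values > 1)) {
    abort("p-values must lie in (0, 1]", class = "pinnet_domain_error")
  }
  sups <- lapply(supports, .as_neglog)
  keep <- !vapply(sups, .is_degenerate, logical(1))
  sups <- sups[keep]
  T_obs <- sum(-log(p_values[keep]))
  if (length(sups) == 0) {
    return(list(T_obs = 0, p_combined = 1, K = 0L, method = "exact"))
  }
  grid_t <- 0; grid_m <- 1
  for (sup in sups) {
    t_new <- as.vector(outer(grid_t, sup$t, `+`))
    m_new <- as.vector(outer(grid_m, sup$mass, `*`))
    o <- order(t_new)
    t_new <- t_new[o]; m_new <- m_new[o]
    # merge atoms within relative tolerance
    if (length(t_new) > 1) {
      tol <- 1e-9 * pmax(t_new[-1], 1)
      grp <- cumsum(c(TRUE, diff(t_new) > tol))
      mm <- as.numeric(rowsum(m_new, grp))
      tt <- as.numeric(rowsum(t_new * m_new, grp)) / pmax(mm, 1e-300)
      t_new <- tt
      m_new <- mm
    }
    grid_t <- t_new; grid_m <- m_new
    if (length(grid_t) > cap) {
      abort("Exact convolution grid exceeds capacity; use a gamma variant",
        class = "pinnet_capacity_error")
    }
  }
  tol_obs <- 1e-9 * max(T_obs, 1)
  p <- sum(grid_m[grid_t >= T_obs - tol_obs])
  list(T_obs = T_obs, p_combined = min(max(p, 0), 1), K = length(sups),
    method = "exact")
}

#' Regional combined p-values for all pairs
#'
#' Groups the per-plot test table by species pair and combines each tail's
#' local p-values across the pair's co-occurrence plots.
#'
#' @param tests Per-plot test table from [pair_plot_tests()].
#' @param variant `"gamma2"`, `"gamma3"` or `"exact"`.
#' @param tails Which tails to combine.
#' @param exact_cap Grid cap for the exact method.
#' @return Tibble with `species_i`, `species_j`, `tail`, `K` (plots whose
#'   support carries evidence), `n_plots` (co-occurrence plots), `T_obs`,
#'   `p_combined`, `method`.
#' @export
combine_pairs <- function(tests, variant = c("gamma2", "gamma3", "exact"),
                          tails = c("plus", "minus"), exact_cap = 1e6) {
  variant <- match.arg(variant)
  tails <- match.arg(tails, c("plus", "minus"), several.ok = TRUE)
  idx <- split(seq_len(nrow(tests)),
    paste(tests$species_i, tests$species_j, sep = "\r"))
  out <- vector("list", length(idx) * length(tails))
  ii <- 0L
  for (rows in idx) {
    si <- tests$species_i[rows[1]]; sj <- tests$species_j[rows[1]]
    for (tl in tails) {
      sups <- lapply(rows, function(r) .neglog_support(
        tests$n_is[r], tests$n_js[r], tests$N_s[r], tl))
      pv <- if (tl == "plus") tests$p_plus[rows] else tests$p_minus[rows]
      res <- if (variant == "exact") {
        combine_exact(pv, sups, cap = exact_cap)
      } else {
        combine_gamma(pv, sups, variant = variant)
      }
      ii <- ii + 1L
      out[[ii]] <- tibble(
        species_i = si, species_j = sj, tail = tl,
        K = res$K, n_plots = length(rows),
        T_obs = res$T_obs, p_combined = res$p_combined, method = res$method
      )
    }
  }
  arrange(bind_rows(out[seq_len(ii)]),
    .data$species_i, .data$species_j, .data$tail)
}

#' Minimum achievable combined p-value per pair
#'
#' Replaces every plot's observed p-value by the smallest value its margins
#' allow and recombines with the same method, yielding the best (smallest)
#' regional p-value the pair could ever reach given its abundances. This is
#' the quantity the detectability pre-filter screens.
#'
#' @inheritParams combine_pairs
#' @return Tibble with `species_i`, `species_j`, `tail`, `p_min_combined`.
#' @export
min_combined_pvalues <- function(tests, variant = c("gamma2", "gamma3", "exact"),
                                 tails = c("plus", "minus"), exact_cap = 1e6) {
  variant <- match.arg(variant)
  tails <- match.arg(tails, c("plus", "minus"), several.ok = TRUE)
  idx <- split(seq_len(nrow(tests)),
    paste(tests$species_i, tests$species_j, sep = "\r"))
  out <- vector("list", length(idx) * length(tails))
  ii <- 0L
  for (rows in idx) {
    si <- tests$species_i[rows[1]]; sj <- tests$species_j[rows[1]]
    for (tl in tails) {
      sups <- lapply(rows, function(r) .neglog_support(
        tests$n_is[r], tests$n_js[r], tests$N_s[r], tl))
      p_min <- vapply(sups, function(s) exp(-max(s$t)), numeric(1))
      res <- if (variant == "exact") {
        combine_exact(p_min, sups, cap = exact_cap)
      } else {
        combine_gamma(p_min, sups, variant = variant)
      }
      ii <- ii + 1L
      out[[ii]] <- tibble(species_i = si, species_j = sj, tail = tl,
        p_min_combined = res$p_combined)
    }
  }
  arrange(bind_rows(out[seq_len(ii)]),
    .data$species_i, .data$species_j, .data$tail)
}
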