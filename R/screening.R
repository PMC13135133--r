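#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (`p_(k) * m / k` with cumulative-minimum
#' monotonisation, clamped at 1, original order restored). Thin wrapper over
#' [stats::p.adjust()] kept as the single adjustment point of the pipeline.
#'
#' @param p Numeric p-values in (0, 1].
#' @return Adjusted values, same order as the input.
#' @export
bh_adjust <- function(p) {
  p.adjust(p, method = "BH")
}

#' Detectability pre-filter over species pairs
#'
#' A pair whose margins cannot produce a small combined p-value can never be
#' significant; testing it only dilutes the FDR correction. Per tail, the
#' minimum achievable combined p-value of every co-occurring pair is
#' BH-adjusted across pairs and only pairs with adjusted minimum strictly
#' below `alpha` are retained for testing. Locally rare pairs thus drop out
#' of the segregation tail and saturating pairs out of the aggregation tail.
#'
#' @param tests Per-plot test table from [pair_plot_tests()].
#' @param alpha Significance level in (0, 1).
#' @param variant Combination method, see [combine_pairs()].
#' @return Tibble with `species_i`, `species_j`, `tail`, `p_min_combined`,
#'   `q_min`, `tested` (logical).
#' @export
prefilter_pairs <- function(tests, alpha = 0.05,
                            variant = c("gamma2", "gamma3", "exact")) {
  variant <- match.arg(variant)
  stopifnot(alpha > 0, alpha < 1)
  if (nrow(tests) == 0) {
    return(tibble(species_i = character(), species_j = character(),
      tail = character(), p_min_combined = numeric(), q_min = numeric(),
      tested = logical()))
  }
  min_combined_pvalues(tests, variant = variant) %>%
    group_by(.data$tail) %>%
    mutate(q_min = bh_adjust(.data$p_min_combined)) %>%
    ungroup() %>%
    mutate(tested = .data$q_min < alpha)
}

#' Regional significance calls
#'
#' BH-adjusts the combined p-values separately per tail (over the pairs
#' tested for that tail), flags significance at `q <= alpha`, and assigns
#' each pair a sign: `positive` (aggregation tail only), `negative`
#' (segregation only), `both`, or `none`.
#'
#' @param combined Long tibble from [combine_pairs()], restricted to tested
#'   pair/tail rows.
#' @param alpha Significance level.
#' @return Wide tibble, one row per pair: `species_i`, `species_j`,
#'   `n_plots`, `p_plus`, `p_minus`, `q_plus`, `q_minus`, `tested_plus`,
#'   `tested_minus`, `significant_plus`, `significant_minus`, `sign`.
#' @export
call_regional <- function(combined, alpha = 0.05) {
  if (nrow(combined) == 0) {
    return(tibble(species_i = character(), species_j = character(),
      n_plots = integer(), p_plus = numeric(), p_minus = numeric(),
      q_plus = numeric(), q_minus = numeric(), tested_plus = logical(),
      tested_minus = logical(), significant_plus = logical(),
      significant_minus = logical(), sign = character()))
  }
  long <- combined %>%
    group_by(.data$tail) %>%
    mutate(q = bh_adjust(.data$p_combined)) %>%
    ungroup() %>%
    mutate(significant = .data$q <= alpha)
  wide <- long %>%
    select("species_i", "species_j", "n_plots", "tail",
      p = "p_combined", q = "q", significant = "significant") %>%
    tidyr::pivot_wider(names_from = "tail",
      values_from = c("p", "q", "significant"),
      names_glue = "{.value}_{tail}")
  for (cl in c("p_plus", "p_minus", "q_plus", "q_minus")) {
    if (!cl %in% names(wide)) wide[[cl]] <- NA_real_
  }
  for (cl in c("significant_plus", "significant_minus")) {
    if (!cl %in% names(wide)) wide[[cl]] <- NA
  }
  wide %>%
    mutate(
      tested_plus = !is.na(.data$p_plus),
      tested_minus = !is.na(.data$p_minus),
      significant_plus = !is.na(.data$significant_plus) & .data$significant_plus,
      significant_minus = !is.na(.data$significant_minus) & .data$significant_minus,
      sign = dplyr::case_when(
        .data$significant_plus & .data$significant_minus ~ "both",
        .data$significant_plus ~ "positive",
        .data$significant_minus ~ "negative",
        TRUE ~ "none"
      )
    ) %>%
    select("species_i", "species_j", "n_plots", "p_plus", "p_minus",
      "q_plus", "q_minus", "tested_plus", "tested_minus",
      "significant_plus", "significant_minus", "sign") %>%
    arrange(.data$species_i, .data$species_j)
}

#' Full screening stage: pre-filter, combine, call
#'
#' Runs the detectability pre-filter, combines the retained pairs' local
#' p-values per tail, applies per-tail BH over the tested pairs and returns
#' the regional association calls. The returned tibble carries a `summary`
#' attribute with the stage counts (co-occurring pairs, tested and
#' significant per tail).
#'
#' @inheritParams prefilter_pairs
#' @param exact_cap Grid cap when `variant = "exact"`.
#' @return Association calls as in [call_regional()]; pairs excluded by the
#'   pre-filter appear with `NA` p-values and `sign = "none"`.
#' @export
screen_associations <- function(tests, alpha = 0.05,
                                variant = c("gamma2", "gamma3", "exact"),
                                exact_cap = 1e6) {
  variant <- match.arg(variant)
  pf <- prefilter_pairs(tests, alpha = alpha, variant = variant)
  if (nrow(pf) == 0) {
    calls <- call_regional(pf[0, c("species_i", "species_j")], alpha = alpha)
    attr(calls, "summary") <- list(
      alpha = alpha, variant = variant, n_cooccurring_pairs = 0L,
      n_tested_plus = 0L, n_tested_minus = 0L, n_significant_plus = 0L,
      n_significant_minus = 0L, n_sign_both = 0L
    )
    return(calls)
  }
  tested <- pf %>% filter(.data$tested)
  combined_parts <- lapply(c("plus", "minus"), function(tl) {
    sel <- tested %>% filter(.data$tail == tl)
    if (nrow(sel) == 0) return(NULL)
    sub <- semi_join(tests, sel, by = c("species_i", "species_j"))
    combine_pairs(sub, variant = variant, tails = tl, exact_cap = exact_cap)
  })
  combined <- bind_rows(combined_parts)
  calls <- call_regional(combined, alpha = alpha)

  all_pairs <- pf %>% distinct(.data$species_i, .data$species_j)
  missing <- anti_join(all_pairs, calls, by = c("species_i", "species_j"))
  if (nrow(missing) > 0) {
    n_pl <- tests %>%
      count(.data$species_i, .data$species_j, name = "n_plots")
    missing <- missing %>%
      left_join(n_pl, by = c("species_i", "species_j")) %>%
      mutate(p_plus = NA_real_, p_minus = NA_real_, q_plus = NA_real_,
        q_minus = NA_real_, tested_plus = FALSE, tested_minus = FALSE,
        significant_plus = FALSE, significant_minus = FALSE, sign = "none")
    calls <- bind_rows(calls, missing) %>%
      arrange(.data$species_i, .data$species_j)
  }
  # a pair can be tested for one tail only; reflect pre-filter outcome
  pf_wide <- pf %>%
    select("species_i", "species_j", "tail", "tested") %>%
    tidyr::pivot_wider(names_from = "tail", values_from = "tested",
      names_prefix = "pf_")
  calls <- calls %>%
    left_join(pf_wide, by = c("species_i", "species_j")) %>%
    mutate(
      tested_plus = .data$tested_plus & .data$pf_plus,
      tested_minus = .data$tested_minus & .data$pf_minus
    ) %>%
    select(-"pf_plus", -"pf_minus")
  attr(calls, "summary") <- list(
    alpha = alpha, variant = variant,
    n_cooccurring_pairs = nrow(all_pairs),
    n_tested_plus = sum(calls$tested_plus),
    n_tested_minus = sum(calls$tested_minus),
    n_significant_plus = sum(calls$significant_plus),
    n_significant_minus = sum(calls$significant_minus),
    n_sign_both = sum(calls$sign == "both")
  )
  calls
}

#' Discrete Benjamini-Hochberg step-up for heterogeneous discrete tests
#'
#' Step-up procedure whose critical constants exploit the attainable-value
#' distributions of the individual tests: candidate thresholds are the union
#' of attainable p-values, and the k-th critical constant is the largest
#' attainable `t` with `sum_i F_i(t) <= k * alpha`, where `F_i` is the null
#' CDF of test i's p-value. With continuous (uniform) supports this reduces
#' exactly to classical BH; with coarse supports it never rejects fewer
#' tests.
#'
#' @param p Observed p-values.
#' @param supports List of p-value supports (tibbles with `value`, `mass`),
#'   one per test, in the same order.
#' @param alpha Target FDR level.
#' @return Logical vector: which tests are rejected.
#' @export
discrete_bh <- function(p, supports, alpha = 0.05) {
  m <- length(p)
  stopifnot(length(supports) == m)
  if (m == 0) return(logical(0))
  cand <- sort(unique(unlist(lapply(supports, function(s) s$value))))
  cand <- cand[cand <= 1]
  # F_i evaluated at every candidate threshold
  Fsum <- rep(0, length(cand))
  for (s in supports) {
    cdf <- cumsum(s$mass)
    idx <- findInterval(cand * (1 + 1e-12), s$value)
    Fsum <- Fsum + ifelse(idx == 0, 0, cdf[pmax(idx, 1)])
  }
  tau <- vapply(seq_len(m), function(k) {
    ok <- which(Fsum <= k * alpha)
    if (length(ok) == 0) 0 else cand[max(ok)]
  }, numeric(1))
  o <- order(p)
  ps <- p[o]
  ks <- which(ps <= tau + 1e-15)
  reject <- logical(m)
  if (length(ks) > 0) {
    k_star <- max(ks)
    reject[o[seq_len(k_star)]] <- TRUE
  }
  reject
}

#' Plots contributing to a regional association
#'
#' For each regionally significant pair and tail, runs the discrete BH
#' step-up over the pair's per-plot p-values (with their hypergeometric
#' supports); the rejected plots are the ones contributing local evidence to
#' the regional pattern. Defined post hoc: requesting it for a pair that is
#' not significant in that tail is a contract error.
#'
#' @param associations Calls from [screen_associations()].
#' @param tests Per-plot test table from [pair_plot_tests()].
#' @param alpha Target FDR level for the per-plot step-up.
#' @param pairs Optional tibble (`species_i`, `species_j`) restricting the
#'   pairs processed; all requested pairs must be significant in at least
#'   one tail.
#' @return `associations` with list columns `contributing_plots_plus` and
#'   `contributing_plots_minus` (character vectors of plot ids; `NULL` for
#'   tails without a significant call).
#' @export
contributing_plots <- function(associations, tests, alpha = 0.05,
                               pairs = NULL) {
  if (!is.null(pairs)) {
    sel <- semi_join(associations, pairs, by = c("species_i", "species_j"))
    if (any(sel$sign == "none") || nrow(sel) < nrow(distinct(pairs))) {
      abort("contributing_plots is defined post hoc: all requested pairs must be regionally significant",
        class = "pinnet_contract_error")
    }
    associations <- sel
  }
  key <- paste(tests$species_i, tests$species_j, sep = "\r")
  idx <- split(seq_len(nrow(tests)), key)
  one_tail <- function(rows, tl) {
    sups <- lapply(rows, function(r) pvalue_support(
      tests$n_is[r], tests$n_js[r], tests$N_s[r], tl))
    pv <- if (tl == "plus") tests$p_plus[rows] else tests$p_minus[rows]
    rej <- discrete_bh(pv, sups, alpha = alpha)
    tests$plot_id[rows][rej]
  }
  plus <- vector("list", nrow(associations))
  minus <- vector("list", nrow(associations))
  for (i in seq_len(nrow(associations))) {
    rows <- idx[[paste(associations$species_i[i], associations$species_j[i],
      sep = "\r")]]
    if (isTRUE(associations$significant_plus[i])) {
      plus[[i]] <- one_tail(rows, "plus")
    }
    if (isTRUE(associations$significant_minus[i])) {
      minus[[i]] <- one_tail(rows, "minus")
    }
  }
  associations$contributing_plots_plus <- plus
  associations$contributing_plots_minus <- minus
  associations
}

#' Count locally significant associations per plot
#'
#' The number of (pair, tail) local associations attributed to each plot by
#' [contributing_plots()]; this is the response of the abiotic
#' association-richness model.
#'
#' @param associations Output of [contributing_plots()].
#' @param plot_ids Optional character vector of all plot ids, so plots with
#'   zero local associations appear with `n_asso = 0`.
#' @return Tibble with `plot_id`, `n_asso`.
#' @export
local_association_counts <- function(associations, plot_ids = NULL) {
  all_plots <- c(
    unlist(associations$contributing_plots_plus),
    unlist(associations$contributing_plots_minus)
  )
  counts <- tibble(plot_id = all_plots) %>%
    count(.data$plot_id, name = "n_asso")
  if (!is.null(plot_ids)) {
    counts <- tibble(plot_id = plot_ids) %>%
      left_join(counts, by = "plot_id") %>%
      mutate(n_asso = dplyr::coalesce(.data$n_asso, 0L))
  }
  counts
}
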