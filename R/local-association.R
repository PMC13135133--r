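#' One-tailed hypergeometric p-values for co-location
#'
#' Within one plot, the number of pinpoints shared by two species under
#' random (exchangeable) allocation of their occupied pinpoints follows a
#' hypergeometric law: `X ~ Hypergeometric(N_s, n_is, n_js)`. The
#' aggregation p-value is the upper tail `P(X >= n_ijs)` and the segregation
#' p-value the lower tail `P(X <= n_ijs)` — the two one-tailed Fisher exact
#' tests. Tails are exact sums over the support; no continuity or mid-p
#' correction is applied (the downstream combination step requires valid,
#' superuniform p-values).
#'
#' All arguments are vectorised and recycled.
#'
#' @param n_ijs Observed co-location count(s).
#' @param n_is,n_js Numbers of pinpoints occupied by each species.
#' @param N_s Number of pinpoints in the plot.
#' @return Tibble with columns `p_plus` (aggregation) and `p_minus`
#'   (segregation), both in (0, 1].
#' @examples
#' hypergeom_pvalues(2, 2, 2, 4) # p_plus = 1/6
#' @export
hypergeom_pvalues <- function(n_ijs, n_is, n_js, N_s) {
  m <- max(length(n_ijs), length(n_is), length(n_js), length(N_s))
  n_ijs <- rep_len(n_ijs, m); n_is <- rep_len(n_is, m)
  n_js <- rep_len(n_js, m); N_s <- rep_len(N_s, m)
  check_margins(n_is, n_js, N_s)
  k_min <- pmax(0, n_is + n_js - N_s)
  k_max <- pmin(n_is, n_js)
  if (any(n_ijs < k_min | n_ijs > k_max)) {
    abort("n_ijs outside the hypergeometric support",
      class = "pinnet_domain_error")
  }
  tibble(
    p_plus = phyper(n_ijs - 1, n_is, N_s - n_is, n_js, lower.tail = FALSE),
    p_minus = phyper(n_ijs, n_is, N_s - n_is, n_js)
  )
}

check_margins <- function(n_is, n_js, N_s) {
  if (any(N_s < 1) || any(n_is < 0) || any(n_js < 0) ||
      any(n_is > N_s) || any(n_js > N_s)) {
    abort("Invalid margins: need 0 <= n_is, n_js <= N_s",
      class = "pinnet_domain_error")
  }
  invisible(NULL)
}

#' Attainable p-values of a one-tailed hypergeometric test
#'
#' A discrete test can only produce the p-values attached to the points of
#' its support; this support, with the null mass of each attainable value,
#' drives both the evidence-combination null and the discrete FDR step.
#' Duplicate p-values (possible in degenerate margins) are merged.
#'
#' @inheritParams hypergeom_pvalues
#' @param tail `"plus"` (aggregation, upper tail) or `"minus"`.
#' @return Tibble with `value` (strictly increasing attainable p-values in
#'   (0, 1]) and `mass` (null probabilities summing to 1).
#' @export
pvalue_support <- function(n_is, n_js, N_s, tail = c("plus", "minus")) {
  tail <- match.arg(tail)
  check_margins(n_is, n_js, N_s)
  k <- seq.int(max(0, n_is + n_js - N_s), min(n_is, n_js))
  mass <- dhyper(k, n_is, N_s - n_is, n_js)
  value <- if (tail == "plus") {
    phyper(k - 1, n_is, N_s - n_is, n_js, lower.tail = FALSE)
  } else {
    phyper(k, n_is, N_s - n_is, n_js)
  }
  o <- order(value)
  value <- value[o]; mass <- mass[o]
  # merge numerically tied attainable values
  grp <- cumsum(c(TRUE, diff(value) > 1e-15 * pmax(value[-1], 1e-300)))
  tibble(
    value = as.numeric(tapply(value, grp, max)),
    mass = as.numeric(tapply(mass, grp, sum))
  )
}

#' Minimum achievable p-values given margins
#'
#' The smallest p-value a pair can possibly produce in a plot, given the two
#' species' abundances: for aggregation it is attained when the rarer
#' species lies entirely on the other's pinpoints
#' (`P(X = min(n_is, n_js))`), for segregation when overlap is at its floor
#' (`P(X = max(0, n_is + n_js - N_s))`). Locally rare pairs therefore cannot
#' show detectable segregation, nor saturating pairs detectable aggregation;
#' the screening stage builds its detectability pre-filter on these values.
#'
#' Vectorised over margins.
#'
#' @inheritParams hypergeom_pvalues
#' @return Tibble with `p_min_plus`, `p_min_minus`.
#' @examples
#' min_achievable_pvalues(3, 3, 300) # segregation undetectable (~0.97)
#' @export
min_achievable_pvalues <- function(n_is, n_js, N_s) {
  m <- max(length(n_is), length(n_js), length(N_s))
  n_is <- rep_len(n_is, m); n_js <- rep_len(n_js, m); N_s <- rep_len(N_s, m)
  check_margins(n_is, n_js, N_s)
  k_min <- pmax(0, n_is + n_js - N_s)
  k_max <- pmin(n_is, n_js)
  tibble(
    p_min_plus = dhyper(k_max, n_is, N_s - n_is, n_js),
    p_min_minus = dhyper(k_min, n_is, N_s - n_is, n_js)
  )
}

#' Per-plot exact tests for every co-occurring pair
#'
#' Runs both one-tailed hypergeometric tests for each species pair in each
#' plot where the two species co-occur. Co-location counts are obtained from
#' the binary plot occupancy matrix.
#'
#' @param survey A `pin_survey`.
#' @param pairs Optional subset of pairs (tibble with `species_i`,
#'   `species_j`); defaults to all co-occurring pairs.
#' @return Tibble with one row per pair per shared plot: `species_i`,
#'   `species_j`, `plot_id`, `n_ijs`, `n_is`, `n_js`, `N_s`, `p_plus`,
#'   `p_minus`.
#' @export
pair_plot_tests <- function(survey, pairs = NULL) {
  stopifnot(inherits(survey, "pin_survey"))
  recs <- survey$records
  if (nrow(recs) == 0) {
    return(tibble(species_i = character(), species_j = character(),
      plot_id = character(), n_ijs = integer(), n_is = integer(),
      n_js = integer(), N_s = integer(),
      p_plus = numeric(), p_minus = numeric()))
  }
  out <- vector("list", nrow(survey$plots))
  for (pi in seq_len(nrow(survey$plots))) {
    pid <- survey$plots$plot_id[pi]
    N_s <- survey$plots$n_pinpoints[pi]
    sub <- recs[recs$plot_id == pid, ]
    if (nrow(sub) == 0) next
    sp <- sort(unique(sub$species_id))
    if (length(sp) < 2) next
    M <- matrix(0L, nrow = length(sp), ncol = N_s,
      dimnames = list(sp, NULL))
    M[cbind(match(sub$species_id, sp), sub$pinpoint_id + 1L)] <- 1L
    co <- tcrossprod(M)
    ns <- rowSums(M)
    idx <- which(upper.tri(co), arr.ind = TRUE)
    out[[pi]] <- tibble(
      species_i = sp[idx[, 1]],
      species_j = sp[idx[, 2]],
      plot_id = pid,
      n_ijs = as.integer(co[idx]),
      n_is = as.integer(ns[idx[, 1]]),
      n_js = as.integer(ns[idx[, 2]]),
      N_s = as.integer(N_s)
    )
  }
  res <- bind_rows(out)
  if (!is.null(pairs)) {
    res <- semi_join(res, pairs, by = c("species_i", "species_j"))
  }
  pv <- hypergeom_pvalues(res$n_ijs, res$n_is, res$n_js, res$N_s)
  res$p_plus <- pv$p_plus
  res$p_minus <- pv$p_minus
  arrange(res, .data$species_i, .data$species_j, .data$plot_id)
}
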