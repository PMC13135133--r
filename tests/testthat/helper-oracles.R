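# Independent oracles used across test files.

# Exact tail probabilities by combinatorial enumeration over placements:
# P(X >= k) = sum_j C(n_j, j) C(N - n_j, n_i - j) / C(N, n_i), j = k..min.
# Independent of phyper/dhyper.
enum_tail_plus <- function(k, n_i, n_j, N) {
  js <- k:min(n_i, n_j)
  sum(choose(n_j, js) * choose(N - n_j, n_i - js)) / choose(N, n_i)
}

enum_tail_minus <- function(k, n_i, n_j, N) {
  js <- max(0, n_i + n_j - N):k
  sum(choose(n_j, js) * choose(N - n_j, n_i - js)) / choose(N, n_i)
}

# Brute-force combined p-value: full enumeration of the joint outcome
# space of the per-stratum -log p distributions (no grid compaction).
enum_combined_p <- function(p_obs, supports) {
  keep <- vapply(supports, function(s) {
    !(nrow(s) == 1 && abs(s$value[1] - 1) < 1e-12)
  }, logical(1))
  supports <- supports[keep]
  p_obs <- p_obs[keep]
  if (length(supports) == 0) return(1)
  T_obs <- sum(-log(p_obs))
  grids <- lapply(supports, function(s) seq_len(nrow(s)))
  combos <- expand.grid(grids)
  total <- 0
  for (r in seq_len(nrow(combos))) {
    tt <- 0; mm <- 1
    for (s in seq_along(supports)) {
      i <- combos[r, s]
      tt <- tt - log(supports[[s]]$value[i])
      mm <- mm * supports[[s]]$mass[i]
    }
    if (tt >= T_obs - 1e-9 * max(T_obs, 1)) total <- total + mm
  }
  total
}

# random valid margins with compact supports
random_margins <- function(N_max = 40, n_max = 12) {
  N <- sample(8:N_max, 1)
  n_i <- sample.int(min(n_max, N - 1), 1)
  n_j <- sample.int(min(n_max, N - 1), 1)
  list(n_i = n_i, n_j = n_j, N = N)
}

# tiny hand-built survey: A and B share pinpoint 0 in P1
tiny_survey <- function() {
  as_survey(
    data.frame(
      plot_id = c("P1", "P1", "P1", "P2", "P2"),
      pinpoint_id = c(0L, 0L, 1L, 2L, 3L),
      species_id = c("A", "B", "A", "A", "B")
    ),
    n_pinpoints = 300
  )
}

# classical BH rejection set (step-up at level alpha), independent of
# p.adjust
bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ks <- which(p[o] <= alpha * seq_len(m) / m)
  rej <- logical(m)
  if (length(ks) > 0) rej[o[seq_len(max(ks))]] <- TRUE
  rej
}

adjusted_rand <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_ind <- si * sj / n2
  (sij - exp_ind) / ((si + sj) / 2 - exp_ind)
}

# safe single draw from a vector (no 1:x surprise on scalars)
sample1 <- function(x) x[sample.int(length(x), 1)]
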