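#' Fit a Bernoulli stochastic block model
#'
#' Partitions the species of the (unsigned) association network into blocks
#' sharing a common connection profile: conditional on block memberships,
#' edges are independent Bernoulli draws with block-pair probabilities
#' `Pi`. The model is fitted by variational EM (mean-field) with a spectral
#' initialisation plus random restarts, separately for each candidate
#' number of blocks; the number of blocks is selected by the integrated
#' completed likelihood (ICL). Blocks are relabelled in decreasing
#' mean-degree order and, when the selected K is 3, named
#' `core` / `subordinate` / `peripheral`; otherwise blocks are reported by
#' rank only.
#'
#' @param x A `pin_network`, an igraph object, or a symmetric 0/1 adjacency
#'   matrix (signs, if any, are ignored: the model is binary).
#' @param K_range Candidate block counts (subset of 1..10).
#' @param n_restarts Random restarts per K, in addition to the spectral
#'   initialisation.
#' @param seed Integer seed.
#' @param max_iter,tol Maximum VEM sweeps and ELBO change tolerance.
#' @return A `pin_sbm` object: list with `K`, `memberships` (tibble
#'   `species_id`, `block`, `role`), `Pi`, `proportions`, `icl` (tibble of
#'   ICL per K), `block_summary` (per-block mean degree with SE and
#'   within-block connectance; `NA` and a flag when a block has fewer than
#'   two members) and `tau` (posterior membership probabilities).
#' @export
fit_sbm <- function(x, K_range = 1:6, n_restarts = 5, seed = 1,
                    max_iter = 200, tol = 1e-8) {
  X <- .as_adjacency(x)
  n <- nrow(X)
  if (n == 0) abort("Empty network", class = "pinnet_domain_error")
  if (any(K_range < 1) || any(K_range > 10)) {
    abort("K_range must lie within 1..10", class = "pinnet_domain_error")
  }
  K_range <- sort(unique(as.integer(K_range)))
  K_range <- K_range[K_range <= n]
  set.seed(seed)
  fits <- lapply(K_range, function(K) {
    .sbm_best_fit(X, K, n_restarts = n_restarts, max_iter = max_iter,
      tol = tol)
  })
  icl <- vapply(fits, function(f) f$icl, numeric(1))
  best <- which.max(icl)
  fit <- fits[[best]]
  K <- K_range[best]

  z <- fit$z
  deg <- rowSums(X)
  mean_deg <- tapply(deg, factor(z, levels = seq_len(K)), mean)
  ord <- order(-ifelse(is.na(mean_deg), -Inf, mean_deg))
  relabel <- match(seq_len(K), ord)
  z_new <- relabel[z]
  Pi <- fit$Pi[ord, ord, drop = FALSE]
  tau <- fit$tau[, ord, drop = FALSE]

  roles <- if (K == 3) c("core", "subordinate", "peripheral") else
    paste0("block_", seq_len(K))
  species <- rownames(X) %||% as.character(seq_len(n))

  block_summary <- lapply(seq_len(K), function(b) {
    members <- which(z_new == b)
    nb <- length(members)
    within_possible <- nb * (nb - 1) / 2
    within_edges <- if (nb >= 2) sum(X[members, members]) / 2 else NA_real_
    tibble(
      block = b, role = roles[b], n_species = nb,
      mean_degree = if (nb > 0) mean(deg[members]) else NA_real_,
      se_degree = if (nb > 1) sd(deg[members]) / sqrt(nb) else NA_real_,
      within_connectance = if (nb >= 2) within_edges / within_possible
        else NA_real_,
      within_defined = nb >= 2
    )
  })

  structure(list(
    K = K,
    memberships = tibble(species_id = species, block = z_new,
      role = roles[z_new]),
    Pi = Pi,
    proportions = as.numeric(table(factor(z_new, levels = seq_len(K)))) / n,
    icl = tibble(K = K_range, icl = icl),
    block_summary = bind_rows(block_summary),
    tau = tau,
    n_nodes = n
  ), class = "pin_sbm")
}

.as_adjacency <- function(x) {
  if (inherits(x, "pin_network")) {
    X <- as.matrix(igraph::as_adjacency_matrix(x$graph))
  } else if (inherits(x, "igraph")) {
    X <- as.matrix(igraph::as_adjacency_matrix(x))
  } else {
    X <- as.matrix(x)
  }
  X <- (X != 0) * 1
  diag(X) <- 0
  if (!isSymmetric(unname(X))) {
    abort("Adjacency must be symmetric (undirected network)",
      class = "pinnet_domain_error")
  }
  X
}

.sbm_best_fit <- function(X, K, n_restarts, max_iter, tol) {
  n <- nrow(X)
  inits <- list(.sbm_init_spectral(X, K))
  for (r in seq_len(n_restarts)) {
    tau <- matrix(rexp(n * K), n, K)
    inits[[r + 1]] <- tau / rowSums(tau)
  }
  best <- NULL
  for (tau0 in inits) {
    fit <- .sbm_vem(X, tau0, max_iter = max_iter, tol = tol)
    if (is.null(best) || fit$icl > best$icl) best <- fit
  }
  best
}

.sbm_init_spectral <- function(X, K) {
  n <- nrow(X)
  if (K == 1) return(matrix(1, n, 1))
  ev <- eigen(X, symmetric = TRUE)
  take <- order(-abs(ev$values))[seq_len(min(K, n))]
  V <- ev$vectors[, take, drop = FALSE]
  cl <- tryCatch(
    kmeans(V, centers = K, nstart = 10)$cluster,
    error = function(e) sample.int(K, n, replace = TRUE)
  )
  tau <- matrix(0.05 / max(K - 1, 1), n, K)
  tau[cbind(seq_len(n), cl)] <- 0.95
  tau / rowSums(tau)
}

.sbm_vem <- function(X, tau, max_iter, tol) {
  n <- nrow(X); K <- ncol(tau)
  eps <- 1e-9
  elbo_old <- -Inf
  O <- 1 - diag(n) # off-diagonal indicator
  for (it in seq_len(max_iter)) {
    # M-step
    pi_k <- pmin(pmax(colMeans(tau), eps), 1)
    num <- t(tau) %*% X %*% tau
    den <- t(tau) %*% O %*% tau
    Pi <- pmin(pmax(num / pmax(den, eps), 1e-6), 1 - 1e-6)
    Pi <- (Pi + t(Pi)) / 2
    # E-step (one fixed-point sweep)
    A <- log(Pi / (1 - Pi))
    B <- log(1 - Pi)
    S <- matrix(colSums(tau), n, K, byrow = TRUE) - tau
    logtau <- matrix(log(pi_k), n, K, byrow = TRUE) +
      X %*% tau %*% t(A) + S %*% t(B)
    logtau <- logtau - apply(logtau, 1, max)
    tau_new <- exp(logtau)
    tau_new <- tau_new / rowSums(tau_new)
    tau_new <- pmin(pmax(tau_new, eps), 1)
    tau_new <- tau_new / rowSums(tau_new)
    elbo <- .sbm_elbo(X, tau_new, pi_k, Pi)
    delta <- abs(elbo - elbo_old)
    tau <- tau_new
    elbo_old <- elbo
    if (delta < tol) break
  }
  z <- max.col(tau, ties.method = "first")
  icl <- .sbm_icl(X, z, K)
  list(tau = tau, Pi = Pi, pi_k = pi_k, z = z, elbo = elbo_old, icl = icl)
}

.sbm_elbo <- function(X, tau, pi_k, Pi) {
  n <- nrow(X)
  A <- log(Pi / (1 - Pi)); B <- log(1 - Pi)
  S1 <- sum((X %*% tau %*% t(A)) * tau) / 2
  O_colsums <- matrix(colSums(tau), n, ncol(tau), byrow = TRUE) - tau
  S2 <- sum((O_colsums %*% t(B)) * tau) / 2
  S3 <- sum(tau %*% log(pi_k))
  S4 <- -sum(tau * log(pmax(tau, 1e-12)))
  S1 + S2 + S3 + S4
}

.sbm_icl <- function(X, z, K) {
  n <- nrow(X)
  # complete-data log-likelihood at hard labels with MLE parameters
  tab <- table(factor(z, levels = seq_len(K)))
  ll_z <- sum(tab * log(pmax(as.numeric(tab) / n, 1e-12)))
  ll_x <- 0
  for (k in seq_len(K)) {
    for (l in k:K) {
      ik <- which(z == k); il <- which(z == l)
      if (k == l) {
        m_pos <- length(ik) * (length(ik) - 1) / 2
        e <- if (length(ik) >= 2) sum(X[ik, ik]) / 2 else 0
      } else {
        m_pos <- length(ik) * length(il)
        e <- sum(X[ik, il, drop = FALSE])
      }
      if (m_pos > 0) {
        ph <- min(max(e / m_pos, 1e-9), 1 - 1e-9)
        ll_x <- ll_x + e * log(ph) + (m_pos - e) * log(1 - ph)
      }
    }
  }
  pen <- 0.5 * (K * (K + 1) / 2) * log(n * (n - 1) / 2) +
    0.5 * (K - 1) * log(n)
  ll_x + ll_z - pen
}

#' @export
print.pin_sbm <- function(x, ...) {
  cat("<pin_sbm> ", x$n_nodes, " species in ", x$K, " block(s); ICL = ",
    signif(max(x$icl$icl), 6), "\n", sep = "")
  print(x$block_summary)
  invisible(x)
}

#' @describeIn fit_sbm Tidy block memberships (one row per species).
#' @param ... Unused.
#' @export
tidy.pin_sbm <- function(x, ...) {
  x$memberships
}

#' @describeIn fit_sbm One-row model summary (selected K, ICL, block sizes).
#' @export
glance.pin_sbm <- function(x, ...) {
  tibble(
    K = x$K,
    icl = max(x$icl$icl),
    n_nodes = x$n_nodes,
    largest_block = max(table(x$memberships$block))
  )
}
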