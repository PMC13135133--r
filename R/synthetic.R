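#' Configuration for synthetic point-intercept data
#'
#' Bundles the knobs of the generator: survey geometry (plots, pinpoints per
#' plot, species pool), the niche-driven abundance law along a latent 1-D
#' environmental gradient, planted pairwise interactions, trait syndromes
#' and the master seed. Defaults emulate the classical field design — 300
#' pinpoints per plot — at a pool size (20 plots, 80 species) where every
#' pipeline stage runs in seconds.
#'
#' Planted interactions tilt the placement of the second species of a pair
#' toward (theta > 0) or away from (theta < 0) the pinpoints occupied by the
#' first, via exponential tilting of sequential sampling without
#' replacement; `theta = 0` reduces exactly to the uniform null. An optional
#' `theta_slope` makes the tilt vary linearly with the plot's gradient
#' position, emulating context-dependent sign switches.
#'
#' @param n_plots Number of plots.
#' @param n_pinpoints Pinpoints per plot (300 in the classical design).
#' @param n_species Species pool size.
#' @param median_abundance Median occupied-pinpoint count at a species'
#'   niche optimum (log-normal across species, `sdlog = 0.5`).
#' @param niche_breadth Gaussian niche breadth on the unit gradient.
#' @param planted Tibble of planted interactions: `species_i`, `species_j`
#'   (ids like `"sp001"`), `theta`, optional `theta_slope`, optional
#'   `plots` list column restricting the affected plots.
#' @param trait_groups Tibble of trait syndromes: `group`, `n_species`, and
#'   a `meanlog` list column of per-trait log-scale means; optional
#'   `sdlog` (default 0.25) and `cor` (common within-group trait
#'   correlation, default 0.2).
#' @param block_sizes,block_Pi Planted block structure for network tests.
#' @param seed Master seed: fully determines every generated object.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_plots = 20, n_pinpoints = 300, n_species = 80,
                         median_abundance = 20, niche_breadth = 0.35,
                         planted = NULL, trait_groups = NULL,
                         block_sizes = c(30, 30),
                         block_Pi = matrix(c(0.75, 0.30, 0.30, 0.02), 2),
                         seed = 1) {
  if (!is.null(planted)) {
    planted <- as_tibble(planted)
    if (!all(c("species_i", "species_j", "theta") %in% names(planted))) {
      abort("planted needs species_i, species_j, theta",
        class = "pinnet_format_error")
    }
    if (any(!is.finite(planted$theta))) {
      abort("theta must be finite", class = "pinnet_domain_error")
    }
    sp_used <- c(planted$species_i, planted$species_j)
    if (anyDuplicated(sp_used)) {
      abort("A species may enter at most one planted pair",
        class = "pinnet_domain_error")
    }
  }
  structure(list(
    n_plots = n_plots, n_pinpoints = n_pinpoints, n_species = n_species,
    median_abundance = median_abundance, niche_breadth = niche_breadth,
    planted = planted, trait_groups = trait_groups,
    block_sizes = block_sizes, block_Pi = block_Pi, seed = seed
  ), class = "synth_config")
}

.species_ids <- function(n) sprintf("sp%03d", seq_len(n))
.plot_ids <- function(n) sprintf("plot%02d", seq_len(n))

#' Generate a point-intercept survey with known truth
#'
#' For each plot, species occupancy counts are Poisson draws around a
#' log-normal abundance modulated by a Gaussian niche on a latent unit
#' gradient (truncated at the number of pinpoints, with a warning if the
#' clamp binds). Non-interacting species are placed uniformly without
#' replacement over pinpoints; for each planted pair the first species is
#' placed uniformly and the second sequentially without replacement with
#' weight proportional to `exp(theta * [pinpoint occupied by the first])`.
#'
#' @param config A [synth_config()].
#' @return List with `survey` (a `pin_survey`), `truth` (list: planted pair
#'   tibble with signs, per-plot margins, niche parameters, gradient) —
#'   byte-identical across runs with the same config.
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n_sp <- config$n_species
  n_pl <- config$n_plots
  N <- config$n_pinpoints
  sp <- .species_ids(n_sp)
  pl <- .plot_ids(n_pl)
  gradient <- if (n_pl == 1) 0.5 else seq(0, 1, length.out = n_pl)

  optimum <- runif(n_sp)
  med <- rlnorm(n_sp, meanlog = log(config$median_abundance), sdlog = 0.5)
  lambda <- outer(med, gradient, function(m, e) m) *
    exp(-(outer(optimum, gradient, `-`))^2 / (2 * config$niche_breadth^2))
  counts <- matrix(rpois(n_sp * n_pl, lambda), n_sp, n_pl,
    dimnames = list(sp, pl))
  if (any(counts > N)) {
    warn("Occupancy counts clamped at the number of pinpoints")
    counts[counts > N] <- N
  }

  planted <- config$planted
  partner <- setNames(rep(NA_character_, n_sp), sp)
  if (!is.null(planted)) {
    bad <- setdiff(c(planted$species_i, planted$species_j), sp)
    if (length(bad) > 0) {
      abort(paste0("Planted species not in pool: ",
        paste(bad, collapse = ", ")), class = "pinnet_domain_error")
    }
    partner[planted$species_i] <- planted$species_j
  }

  recs <- vector("list", n_pl)
  for (s in seq_len(n_pl)) {
    placed <- list()
    occ <- list()
    # planted pairs first: i uniform, then j tilted toward/away from i
    if (!is.null(planted)) {
      for (r in seq_len(nrow(planted))) {
        i <- planted$species_i[r]; j <- planted$species_j[r]
        in_plot <- if ("plots" %in% names(planted) &&
            !is.null(planted$plots[[r]])) {
          pl[s] %in% planted$plots[[r]]
        } else {
          TRUE
        }
        th <- planted$theta[r]
        if ("theta_slope" %in% names(planted)) {
          th <- th + planted$theta_slope[r] * (gradient[s] - 0.5)
        }
        if (!in_plot) th <- 0
        ni <- counts[i, s]; nj <- counts[j, s]
        pts_i <- if (ni > 0) sample.int(N, ni) else integer(0)
        pts_j <- .tilted_sample(N, nj, pts_i, th)
        occ[[i]] <- pts_i; occ[[j]] <- pts_j
      }
    }
    for (i in sp[is.na(partner) & !(sp %in% names(occ))]) {
      ni <- counts[i, s]
      if (ni > 0) occ[[i]] <- sample.int(N, ni)
    }
    occ <- occ[lengths(occ) > 0]
    if (length(occ) > 0) {
      recs[[s]] <- tibble(
        plot_id = pl[s],
        pinpoint_id = unlist(occ, use.names = FALSE) - 1L,
        species_id = rep(names(occ), lengths(occ))
      )
    }
  }
  survey <- as_survey(bind_rows(recs),
    plots = tibble(plot_id = pl, n_pinpoints = N))
  truth <- list(
    planted = if (is.null(planted)) NULL else planted %>%
      mutate(sign = if_else(.data$theta >= 0, "positive", "negative")),
    margins = counts,
    gradient = tibble(plot_id = pl, gradient = gradient),
    optimum = tibble(species_id = sp, optimum = optimum,
      median_abundance = med)
  )
  list(survey = survey, truth = truth)
}

# sequential sampling without replacement, weight exp(theta * in_target);
# theta = 0 gives equal weights, i.e. exactly uniform sampling
.tilted_sample <- function(N, n, target, theta) {
  if (n == 0) return(integer(0))
  remaining <- seq_len(N)
  in_target <- remaining %in% target
  out <- integer(n)
  for (k in seq_len(n)) {
    w <- exp(theta * in_target)
    pick <- sample.int(length(remaining), 1, prob = w)
    out[k] <- remaining[pick]
    remaining <- remaining[-pick]
    in_target <- in_target[-pick]
  }
  out
}

#' Generate a species trait table with group syndromes
#'
#' Log-normal traits per group: each group has a vector of log-scale trait
#' means; within-group log-traits share a common correlation and standard
#' deviation. The default emulates a conservative core-group syndrome (high
#' LDMC, small leaves, short stature) against an unstructured background.
#'
#' @param config A [synth_config()] with a `trait_groups` tibble, or `NULL`
#'   to use the built-in two-group default sized to the species pool.
#' @return List with `traits` (tibble `species_id` + 5 traits) and `groups`
#'   (tibble `species_id`, `group`).
#' @export
generate_traits <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  tg <- config$trait_groups
  trait_names <- c("SLA", "LDMC", "leaf_area", "vegetative_height",
    "seed_mass")
  if (is.null(tg)) {
    n_core <- max(4L, round(config$n_species * 0.1))
    tg <- tibble(
      group = c("core", "background"),
      n_species = c(n_core, config$n_species - n_core),
      meanlog = list(
        c(SLA = log(12), LDMC = log(350), leaf_area = log(80),
          vegetative_height = log(0.12), seed_mass = log(0.8)),
        c(SLA = log(20), LDMC = log(220), leaf_area = log(300),
          vegetative_height = log(0.35), seed_mass = log(1.2))
      )
    )
  }
  sdlog <- if ("sdlog" %in% names(tg)) tg$sdlog else rep(0.25, nrow(tg))
  rho <- if ("cor" %in% names(tg)) tg$cor else rep(0.2, nrow(tg))
  total <- sum(tg$n_species)
  sp <- .species_ids(total)
  rows <- list(); labels <- character(0)
  offset <- 0L
  for (g in seq_len(nrow(tg))) {
    ng <- tg$n_species[g]
    mu <- tg$meanlog[[g]][trait_names]
    p <- length(trait_names)
    Sigma <- sdlog[g]^2 * ((1 - rho[g]) * diag(p) + rho[g])
    L <- tryCatch(chol(Sigma), error = function(e) {
      abort("Trait covariance is not positive-definite",
        class = "pinnet_domain_error")
    })
    Z <- matrix(rnorm(ng * p), ng, p) %*% L
    logtr <- sweep(Z, 2, mu, `+`)
    rows[[g]] <- exp(logtr)
    labels <- c(labels, rep(tg$group[g], ng))
    offset <- offset + ng
  }
  traits <- as_tibble(do.call(rbind, rows), .name_repair = "minimal")
  names(traits) <- trait_names
  traits <- bind_cols(tibble(species_id = sp), traits)
  list(traits = traits, groups = tibble(species_id = sp, group = labels))
}

#' Generate a plot-level environment table tied to the gradient
#'
#' Builds soil and climate covariates as monotone (noisy) functions of the
#' latent gradient used by [generate_survey()], so abundance-environment
#' relationships planted through niches are recoverable.
#'
#' @param config A [synth_config()].
#' @return Tibble, one row per plot: `plot_id`, `gradient`, `pH`, `N_pct`,
#'   `CN_ratio`, `organic_matter`, `GDD`, `FDD`, `ETP`, `T_mean`,
#'   `T_min_coldest`, `precipitation`.
#' @export
generate_environment <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 2L)
  n_pl <- config$n_plots
  g <- if (n_pl == 1) 0.5 else seq(0, 1, length.out = n_pl)
  tibble(
    plot_id = .plot_ids(n_pl),
    gradient = g,
    pH = 6.2 - 1.6 * g + rnorm(n_pl, 0, 0.2),
    N_pct = pmax(0.05, 0.3 + 0.5 * g + rnorm(n_pl, 0, 0.08)),
    CN_ratio = 12 + 6 * g + rnorm(n_pl, 0, 1),
    organic_matter = pmax(1, 8 + 25 * g + rnorm(n_pl, 0, 3)),
    GDD = 2200 - 1500 * g + rnorm(n_pl, 0, 100),
    FDD = -(50 + 500 * g + rnorm(n_pl, 0, 40)),
    ETP = 650 - 250 * g + rnorm(n_pl, 0, 30),
    T_mean = 9 - 6 * g + rnorm(n_pl, 0, 0.4),
    T_min_coldest = -2 - 8 * g + rnorm(n_pl, 0, 0.5),
    precipitation = 900 + 600 * g + rnorm(n_pl, 0, 60)
  )
}

#' Generate a block-structured random graph
#'
#' Undirected Bernoulli adjacency with planted block memberships: an edge
#' between nodes of blocks k and l appears with probability `Pi[k, l]`.
#' No self-loops.
#'
#' @param block_sizes Integer vector of block sizes.
#' @param Pi Symmetric block connection matrix with entries in `[0, 1]`.
#' @param seed Integer seed.
#' @return Adjacency matrix with a `membership` attribute.
#' @export
generate_block_network <- function(block_sizes, Pi, seed = 1) {
  Pi <- as.matrix(Pi)
  if (!isSymmetric(unname(Pi)) || any(Pi < 0) || any(Pi > 1)) {
    abort("Pi must be symmetric with entries in [0, 1]",
      class = "pinnet_domain_error")
  }
  stopifnot(length(block_sizes) == nrow(Pi))
  set.seed(seed)
  z <- rep(seq_along(block_sizes), block_sizes)
  n <- length(z)
  X <- matrix(0L, n, n)
  ut <- which(upper.tri(X), arr.ind = TRUE)
  pr <- Pi[cbind(z[ut[, 1]], z[ut[, 2]])]
  X[ut] <- rbinom(nrow(ut), 1, pr)
  X <- X + t(X)
  dimnames(X) <- list(.species_ids(n), .species_ids(n))
  attr(X, "membership") <- z
  X
}
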