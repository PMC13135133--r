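#' PCA of standardised traits
#'
#' Principal component analysis of centred and scaled (z-scored) traits,
#' i.e. an eigendecomposition of the trait correlation structure. Species
#' with incomplete traits are dropped.
#'
#' @param traits Tibble with `species_id` and numeric trait columns.
#' @param trait_cols Trait columns to use; defaults to all numeric columns.
#' @return A `pin_pca`: list with `scores` (tibble `species_id` + PCs),
#'   `loadings` (tibble `trait` + PCs), `variance` (tibble `component`,
#'   `variance_fraction`) and the underlying `prcomp` fit.
#' @export
trait_pca <- function(traits, trait_cols = NULL) {
  if (is.null(trait_cols)) {
    trait_cols <- names(traits)[vapply(traits, is.numeric, logical(1))]
  }
  X <- traits[stats::complete.cases(traits[trait_cols]), , drop = FALSE]
  if (nrow(X) < 3) {
    abort("Need at least 3 species with complete traits",
      class = "pinnet_domain_error")
  }
  M <- as.matrix(X[trait_cols])
  sds <- apply(M, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("Constant trait column(s): ",
      paste(trait_cols[sds == 0], collapse = ", ")),
      class = "pinnet_domain_error")
  }
  fit <- prcomp(M, center = TRUE, scale. = TRUE)
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(
    scores = bind_cols(tibble(species_id = X$species_id),
      as_tibble(fit$x)),
    loadings = bind_cols(tibble(trait = trait_cols),
      as_tibble(unclass(fit$rotation))),
    variance = tibble(component = colnames(fit$x), variance_fraction = vf),
    fit = fit
  ), class = "pin_pca")
}

#' @export
print.pin_pca <- function(x, ...) {
  cat("<pin_pca> ", nrow(x$scores), " species, ",
    nrow(x$loadings), " traits; PC1+PC2 = ",
    round(100 * sum(x$variance$variance_fraction[1:2])), "% variance\n",
    sep = "")
  invisible(x)
}

#' @describeIn trait_pca Tidy loadings (one row per trait per component).
#' @param x A `pin_pca`.
#' @param ... Unused.
#' @export
tidy.pin_pca <- function(x, ...) {
  x$loadings %>%
    tidyr::pivot_longer(-"trait", names_to = "component",
      values_to = "loading")
}

#' Pairwise PERMANOVA between group centroids
#'
#' For every unordered pair of groups with at least two members each, a
#' permutational MANOVA (via [vegan::adonis2()]) compares the two centroids
#' in the given coordinate space; pseudo-F comes from among/within sums of
#' squared distances and the p-value from label permutations with the
#' `(1 + exceedances)/(n_perm + 1)` convention. P-values are BH-adjusted
#' across group pairs. Groups with a single member are skipped with a
#' warning.
#'
#' @param x Numeric matrix/data frame of coordinates (rows = observations),
#'   or a `dist`.
#' @param groups Group labels, one per observation.
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutations.
#' @return Tibble with `group_1`, `group_2`, `n_1`, `n_2`, `pseudo_F`, `p`,
#'   `q`.
#' @export
pairwise_permanova <- function(x, groups, n_perm = 999, seed = 1) {
  d <- if (inherits(x, "dist")) x else dist(as.matrix(x))
  groups <- as.character(groups)
  stopifnot(length(groups) == attr(d, "Size"))
  sizes <- table(groups)
  usable <- names(sizes)[sizes >= 2]
  if (length(setdiff(names(sizes), usable)) > 0) {
    warn(paste0("Skipping single-member group(s): ",
      paste(setdiff(names(sizes), usable), collapse = ", ")))
  }
  if (length(usable) < 2) {
    abort("Need at least two groups with two or more members",
      class = "pinnet_domain_error")
  }
  combos <- utils::combn(sort(usable), 2)
  D <- as.matrix(d)
  set.seed(seed)
  out <- lapply(seq_len(ncol(combos)), function(i) {
    g1 <- combos[1, i]; g2 <- combos[2, i]
    keep <- groups %in% c(g1, g2)
    dat <- data.frame(g = factor(groups[keep]))
    fit <- vegan::adonis2(stats::as.dist(D[keep, keep]) ~ g, data = dat,
      permutations = n_perm)
    tibble(group_1 = g1, group_2 = g2,
      n_1 = sum(groups == g1), n_2 = sum(groups == g2),
      pseudo_F = fit$F[1], p = fit$`Pr(>F)`[1])
  })
  bind_rows(out) %>% mutate(q = bh_adjust(.data$p))
}

#' Functional distinctiveness and scarcity
#'
#' Within each plot, a species' functional distinctiveness is its
#' abundance-weighted mean trait distance to the co-occurring species:
#' `D_is = sum_{j != i} d_ij a_js / sum_{j != i} a_js`, with `d` the
#' Euclidean distance on z-scored traits rescaled to `[0, 1]` by the
#' observed maximum, and `a` relative abundances. Scarcity is
#' `S_is = exp(-N_p * ln(2) * a_is)` with `N_p` the plot richness, so a
#' species at the evenness abundance `1/N_p` scores 0.5 and rarer species
#' approach 1. Per-species values are averaged over occupied plots. A
#' species alone in a plot has undefined distinctiveness (`NA`, flagged);
#' species absent everywhere are dropped with a warning.
#'
#' @param traits Tibble with `species_id` and trait columns.
#' @param abundances Tibble with `plot_id`, `species_id`, `n` (occupied
#'   pinpoints), e.g. from [species_counts()].
#' @param trait_cols Traits used for the distance (default: all numeric);
#'   a single trait gives the scaled absolute-difference distance.
#' @return A `pin_rarity`: list with `per_plot` (tibble `plot_id`,
#'   `species_id`, `distinctiveness`, `scarcity`, `alone`) and `per_species`
#'   (means over occupied plots).
#' @export
functional_rarity <- function(traits, abundances, trait_cols = NULL) {
  if (is.null(trait_cols)) {
    trait_cols <- names(traits)[vapply(traits, is.numeric, logical(1))]
  }
  tr <- traits[stats::complete.cases(traits[trait_cols]), , drop = FALSE]
  absent <- setdiff(tr$species_id, abundances$species_id)
  if (length(absent) > 0) {
    warn(paste0(length(absent), " species absent from every plot excluded"))
    tr <- tr %>% filter(!.data$species_id %in% absent)
  }
  M <- as.matrix(tr[trait_cols])
  sds <- apply(M, 2, sd)
  sds[sds == 0 | is.na(sds)] <- 1 # constant traits carry no distance
  M <- scale(M, center = TRUE, scale = sds)
  D <- as.matrix(dist(M))
  mx <- max(D)
  if (mx > 0) D <- D / mx
  rownames(D) <- colnames(D) <- tr$species_id

  ab <- abundances %>% filter(.data$species_id %in% tr$species_id)
  per_plot <- ab %>%
    group_by(.data$plot_id) %>%
    group_modify(function(df, key) {
      a <- df$n / sum(df$n)
      Np <- nrow(df)
      sp <- df$species_id
      dist_i <- rep(NA_real_, Np)
      if (Np >= 2) {
        Dsub <- D[sp, sp, drop = FALSE]
        for (i in seq_len(Np)) {
          w <- a[-i]
          dist_i[i] <- sum(Dsub[i, -i] * w) / sum(w)
        }
      }
      tibble(species_id = sp,
        distinctiveness = dist_i,
        scarcity = exp(-Np * log(2) * a),
        alone = Np == 1)
    }) %>%
    ungroup()
  per_species <- per_plot %>%
    group_by(.data$species_id) %>%
    summarise(
      mean_distinctiveness = mean(.data$distinctiveness, na.rm = TRUE),
      mean_scarcity = mean(.data$scarcity),
      n_plots = dplyr::n(), .groups = "drop"
    )
  structure(list(per_plot = per_plot, per_species = per_species,
    trait_cols = trait_cols), class = "pin_rarity")
}

#' @export
print.pin_rarity <- function(x, ...) {
  cat("<pin_rarity> ", nrow(x$per_species), " species over ",
    dplyr::n_distinct(x$per_plot$plot_id), " plots; traits: ",
    paste(x$trait_cols, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Rank-based group contrasts
#'
#' Compares a per-species metric among network groups: pairwise two-sided
#' Wilcoxon rank-sum tests (BH-adjusted across group pairs), or one
#' Kruskal-Wallis test across all groups.
#'
#' @param data Tibble holding the metric and the group label.
#' @param value_col,group_col Column names (strings).
#' @param test `"wilcoxon"` (pairwise) or `"kruskal"` (global).
#' @return Tibble of test results.
#' @export
group_contrasts <- function(data, value_col, group_col,
                            test = c("wilcoxon", "kruskal")) {
  test <- match.arg(test)
  v <- data[[value_col]]
  g <- as.character(data[[group_col]])
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  if (test == "kruskal") {
    fit <- kruskal.test(v, factor(g))
    return(tibble(metric = value_col, statistic = unname(fit$statistic),
      df = unname(fit$parameter), p = fit$p.value))
  }
  lev <- sort(unique(g))
  combos <- utils::combn(lev, 2)
  out <- lapply(seq_len(ncol(combos)), function(i) {
    g1 <- combos[1, i]; g2 <- combos[2, i]
    fit <- wilcox.test(v[g == g1], v[g == g2], exact = FALSE)
    tibble(metric = value_col, group_1 = g1, group_2 = g2,
      statistic = unname(fit$statistic), p = fit$p.value)
  })
  bind_rows(out) %>% mutate(q = bh_adjust(.data$p))
}

#' Model local association richness from abiotic context
#'
#' Quasi-Poisson (log link) models of the number of locally significant
#' associations per plot. The baseline model uses the plot's total contact
#' count (`n_individuals`) alone; the full model adds abiotic covariates
#' and any stated interactions. Stepwise selection (both directions,
#' starting from the full model, `n_individuals` always retained) maximises
#' the adjusted deviance R-squared. Collinear covariate pairs above
#' |r| = 0.95 are refused with an error naming the pair, so the caller
#' drops one.
#'
#' @param data Tibble with the response, `n_individuals`, and covariates;
#'   one row per plot.
#' @param covariates Abiotic covariate names.
#' @param interactions Interaction terms as formula strings, e.g.
#'   `"n_individuals:ETP"`.
#' @param response Response column (default `n_asso`).
#' @param stepwise Run the adjusted-R2 stepwise search.
#' @return A `pin_richness` object: list with `baseline`, `full`,
#'   `selected` (glm fits), `r2` (tibble), `coefficients` (tidy tibble of
#'   the selected model), `terms_selected`, and `partition` (hierarchical
#'   partitioning of the selected model's terms).
#' @export
association_richness_model <- function(data, covariates,
                                       interactions = character(),
                                       response = "n_asso",
                                       stepwise = TRUE) {
  stopifnot(all(c(response, "n_individuals", covariates) %in% names(data)))
  if (length(covariates) >= 2) {
    cm <- stats::cor(data[covariates], use = "pairwise.complete.obs")
    cm[upper.tri(cm, diag = TRUE)] <- 0
    bad <- which(abs(cm) > 0.95, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      abort(paste0("Collinear covariates (|r| > 0.95): ",
        rownames(cm)[bad[1, 1]], " ~ ", colnames(cm)[bad[1, 2]],
        "; drop one of them"), class = "pinnet_collinearity_error")
    }
  }
  data <- data[stats::complete.cases(data[c(response, "n_individuals",
    covariates)]), , drop = FALSE]
  fam <- quasipoisson()
  base_f <- as.formula(paste(response, "~ n_individuals"))
  baseline <- glm(base_f, data = data, family = fam)
  all_terms <- c(covariates, interactions)
  full_f <- as.formula(paste(response, "~ n_individuals +",
    paste(all_terms, collapse = " + ")))
  full <- glm(full_f, data = data, family = fam)

  fit_terms <- function(terms) {
    f <- if (length(terms) == 0) base_f else
      as.formula(paste(response, "~ n_individuals +",
        paste(terms, collapse = " + ")))
    glm(f, data = data, family = fam)
  }
  selected_terms <- all_terms
  if (stepwise) {
    current <- all_terms
    best_r2 <- adjusted_deviance_r2(full)
    repeat {
      moves <- list()
      for (tm in current) moves[[length(moves) + 1]] <- setdiff(current, tm)
      for (tm in setdiff(all_terms, current)) {
        moves[[length(moves) + 1]] <- c(current, tm)
      }
      if (length(moves) == 0) break
      r2s <- vapply(moves, function(tms) {
        r2 <- tryCatch(adjusted_deviance_r2(fit_terms(tms)),
          error = function(e) NA_real_)
        if (is.finite(r2)) r2 else -Inf
      }, numeric(1))
      if (max(r2s) > best_r2 + 1e-10) {
        current <- moves[[which.max(r2s)]]
        best_r2 <- max(r2s)
      } else {
        break
      }
    }
    selected_terms <- current
  }
  selected <- fit_terms(selected_terms)
  cf <- summary(selected)$coefficients
  partition <- hierarchical_partition(data, response = response,
    terms = c("n_individuals", selected_terms))
  structure(list(
    baseline = baseline, full = full, selected = selected,
    terms_selected = selected_terms,
    r2 = tibble(
      model = c("baseline", "full", "selected"),
      adjusted_r2 = c(adjusted_deviance_r2(baseline),
        adjusted_deviance_r2(full), adjusted_deviance_r2(selected))
    ),
    coefficients = tibble(term = rownames(cf), estimate = cf[, 1],
      std_error = cf[, 2], p_value = cf[, 4]),
    partition = partition,
    dispersion = sum(residuals(selected, type = "pearson")^2) /
      selected$df.residual
  ), class = "pin_richness")
}

#' @export
print.pin_richness <- function(x, ...) {
  cat("<pin_richness> adjusted R2: baseline ",
    signif(x$r2$adjusted_r2[1], 3), " -> selected ",
    signif(x$r2$adjusted_r2[3], 3), " (terms: n_individuals",
    if (length(x$terms_selected)) paste0(", ",
      paste(x$terms_selected, collapse = ", ")), ")\n", sep = "")
  invisible(x)
}

#' @describeIn association_richness_model Tidy coefficient table of the
#'   selected model.
#' @param x A `pin_richness`.
#' @param ... Unused.
#' @export
tidy.pin_richness <- function(x, ...) {
  x$coefficients
}

#' @describeIn association_richness_model One-row fit summary.
#' @export
glance.pin_richness <- function(x, ...) {
  tibble(
    r2_baseline = x$r2$adjusted_r2[1],
    r2_full = x$r2$adjusted_r2[2],
    r2_selected = x$r2$adjusted_r2[3],
    dispersion = x$dispersion,
    n_terms = length(x$terms_selected) + 1L
  )
}

#' Hierarchical partitioning of explained variance
#'
#' Distributes the full model's adjusted deviance R-squared over its
#' predictors: each predictor's independent contribution is its average
#' incremental R-squared over all orderings, computed by all-subsets
#' averaging with per-hierarchy-level weights. Contributions sum exactly to
#' the full-model R-squared; shares are also given as percentages of it.
#' Capacity is capped at 8 predictors (2^8 model fits).
#'
#' @param data Model data (one row per plot).
#' @param response Response column name.
#' @param terms Predictor terms (may include interaction strings).
#' @param family GLM family (default quasi-Poisson).
#' @return Tibble with `term`, `independent` (R-squared units) and
#'   `share_pct` (percentage of the full-model R-squared).
#' @export
hierarchical_partition <- function(data, response, terms,
                                   family = quasipoisson()) {
  p <- length(terms)
  if (p > 8) {
    abort("Hierarchical partitioning capped at 8 predictors",
      class = "pinnet_capacity_error")
  }
  gof <- new.env()
  key <- function(s) paste0("k:", paste(sort(s), collapse = "|"))
  gof_of <- function(s) {
    k <- key(s)
    if (!is.null(gof[[k]])) return(gof[[k]])
    f <- if (length(s) == 0) as.formula(paste(response, "~ 1")) else
      as.formula(paste(response, "~", paste(s, collapse = " + ")))
    val <- adjusted_deviance_r2(glm(f, data = data, family = family))
    gof[[k]] <- val
    val
  }
  subsets <- lapply(0:p, function(h) {
    if (h == 0) list(character(0)) else
      apply(utils::combn(terms, h), 2, identity, simplify = FALSE)
  })
  indep <- setNames(numeric(p), terms)
  for (tm in terms) {
    total <- 0
    for (h in 0:(p - 1)) {
      incs <- vapply(subsets[[h + 1]], function(s) {
        if (tm %in% s) return(NA_real_)
        gof_of(c(s, tm)) - gof_of(s)
      }, numeric(1))
      incs <- incs[!is.na(incs)]
      total <- total + mean(incs) / p
    }
    indep[tm] <- total
  }
  full_r2 <- gof_of(terms)
  tibble(term = terms, independent = unname(indep),
    share_pct = 100 * unname(indep) / full_r2)
}
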