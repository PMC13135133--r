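#' Point-intercept survey collections
#'
#' A survey collection couples the presence records of a point-intercept
#' campaign (one row per plot x pinpoint x species contact) with a plot
#' manifest giving the number of sampling points per plot. Pinpoint indices
#' are 0-based and live in `[0, n_pinpoints)`; presence is binary per
#' (pinpoint, species), so duplicated input rows are collapsed. Several
#' species may contact the same pinpoint.
#'
#' @param records A data frame with columns `plot_id`, `pinpoint_id`,
#'   `species_id`; one row per presence record.
#' @param plots Optional plot manifest, a data frame with columns `plot_id`
#'   and `n_pinpoints`. When absent, `n_pinpoints` defaults to
#'   `max(pinpoint_id) + 1` per plot or to the `n_pinpoints` argument.
#' @param n_pinpoints Optional single number of pinpoints applied to every
#'   plot (the classical design uses 300).
#'
#' @return A `pin_survey` object: a list with tibbles `records` (collapsed,
#'   sorted) and `plots` (`plot_id`, `n_pinpoints`).
#' @examples
#' rec <- data.frame(
#'   plot_id = c("P1", "P1", "P1"),
#'   pinpoint_id = c(0L, 0L, 1L),
#'   species_id = c("A", "B", "A")
#' )
#' sv <- as_survey(rec, n_pinpoints = 300)
#' species_counts(sv)
#' @export
as_survey <- function(records, plots = NULL, n_pinpoints = NULL) {
  req <- c("plot_id", "pinpoint_id", "species_id")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Survey table lacks column(s): ", paste(missing_cols, collapse = ", ")
    ), class = "pinnet_format_error")
  }
  records <- tibble::as_tibble(records[req])
  records$plot_id <- as.character(records$plot_id)
  records$species_id <- as.character(records$species_id)
  records$pinpoint_id <- as.integer(records$pinpoint_id)
  records <- records %>%
    distinct() %>%
    arrange(.data$plot_id, .data$pinpoint_id, .data$species_id)

  if (is.null(plots)) {
    if (nrow(records) == 0) {
      plots <- tibble(plot_id = character(), n_pinpoints = integer())
    } else {
      plots <- records %>%
        group_by(.data$plot_id) %>%
        summarise(n_pinpoints = max(.data$pinpoint_id) + 1L, .groups = "drop")
      if (!is.null(n_pinpoints)) {
        plots$n_pinpoints <- as.integer(n_pinpoints)
      }
    }
  } else {
    if (!all(c("plot_id", "n_pinpoints") %in% names(plots))) {
      abort("Plot manifest needs columns plot_id, n_pinpoints",
        class = "pinnet_format_error")
    }
    plots <- tibble::as_tibble(plots[c("plot_id", "n_pinpoints")])
    plots$plot_id <- as.character(plots$plot_id)
    plots$n_pinpoints <- as.integer(plots$n_pinpoints)
    if (anyDuplicated(plots$plot_id)) {
      abort("Duplicated plot_id in manifest", class = "pinnet_validation_error")
    }
    unknown <- setdiff(unique(records$plot_id), plots$plot_id)
    if (length(unknown) > 0) {
      abort(paste0("Records reference plots absent from manifest: ",
        paste(unknown, collapse = ", ")), class = "pinnet_validation_error")
    }
  }

  chk <- records %>% left_join(plots, by = "plot_id")
  bad <- chk$pinpoint_id < 0L | chk$pinpoint_id >= chk$n_pinpoints
  if (any(bad)) {
    abort(paste0(
      "pinpoint_id outside [0, n_pinpoints) for ", sum(bad), " record(s)"
    ), class = "pinnet_validation_error")
  }

  structure(
    list(records = records, plots = arrange(plots, .data$plot_id)),
    class = "pin_survey"
  )
}

#' Read / write point-intercept survey tables
#'
#' TSV dialect, UTF-8, header row: `plot_id`, `pinpoint_id`, `species_id`.
#' An optional plot manifest TSV has columns `plot_id`, `n_pinpoints`.
#' `write_survey()` emits the collapsed record set in the same dialect, so
#' that read-write round-trips are exact.
#'
#' @param path Path to the survey TSV.
#' @param manifest_path Optional path to a plot-manifest TSV.
#' @inheritParams as_survey
#' @return `read_survey()` a `pin_survey`; `write_survey()` `path`, invisibly.
#' @export
read_survey <- function(path, manifest_path = NULL, n_pinpoints = NULL) {
  records <- readr::read_tsv(path, col_types = readr::cols(
    plot_id = readr::col_character(),
    pinpoint_id = readr::col_integer(),
    species_id = readr::col_character()
  ))
  plots <- NULL
  if (!is.null(manifest_path)) {
    plots <- readr::read_tsv(manifest_path, col_types = readr::cols(
      plot_id = readr::col_character(),
      n_pinpoints = readr::col_integer()
    ))
  }
  as_survey(records, plots = plots, n_pinpoints = n_pinpoints)
}

#' @rdname read_survey
#' @param survey A `pin_survey`.
#' @export
write_survey <- function(survey, path, manifest_path = NULL) {
  stopifnot(inherits(survey, "pin_survey"))
  readr::write_tsv(survey$records, path)
  if (!is.null(manifest_path)) readr::write_tsv(survey$plots, manifest_path)
  invisible(path)
}

#' @export
print.pin_survey <- function(x, ...) {
  cat("<pin_survey> ", nrow(x$plots), " plot(s), ",
    dplyr::n_distinct(x$records$species_id), " species, ",
    nrow(x$records), " presence records\n", sep = "")
  invisible(x)
}

#' Per-plot species occupancy counts
#'
#' Counts, for every plot and species, the number of pinpoints the species
#' occupies (`n_is`). The sum of counts within a plot equals the number of
#' distinct (pinpoint, species) records of that plot; it also defines the
#' plot-level "number of individuals" used by downstream abundance models.
#'
#' @param survey A `pin_survey`.
#' @return Tibble with `plot_id`, `species_id`, `n`, `n_pinpoints`.
#' @export
species_counts <- function(survey) {
  stopifnot(inherits(survey, "pin_survey"))
  survey$records %>%
    count(.data$plot_id, .data$species_id, name = "n") %>%
    left_join(survey$plots, by = "plot_id")
}

#' Plot-level total contact counts
#'
#' @param survey A `pin_survey`.
#' @return Tibble with `plot_id`, `n_individuals` (sum of per-species
#'   occupied-pinpoint counts) and `richness`.
#' @export
plot_totals <- function(survey) {
  species_counts(survey) %>%
    group_by(.data$plot_id) %>%
    summarise(
      n_individuals = sum(.data$n),
      richness = dplyr::n(),
      .groups = "drop"
    )
}

#' Co-occurring species pairs
#'
#' Two species co-occur when both are present (occupy at least one pinpoint)
#' in the same plot; the downstream association tests are run only in those
#' shared plots. Pairs sharing no plot are omitted.
#'
#' @param survey A `pin_survey`.
#' @return Tibble with `species_i`, `species_j` (`species_i < species_j`),
#'   `plot_ids` (list column of shared plots) and `n_plots`.
#' @export
cooccurring_pairs <- function(survey) {
  stopifnot(inherits(survey, "pin_survey"))
  pres <- species_counts(survey)
  if (nrow(pres) == 0) {
    return(tibble(species_i = character(), species_j = character(),
      plot_ids = list(), n_plots = integer()))
  }
  pairs <- inner_join(
    pres %>% select(plot_id = "plot_id", species_i = "species_id"),
    pres %>% select(plot_id = "plot_id", species_j = "species_id"),
    by = "plot_id", relationship = "many-to-many"
  ) %>%
    filter(.data$species_i < .data$species_j)
  pairs %>%
    group_by(.data$species_i, .data$species_j) %>%
    summarise(plot_ids = list(.data$plot_id), .groups = "drop") %>%
    mutate(n_plots = lengths(.data$plot_ids))
}

#' Read a plot-level environment table
#'
#' One row per plot; recognised columns are `plot_id`, soil descriptors
#' (`pH`, `N_pct`, `CN_ratio`, `organic_matter`) and climate summaries
#' (`GDD`, `FDD`, `ETP`, `T_mean`, `T_min_coldest`, `precipitation`).
#' Extra columns are kept. Missing values are allowed but flagged.
#'
#' @param path TSV path.
#' @return Tibble, one row per plot, with an `n_missing` column counting
#'   missing entries per row.
#' @export
read_environment <- function(path) {
  env <- readr::read_tsv(path, col_types = readr::cols(
    plot_id = readr::col_character(), .default = readr::col_double()
  ))
  if (!"plot_id" %in% names(env)) {
    abort("Environment table lacks plot_id", class = "pinnet_format_error")
  }
  if (anyDuplicated(env$plot_id)) {
    abort("Environment table must have one row per plot",
      class = "pinnet_validation_error")
  }
  if ("N_pct" %in% names(env) && any(env$N_pct < 0, na.rm = TRUE)) {
    abort("N_pct must be non-negative", class = "pinnet_validation_error")
  }
  env$n_missing <- rowSums(is.na(env))
  if (any(env$n_missing > 0)) {
    warn(paste0(sum(env$n_missing > 0), " plot(s) have missing environment values"))
  }
  env
}

#' Read a species trait table
#'
#' One row per species. Recognised traits: `SLA` (mm2/mg), `LDMC` (mg/g),
#' `leaf_area` (mm2), `vegetative_height` (m), `seed_mass` (mg); optional
#' CSR strategy coordinates `C`, `S`, `R` (fractions summing to 1).
#'
#' @param path TSV path.
#' @return Tibble keyed by `species_id`.
#' @export
read_traits <- function(path) {
  tr <- readr::read_tsv(path, col_types = readr::cols(
    species_id = readr::col_character(), .default = readr::col_double()
  ))
  if (!"species_id" %in% names(tr)) {
    abort("Trait table lacks species_id", class = "pinnet_format_error")
  }
  validate_traits(tr)
  tr
}

validate_traits <- function(tr) {
  trait_cols <- intersect(
    c("SLA", "LDMC", "leaf_area", "vegetative_height", "seed_mass"), names(tr)
  )
  for (cl in trait_cols) {
    if (any(tr[[cl]] <= 0, na.rm = TRUE)) {
      abort(paste0("Trait ", cl, " must be strictly positive where present"),
        class = "pinnet_validation_error")
    }
  }
  if (all(c("C", "S", "R") %in% names(tr))) {
    csr <- tr$C + tr$S + tr$R
    ok <- is.na(csr) | abs(csr - 1) <= 1e-9
    if (!all(ok)) {
      abort("CSR coordinates must sum to 1", class = "pinnet_validation_error")
    }
  }
  invisible(tr)
}
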