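# End-to-end orchestration: read a directory of Google-Trends-dialect CSVs
# (real exports or simulator output), impute, anchor, test, decompose, and
# emit the three study tables -- the global popularity ranking, the per-topic
# trend/seasonality table, and the per-country winner table -- plus metadata
# recording the processing decisions.

#' Analysis configuration
#'
#' @param input_dir directory of GT-dialect CSVs (see
#'   [simulate_world_csvs()] for the expected file names).
#' @param output_dir directory for CSV/JSON outputs; `NULL` to skip writing.
#' @param registry a `topic_registry`; defaults to [default_registry()].
#' @param reference reference topic id; defaults to the registry's.
#' @param period seasonal period in months.
#' @param alpha significance level.
#' @param min_topics low-volume exclusion threshold (positive topics per
#'   country).
#' @param precision report-mode decimals.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(input_dir, output_dir = NULL, registry = NULL,
                            reference = NULL, period = 12, alpha = 0.05,
                            min_topics = 5, precision = 2) {
  registry <- registry %||% default_registry()
  stopifnot(alpha > 0, alpha < 1, min_topics >= 1)
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 registry = registry,
                 reference = reference %||% registry_reference(registry),
                 period = period, alpha = alpha, min_topics = min_topics,
                 precision = precision),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Recognized keys: `input_dir`, `output_dir`, `reference`, `period`,
#' `alpha`, `min_topics`, `precision`, and optionally an embedded registry
#' block (as written by [registry_to_yaml()]) under `registry`.
#'
#' @param path YAML file path.
#' @return an [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  obj <- yaml::yaml.load_file(path)
  registry <- if (!is.null(obj$registry)) {
    registry_from_yaml(yaml::as.yaml(obj$registry))
  } else NULL
  analysis_config(input_dir = obj$input_dir,
                  output_dir = obj$output_dir,
                  registry = registry,
                  reference = obj$reference,
                  period = obj$period %||% 12,
                  alpha = obj$alpha %||% 0.05,
                  min_topics = obj$min_topics %||% 5,
                  precision = obj$precision %||% 2)
}

#' @keywords internal
read_series_file <- function(path) {
  parse_interest_over_time(readLines(path, encoding = "UTF-8"))
}

#' Run the full analysis pipeline
#'
#' For every topic in the registry (reference topic included):
#' * global popularity: pairwise interest-over-time files are imputed and
#'   reduced to the adjusted proportion relative to the reference (the
#'   reference itself is emitted at exactly 1.00);
#' * secular trend: non-adjusted series get the Seasonal Mann-Kendall test
#'   and, when significant, the OLS slope in RSV/year;
#' * seasonality: periodic-STL decomposition with the harmonic F-test,
#'   peak/trough months and amplitude;
#' * geography: compared-breakdown region shares are imputed and anchored
#'   at reference = 50, low-volume countries are excluded, and per-country
#'   rankings with winners are computed.
#'
#' The pipeline is a pure function of its inputs: rerunning over the same
#' directory yields identical tables.
#'
#' @param cfg an [analysis_config()].
#' @return list with `proportion_table`, `trend_table`, `country_table`,
#'   `metadata`. If `cfg$output_dir` is set, tables are also written as CSV
#'   (report mode) and JSON (machine mode) plus `metadata.json`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  if (!dir.exists(cfg$input_dir)) {
    stop("input directory does not exist: ", cfg$input_dir, call. = FALSE)
  }
  reg <- cfg$registry
  ids <- reg$topics$id
  ref <- cfg$reference
  if (!ref %in% ids) stop("reference topic '", ref,
                          "' is not in the registry", call. = FALSE)
  fp <- function(kind, id) file.path(cfg$input_dir,
                                     paste0(kind, "_", id, ".csv"))

  # --- global popularity (time mode) --------------------------------------
  prop_rows <- lapply(ids, function(id) {
    if (id == ref) {
      return(data.frame(topic_id = id, scope = "world-time", value = 1.0,
                        stringsAsFactors = FALSE))
    }
    path <- fp("pairwise", id)
    if (!file.exists(path)) {
      stop("missing pairwise comparison file for topic '", id, "': ",
           path, call. = FALSE)
    }
    series <- read_series_file(path)
    by_id <- stats::setNames(series,
                             vapply(series, function(s) s$topic_id,
                                    character(1)))
    if (!ref %in% names(by_id)) {
      stop("pairwise file for '", id, "' lacks the reference column '",
           ref, "'", call. = FALSE)
    }
    adjusted_proportion(pairwise_comparison(
      impute_censored(by_id[[id]]), impute_censored(by_id[[ref]])))
  })
  proportion_table <- do.call(rbind, prop_rows)
  proportion_table <- proportion_table[order(-proportion_table$value,
                                             match(proportion_table$topic_id,
                                                   ids)), ]
  rownames(proportion_table) <- NULL

  # --- trend + seasonality (non-adjusted time series) ---------------------
  trend_rows <- lapply(ids, function(id) {
    path <- fp("nonadjusted", id)
    if (!file.exists(path)) {
      stop("missing non-adjusted series for topic '", id, "'",
           call. = FALSE)
    }
    s <- impute_censored(read_series_file(path)[[1]])
    mk <- seasonal_mann_kendall(s, period = cfg$period, alpha = cfg$alpha)
    sl <- ols_slope(s)
    dec <- stl_periodic(s, period = cfg$period, alpha = cfg$alpha)
    data.frame(topic_id = id, S = mk$S, var_S = mk$var_S, Z = mk$Z,
               tau = mk$tau, p = mk$p_two_sided,
               stars = significance_stars(mk$p_two_sided),
               slope = ifelse(mk$significant, sl$slope, NA_real_),
               slope_p = ifelse(mk$significant, sl$slope_p, NA_real_),
               seasonal = dec$seasonal_present,
               seasonal_p = dec$seasonal_p,
               seasonal_period = ifelse(dec$seasonal_present, cfg$period,
                                        NA_integer_),
               peak_month = ifelse(dec$seasonal_present, dec$peak_month,
                                   NA_character_),
               peak_value = ifelse(dec$seasonal_present, dec$peak_value,
                                   NA_real_),
               trough_month = ifelse(dec$seasonal_present,
                                     dec$trough_month, NA_character_),
               trough_value = ifelse(dec$seasonal_present,
                                     dec$trough_value, NA_real_),
               amplitude = ifelse(dec$seasonal_present, dec$amplitude,
                                  NA_real_),
               stringsAsFactors = FALSE)
  })
  trend_table <- do.call(rbind, trend_rows)
  rownames(trend_table) <- NULL

  # --- geography ----------------------------------------------------------
  region_single <- do.call(rbind, lapply(ids, function(id) {
    path <- fp("region_single", id)
    if (!file.exists(path)) return(NULL)
    lines <- readLines(path, encoding = "UTF-8")
    cells <- strsplit(lines[-1], ",", fixed = TRUE)
    vals <- vapply(cells, function(r) if (length(r) > 1) r[2] else "",
                   character(1))
    data.frame(country = vapply(cells, `[`, character(1), 1),
               topic_id = id,
               value = ifelse(nzchar(vals), vals, NA_character_),
               stringsAsFactors = FALSE)
  }))
  anchored <- do.call(rbind, lapply(setdiff(ids, ref), function(id) {
    path <- fp("region_pair", id)
    if (!file.exists(path)) return(NULL)
    tbl <- parse_interest_by_region(readLines(path, encoding = "UTF-8"),
                                    topic_id = id, reference_id = ref)
    anchor_region(impute_censored(tbl))
  }))
  country_table <- NULL
  excluded <- character()
  if (!is.null(anchored) && nrow(anchored)) {
    masked_countries <- unique(anchored$country[anchored$excluded])
    low_volume <- if (!is.null(region_single)) {
      setdiff(exclude_low_volume(region_single,
                                 min_topics = cfg$min_topics),
              masked_countries)
    } else character()
    excluded <- c(stats::setNames(rep("masked", length(masked_countries)),
                                  masked_countries),
                  stats::setNames(rep("low_volume", length(low_volume)),
                                  low_volume))
    country_table <- rank_topics_by_country(anchored, reg,
                                            excluded = excluded)
  }

  metadata <- list(
    reference = ref,
    period = cfg$period,
    alpha = cfg$alpha,
    min_topics = cfg$min_topics,
    n_topics = length(ids),
    imputation = "censored '<1' -> 0.5; zero -> 0.1 (applied to time series and region shares)",
    seasonality_presence_test = "harmonic-regression F-test (two Fourier pairs vs linear trend)",
    stars = "*** p<0.001, ** p<0.01, * p<0.05",
    n_countries_included = if (!is.null(country_table))
      sum(!country_table$excluded) else 0L,
    excluded_countries = as.list(excluded),
    package_version = as.character(utils::packageVersion("skintrends"))
  )

  out <- list(proportion_table = proportion_table,
              trend_table = trend_table,
              country_table = country_table,
              metadata = metadata)
  if (!is.null(cfg$output_dir)) {
    if (!dir.exists(cfg$output_dir)) dir.create(cfg$output_dir,
                                                recursive = TRUE)
    od <- cfg$output_dir
    write_table(proportion_table, file.path(od, "proportions.csv"),
                format = "csv", mode = "report", digits = cfg$precision)
    write_table(proportion_table, file.path(od, "proportions.json"),
                format = "json")
    write_table(trend_table, file.path(od, "trend.csv"),
                format = "csv", mode = "report", digits = cfg$precision)
    write_table(trend_table, file.path(od, "trend.json"), format = "json")
    if (!is.null(country_table)) {
      write_table(country_table, file.path(od, "countries.csv"),
                  format = "csv", mode = "report", digits = cfg$precision)
      write_table(country_table, file.path(od, "countries.json"),
                  format = "json")
      render_country_winners(country_table,
                             file.path(od, "country_winners.csv"))
    }
    jsonlite::write_json(metadata, file.path(od, "metadata.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Export the per-country winner table for mapping
#'
#' Two-column CSV (country code, winning topic) covering included countries
#' only -- the input a choropleth tool needs. Excluded countries are listed
#' in a `<path>.excluded.csv` sidecar with their reasons.
#'
#' @param country_table output of [rank_topics_by_country()] /
#'   [run_pipeline()].
#' @param path output CSV path; `NULL` returns the data.frame only.
#' @return data.frame of `country`, `winner` (invisibly when written).
#' @export
render_country_winners <- function(country_table, path = NULL) {
  stopifnot(is.data.frame(country_table), nrow(country_table) > 0)
  keep <- country_table[!country_table$excluded,
                        c("country", "winner")]
  rownames(keep) <- NULL
  if (!is.null(path)) {
    utils::write.csv(keep, path, row.names = FALSE, quote = FALSE)
    side <- country_table[country_table$excluded,
                          c("country", "reason")]
    utils::write.csv(side, paste0(path, ".excluded.csv"),
                     row.names = FALSE, quote = FALSE)
    return(invisible(keep))
  }
  keep
}
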