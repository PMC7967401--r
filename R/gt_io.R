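# Google-Trends-dialect I/O. Interest-over-time exports are monthly CSVs with
# an optional two-line preamble ("Category: ...", blank line), a header
# "Month,<query>[,<query2>]" and integer RSV values 0-100, where Google
# censors nonzero sub-1% interest to the token "<1" (some export dialects
# print "<1%"). Compared-breakdown-by-region exports have one row per country
# with the two compared topics' shares summing to 100; countries below
# Google's volume threshold export empty cells.

CENSOR_TOKENS <- c("<1", "<1%", "<1 %")

#' Construct a topic RSV series
#'
#' A `topic_series` holds one topic's monthly relative-search-volume values
#' for one region scope, either in raw token form (integers 0-100 as strings
#' plus the censoring token `"<1"`) or in imputed numeric form.
#'
#' @param topic_id topic identifier.
#' @param months consecutive `"YYYY-MM"` strings.
#' @param values character tokens (raw) or numeric values (imputed).
#' @param region ISO country code or `"world"`.
#' @param imputed logical; `TRUE` if `values` are imputed numerics.
#' @return object of class `topic_series`.
#' @export
topic_series <- function(topic_id, months, values, region = "world",
                         imputed = FALSE) {
  idx <- ym_to_index(months)
  if (length(idx) > 1L && any(diff(idx) != 1L)) {
    stop("months are not consecutive for topic '", topic_id, "'",
         call. = FALSE)
  }
  if (length(values) != length(months)) {
    stop("values and months differ in length", call. = FALSE)
  }
  if (imputed) {
    values <- as.numeric(values)
    # tolerate float jitter at the top of the scale (100 * x / max(x))
    values[values > 100 & values < 100 + 1e-6] <- 100
    if (any(!is.finite(values)) || any(values < 0) || any(values > 100)) {
      stop("imputed values must be finite and within [0, 100]",
           call. = FALSE)
    }
  } else {
    values <- as.character(values)
    bad <- !(values %in% c(CENSOR_TOKENS, as.character(0:100)))
    if (any(bad)) {
      stop("invalid raw RSV token(s): ",
           paste(unique(values[bad]), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(topic_id = topic_id, region = region, months = months,
                 values = values, imputed = imputed),
            class = "topic_series")
}

#' @export
print.topic_series <- function(x, ...) {
  cat("<topic_series> ", x$topic_id, " [", x$region, "] ",
      x$months[1], "..", x$months[length(x$months)],
      " (", length(x$values), " months, ",
      if (x$imputed) "imputed" else "raw", ")\n", sep = "")
  invisible(x)
}

# Strip the optional GT preamble and return cleaned lines.
#' @keywords internal
strip_gt_preamble <- function(lines) {
  while (length(lines) &&
         (grepl("^Category:", lines[1]) || !nzchar(trimws(lines[1])))) {
    lines <- lines[-1L]
  }
  lines
}

#' Parse a Google Trends interest-over-time CSV
#'
#' Accepts the monthly export dialect: optional preamble, header
#' `Month,<query1>[,<query2>]`, rows `YYYY-MM,value[,value]`. Censoring
#' tokens `"<1"` and `"<1%"` are preserved as censored values; weekly or
#' daily exports (dates with a day component) are rejected.
#'
#' @param csv_text the CSV contents as a single string or character vector of
#'   lines.
#' @return list of raw [topic_series()], one per query column, sharing the
#'   same months.
#' @export
parse_interest_over_time <- function(csv_text) {
  lines <- if (length(csv_text) == 1L) strsplit(csv_text, "\r?\n")[[1]]
           else csv_text
  lines <- strip_gt_preamble(lines)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty interest-over-time CSV", call. = FALSE)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (tolower(trimws(header[1])) != "month" || length(header) < 2L) {
    stop("expected header 'Month,<query>[,<query2>]', got: ", lines[1],
         call. = FALSE)
  }
  queries <- trimws(header[-1L])
  body <- lines[-1L]
  cells <- strsplit(body, ",", fixed = TRUE)
  months <- character(length(body))
  vals <- matrix("", nrow = length(body), ncol = length(queries))
  for (i in seq_along(body)) {
    row <- trimws(cells[[i]])
    if (length(row) != length(queries) + 1L) {
      stop("row ", i + 1L, ": expected ", length(queries) + 1L,
           " cells, got ", length(row), call. = FALSE)
    }
    if (grepl("^\\d{4}-\\d{2}-\\d{2}$", row[1])) {
      stop("row ", i + 1L, ": date '", row[1],
           "' has a day component; only monthly exports are supported",
           call. = FALSE)
    }
    if (!grepl("^\\d{4}-(0[1-9]|1[0-2])$", row[1])) {
      stop("row ", i + 1L, ": malformed month '", row[1], "'",
           call. = FALSE)
    }
    months[i] <- row[1]
    for (j in seq_along(queries)) {
      v <- row[j + 1L]
      if (!(v %in% CENSOR_TOKENS)) {
        n <- suppressWarnings(as.numeric(v))
        if (is.na(n) || n != round(n) || n < 0 || n > 100) {
          stop("row ", i + 1L, ": RSV value '", v,
               "' outside integer range [0, 100]", call. = FALSE)
        }
      }
      vals[i, j] <- v
    }
  }
  idx <- ym_to_index(months)
  if (length(idx) > 1L && any(diff(idx) != 1L)) {
    gap <- which(diff(idx) != 1L)[1]
    stop("non-contiguous months at row ", gap + 2L, " ('",
         months[gap], "' -> '", months[gap + 1L], "')", call. = FALSE)
  }
  lapply(seq_along(queries), function(j) {
    topic_series(queries[j], months, vals[, j], region = "world",
                 imputed = FALSE)
  })
}

#' Construct a compared-breakdown-by-region share table
#'
#' @param topic_id,reference_id the two compared topic ids.
#' @param countries country identifiers (ISO codes or names).
#' @param share_topic,share_reference per-country shares (numeric, `NA` for
#'   masked countries).
#' @param masked logical; country masked by Google's low-volume threshold.
#' @param imputed logical; shares already imputed (0 -> 0.1).
#' @return object of class `region_share_table` (a data.frame with
#'   attributes `topic_pair` and `imputed`).
#' @export
region_share_table <- function(topic_id, reference_id, countries,
                               share_topic, share_reference,
                               masked = rep(FALSE, length(countries)),
                               imputed = FALSE) {
  stopifnot(length(countries) == length(share_topic),
            length(countries) == length(share_reference),
            length(countries) == length(masked))
  df <- data.frame(country = countries, share_topic = share_topic,
                   share_reference = share_reference, masked = masked,
                   stringsAsFactors = FALSE)
  ok <- !df$masked
  if (!imputed) {
    tot <- df$share_topic[ok] + df$share_reference[ok]
    bad <- tot < 99 - 1e-9 | tot > 101 + 1e-9
    if (any(bad)) {
      stop("shares do not sum to 100 (within rounding) for: ",
           paste(df$country[ok][bad], collapse = ", "), call. = FALSE)
    }
  }
  structure(df, topic_pair = c(topic = topic_id, reference = reference_id),
            imputed = imputed,
            class = c("region_share_table", "data.frame"))
}

#' Parse a Google Trends compared-breakdown-by-region CSV
#'
#' Header `Country,<query1>,<query2>`, one row per country. Rows where both
#' cells are empty (or both zero) are marked masked: Google withholds
#' breakdowns for countries with too little search volume.
#'
#' @param csv_text CSV contents (string or lines).
#' @param topic_id,reference_id ids to attach to the two query columns;
#'   default to the header names.
#' @return a [region_share_table()] with raw (unimputed) shares.
#' @export
parse_interest_by_region <- function(csv_text, topic_id = NULL,
                                     reference_id = NULL) {
  lines <- if (length(csv_text) == 1L) strsplit(csv_text, "\r?\n")[[1]]
           else csv_text
  lines <- strip_gt_preamble(lines)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty region CSV", call. = FALSE)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (tolower(trimws(header[1])) != "country" || length(header) != 3L) {
    stop("expected header 'Country,<query1>,<query2>', got: ", lines[1],
         call. = FALSE)
  }
  topic_id <- topic_id %||% trimws(header[2])
  reference_id <- reference_id %||% trimws(header[3])
  body <- lines[-1L]
  parse_cell <- function(v) {
    if (!nzchar(v)) return(NA_real_)
    if (v %in% CENSOR_TOKENS) return(0.5)  # censored share, pre-imputed form
    n <- suppressWarnings(as.numeric(v))
    if (is.na(n) || n < 0 || n > 100) {
      stop("region share '", v, "' outside [0, 100]", call. = FALSE)
    }
    n
  }
  rows <- strsplit(body, ",", fixed = TRUE)
  country <- character(length(body))
  s1 <- s2 <- numeric(length(body))
  masked <- logical(length(body))
  for (i in seq_along(body)) {
    row <- trimws(rows[[i]])
    length(row) <- 3L
    row[is.na(row)] <- ""
    country[i] <- row[1]
    a <- parse_cell(row[2]); b <- parse_cell(row[3])
    if ((is.na(a) && is.na(b)) ||
        (!is.na(a) && !is.na(b) && a == 0 && b == 0)) {
      masked[i] <- TRUE
      s1[i] <- NA_real_; s2[i] <- NA_real_
    } else {
      s1[i] <- if (is.na(a)) 0 else a
      s2[i] <- if (is.na(b)) 0 else b
    }
  }
  region_share_table(topic_id, reference_id, country, s1, s2, masked,
                     imputed = FALSE)
}

#' Impute censored RSV values
#'
#' Applies the study's imputation rule: censored `"<1"` data points become
#' 0.5 and exact-zero points become 0.1, so that downstream ratios are always
#' defined and the token order 0 < "<1" < 1 is preserved numerically
#' (0.1 < 0.5 < 1).
#'
#' @param s a raw [topic_series()] or raw [region_share_table()].
#' @return the same object with numeric imputed values and `imputed = TRUE`.
#' @export
impute_censored <- function(s) UseMethod("impute_censored")

#' @export
impute_censored.topic_series <- function(s) {
  if (s$imputed) stop("series is already imputed", call. = FALSE)
  v <- suppressWarnings(as.numeric(s$values))
  v[s$values %in% CENSOR_TOKENS] <- 0.5
  v[s$values == "0"] <- 0.1
  topic_series(s$topic_id, s$months, v, region = s$region, imputed = TRUE)
}

#' @export
impute_censored.region_share_table <- function(s) {
  if (isTRUE(attr(s, "imputed"))) {
    stop("share table is already imputed", call. = FALSE)
  }
  imp <- function(x) ifelse(is.na(x), NA_real_,
                            ifelse(x == 0, 0.1, ifelse(x < 1, 0.5, x)))
  pair <- attr(s, "topic_pair")
  region_share_table(pair[["topic"]], pair[["reference"]], s$country,
                     imp(s$share_topic), imp(s$share_reference),
                     s$masked, imputed = TRUE)
}

#' Write an analysis table to CSV or JSON
#'
#' Report mode rounds numeric columns to a fixed number of decimals (the
#' convention for study tables is two); machine mode keeps full precision.
#' is preserved as given, so output is deterministic.
#'
#' @param rows non-empty data.frame.
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @param mode `"machine"` (full precision) or `"report"` (rounded).
#' @param digits decimals in report mode.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, format = c("csv", "json"),
                        mode = c("machine", "report"), digits = 2) {
  format <- match.arg(format)
  mode <- match.arg(mode)
  if (!is.data.frame(rows) || nrow(rows) == 0L) {
    stop("rows must be a non-empty data.frame", call. = FALSE)
  }
  out <- as.data.frame(rows, stringsAsFactors = FALSE)
  class(out) <- "data.frame"
  attr(out, "topic_pair") <- NULL
  if (mode == "report") {
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(x) round(x, digits))
  }
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Write a topic series back out in the Google Trends CSV dialect
#'
#' @param series list of [topic_series()] sharing months (raw or imputed;
#'   imputed values are written as-is).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interest_over_time <- function(series, path) {
  if (inherits(series, "topic_series")) series <- list(series)
  months <- series[[1]]$months
  for (s in series) {
    if (!identical(s$months, months)) {
      stop("all series must share months", call. = FALSE)
    }
  }
  header <- paste(c("Month", vapply(series, function(s) s$topic_id,
                                    character(1))), collapse = ",")
  vals <- vapply(series, function(s) as.character(s$values),
                 character(length(months)))
  body <- apply(cbind(months, vals), 1, paste, collapse = ",")
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Write a region share table in the Google Trends CSV dialect
#'
#' Masked countries are written with empty cells, mirroring the export.
#'
#' @param tbl a [region_share_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interest_by_region <- function(tbl, path) {
  pair <- attr(tbl, "topic_pair")
  header <- paste("Country", pair[["topic"]], pair[["reference"]], sep = ",")
  fmt <- function(x, masked) ifelse(masked, "", as.character(x))
  body <- paste(tbl$country, fmt(tbl$share_topic, tbl$masked),
                fmt(tbl$share_reference, tbl$masked), sep = ",")
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}
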