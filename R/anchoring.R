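# Benchmark anchoring. Google Trends only reports popularity on a scale that
# is relative to the queried set, so topics are made comparable by comparing
# each one pairwise against a fixed reference topic and taking ratios:
# globally over time the reference is pinned at 1.00, per country the
# reference share is rescaled to 50.

#' Pair a topic series with the reference series
#'
#' A pairwise comparison holds two series that were exported together (and
#' therefore share Google's joint max-100 scale), both in imputed form.
#'
#' @param topic,reference imputed [topic_series()] sharing months and region.
#' @param jointly_scaled logical; `TRUE` when the raw inputs came from a
#'   joint (two-query) export.
#' @return object of class `pairwise_comparison`.
#' @export
pairwise_comparison <- function(topic, reference, jointly_scaled = TRUE) {
  stopifnot(inherits(topic, "topic_series"),
            inherits(reference, "topic_series"))
  if (!topic$imputed || !reference$imputed) {
    stop("both series must be imputed (see impute_censored())",
         call. = FALSE)
  }
  if (!identical(topic$months, reference$months)) {
    stop("topic and reference series do not share months", call. = FALSE)
  }
  if (!identical(topic$region, reference$region)) {
    stop("topic and reference series do not share a region", call. = FALSE)
  }
  structure(list(topic = topic, reference = reference,
                 jointly_scaled = jointly_scaled),
            class = "pairwise_comparison")
}

#' Adjusted global proportion of a topic relative to the reference
#'
#' The cross-topic popularity index: the ratio of the topic's mean RSV to the
#' reference's mean RSV over the whole study period, computed from a jointly
#' scaled pairwise export. The reference compared against itself is emitted
#' as exactly 1.00 by construction. The ratio-of-means aggregate is robust to
#' censored months and is invariant to the joint scale factor.
#'
#' @param c a [pairwise_comparison()] with at least 12 months.
#' @return one-row data.frame with columns `topic_id`, `scope`, `value`.
#' @examples
#' m <- month_seq("2004-01", "2004-12")
#' a <- topic_series("itch", m, rep(80, 12), imputed = TRUE)
#' b <- topic_series("scar", m, rep(40, 12), imputed = TRUE)
#' adjusted_proportion(pairwise_comparison(a, b))$value  # 2
#' @export
adjusted_proportion <- function(c) {
  stopifnot(inherits(c, "pairwise_comparison"))
  if (length(c$topic$values) < 12L) {
    stop("need at least 12 months for a stable proportion", call. = FALSE)
  }
  value <- if (identical(c$topic$topic_id, c$reference$topic_id)) {
    1.0  # the reference's proportion is fixed by definition
  } else {
    mean(c$topic$values) / mean(c$reference$values)
  }
  data.frame(topic_id = c$topic$topic_id, scope = "world-time",
             value = value, stringsAsFactors = FALSE)
}

#' Anchor per-country shares to the reference at 50
#'
#' Rescales each country's compared-breakdown shares so the reference topic
#' sits at RSV 50 everywhere: `50 * share_topic / share_reference`. Masked
#' countries are reported with `NA` and reason `"masked"` rather than being
#' dropped, so exclusions stay auditable.
#'
#' @param t an imputed [region_share_table()].
#' @return data.frame with columns `country`, `topic_id`, `value`,
#'   `excluded`, `reason`.
#' @export
anchor_region <- function(t) {
  stopifnot(inherits(t, "region_share_table"))
  if (!isTRUE(attr(t, "imputed"))) {
    stop("share table must be imputed (see impute_censored())",
         call. = FALSE)
  }
  pair <- attr(t, "topic_pair")
  value <- ifelse(t$masked, NA_real_,
                  50 * t$share_topic / t$share_reference)
  data.frame(country = t$country,
             topic_id = pair[["topic"]],
             value = value,
             excluded = t$masked,
             reason = ifelse(t$masked, "masked", ""),
             stringsAsFactors = FALSE)
}

#' Exclude countries with too few active topics
#'
#' The study's low-search-volume rule: a country is excluded when strictly
#' fewer than `min_topics` topics have a non-adjusted regional RSV above
#' zero there. Censored (`"<1"`) values count as above zero; masked or
#' missing cells do not.
#'
#' @param region_values data.frame with columns `country`, `topic_id`,
#'   `value` where `value` holds non-adjusted regional RSV tokens (numeric,
#'   `"<1"` strings, or `NA` for masked).
#' @param min_topics minimum number of positive topics; default 5.
#' @return character vector of excluded countries.
#' @export
exclude_low_volume <- function(region_values, min_topics = 5) {
  stopifnot(is.data.frame(region_values),
            all(c("country", "topic_id", "value") %in% names(region_values)))
  v <- region_values$value
  positive <- if (is.character(v)) {
    !is.na(v) & (v %in% CENSOR_TOKENS | suppressWarnings(as.numeric(v)) > 0)
  } else {
    !is.na(v) & v > 0
  }
  counts <- tapply(positive, region_values$country, sum)
  names(counts)[counts < min_topics]
}

#' Rank topics within each country by anchored popularity
#'
#' Orders topics per country by their 50-anchored RSV, descending. The
#' reference topic participates with value 50 in every country. Ties are
#' broken by registry order; a country where every topic ties is flagged
#' degenerate. Excluded countries carry no winner.
#'
#' @param anchored data.frame from [anchor_region()] rows across topics
#'   (columns `country`, `topic_id`, `value`).
#' @param registry a `topic_registry` supplying topic order and the
#'   reference id.
#' @param excluded character vector of excluded countries (from
#'   [exclude_low_volume()] and/or masking). If named, names are countries
#'   and values the exclusion reasons; otherwise the reason defaults to
#'   `"low_volume"`.
#' @return data.frame with one row per country: `country`, `winner`, `top5`
#'   (semicolon-joined), `excluded`, `reason`, `tie`, `degenerate`.
#' @export
rank_topics_by_country <- function(anchored, registry,
                                   excluded = character()) {
  stopifnot(inherits(registry, "topic_registry"))
  order_ids <- registry$topics$id
  ref_id <- registry_reference(registry)
  if (is.null(names(excluded)) && length(excluded)) {
    excluded <- stats::setNames(rep("low_volume", length(excluded)),
                                excluded)
  }
  countries <- unique(anchored$country)
  rows <- lapply(countries, function(cty) {
    if (cty %in% names(excluded)) {
      return(data.frame(country = cty, winner = NA_character_,
                        top5 = NA_character_, excluded = TRUE,
                        reason = unname(excluded[[cty]]), tie = FALSE,
                        degenerate = FALSE, stringsAsFactors = FALSE))
    }
    sub <- anchored[anchored$country == cty & !is.na(anchored$value), ]
    vals <- stats::setNames(rep(0.1, length(order_ids)), order_ids)
    vals[sub$topic_id] <- sub$value  # absent topics: imputed-zero value
    vals[ref_id] <- 50
    reg_pos <- seq_along(order_ids)
    ord <- order(-vals, reg_pos)
    ranked <- order_ids[ord]
    top <- vals[ord]
    tie <- length(top) > 1L && any(top[1] == top[-1])
    degenerate <- length(unique(top)) == 1L
    data.frame(country = cty, winner = ranked[1],
               top5 = paste(utils::head(ranked, 5), collapse = ";"),
               excluded = FALSE, reason = "", tie = tie,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
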