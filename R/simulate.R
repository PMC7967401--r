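# Synthetic Google-Trends-like data with known ground truth. The latent
# model is additive on the topic's own RSV-like scale: level + secular slope
# + fixed monthly pattern (+ optional December dip) + Gaussian noise, clipped
# to stay positive. The observation transform then mimics what Google
# Trends does to latent search intensity: max-100 rescaling (per series or
# jointly for a compared pair), integer rounding, censoring of nonzero
# sub-1% values to "<1", per-country share breakdowns, and masking of
# low-volume countries. All randomness is seeded Mersenne-Twister, so
# fixtures are bit-identical across runs and platforms.

LATENT_EPS <- 0.001
LATENT_VOLUME_UNIT <- 60  # latent volume of a popularity-ratio-1 topic

#' Latent model for one topic's search intensity
#'
#' @param topic_id topic identifier.
#' @param baseline positive level, in the topic's own RSV-like units.
#' @param slope secular trend, units per year.
#' @param monthly_pattern 12 seasonal offsets summing to 0 (Jan..Dec).
#' @param december_dip extra additive December offset, `<= 0` (holiday lull
#'   in search activity).
#' @param noise_sd standard deviation of the iid Gaussian noise.
#' @param popularity_ratio latent search volume relative to the reference
#'   topic (1 = same volume).
#' @return object of class `latent_topic_model`.
#' @export
latent_topic_model <- function(topic_id, baseline, slope = 0,
                               monthly_pattern = numeric(12),
                               december_dip = 0, noise_sd = 0,
                               popularity_ratio = 1) {
  stopifnot(baseline > 0, length(monthly_pattern) == 12,
            december_dip <= 0, noise_sd >= 0, popularity_ratio > 0)
  if (abs(sum(monthly_pattern)) > 1e-8) {
    stop("monthly_pattern must sum to 0", call. = FALSE)
  }
  if (baseline + min(monthly_pattern) + december_dip <= 0) {
    stop("latent intensity would go non-positive before noise",
         call. = FALSE)
  }
  structure(list(topic_id = topic_id, baseline = baseline, slope = slope,
                 monthly_pattern = monthly_pattern,
                 december_dip = december_dip, noise_sd = noise_sd,
                 popularity_ratio = popularity_ratio),
            class = "latent_topic_model")
}

#' @keywords internal
latent_profile <- function(m, months) {
  t_idx <- seq_along(months) - 1
  mo <- month_of(months)
  m$baseline + m$slope * t_idx / 12 + m$monthly_pattern[mo] +
    m$december_dip * (mo == 12L)
}

#' Simulate a latent search-intensity series
#'
#' In the default (profile) form the series is
#' `x_t = max(eps, baseline * popularity_ratio + slope * t/12 +
#' monthly_pattern[month] + december_dip * [Dec] + N(0, noise_sd^2))`.
#' With `volume_scaled = TRUE` the whole noisy profile (level computed with
#' `popularity_ratio = 1`) is instead multiplied by the topic's latent
#' volume, `popularity_ratio * 60 / mean(profile)`: the topic keeps its own
#' trend/seasonal shape, its *mean* volume is exactly `popularity_ratio`
#' times the volume of a ratio-1 topic, and noise scales with volume. This
#' is the form used for pairwise comparisons, where the estimand is the
#' ratio of mean intensities.
#'
#' @param m a [latent_topic_model()].
#' @param months `"YYYY-MM"` months to simulate.
#' @param seed integer RNG seed.
#' @param volume_scaled logical, see above.
#' @return positive numeric series, one value per month.
#' @export
simulate_latent <- function(m, months, seed, volume_scaled = FALSE) {
  stopifnot(inherits(m, "latent_topic_model"))
  det <- latent_profile(m, months)
  noise <- with_seed(seed, stats::rnorm(length(months), 0, m$noise_sd))
  if (volume_scaled) {
    vol <- m$popularity_ratio * LATENT_VOLUME_UNIT / mean(det)
    pmax(LATENT_EPS, (det + noise) * vol)
  } else {
    pmax(LATENT_EPS, det + (m$popularity_ratio - 1) * m$baseline + noise)
  }
}

#' @keywords internal
tokenize_scaled <- function(latent, scaled) {
  ifelse(latent == 0, "0",
         ifelse(round(scaled) < 1, "<1", as.character(round(scaled))))
}

#' Google Trends observation transform, single series
#'
#' Rescales a latent series so its maximum is 100, then quantizes the way a
#' GT export does: integer rounding, `"<1"` for nonzero values rounding
#' below 1, `"0"` for exact zeros. The realized rescaling factor
#' `100 / max(latent)` is attached as attribute `scale_factor` (this is the
#' factor that converts latent slopes into observed RSV slopes).
#'
#' @param latent non-negative latent series, not all zero.
#' @param topic_id,months,region metadata for the returned series.
#' @param quantize if `FALSE`, skip rounding/censoring and return an
#'   imputed-form series of continuous rescaled values (the
#'   censoring-free observation model).
#' @return raw (or, with `quantize = FALSE`, imputed) [topic_series()].
#' @export
gt_transform_single <- function(latent, topic_id, months, region = "world",
                                quantize = TRUE) {
  if (any(latent < 0)) stop("latent series must be non-negative",
                            call. = FALSE)
  mx <- max(latent)
  if (mx == 0) stop("all-zero series: Google Trends would mask it",
                    call. = FALSE)
  scaled <- 100 * latent / mx
  out <- if (quantize) {
    topic_series(topic_id, months, tokenize_scaled(latent, scaled),
                 region = region, imputed = FALSE)
  } else {
    topic_series(topic_id, months, scaled, region = region, imputed = TRUE)
  }
  attr(out, "scale_factor") <- 100 / mx
  out
}

#' Google Trends observation transform, jointly scaled pair
#'
#' Applies one common rescaling factor `100 / max(both series)` -- the
#' two-query export semantics, where 100 marks the peak of the more popular
#' series -- then quantizes each series as in [gt_transform_single()].
#'
#' @param latent_topic,latent_reference non-negative latent series of equal
#'   length, not both all-zero.
#' @param topic_id,reference_id series identifiers.
#' @param months,region metadata.
#' @param quantize as in [gt_transform_single()].
#' @return list with raw [topic_series()] `topic` and `reference` and the
#'   common `scale_factor`.
#' @export
gt_transform_pairwise <- function(latent_topic, latent_reference,
                                  topic_id, reference_id, months,
                                  region = "world", quantize = TRUE) {
  if (length(latent_topic) != length(latent_reference)) {
    stop("series lengths differ", call. = FALSE)
  }
  mx <- max(latent_topic, latent_reference)
  if (mx == 0) stop("both series all-zero: Google Trends would mask them",
                    call. = FALSE)
  sc_t <- 100 * latent_topic / mx
  sc_r <- 100 * latent_reference / mx
  mk <- function(latent, scaled, id) {
    if (quantize) {
      topic_series(id, months, tokenize_scaled(latent, scaled),
                   region = region, imputed = FALSE)
    } else {
      topic_series(id, months, scaled, region = region, imputed = TRUE)
    }
  }
  list(topic = mk(latent_topic, sc_t, topic_id),
       reference = mk(latent_reference, sc_r, reference_id),
       scale_factor = 100 / mx)
}

# ---------------------------------------------------------------------------
# World fixtures: a full synthetic study with per-topic latent models and
# per-country volumes/weights.

# Per-topic defaults of the "study" preset: the global popularity ratios
# (relative to scar = 1.00), secular slopes in RSV/year, and seasonal
# peak/trough month components that define the study conditions the
# package is designed around. hair_loss is the one aseasonal topic.
study_topic_params <- function() {
  p <- data.frame(
    id = c("itch", "hair_loss", "skin_rash", "perspiration", "scar",
           "wart", "pustule", "blister", "hives", "cellulite",
           "stretch_marks", "comedo", "skin_ulcer", "nevus", "nodule",
           "dandruff", "eczema", "xeroderma", "melanocytic_nevus",
           "erythema", "freckle", "papilloma", "melasma", "skin_tag",
           "papule", "vesicle", "hyperpigmentation", "telangiectasia",
           "liver_spot", "petechia", "abrasion", "eschar", "skin_fissure",
           "cafe_au_lait_spot"),
    rho = c(2.21, 1.56, 1.38, 1.32, 1.00, 0.85, 0.85, 0.56, 0.54, 0.50,
            0.47, 0.46, 0.46, 0.38, 0.38, 0.37, 0.43, 0.33, 0.32, 0.28,
            0.26, 0.22, 0.18, 0.13, 0.09, 0.08, 0.07, 0.07, 0.06, 0.06,
            0.05, 0.04, 0.02, 0.01),
    slope = c(4.83, 1.34, 3.34, 2.85, 3.63, 2.42, 3.89, 3.37, 2.03, 1.15,
              2.52, 5.15, 3.21, 4.17, 3.78, 4.66, 2.50, 4.02, 2.73, 1.57,
              3.36, 2.15, 4.62, 3.94, 1.09, 1.06, 3.39, 0.96, 1.47, 2.15,
              2.83, 1.70, 3.46, 0.47),
    peak_month = c(7, NA, 7, 7, 7, 7, 7, 7, 7, 5,
                   7, 8, 10, 7, 5, 1, 5, 1, 7, 7,
                   6, 10, 7, 8, 7, 10, 6, 6, 7, 5,
                   6, 6, 12, 7),
    trough_month = c(12, NA, 12, 12, 12, 12, 12, 12, 12, 12,
                     12, 10, 1, 11, 12, 6, 9, 9, 12, 12,
                     12, 12, 12, 12, 12, 7, 12, 12, 12, 12,
                     12, 12, 9, 11),
    peak_value = c(5.32, NA, 8.35, 12.30, 4.26, 11.78, 6.63, 15.47, 5.33,
                   21.61, 11.51, 3.27, 1.77, 4.87, 2.31, 9.08, 6.25,
                   10.77, 11.93, 6.40, 5.32, 5.69, 6.20, 8.33, 3.65,
                   17.25, 6.96, 15.05, 16.15, 10.59, 8.87, 1.58, 12.23,
                   12.32),
    trough_value = c(-3.20, NA, -5.57, -9.71, -5.65, -11.09, -6.40, -9.52,
                     -6.06, -22.16, -11.74, -2.50, -2.73, -5.02, -5.88,
                     -7.60, -6.69, -8.34, -12.03, -8.37, -7.75, -12.64,
                     -8.00, -6.14, -5.75, -14.24, -11.05, -15.25, -17.20,
                     -9.04, -8.66, -4.87, -6.85, -8.35),
    stringsAsFactors = FALSE
  )
  p$seasonal <- !is.na(p$peak_month)
  p
}

# Smooth periodic pattern with an exact max at `peak` and min at `trough`:
# cosine-arc interpolation along both ways around the annual circle, then
# centred to sum to zero (centring shifts all values, not the amplitude).
#' @keywords internal
make_monthly_pattern <- function(peak, trough, peak_value, trough_value) {
  stopifnot(peak != trough)
  k <- (trough - peak) %% 12
  m <- 1:12
  a <- (m - peak) %% 12
  s <- ifelse(a <= k, a / k, (12 - a) / (12 - k))
  pat <- peak_value + (trough_value - peak_value) * (1 - cos(pi * s)) / 2
  pat - mean(pat)
}

#' Build a synthetic study world
#'
#' Constructs the full ground truth for a synthetic study: per-topic latent
#' models and per-country latent volumes and topic weights.
#'
#' Presets:
#' * `"study"` -- 34 dermatology topics with popularity ratios spanning
#'   0.01-2.21, positive secular slopes of 0.47-5.15 RSV/year, and
#'   warm-month-peaked seasonal patterns with December troughs for most
#'   topics; `hair_loss` is aseasonal.
#' * `"null"` -- the same topics with no trend and no seasonality (pure
#'   noise around a flat level), for calibration runs.
#' * `"southern"` -- the study world with every seasonal pattern
#'   phase-shifted by 6 months (opposite-hemisphere seasons).
#'
#' Countries get lognormal latent volumes; countries below `mask_threshold`
#' emulate Google's low-volume masking (about a tenth of the default
#' country set). Per-country topic weights are the topic's popularity ratio
#' times country volume times lognormal country taste noise, with rare
#' topics stochastically absent in small countries.
#'
#' @param preset `"study"`, `"null"`, or `"southern"`.
#' @param seed integer seed; the world is a pure function of
#'   `(preset, seed)`.
#' @param noise_sd observation-month noise, RSV units.
#' @param n_months number of months from January 2004.
#' @return object of class `latent_world`.
#' @export
make_world_fixture <- function(preset = c("study", "null", "southern"),
                               seed = 1, noise_sd = 2, n_months = 192) {
  preset <- match.arg(preset)
  params <- study_topic_params()
  months <- index_to_ym(seq.int(ym_to_index("2004-01"), length.out = n_months))
  horizon_years <- (n_months - 1) / 12

  shift <- if (preset == "southern") 6L else 0L
  topics <- vector("list", nrow(params))
  for (i in seq_len(nrow(params))) {
    pr <- params[i, ]
    if (preset == "null") {
      pat <- numeric(12)
      slope <- 0
      baseline <- 50
    } else if (pr$seasonal) {
      peak <- (pr$peak_month - 1 + shift) %% 12 + 1
      trough <- (pr$trough_month - 1 + shift) %% 12 + 1
      pat <- make_monthly_pattern(peak, trough, pr$peak_value,
                                  pr$trough_value)
      slope <- pr$slope
      baseline <- 100 - slope * horizon_years - max(pat)
    } else {
      pat <- numeric(12)
      slope <- pr$slope
      baseline <- 100 - slope * horizon_years
    }
    topics[[i]] <- latent_topic_model(
      pr$id, baseline = baseline, slope = slope, monthly_pattern = pat,
      december_dip = 0, noise_sd = noise_sd, popularity_ratio = pr$rho)
  }
  names(topics) <- params$id

  countries <- c("US", "GB", "DE", "FR", "IT", "ES", "PL", "NL", "BE",
                 "SE", "NO", "FI", "DK", "IE", "PT", "GR", "CZ", "SK",
                 "HU", "RO", "BG", "HR", "SI", "AT", "CH", "RU", "UA",
                 "TR", "IL", "SA", "AE", "EG", "MA", "ZA", "NG", "KE",
                 "IN", "PK", "BD", "LK", "TH", "VN", "ID", "MY", "PH",
                 "SG", "JP", "KR", "CN", "TW", "HK", "AU", "NZ", "BR",
                 "AR", "CL", "CO", "PE", "MX", "CA", "VE", "EC", "UY",
                 "BO", "CR", "PA", "DO", "JM", "TT", "IS", "MT", "LU")
  mask_threshold <- 0.28
  world <- with_seed(seed, {
    volume <- stats::rlnorm(length(countries), meanlog = 0, sdlog = 1)
    weights <- matrix(0, nrow = length(countries), ncol = length(topics),
                      dimnames = list(countries, names(topics)))
    for (j in seq_along(topics)) {
      rho <- topics[[j]]$popularity_ratio
      present <- stats::rbinom(length(countries), 1,
                               1 - exp(-2 * volume * rho))
      taste <- stats::rlnorm(length(countries), meanlog = 0, sdlog = 0.35)
      weights[, j] <- present * volume * rho * taste
    }
    list(volume = volume, weights = weights)
  })
  structure(list(preset = preset, seed = as.integer(seed),
                 months = months, topics = topics,
                 countries = data.frame(country = countries,
                                        total_volume = world$volume,
                                        masked = world$volume <
                                          mask_threshold,
                                        stringsAsFactors = FALSE),
                 weights = world$weights,
                 mask_threshold = mask_threshold,
                 noise_sd = noise_sd),
            class = "latent_world")
}

#' @export
print.latent_world <- function(x, ...) {
  cat("<latent_world> preset '", x$preset, "', seed ", x$seed, ": ",
      length(x$topics), " topics x ", length(x$months), " months, ",
      nrow(x$countries), " countries (", sum(x$countries$masked),
      " masked)\n", sep = "")
  invisible(x)
}

#' Simulate a compared-breakdown-by-region table
#'
#' Per country, the share of the topic among (topic + reference) query
#' volume, rounded to integers summing to 100 -- the two-query region export
#' semantics. Countries below the world's masking threshold emit masked
#' rows. The unrounded ground-truth shares are returned alongside for
#' recovery tests.
#'
#' @param w a [make_world_fixture()] world.
#' @param topic_id,reference_id topics present in the world.
#' @return list with `table` (raw [region_share_table()]) and `truth`
#'   (data.frame `country`, `true_share_topic`).
#' @export
simulate_region_breakdown <- function(w, topic_id,
                                      reference_id = "scar") {
  stopifnot(inherits(w, "latent_world"),
            topic_id %in% colnames(w$weights),
            reference_id %in% colnames(w$weights))
  wt <- w$weights[, topic_id]
  wr <- w$weights[, reference_id]
  tot <- wt + wr
  true_share <- ifelse(tot > 0, 100 * wt / tot, NA_real_)
  masked <- w$countries$masked | tot == 0
  share_t <- ifelse(masked, NA_real_, round(true_share))
  share_r <- ifelse(masked, NA_real_, 100 - round(true_share))
  list(table = region_share_table(topic_id, reference_id,
                                  w$countries$country, share_t, share_r,
                                  masked = masked, imputed = FALSE),
       truth = data.frame(country = w$countries$country,
                          true_share_topic = true_share,
                          stringsAsFactors = FALSE))
}

#' Simulate a single-topic (non-adjusted) region export
#'
#' Regional RSV for one topic alone: each country's per-volume interest
#' rescaled so the most interested country reads 100, quantized with the
#' usual rounding/censoring, `NA` for masked countries.
#'
#' @param w a [make_world_fixture()] world.
#' @param topic_id topic present in the world.
#' @return data.frame `country`, `topic_id`, `value` (character tokens,
#'   `NA` when masked).
#' @export
simulate_region_single <- function(w, topic_id) {
  stopifnot(inherits(w, "latent_world"), topic_id %in% colnames(w$weights))
  interest <- w$weights[, topic_id] / w$countries$total_volume
  interest[w$countries$masked] <- NA
  mx <- max(interest, na.rm = TRUE)
  value <- if (mx == 0) rep("0", length(interest)) else {
    scaled <- 100 * interest / mx
    tokenize_scaled(interest, scaled)
  }
  value[w$countries$masked] <- NA_character_
  data.frame(country = w$countries$country, topic_id = topic_id,
             value = value, stringsAsFactors = FALSE)
}

#' @keywords internal
topic_seed <- function(seed, salt) {
  (as.numeric(seed) * 7919 + salt) %% 2147483647
}

#' Simulate a jointly exported topic/reference pair for a world
#'
#' Draws volume-scaled latent series for the topic and the reference (each
#' with its own noise realization, as two queries in one export would have)
#' and applies the joint max-100 transform.
#'
#' @param w a [make_world_fixture()] world.
#' @param topic_id topic id.
#' @param reference_id reference topic id.
#' @param quantize as in [gt_transform_pairwise()].
#' @return as [gt_transform_pairwise()], plus `true_ratio` (the ground-truth
#'   ratio of mean latent intensities).
#' @export
simulate_pairwise <- function(w, topic_id, reference_id = "scar",
                              quantize = TRUE) {
  stopifnot(inherits(w, "latent_world"))
  mt <- w$topics[[topic_id]]
  mr <- w$topics[[reference_id]]
  lt <- simulate_latent(mt, w$months,
                        seed = topic_seed(w$seed, match(topic_id,
                                                        names(w$topics))),
                        volume_scaled = TRUE)
  lr <- simulate_latent(mr, w$months,
                        seed = topic_seed(w$seed,
                                          1000 + match(topic_id,
                                                       names(w$topics))),
                        volume_scaled = TRUE)
  out <- gt_transform_pairwise(lt, lr, topic_id, reference_id, w$months,
                               quantize = quantize)
  out$true_ratio <- mt$popularity_ratio / mr$popularity_ratio
  out
}

#' Simulate a non-adjusted interest-over-time export for a world topic
#'
#' @param w a [make_world_fixture()] world.
#' @param topic_id topic id.
#' @param quantize as in [gt_transform_single()].
#' @return raw [topic_series()] with attributes `scale_factor` (realized
#'   100/max rescaling) and `true_rsv_slope` (latent slope expressed on the
#'   observed RSV scale).
#' @export
simulate_interest_over_time <- function(w, topic_id, quantize = TRUE) {
  stopifnot(inherits(w, "latent_world"))
  m <- w$topics[[topic_id]]
  # A single-topic export is rescaled by its own maximum, so the topic's
  # latent volume (popularity_ratio) must not alter the series shape:
  # simulate the profile at ratio 1 and let the transform set the scale.
  m1 <- m
  m1$popularity_ratio <- 1
  latent <- simulate_latent(
    m1, w$months,
    seed = topic_seed(w$seed, 2000 + match(topic_id, names(w$topics))))
  out <- gt_transform_single(latent, topic_id, w$months, quantize = quantize)
  attr(out, "true_rsv_slope") <- m$slope * attr(out, "scale_factor")
  out
}

#' Write a world out as Google-Trends-dialect CSV files
#'
#' Emits, under `dir`: `nonadjusted_<topic>.csv` (single-topic interest over
#' time), `pairwise_<topic>.csv` (topic + reference, jointly scaled),
#' `region_pair_<topic>.csv` (compared breakdown by region),
#' `region_single_<topic>.csv` (non-adjusted region RSV), and
#' `ground_truth.json` with the latent parameters, realized rescaling
#' factors, and true shares.
#'
#' @param w a [make_world_fixture()] world.
#' @param dir output directory (created if missing).
#' @param reference_id the reference topic (gets no pairwise file of its
#'   own).
#' @return `dir`, invisibly.
#' @export
simulate_world_csvs <- function(w, dir, reference_id = "scar") {
  stopifnot(inherits(w, "latent_world"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- names(w$topics)
  truth_topics <- list()
  for (id in ids) {
    ts <- simulate_interest_over_time(w, id)
    write_interest_over_time(ts, file.path(dir,
                                           paste0("nonadjusted_", id,
                                                  ".csv")))
    rs <- simulate_region_single(w, id)
    reg_lines <- c(paste0("Country,", id),
                   paste(rs$country,
                         ifelse(is.na(rs$value), "", rs$value), sep = ","))
    writeLines(reg_lines, file.path(dir, paste0("region_single_", id,
                                                ".csv")), useBytes = TRUE)
    m <- w$topics[[id]]
    truth <- list(popularity_ratio = m$popularity_ratio,
                  latent_slope = m$slope,
                  true_rsv_slope = attr(ts, "true_rsv_slope"),
                  scale_factor = attr(ts, "scale_factor"),
                  seasonal = any(m$monthly_pattern != 0),
                  monthly_pattern = m$monthly_pattern,
                  amplitude = max(m$monthly_pattern) -
                    min(m$monthly_pattern))
    if (id != reference_id) {
      pw <- simulate_pairwise(w, id, reference_id)
      write_interest_over_time(list(pw$topic, pw$reference),
                               file.path(dir, paste0("pairwise_", id,
                                                     ".csv")))
      rb <- simulate_region_breakdown(w, id, reference_id)
      write_interest_by_region(rb$table,
                               file.path(dir, paste0("region_pair_", id,
                                                     ".csv")))
      truth$pairwise_scale_factor <- pw$scale_factor
      truth$true_region_share <- rb$truth$true_share_topic
    }
    truth_topics[[id]] <- truth
  }
  jsonlite::write_json(
    list(preset = w$preset, seed = w$seed, reference = reference_id,
         months = c(w$months[1], w$months[length(w$months)]),
         mask_threshold = w$mask_threshold,
         countries = w$countries, topics = truth_topics),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
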