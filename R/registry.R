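# Topic registry: the catalogue of Google Trends topics under study, the
# reference (benchmark) topic used for cross-topic anchoring, and the study
# period. Topic ids are lower-snake-case ASCII transliterations of the
# display names so they can serve as stable file and config keys.

# 34 dermatologic clinical-sign topics; 'Scar' is the benchmark because it has
# measurable search volume in essentially every analyzable country, which is
# what a cross-country anchor needs.
CLINICAL_SIGN_TOPICS <- data.frame(
  id = c("abrasion", "blister", "cafe_au_lait_spot", "cellulite", "comedo",
         "dandruff", "eczema", "erythema", "eschar", "freckle", "hair_loss",
         "hyperpigmentation", "hives", "itch", "liver_spot",
         "melanocytic_nevus", "melasma", "nevus", "nodule", "papilloma",
         "papule", "perspiration", "petechia", "pustule", "scar",
         "skin_fissure", "skin_rash", "skin_tag", "skin_ulcer",
         "stretch_marks", "telangiectasia", "vesicle", "wart", "xeroderma"),
  display_name = c("Abrasion", "Blister", "Café au lait spot",
                   "Cellulite", "Comedo", "Dandruff", "Eczema", "Erythema",
                   "Eschar", "Freckle", "Hair loss", "Hyperpigmentation",
                   "Hives", "Itch", "Liver spot", "Melanocytic nevus",
                   "Melasma", "Nevus", "Nodule", "Papilloma", "Papule",
                   "Perspiration", "Petechia", "Pustule", "Scar",
                   "Skin fissure", "Skin rash", "Skin tag", "Skin ulcer",
                   "Stretch marks", "Telangiectasia", "Vesicle", "Wart",
                   "Xeroderma"),
  stringsAsFactors = FALSE
)

DISEASE_CONTROL_TOPICS <- data.frame(
  id = c("atopic_dermatitis", "basal_cell_carcinoma", "melanoma", "psoriasis",
         "rosacea", "scabies", "squamous_cell_skin_cancer"),
  display_name = c("Atopic dermatitis", "Basal-cell carcinoma", "Melanoma",
                   "Psoriasis", "Rosacea", "Scabies",
                   "Squamous cell skin cancer"),
  stringsAsFactors = FALSE
)

NONMEDICAL_CONTROL_TOPICS <- data.frame(
  id = c("car", "fc_bayern_munich", "rome", "star_wars", "tomato"),
  display_name = c("Car", "FC Bayern Munich", "Rome", "Star Wars", "Tomato"),
  stringsAsFactors = FALSE
)

#' Construct a topic registry
#'
#' A registry holds the ordered topic catalogue (id, display name, category,
#' reference flag) plus the study period. Use [default_registry()] for the
#' study's dermatologic catalogue.
#'
#' @param topics data.frame with columns `id`, `display_name`, `category`
#'   (one of `"clinical_sign"`, `"disease_control"`, `"nonmedical_control"`)
#'   and logical `is_reference`.
#' @param period_start,period_end study period bounds as `"YYYY-MM"`.
#' @return object of class `topic_registry`.
#' @seealso [default_registry()], [validate_registry()]
#' @export
topic_registry <- function(topics, period_start = "2004-01",
                           period_end = "2019-12") {
  stopifnot(is.data.frame(topics),
            all(c("id", "display_name", "category", "is_reference") %in%
                  names(topics)))
  ym_to_index(c(period_start, period_end))  # validates format
  structure(
    list(topics = topics, period_start = period_start,
         period_end = period_end),
    class = "topic_registry"
  )
}

#' Default topic registry for the skin-problem study
#'
#' Returns the 34 clinical-sign topics with `scar` flagged as the reference
#' (benchmark) topic, optionally extended with the 7 skin-disease control
#' topics and the 5 non-medical control topics used in sensitivity analyses.
#' The default study period is January 2004 through December 2019
#' (192 monthly points).
#'
#' @param include_controls logical; append disease and non-medical controls.
#' @return a `topic_registry`.
#' @examples
#' r <- default_registry()
#' sum(r$topics$category == "clinical_sign")  # 34
#' registry_reference(r)                      # "scar"
#' @export
default_registry <- function(include_controls = FALSE) {
  signs <- CLINICAL_SIGN_TOPICS
  signs$category <- "clinical_sign"
  signs$is_reference <- signs$id == "scar"
  topics <- signs
  if (include_controls) {
    dis <- DISEASE_CONTROL_TOPICS
    dis$category <- "disease_control"
    dis$is_reference <- FALSE
    non <- NONMEDICAL_CONTROL_TOPICS
    non$category <- "nonmedical_control"
    non$is_reference <- FALSE
    topics <- rbind(topics, dis, non)
  }
  topic_registry(topics)
}

#' Validate a topic registry
#'
#' Checks the registry invariants and reports violations rather than raising:
#' unique non-empty ids, known categories, exactly one reference topic, and a
#' well-ordered study period.
#'
#' @param r a `topic_registry`.
#' @return character vector of violation messages; empty if the registry is
#'   valid.
#' @export
validate_registry <- function(r) {
  stopifnot(inherits(r, "topic_registry"))
  t <- r$topics
  msgs <- character()
  if (any(!nzchar(t$id))) msgs <- c(msgs, "empty topic id")
  dup <- unique(t$id[duplicated(t$id)])
  if (length(dup)) {
    msgs <- c(msgs, paste0("duplicate topic id: ", dup))
  }
  bad_cat <- setdiff(unique(t$category),
                     c("clinical_sign", "disease_control",
                       "nonmedical_control"))
  if (length(bad_cat)) {
    msgs <- c(msgs, paste0("unknown category: ", bad_cat))
  }
  nref <- sum(t$is_reference)
  if (nref == 0L) msgs <- c(msgs, "no topic flagged as reference")
  if (nref > 1L) {
    msgs <- c(msgs, paste0("multiple topics flagged as reference: ",
                           paste(t$id[t$is_reference], collapse = ", ")))
  }
  if (ym_to_index(r$period_end) < ym_to_index(r$period_start)) {
    msgs <- c(msgs, "period_end precedes period_start")
  }
  msgs
}

#' Reference topic id of a registry
#' @param r a `topic_registry`.
#' @return the id of the reference topic.
#' @export
registry_reference <- function(r) {
  stopifnot(inherits(r, "topic_registry"))
  r$topics$id[r$topics$is_reference][1L]
}

#' Months spanned by a registry's study period
#' @param r a `topic_registry`.
#' @return character vector of consecutive `"YYYY-MM"` months.
#' @export
registry_months <- function(r) month_seq(r$period_start, r$period_end)

#' Serialize / deserialize a registry as YAML
#'
#' The YAML block has keys `reference`, `period` (`start`/`end`) and `topics`
#' (a list of `id`/`display_name`/`category` entries), suitable for embedding
#' in an analysis config file.
#'
#' @param r a `topic_registry`.
#' @param text YAML text produced by `registry_to_yaml()`.
#' @return `registry_to_yaml()` returns a YAML string; `registry_from_yaml()`
#'   a `topic_registry`.
#' @export
registry_to_yaml <- function(r) {
  stopifnot(inherits(r, "topic_registry"))
  yaml::as.yaml(list(
    reference = registry_reference(r),
    period = list(start = r$period_start, end = r$period_end),
    topics = lapply(seq_len(nrow(r$topics)), function(i) {
      list(id = r$topics$id[i],
           display_name = r$topics$display_name[i],
           category = r$topics$category[i])
    })
  ))
}

#' @rdname registry_to_yaml
#' @export
registry_from_yaml <- function(text) {
  obj <- yaml::yaml.load(text)
  topics <- do.call(rbind, lapply(obj$topics, function(t) {
    data.frame(id = t$id, display_name = t$display_name,
               category = t$category, stringsAsFactors = FALSE)
  }))
  topics$is_reference <- topics$id == obj$reference
  topic_registry(topics, obj$period$start, obj$period$end)
}

#' @export
print.topic_registry <- function(x, ...) {
  cat("<topic_registry> ", nrow(x$topics), " topics (",
      sum(x$topics$category == "clinical_sign"), " clinical signs), ",
      "reference: ", registry_reference(x), ", period ",
      x$period_start, "..", x$period_end, "\n", sep = "")
  invisible(x)
}
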