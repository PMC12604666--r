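#' Default frequency-weight table
#'
#' Numeric weights attached to symptom-frequency terms for disorder
#' scoring: a symptom that always accompanies a disorder contributes 4
#' (strong relationship), very frequently 3, frequently 2, sometimes 1,
#' unusually and rarely 0.5 each, and an absent frequency 0. The mapping of
#' the three weakest terms preserves the monotone ordering of the
#' vocabulary; pass a modified table to the scoring functions to use a
#' different reading.
#'
#' @return Named numeric vector over [frequency_terms].
#' @examples
#' default_frequency_weights()["ALWAYS"]
#' @export
default_frequency_weights <- function() {
  c(ALWAYS = 4, VERY_FREQUENTLY = 3, FREQUENTLY = 2, SOMETIMES = 1,
    UNUSUALLY = 0.5, RARELY = 0.5, NONE = 0)
}

.check_weights <- function(weights) {
  missing <- setdiff(frequency_terms, names(weights))
  if (length(missing) > 0L) {
    abort(paste0("weight table must name every frequency term; missing: ",
                 paste(missing, collapse = ", ")))
  }
  w <- weights[frequency_terms]
  if (any(w < 0)) abort("weights must be non-negative")
  if (any(diff(unname(w)) > 0)) {
    abort(paste0("weights must be monotone non-increasing in the order ",
                 paste(frequency_terms, collapse = " >= ")))
  }
  w
}

#' Look up the weight of a frequency term
#'
#' @param term Character vector of terms from [frequency_terms].
#' @param weights Named numeric weight table; see
#'   [default_frequency_weights()].
#' @return Numeric vector of weights; `NONE` maps to 0 under the default
#'   table.
#' @export
frequency_weight <- function(term, weights = default_frequency_weights()) {
  w <- .check_weights(weights)
  if (!all(term %in% frequency_terms)) {
    abort("unknown frequency term; see frequency_terms")
  }
  unname(w[term])
}

.filter_category <- function(associations, disorders, category) {
  if (is.null(category) || identical(toupper(category), "ALL")) {
    return(associations)
  }
  if (is.null(disorders)) {
    abort("a disorders table is required to filter by category")
  }
  valid <- sort(unique(disorders$category))
  if (!category %in% valid) {
    abort(paste0("unknown category '", category, "'; valid categories: ",
                 paste(valid, collapse = ", ")))
  }
  keep <- disorders$name[disorders$category == category]
  associations[associations$disorder_name %in% keep, , drop = FALSE]
}

#' List the clinical symptoms available for selection
#'
#' @param associations Symptom-association tibble
#'   ([read_symptom_associations()]).
#' @param disorders Optional disorder tibble, required when filtering by
#'   category.
#' @param category A category name or `"ALL"` (default).
#' @return Sorted unique character vector of symptom terms.
#' @export
list_symptoms <- function(associations, disorders = NULL, category = "ALL") {
  a <- .filter_category(associations, disorders, category)
  sort(unique(a$symptom))
}

#' Score every disorder against a symptom selection
#'
#' A disorder's score is the sum, over the selected symptoms it is
#' associated with, of the weight of the association's frequency term:
#' `S(d) = sum over s in selection of w(freq(s, d))`. Selected symptoms a
#' disorder lacks contribute nothing, as do the disorder's unselected
#' symptoms.
#'
#' @param associations Symptom-association tibble.
#' @param symptoms Non-empty character vector of selected symptoms.
#' @param weights Frequency-weight table.
#' @return Tibble with one row per disorder carrying at least one selected
#'   symptom: `disorder_name`, `score`, `n_matched`, `matched_symptoms`
#'   (list-column of tibbles with `symptom`, `frequency_term`, `weight`).
#' @export
score_disorders <- function(associations, symptoms,
                            weights = default_frequency_weights()) {
  w <- .check_weights(weights)
  symptoms <- unique(as.character(symptoms))
  if (length(symptoms) == 0L || all(!nzchar(symptoms))) {
    abort("at least one symptom must be selected")
  }
  hits <- associations |>
    filter(.data$symptom %in% symptoms) |>
    mutate(weight = unname(w[.data$frequency_term]))
  if (nrow(hits) == 0L) {
    return(tibble(disorder_name = character(0), score = numeric(0),
                  n_matched = integer(0), matched_symptoms = list()))
  }
  hits |>
    group_by(.data$disorder_name) |>
    summarise(
      score = sum(.data$weight),
      n_matched = dplyr::n(),
      matched_symptoms = list(tibble(
        symptom = symptom,
        frequency_term = frequency_term,
        weight = weight
      )),
      .groups = "drop"
    )
}

#' Predict disorders from selected symptoms
#'
#' Scores every disorder passing the category filter with
#' [score_disorders()], drops zero-score disorders (a disorder sharing no
#' selected symptom is not a prediction), sorts by score descending with
#' exact-score ties broken alphabetically by disorder name
#' (case-insensitive), and returns the top `k` (default 10).
#'
#' @param associations Symptom-association tibble.
#' @param symptoms Non-empty character vector of selected symptoms.
#' @param disorders Optional disorder tibble (adds `category` to the output
#'   and enables category filtering).
#' @param category A category name or `"ALL"`.
#' @param k Maximum number of predictions returned; default 10.
#' @param weights Frequency-weight table.
#' @return A `rgd_prediction` tibble: `rank`, `disorder_name`, `score`,
#'   `n_matched`, `category` (if `disorders` given), `matched_symptoms`
#'   list-column. Deterministic for fixed inputs.
#' @examples
#' assoc <- tibble::tibble(
#'   disorder_name = c("A", "A", "B"),
#'   symptom = c("seizures", "ataxia", "seizures"),
#'   medical_term = NA_character_,
#'   frequency_term = c("ALWAYS", "FREQUENTLY", "SOMETIMES"),
#'   description = NA_character_)
#' predict_disorders(assoc, c("seizures", "ataxia"))
#' @export
predict_disorders <- function(associations, symptoms, disorders = NULL,
                              category = "ALL", k = 10,
                              weights = default_frequency_weights()) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1) {
    abort("k must be a positive integer")
  }
  k <- as.integer(k)
  a <- .filter_category(associations, disorders, category)
  scored <- score_disorders(a, symptoms, weights) |>
    filter(.data$score > 0)
  scored <- scored[order(-scored$score, tolower(scored$disorder_name)), ]
  scored <- head(scored, k)
  scored$rank <- seq_len(nrow(scored))
  if (!is.null(disorders)) {
    scored <- left_join(scored,
                        distinct(disorders[c("name", "category")]),
                        by = c(disorder_name = "name"))
  } else {
    scored$category <- NA_character_
  }
  out <- relocate(scored, "rank", "disorder_name", "score", "n_matched",
                  "category")
  class(out) <- c("rgd_prediction", class(out))
  attr(out, "symptoms") <- sort(unique(as.character(symptoms)))
  out
}

#' @export
print.rgd_prediction <- function(x, ...) {
  cat("# Top predicted disorders (", nrow(x), " of k requested)\n", sep = "")
  NextMethod()
}
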