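#' Read a model specification from JSON
#'
#' Parses and schema-validates a model-specification document of the form
#' ```
#' {"categories":  [{"label": "...", "reference": true}, ...],
#'  "covariates":  [{"name": "...", "kind": "continuous|binary",
#'                   "unit": "...", "range": [lo, hi]}, ...],
#'  "intercepts":  [...],
#'  "coefficients": [[...], ...],
#'  "metadata":    {...}}
#' ```
#' Coefficient rows follow the non-reference categories in listed order;
#' columns follow the covariates. Unknown keys are rejected; at most one
#' category may be flagged `reference` (default: the last listed). Numbers
#' are parsed at full double precision. An optional free-form `metadata`
#' block is preserved as the `"metadata"` attribute of the result.
#'
#' @param path path to a JSON file, or a JSON string.
#' @return An [mn_model()].
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  errs <- character()
  err <- function(where, msg) errs[[length(errs) + 1L]] <<-
    sprintf("%s: %s", where, msg)

  allowed <- c("categories", "covariates", "intercepts", "coefficients",
               "metadata")
  unknown <- setdiff(names(doc), allowed)
  for (u in unknown) err(paste0("$.", u), "unknown key")
  for (req in setdiff(allowed, "metadata"))
    if (is.null(doc[[req]])) err(paste0("$.", req), "missing")
  if (length(errs)) stop_mn("model spec schema violation:\n  - %s",
                            paste(errs, collapse = "\n  - "))

  cats <- character(); ref <- NULL
  for (i in seq_along(doc$categories)) {
    c_i <- doc$categories[[i]]
    where <- sprintf("$.categories[%d]", i)
    bad <- setdiff(names(c_i), c("label", "reference"))
    for (u in bad) err(paste0(where, ".", u), "unknown key")
    if (!is.character(c_i$label %||% NULL)) {
      err(paste0(where, ".label"), "must be a string")
    } else {
      cats <- c(cats, c_i$label)
      if (isTRUE(c_i$reference)) {
        if (!is.null(ref)) err(where, "more than one reference category")
        ref <- c_i$label
      }
    }
  }
  K <- length(cats)
  cov_rows <- list()
  for (i in seq_along(doc$covariates)) {
    cv <- doc$covariates[[i]]
    where <- sprintf("$.covariates[%d]", i)
    bad <- setdiff(names(cv), c("name", "kind", "unit", "range"))
    for (u in bad) err(paste0(where, ".", u), "unknown key")
    if (!is.character(cv$name %||% NULL))
      err(paste0(where, ".name"), "must be a string")
    if (!is.character(cv$kind %||% NULL) ||
        !cv$kind %in% c("continuous", "binary"))
      err(paste0(where, ".kind"), "must be 'continuous' or 'binary'")
    rng <- unlist(cv$range)
    if (length(rng) != 2L || !is.numeric(rng))
      err(paste0(where, ".range"), "must be a numeric pair [lo, hi]")
    else
      cov_rows[[length(cov_rows) + 1L]] <- data.frame(
        name = cv$name %||% NA_character_,
        kind = cv$kind %||% NA_character_,
        unit = cv$unit %||% "", lower = rng[1], upper = rng[2],
        stringsAsFactors = FALSE)
  }
  intercepts <- unlist(doc$intercepts)
  if (!is.numeric(intercepts) || length(intercepts) != K - 1L)
    err("$.intercepts",
        sprintf("must be %d numbers (one per non-reference category), got %d",
                K - 1L, length(intercepts)))
  if (length(doc$coefficients) != K - 1L)
    err("$.coefficients",
        sprintf("must have %d rows (one per non-reference category), got %d",
                K - 1L, length(doc$coefficients)))
  J <- length(cov_rows)
  coef_rows <- lapply(seq_along(doc$coefficients), function(i) {
    row <- unlist(doc$coefficients[[i]])
    if (!is.numeric(row) || length(row) != J)
      err(sprintf("$.coefficients[%d]", i),
          sprintf("must be %d numbers (one per covariate), got %d",
                  J, length(row)))
    row
  })
  if (length(errs)) stop_mn("model spec schema violation:\n  - %s",
                            paste(errs, collapse = "\n  - "))
  model <- mn_model(categories = cats,
                    covariates = do.call(rbind, cov_rows),
                    intercepts = intercepts,
                    coefficients = do.call(rbind, coef_rows),
                    reference = ref)
  attr(model, "metadata") <- doc$metadata
  model
}

#' Write a model specification to JSON
#'
#' Inverse of [read_model_json()]; numbers are written at full precision,
#' so a save-then-load round trip reproduces the model exactly.
#'
#' @param model an [mn_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  doc <- list(
    categories = lapply(model$categories, function(lab) {
      if (identical(lab, model$reference))
        list(label = lab, reference = TRUE) else list(label = lab)
    }),
    covariates = lapply(seq_len(nrow(model$covariates)), function(j) {
      cv <- model$covariates[j, ]
      list(name = cv$name, kind = cv$kind, unit = cv$unit,
           range = c(cv$lower, cv$upper))
    }),
    intercepts = unname(model$alpha),
    coefficients = lapply(seq_len(nrow(model$beta)),
                          function(k) unname(model$beta[k, ])))
  md <- attr(model, "metadata")
  if (!is.null(md)) doc$metadata <- md
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' The packaged antepartum operative-delivery model
#'
#' Loads the published multinomial antepartum prediction model for the
#' risk of operative delivery (five outcome categories: spontaneous
#' vaginal delivery as reference, and instrumental vaginal delivery or
#' caesarean section each due to fetal distress or failure to progress;
#' seven antepartum covariates), with coefficients as published. The
#' covariate ranges in the file are plausible clinical ranges chosen for
#' this package (marked `synthetic_ranges` in the file's metadata); the
#' development-data ranges were not published.
#'
#' @return An [mn_model()] with a `"metadata"` attribute carrying the
#'   published hypothetical case profile and its published chart readings.
#' @export
schuit_model <- function() {
  read_model_json(system.file("extdata", "schuit2012.json",
                              package = "multinomogram", mustWork = TRUE))
}

#' @rdname schuit_model
#' @return `schuit_case()`: the published hypothetical case profile (a
#'   32-year-old nulliparous diabetic woman at 40 weeks' gestation
#'   expecting a boy with an estimated birth weight of 3540 g) as a named
#'   numeric vector.
#' @export
schuit_case <- function() {
  md <- attr(schuit_model(), "metadata")
  unlist(md$published_case$profile)
}

#' Read covariate profiles from CSV
#'
#' One row per subject, header naming the covariates. When a model is
#' supplied the columns are checked and reordered to the model's
#' covariate order.
#'
#' @param path CSV file path.
#' @param model optionally, an [mn_model()] to align against.
#' @return Data frame of profiles.
#' @export
read_profiles <- function(path, model = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(model)) {
    missing <- setdiff(model$covariates$name, names(df))
    if (length(missing))
      stop_mn("profile CSV is missing covariate column(s): %s",
              paste(missing, collapse = ", "))
    df <- df[, model$covariates$name, drop = FALSE]
  }
  df
}

#' Write predicted probabilities to CSV
#'
#' @param predictions data frame as returned by [predict.mn_model()].
#' @param path output file path, or `""` for standard output.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.csv(predictions, path, row.names = FALSE)
  invisible(path)
}
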