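#' Specify a fitted multinomial logistic prediction model
#'
#' Represents a fitted multinomial logistic regression model with `K`
#' mutually exclusive outcome categories and `J` covariates, given as a
#' coefficient table (the model is supplied, never estimated here). One
#' category acts as the reference; the remaining `K - 1` categories each
#' carry an intercept \eqn{\alpha_k} and a row of coefficients
#' \eqn{\beta_{jk}}, so that the linear predictor (log-odds versus the
#' reference) for category `k` at covariate profile `x` is
#' \deqn{lp_k(x) = \alpha_k + \sum_j \beta_{jk} x_j.}
#'
#' Covariates are either continuous (with a declared relevant range
#' `[lower, upper]`) or binary (coded 0/1). The declared ranges drive the
#' scoring-chart standardization and the default nomogram axis ranges, so
#' they are part of the model specification. Multi-level categorical
#' covariates must be supplied pre-coded as 0/1 dummies.
#'
#' @param categories character vector of `K >= 2` distinct outcome labels.
#' @param covariates data frame with one row per covariate and columns
#'   `name`, `kind` (`"continuous"` or `"binary"`), `lower`, `upper`, and
#'   optionally `unit` (free-text unit string). Binary covariates must use
#'   `lower = 0`, `upper = 1`.
#' @param intercepts numeric vector of `K - 1` intercepts, ordered as the
#'   non-reference categories appear in `categories`.
#' @param coefficients numeric `(K - 1) x J` matrix of log-odds-ratio
#'   coefficients; rows follow the non-reference category order, columns
#'   follow the covariate order.
#' @param reference label of the reference category. Defaults to the last
#'   element of `categories`.
#'
#' @return An object of class `"mn_model"`.
#' @seealso [validate_model()], [category_probabilities()],
#'   [scoring_chart()], [nomogram_layout()]
#' @examples
#' m <- mn_model(
#'   categories = c("A", "B", "none"),
#'   covariates = data.frame(
#'     name = c("x1", "x2"), kind = c("continuous", "binary"),
#'     lower = c(0, 0), upper = c(10, 1)),
#'   intercepts = c(-2, -1),
#'   coefficients = rbind(c(0.2, 1.0), c(-0.1, 2.0)))
#' category_probabilities(m, c(x1 = 5, x2 = 1))$pi
#' @export
mn_model <- function(categories, covariates, intercepts, coefficients,
                     reference = NULL) {
  categories <- as.character(categories)
  reference <- reference %||% categories[length(categories)]
  if (!is.data.frame(covariates))
    stop_mn("covariates must be a data frame")
  if (is.null(covariates$unit)) covariates$unit <- ""
  covariates <- data.frame(
    name = as.character(covariates$name),
    kind = as.character(covariates$kind),
    unit = as.character(covariates$unit),
    lower = as.numeric(covariates$lower),
    upper = as.numeric(covariates$upper),
    stringsAsFactors = FALSE)
  coefficients <- rbind(coefficients)
  model <- structure(
    list(categories = categories,
         reference = reference,
         covariates = covariates,
         alpha = as.numeric(intercepts),
         beta = coefficients),
    class = "mn_model")
  findings <- validate_model(model)
  if (length(findings$errors))
    stop_mn("invalid model specification:\n  - %s",
            paste(findings$errors, collapse = "\n  - "))
  nonref <- nonref_categories(model)
  names(model$alpha) <- nonref
  dimnames(model$beta) <- list(nonref, covariates$name)
  model
}

#' Validate a multinomial model specification
#'
#' Structural and numerical checks on a model specification, returned as
#' findings rather than raised as conditions: `errors` are violations that
#' make the model unusable (dimension mismatches, non-finite values, bad
#' ranges), `warnings` flag legal but suspicious content (a covariate whose
#' coefficients are all zero and so carries no points; a `K = 2` model,
#' which is a plain binary logistic model).
#'
#' @param model an [mn_model()] object, or a bare list with the same fields
#'   (so that broken specifications can be diagnosed before construction).
#' @return An object of class `"mn_findings"`: a list with character
#'   vectors `errors` and `warnings`.
#' @export
validate_model <- function(model) {
  errors <- character()
  warnings <- character()
  cats <- as.character(model$categories %||% character())
  K <- length(cats)
  if (K < 2) errors <- c(errors, "need at least 2 outcome categories")
  if (anyDuplicated(cats))
    errors <- c(errors, "duplicated category labels")
  ref <- model$reference
  if (is.null(ref) || length(ref) != 1L || !ref %in% cats)
    errors <- c(errors, "exactly one category must be flagged as reference")
  cov <- model$covariates
  J <- if (is.data.frame(cov)) nrow(cov) else 0L
  if (J < 1) errors <- c(errors, "need at least 1 covariate")
  if (J >= 1) {
    if (anyDuplicated(cov$name))
      errors <- c(errors, "duplicated covariate names")
    bad_kind <- !cov$kind %in% c("continuous", "binary")
    if (any(bad_kind))
      errors <- c(errors, sprintf(
        "covariate '%s': kind must be 'continuous' or 'binary'",
        cov$name[bad_kind]))
    if (!all(is.finite(cov$lower)) || !all(is.finite(cov$upper))) {
      errors <- c(errors, "covariate ranges must be finite")
    } else {
      cont <- cov$kind == "continuous"
      bad_rng <- cont & cov$lower >= cov$upper
      if (any(bad_rng))
        errors <- c(errors, sprintf(
          "covariate '%s': lower bound must be below upper bound",
          cov$name[bad_rng]))
      bin <- cov$kind == "binary"
      bad_bin <- bin & (cov$lower != 0 | cov$upper != 1)
      if (any(bad_bin))
        errors <- c(errors, sprintf(
          "covariate '%s': binary covariates must have range [0, 1]",
          cov$name[bad_bin]))
    }
  }
  alpha <- model$alpha
  beta <- model$beta
  if (length(alpha) != K - 1L)
    errors <- c(errors, sprintf(
      "expected %d intercepts (one per non-reference category), got %d",
      K - 1L, length(alpha)))
  if (is.null(dim(beta)) || nrow(beta) != K - 1L || ncol(beta) != J)
    errors <- c(errors, sprintf(
      "coefficient matrix must be %d x %d (categories x covariates), got %s",
      K - 1L, J,
      if (is.null(dim(beta))) "a non-matrix" else
        paste(dim(beta), collapse = " x ")))
  if (!all(is.finite(alpha)) || !all(is.finite(unlist(beta))))
    errors <- c(errors, "intercepts and coefficients must be finite")
  if (!length(errors)) {
    zero_col <- colSums(abs(beta)) == 0
    if (any(zero_col))
      warnings <- c(warnings, sprintf(
        "covariate '%s' has all-zero coefficients and carries no points",
        cov$name[zero_col]))
    if (K == 2L)
      warnings <- c(warnings,
        "K = 2: the model is an ordinary binary logistic model")
  }
  structure(list(errors = errors, warnings = warnings),
            class = "mn_findings")
}

#' @export
print.mn_findings <- function(x, ...) {
  if (!length(x$errors) && !length(x$warnings)) {
    cat("model specification OK: no errors, no warnings\n")
  } else {
    for (e in x$errors) cat("error:  ", e, "\n", sep = "")
    for (w in x$warnings) cat("warning:", w, "\n")
  }
  invisible(x)
}

#' @export
print.mn_model <- function(x, ...) {
  K <- length(x$categories)
  cat(sprintf("Multinomial logistic model: %d categories, %d covariates\n",
              K, nrow(x$covariates)))
  cat("  reference category:", x$reference, "\n")
  cat("  categories:", paste(x$categories, collapse = ", "), "\n")
  cat("  covariates:\n")
  for (j in seq_len(nrow(x$covariates))) {
    with(x$covariates[j, ], cat(sprintf(
      "    %-20s %-10s [%g, %g] %s\n", name, kind, lower, upper, unit)))
  }
  invisible(x)
}

#' Linear predictors for a covariate profile
#'
#' Evaluates the `K - 1` linear predictors
#' \eqn{lp_k(x) = \alpha_k + \sum_j \beta_{jk} x_j}, the log-odds of each
#' non-reference category versus the reference category.
#'
#' @param model an [mn_model()].
#' @param profile numeric vector of covariate values, named by covariate or
#'   positional in the model's covariate order.
#' @param clamp if `TRUE`, out-of-range values are truncated to the
#'   declared covariate range instead of raising an error.
#' @return Named numeric vector of `K - 1` log-odds, in non-reference
#'   category order.
#' @export
linear_predictors <- function(model, profile, clamp = FALSE) {
  x <- align_profile(model, profile, clamp = clamp)
  l <- as.vector(model$alpha + model$beta %*% x)
  names(l) <- nonref_categories(model)
  l
}

#' Shared log-denominator term s of the log-probability decomposition
#'
#' Computes \eqn{s = -\ln(1 + \sum_p e^{lp_p})}, the term shared by all
#' category log-probabilities: \eqn{\ln \pi_k = lp_k + s} for non-reference
#' categories and \eqn{\ln \pi_K = s} for the reference. `s` is always
#' negative for finite linear predictors. Evaluated with log-sum-exp
#' stabilization so extreme coefficients do not overflow.
#'
#' @param l numeric vector of `K - 1` linear predictors.
#' @return Scalar `s < 0`.
#' @export
s_value <- function(l) {
  if (!length(l) || !all(is.finite(l)))
    stop_mn("linear predictors must be a non-empty finite vector")
  m <- max(0, l)
  -(m + log(sum(exp(c(0, l) - m))))
}

#' Category probabilities for a covariate profile
#'
#' Evaluates the multinomial logistic probabilities
#' \deqn{\pi_k(x) = e^{lp_k(x)} / (1 + \sum_p e^{lp_p(x)}), \qquad
#'       \pi_K(x) = 1 / (1 + \sum_p e^{lp_p(x)}),}
#' together with the additive decomposition the nomogram exploits:
#' on the log scale \eqn{\ln \pi_k = lp_k + s} with the shared term
#' \eqn{s} of [s_value()].
#'
#' @inheritParams linear_predictors
#' @return An object of class `"mn_prediction"`: a list with `l` (the
#'   `K - 1` linear predictors), `s` (scalar), `o` (the `K` log
#'   probabilities, in model category order), and `pi` (the `K`
#'   probabilities, in model category order, summing to 1).
#' @examples
#' m <- schuit_model()
#' round(category_probabilities(m, schuit_case())$pi, 3)
#' @export
category_probabilities <- function(model, profile, clamp = FALSE) {
  l <- linear_predictors(model, profile, clamp = clamp)
  s <- s_value(l)
  o_by_cat <- c(l + s, stats::setNames(s, model$reference))
  o <- o_by_cat[model$categories]
  structure(list(l = l, s = s, o = o, pi = exp(o)),
            class = "mn_prediction")
}

#' @export
print.mn_prediction <- function(x, digits = 4, ...) {
  cat("Multinomial prediction\n")
  cat("  linear predictors:\n")
  print(round(x$l, digits))
  cat(sprintf("  s = %.*f   (sum exp(lp) = %.*f)\n",
              digits, x$s, digits, expm1(-x$s)))
  cat("  probabilities:\n")
  print(round(x$pi, digits))
  invisible(x)
}

#' Predict probabilities for a batch of profiles
#'
#' @param object an [mn_model()].
#' @param newdata data frame of profiles, one row per subject, with one
#'   column per model covariate (by name).
#' @param type `"probs"` for category probabilities (default) or `"lp"`
#'   for linear predictors.
#' @param clamp truncate out-of-range values to the declared ranges.
#' @param ... unused.
#' @return Data frame with one row per profile and one column per category
#'   (`type = "probs"`) or per non-reference category (`type = "lp"`).
#' @export
predict.mn_model <- function(object, newdata, type = c("probs", "lp"),
                             clamp = FALSE, ...) {
  type <- match.arg(type)
  if (!is.data.frame(newdata)) newdata <- as.data.frame(newdata)
  rows <- lapply(seq_len(nrow(newdata)), function(i) {
    pred <- category_probabilities(object, newdata[i, , drop = FALSE],
                                   clamp = clamp)
    if (type == "probs") pred$pi else pred$l
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- if (type == "probs") object$categories else
    nonref_categories(object)
  out
}
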