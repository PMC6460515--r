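# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mn <- function(...) stop(sprintf(...), call. = FALSE)

# non-reference category labels, in model category order
nonref_categories <- function(model) {
  setdiff(model$categories, model$reference)
}

# Align a covariate profile to the model's covariate order.
# Accepts a named or positional numeric vector (or 1-row data frame);
# checks finiteness and the declared ranges (strict by default, clamped
# to [lower, upper] when clamp = TRUE).
align_profile <- function(model, profile, clamp = FALSE) {
  if (is.data.frame(profile)) {
    if (nrow(profile) != 1L)
      stop_mn("expected a single profile, got %d rows", nrow(profile))
    profile <- unlist(profile[1L, , drop = TRUE])
  }
  profile <- unlist(profile)
  J <- nrow(model$covariates)
  nm <- model$covariates$name
  if (!is.null(names(profile)) && any(nzchar(names(profile)))) {
    missing <- setdiff(nm, names(profile))
    if (length(missing))
      stop_mn("profile is missing covariate(s): %s",
              paste(missing, collapse = ", "))
    profile <- profile[nm]
  } else if (length(profile) != J) {
    stop_mn("profile has %d values but the model has %d covariates",
            length(profile), J)
  }
  x <- as.numeric(profile)
  if (!all(is.finite(x)))
    stop_mn("profile contains non-finite values")
  lo <- model$covariates$lower
  up <- model$covariates$upper
  eps <- 1e-9 * pmax(1, up - lo)
  out <- x < lo - eps | x > up + eps
  if (any(out)) {
    if (clamp) {
      x <- pmin(pmax(x, lo), up)
    } else {
      stop_mn("profile value out of declared range for covariate(s): %s",
              paste(nm[out], collapse = ", "))
    }
  } else {
    # absorb representation noise at the boundaries
    x <- pmin(pmax(x, lo), up)
  }
  names(x) <- nm
  x
}

# fingerprint of a model's numeric content, used to guard against mixing
# a layout and a scoring chart built from different models
model_fingerprint <- function(model) {
  paste(c(model$categories, model$reference, model$covariates$name,
          model$covariates$kind,
          format(c(model$alpha, as.vector(model$beta),
                   model$covariates$lower, model$covariates$upper),
                 digits = 17L)),
        collapse = "|")
}

# 1-2-5 "nice number" values per decade covering [lo, hi], lo > 0
decade_125 <- function(lo, hi) {
  stopifnot(lo > 0, hi >= lo)
  decades <- floor(log10(lo)):ceiling(log10(hi))
  v <- sort(as.vector(outer(c(1, 2, 5), 10^decades)))
  v[v >= lo * (1 - 1e-12) & v <= hi * (1 + 1e-12)]
}

# enumerate the vertices of the covariate box as an n x J matrix
covariate_vertices <- function(model) {
  J <- nrow(model$covariates)
  grid <- expand.grid(lapply(seq_len(J), function(j) {
    c(model$covariates$lower[j], model$covariates$upper[j])
  }), KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(grid)
  colnames(m) <- model$covariates$name
  m
}

# deterministic number formatting for SVG output
fmt_px <- function(x) sprintf("%.2f", x)
fmt_attr <- function(x) sprintf("%.10g", x)

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# run an expression with a locally seeded RNG, restoring global state
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
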