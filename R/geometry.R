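#' Construct the parallel-scale nomogram layout
#'
#' Builds the geometry of a three-axis parallel-scale nomogram for the
#' additive relation \eqn{o = l + s} between a category's log probability
#' `o`, its linear predictor `l` and the shared term `s`. The two outer
#' axes (`L` left, `S` right) have common height `h` and horizontal
#' distance `d`; their scaling factors are
#' \eqn{m_1 = h / (l^{up} - l^{low})} and
#' \eqn{m_3 = h / (s^{up} - s^{low})}. The middle `O` axis carries scaling
#' factor \eqn{m_2 = m_1 m_3 / (m_1 + m_3)} and sits at horizontal offset
#' \eqn{d_{LO} = d - d / (m_1 / m_3 + 1)} from the `L` axis (equivalently
#' \eqn{d \, m_1 / (m_1 + m_3)}; both forms are computed and must agree).
#' All three axes share a common baseline: position 0 on each axis is its
#' lower value, so a straight line (isopleth) through `l` on `L` and `s`
#' on `S` crosses `O` exactly at \eqn{o = l + s}.
#'
#' @param model optionally, an [mn_model()]; required when `l_range` or
#'   `s_range` is missing, in which case [default_ranges()] supplies them.
#' @param h common axis height, in arbitrary length units (e.g. cm).
#' @param d horizontal distance between the outer axes, same units.
#' @param l_range numeric `c(lower, upper)` range of the `L` axis
#'   (log-odds).
#' @param s_range numeric `c(lower, upper)` range of the `S` axis (log
#'   scale; `s` is always negative).
#' @param margin additive widening applied to automatically derived ranges
#'   (log units); passed to [default_ranges()].
#' @param profiles optional data frame of observed profiles from which
#'   automatic ranges are taken instead of the covariate box; passed to
#'   [default_ranges()].
#' @return An object of class `"nomogram_layout"` with fields `h`, `d`,
#'   `l_range`, `s_range`, `o_low = l_low + s_low`, `m1`, `m2`, `m3`,
#'   and `d_LO`.
#' @examples
#' lay <- nomogram_layout(h = 10, d = 10, l_range = c(-5, 0),
#'                        s_range = c(-2, 0))
#' c(lay$m1, lay$m2, lay$m3, lay$d_LO)
#' @export
nomogram_layout <- function(model = NULL, h = 10, d = 10,
                            l_range = NULL, s_range = NULL,
                            margin = 0, profiles = NULL) {
  if (!is.finite(h) || h <= 0 || !is.finite(d) || d <= 0)
    stop_mn("axis height h and distance d must be positive")
  if (is.null(l_range) || is.null(s_range)) {
    if (is.null(model))
      stop_mn("supply either a model or explicit l_range and s_range")
    auto <- default_ranges(model, margin = margin, profiles = profiles)
    l_range <- l_range %||% auto$l_range
    s_range <- s_range %||% auto$s_range
  }
  l_range <- as.numeric(l_range)
  s_range <- as.numeric(s_range)
  if (length(l_range) != 2L || !all(is.finite(l_range)) ||
      l_range[1] >= l_range[2])
    stop_mn("l_range must be a finite increasing pair")
  if (length(s_range) != 2L || !all(is.finite(s_range)) ||
      s_range[1] >= s_range[2])
    stop_mn("s_range must be a finite increasing pair")
  m1 <- h / diff(l_range)
  m3 <- h / diff(s_range)
  m2 <- m1 * m3 / (m1 + m3)
  d_LO <- d - d / (m1 / m3 + 1)
  d_LO_alt <- d * m1 / (m1 + m3)
  if (abs(d_LO - d_LO_alt) > 1e-12 * d)
    stop_mn("internal error: the two d_LO expressions disagree")
  structure(
    list(h = h, d = d, l_range = l_range, s_range = s_range,
         o_low = l_range[1] + s_range[1],
         m1 = m1, m2 = m2, m3 = m3, d_LO = d_LO,
         model_fingerprint = if (!is.null(model)) model_fingerprint(model)),
    class = "nomogram_layout")
}

#' @export
print.nomogram_layout <- function(x, ...) {
  cat("Parallel-scale nomogram layout\n")
  cat(sprintf("  h = %g, d = %g (d_LO = %g)\n", x$h, x$d, x$d_LO))
  cat(sprintf("  L: [%g, %g]  m1 = %g\n", x$l_range[1], x$l_range[2], x$m1))
  cat(sprintf("  S: [%g, %g]  m3 = %g\n", x$s_range[1], x$s_range[2], x$m3))
  cat(sprintf("  O: log-probability from o_low = %g  m2 = %g\n",
              x$o_low, x$m2))
  invisible(x)
}

#' Default axis ranges from the covariate box
#'
#' Derives the `L` and `S` axis ranges a model can reach over its declared
#' covariate ranges. The linear predictors are affine, hence coordinate-wise
#' monotone, so their extremes over the covariate box occur at its
#' vertices; `l_range` is the range of all `K - 1` linear predictors over
#' the `2^J` vertices. The sum \eqn{g(x) = \sum_p e^{lp_p(x)}} is convex
#' in `x`, so its maximum (giving `s_low`) is also attained at a vertex,
#' while its minimum (giving `s_up`) may be interior and is found by
#' box-constrained minimization polished from the best vertex.
#'
#' When `profiles` is supplied, ranges are instead taken from the observed
#' profiles, mirroring the option of ranging axes by the development data.
#' With more than `vertex_cap` covariates the vertex enumeration is
#' replaced by conservative coordinate-wise bounds, with a warning.
#'
#' @inheritParams nomogram_layout
#' @param vertex_cap largest `J` for which the `2^J` vertex enumeration is
#'   attempted.
#' @return List with `l_range` and `s_range`, each `c(lower, upper)`.
#' @export
default_ranges <- function(model, margin = 0, profiles = NULL,
                           vertex_cap = 20) {
  findings <- validate_model(model)
  if (length(findings$errors))
    stop_mn("invalid model: %s", paste(findings$errors, collapse = "; "))
  J <- nrow(model$covariates)
  lo <- model$covariates$lower
  up <- model$covariates$upper
  if (!is.null(profiles)) {
    X <- as.matrix(profiles[, model$covariates$name, drop = FALSE])
    L <- matrix(model$alpha, nrow(X), length(model$alpha), byrow = TRUE) +
      X %*% t(model$beta)
    l_range <- range(L)
    s_range <- range(-log1p(rowSums(exp(L))))
  } else if (J <= vertex_cap) {
    V <- covariate_vertices(model)
    L <- matrix(model$alpha, nrow(V), length(model$alpha), byrow = TRUE) +
      V %*% t(model$beta)
    l_range <- range(L)
    g <- rowSums(exp(L))
    s_low <- -log1p(max(g))          # max of a convex g is at a vertex
    g_fun <- function(x) sum(exp(model$alpha + as.vector(model$beta %*% x)))
    g_grad <- function(x) {
      e <- exp(model$alpha + as.vector(model$beta %*% x))
      as.vector(t(model$beta) %*% e)
    }
    start <- V[which.min(g), ]
    g_min <- min(g)
    for (par in list(start, (lo + up) / 2)) {
      fit <- tryCatch(
        stats::optim(par, g_fun, g_grad, method = "L-BFGS-B",
                     lower = lo, upper = up),
        error = function(e) NULL)
      if (!is.null(fit)) g_min <- min(g_min, fit$value)
    }
    s_range <- c(s_low, -log1p(g_min))
  } else {
    warning(sprintf(
      "%d covariates exceed the vertex enumeration cap (%d); using conservative coordinate-wise bounds",
      J, vertex_cap), call. = FALSE)
    contrib_lo <- pmin(sweep(model$beta, 2, lo, "*"),
                       sweep(model$beta, 2, up, "*"))
    contrib_up <- pmax(sweep(model$beta, 2, lo, "*"),
                       sweep(model$beta, 2, up, "*"))
    l_min <- model$alpha + rowSums(contrib_lo)
    l_max <- model$alpha + rowSums(contrib_up)
    l_range <- c(min(l_min), max(l_max))
    s_range <- c(-log1p(sum(exp(l_max))), -log1p(sum(exp(l_min))))
  }
  if (diff(l_range) <= 0 || diff(s_range) <= 0)
    stop_mn(paste(
      "degenerate axis range (the model spans no variation over its",
      "covariate box); supply explicit l_range and s_range"))
  l_range <- l_range + c(-1, 1) * margin
  s_range <- s_range + c(-1, 1) * margin
  list(l_range = l_range, s_range = s_range)
}

# thin a 1-2-5 tick sequence that spans too many decades to label legibly:
# fall back to powers of ten, then to every n-th power of ten
thin_125 <- function(v, max_n = 24) {
  if (length(v) > max_n) {
    keep <- abs(log10(v) - round(log10(v))) < 1e-9
    if (any(keep)) v <- v[keep]
  }
  if (length(v) > max_n) {
    step <- ceiling(length(v) / max_n)
    v <- v[seq(1, length(v), by = step)]
  }
  v
}

# enforce a minimum spacing between tick positions on log-compressed
# axes: round powers of ten have priority, then the 2/5 subdivisions in
# order; deterministic
space_ticks <- function(ticks, min_gap) {
  if (nrow(ticks) <= 1L) return(ticks)
  v <- abs(log10(abs(as.numeric(ticks$label))))
  priority <- order(abs(v - round(v)) >= 1e-9, seq_len(nrow(ticks)))
  keep <- integer()
  for (i in priority) {
    if (!length(keep) ||
        min(abs(ticks$position[keep] - ticks$position[i])) >= min_gap)
      keep <- c(keep, i)
  }
  ticks[sort(keep), , drop = FALSE]
}

# shared range guard for axis positions; affine formulas extrapolate
# exactly, so a small tolerance only affects error reporting
check_axis_range <- function(v, rng, what, clamp, eps_rel = 1e-7) {
  eps <- eps_rel * diff(rng)
  out <- v < rng[1] - eps | v > rng[2] + eps
  if (any(out)) {
    if (!clamp)
      stop_mn("%s value(s) outside the axis range [%g, %g]",
              what, rng[1], rng[2])
    v <- pmin(pmax(v, rng[1]), rng[2])
  }
  v
}

#' Axis positions on the L, S and O scales
#'
#' Positions are measured upward from each axis's lower end, in the
#' layout's length units: `position_on_L(l) = m1 (l - l_low)`,
#' `position_on_S(s) = m3 (s - s_low)`, and for a probability `p`,
#' `position_on_O(p) = m2 (ln p - o_low)` with `o_low = l_low + s_low`.
#' Axis minima map to 0 and the `L`/`S` maxima map to `h`.
#'
#' @param layout a [nomogram_layout()].
#' @param l,s,p values on the respective scales (vectorized).
#' @param clamp truncate out-of-range values to the axis range instead of
#'   raising an error.
#' @return Numeric position(s) along the axis.
#' @name axis_positions
NULL

#' @rdname axis_positions
#' @export
position_on_L <- function(layout, l, clamp = FALSE) {
  l <- check_axis_range(l, layout$l_range, "L-axis", clamp)
  layout$m1 * (l - layout$l_range[1])
}

#' @rdname axis_positions
#' @export
position_on_S <- function(layout, s, clamp = FALSE) {
  s <- check_axis_range(s, layout$s_range, "S-axis", clamp)
  layout$m3 * (s - layout$s_range[1])
}

#' @rdname axis_positions
#' @export
position_on_O <- function(layout, p, clamp = FALSE) {
  if (any(p <= 0))
    stop_mn("probabilities on the O axis must be positive")
  o <- check_axis_range(log(p), c(layout$o_low, 0), "O-axis (log p)", clamp)
  layout$m2 * (o - layout$o_low)
}

#' Convert between the S-axis label scale and the s scale
#'
#' The `S` axis is positioned on \eqn{s = -\ln(1 + g)} but labeled by
#' \eqn{g = \sum_p e^{lp_p}}, the sum of exponentiated linear predictors
#' read off a scoring chart. `s_label_to_s()` maps a label value `g` to
#' `s`; `g_from_s()` is its exact inverse.
#'
#' @param g sum of exponentiated linear predictors, `g >= 0` (`g = 0` is
#'   the limiting label `s = 0`).
#' @param s value on the s scale.
#' @return `s` (respectively `g`).
#' @export
s_label_to_s <- function(g) {
  if (any(!is.finite(g) | g < 0))
    stop_mn("S-axis labels g must be finite and non-negative")
  -log1p(g)
}

#' @rdname s_label_to_s
#' @export
g_from_s <- function(s) expm1(-s)

#' Read a probability off the nomogram geometrically
#'
#' Constructs the isopleth: the straight line through the point `l` on the
#' `L` axis (at horizontal coordinate 0) and the point `s` on the `S` axis
#' (at `d`), intersects it with the vertical `O` axis at `d_LO`, and
#' converts the intersection height back through the `O` scale. By the
#' parallel-scale construction the result equals \eqn{e^{l+s} = \pi_k}
#' up to floating-point error.
#'
#' @inheritParams axis_positions
#' @return Probability read at the `O` axis (vectorized over `l`).
#' @export
read_probability <- function(layout, l, s, clamp = FALSE) {
  yL <- position_on_L(layout, l, clamp = clamp)
  yS <- position_on_S(layout, s, clamp = clamp)
  y <- yL + (yS - yL) * (layout$d_LO / layout$d)
  exp(y / layout$m2 + layout$o_low)
}

#' Tick marks for the nomogram axes
#'
#' Generates tick sequences: the `L` axis uses linear "nice number" steps
#' over its value range; the `O` axis places ticks at round probabilities
#' (1-2-5 per decade) between `exp(o_low)` and 1; the `S` axis is labeled
#' by `g` (the sum of exponentiated linear predictors) at 1-2-5
#' log-spaced label values, positioned through `s = -ln(1 + g)`. Larger
#' `g` means smaller `s`, so `S` positions decrease as labels increase.
#'
#' @param layout a [nomogram_layout()].
#' @param axis `"L"`, `"S"` or `"O"`.
#' @param n target number of ticks for the linear `L` axis.
#' @return Data frame with columns `value` (underlying axis-scale value:
#'   log-odds for `L`, `s` for `S`, probability for `O`), `label`
#'   (displayed label: the `g` value for `S`), and `position` (length
#'   units from the axis lower end, within `[0, h]`).
#' @export
axis_ticks <- function(layout, axis = c("L", "S", "O"), n = 6) {
  axis <- match.arg(axis)
  if (axis == "L") {
    v <- pretty(layout$l_range, n = n)
    v <- v[v >= layout$l_range[1] - 1e-12 & v <= layout$l_range[2] + 1e-12]
    out <- data.frame(value = v, label = sprintf("%g", v),
                      position = position_on_L(layout, v, clamp = TRUE),
                      stringsAsFactors = FALSE)
  } else if (axis == "O") {
    p <- thin_125(decade_125(exp(layout$o_low), 1))
    out <- data.frame(value = p, label = sprintf("%g", p),
                      position = position_on_O(layout, p, clamp = TRUE),
                      stringsAsFactors = FALSE)
  } else {
    g_lo <- g_from_s(layout$s_range[2])
    g_hi <- g_from_s(layout$s_range[1])
    g <- thin_125(decade_125(max(g_lo, 1e-12), g_hi))
    s <- s_label_to_s(g)
    out <- data.frame(value = s, label = sprintf("%g", g),
                      position = position_on_S(layout, s, clamp = TRUE),
                      stringsAsFactors = FALSE)
  }
  out <- out[out$position >= -1e-9 & out$position <= layout$h + 1e-9, ,
             drop = FALSE]
  if (axis != "L") out <- space_ticks(out, min_gap = 0.032 * layout$h)
  rownames(out) <- NULL
  out
}
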