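#' Rendering configuration
#'
#' Options shared by [render_nomogram()] and [render_scoring_chart()].
#' All geometry in the emitted SVG is a pure function of the inputs, and
#' fonts are referenced by generic family only, so identical inputs give
#' byte-identical output on any platform.
#'
#' @param margin page margin in pixels.
#' @param scale pixels per layout length unit.
#' @param font_size label font size in pixels.
#' @param tick_length tick mark length in pixels.
#' @param show_raw_l_labels also print the raw log-odds value under each
#'   total-points label on the nomogram's `L` axis.
#' @param integer_points round case points to integers before overlaying
#'   (display-style reading; see [case_reading()] for the error bound).
#' @param row_order `"covariate"` groups scoring-chart rows by covariate
#'   (all categories of a covariate together); `"category"` groups by
#'   category.
#' @param chart_width width of the scoring chart's 0-100 points ruler in
#'   pixels.
#' @param row_height vertical spacing of scoring-chart rows in pixels.
#' @param label_col width reserved for row labels in pixels.
#' @return An object of class `"render_config"`.
#' @export
render_config <- function(margin = 70, scale = 40, font_size = 11,
                          tick_length = 5, show_raw_l_labels = FALSE,
                          integer_points = FALSE,
                          row_order = c("covariate", "category"),
                          chart_width = 520, row_height = 26,
                          label_col = 190) {
  stopifnot(margin > 0, scale > 0, font_size > 0, tick_length > 0,
            chart_width > 0, row_height > 0, label_col > 0)
  structure(list(margin = margin, scale = scale, font_size = font_size,
                 tick_length = tick_length,
                 show_raw_l_labels = isTRUE(show_raw_l_labels),
                 integer_points = isTRUE(integer_points),
                 row_order = match.arg(row_order),
                 chart_width = chart_width, row_height = row_height,
                 label_col = label_col),
            class = "render_config")
}

svg_header <- function(width, height, font_size) {
  c('<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                   'width="%s" height="%s" viewBox="0 0 %s %s">'),
            fmt_px(width), fmt_px(height), fmt_px(width), fmt_px(height)),
    '<style>',
    sprintf(paste0('text { font-family: sans-serif; font-size: %spx; ',
                   'fill: #000; }'), fmt_px(font_size)),
    sprintf('.axis-title { font-size: %spx; font-weight: bold; }',
            fmt_px(font_size + 1)),
    sprintf('.tick-sublabel { font-size: %spx; fill: #666; }',
            fmt_px(font_size - 3)),
    'line { stroke: #000; stroke-width: 1; }',
    '.isopleth { stroke: #777; stroke-width: 1; }',
    '.case-line { stroke: #777; stroke-width: 1; stroke-dasharray: 4 3; }',
    '.case-marker { fill: #777; stroke: none; }',
    '.zero-points { fill: #666; }',
    '</style>')
}

svg_line <- function(x1, y1, x2, y2, class, extra = "") {
  sprintf('<line class="%s"%s x1="%s" y1="%s" x2="%s" y2="%s"/>',
          class, extra, fmt_px(x1), fmt_px(y1), fmt_px(x2), fmt_px(y2))
}

svg_text <- function(x, y, text, class, anchor = "start", extra = "") {
  sprintf('<text class="%s"%s x="%s" y="%s" text-anchor="%s">%s</text>',
          class, extra, fmt_px(x), fmt_px(y), anchor, xml_escape(text))
}

check_same_model <- function(layout, chart) {
  if (!is.null(layout$model_fingerprint) &&
      !is.null(chart$model_fingerprint) &&
      !identical(layout$model_fingerprint, chart$model_fingerprint))
    stop_mn("layout and scoring chart were built from different models")
}

#' Render the nomogram as SVG
#'
#' Draws the three parallel vertical axes: `L` at horizontal offset 0,
#' `O` at `d_LO`, `S` at `d` (scaled to pixels), with positions measured
#' upward from the common baseline. When a scoring chart is supplied the
#' `L` axis is labeled in total-points units through [total_label_for_l()]
#' (optionally with raw log-odds sub-labels); otherwise it is labeled in
#' log-odds. The `O` axis carries round probability labels and the `S`
#' axis is labeled by the sum of exponentiated linear predictors. A case
#' reading adds one straight isopleth per non-reference category, from the
#' category's point on `L` through the shared point on `S`.
#'
#' Every tick element carries `data-axis`, `data-value` and `data-pos`
#' attributes recording the underlying value and its position along the
#' axis (in layout length units), so the drawing can be re-checked against
#' the geometry operations.
#'
#' @param layout a [nomogram_layout()].
#' @param chart optionally, the matching [scoring_chart()]; an error is
#'   raised if layout and chart stem from different models.
#' @param case optionally, a [case_reading()] to overlay.
#' @param config a [render_config()].
#' @return The SVG document as a single character string.
#' @export
render_nomogram <- function(layout, chart = NULL, case = NULL,
                            config = render_config()) {
  if (!is.null(chart)) check_same_model(layout, chart)
  cf <- config
  xL <- cf$margin
  xO <- cf$margin + cf$scale * layout$d_LO
  xS <- cf$margin + cf$scale * layout$d
  y_of <- function(pos) cf$margin + cf$scale * (layout$h - pos)
  width <- 2 * cf$margin + cf$scale * layout$d
  height <- 2 * cf$margin + cf$scale * layout$h
  out <- svg_header(width, height, cf$font_size)

  if (!is.null(chart)) {
    t_rng <- total_label_for_l(chart, layout$l_range)
    tv <- pretty(t_rng, n = 6)
    tv <- tv[tv >= t_rng[1] - 1e-9 & tv <= t_rng[2] + 1e-9]
    l_ticks <- data.frame(value = l_for_total(chart, tv),
                          label = sprintf("%g", tv),
                          position = NA_real_, stringsAsFactors = FALSE)
    l_ticks$position <- position_on_L(layout, l_ticks$value, clamp = TRUE)
    l_title <- "Total Points"
  } else {
    l_ticks <- axis_ticks(layout, "L")
    l_title <- "Linear predictor"
  }
  o_ticks <- axis_ticks(layout, "O")
  s_ticks <- axis_ticks(layout, "S")

  axis_block <- function(id, x, ticks, side, title) {
    sgn <- if (side == "left") -1 else 1
    block <- c(
      sprintf('<g id="axis-%s">', id),
      svg_text(x, cf$margin - 22, title, "axis-title", "middle"),
      svg_line(x, y_of(0), x, y_of(layout$h), "axis-line",
               sprintf(' data-axis="%s"', id)))
    for (i in seq_len(nrow(ticks))) {
      y <- y_of(ticks$position[i])
      extra <- sprintf(' data-axis="%s" data-value="%s" data-pos="%s"',
                       id, fmt_attr(ticks$value[i]),
                       fmt_attr(ticks$position[i]))
      block <- c(block,
        svg_line(x, y, x + sgn * cf$tick_length, y, "tick", extra),
        svg_text(x + sgn * (cf$tick_length + 4), y + 0.35 * cf$font_size,
                 ticks$label[i], "tick-label",
                 if (side == "left") "end" else "start", extra))
      if (id == "L" && !is.null(chart) && cf$show_raw_l_labels)
        block <- c(block,
          svg_text(x + sgn * (cf$tick_length + 4),
                   y + 0.35 * cf$font_size + cf$font_size - 2,
                   sprintf("(%.2f)", ticks$value[i]), "tick-sublabel",
                   "end"))
    }
    c(block, '</g>')
  }

  out <- c(out,
    axis_block("L", xL, l_ticks, "left", l_title),
    axis_block("O", xO, o_ticks, "left", "Probability"),
    axis_block("S", xS, s_ticks, "right", "Sum exp(lp)"))

  if (!is.null(case)) {
    if (!inherits(case, "case_reading"))
      stop_mn("case must be a case_reading object")
    yS <- y_of(position_on_S(layout, case$s, clamp = TRUE))
    iso <- c('<g id="isopleths">')
    for (k in names(case$l)) {
      yL <- y_of(position_on_L(layout, case$l[[k]], clamp = TRUE))
      iso <- c(iso, svg_line(xL, yL, xS, yS, "isopleth",
                             sprintf(' data-category="%s"',
                                     xml_escape(k))))
    }
    out <- c(out, iso, '</g>')
  }
  paste(c(out, '</svg>'), collapse = "\n")
}

#' Render the scoring chart as SVG
#'
#' Draws the standardized points system: a 0-100 points ruler at the top;
#' one row per (covariate, category) with covariate-value ticks mapped
#' through the points map (a covariate with zero coefficient for a
#' category keeps its row, annotated as zero points, so every category has
#' a structurally identical row set); the per-category baseline points;
#' and, at the bottom, the total-points axis with the
#' exponentiated-linear-predictor axis aligned under it via
#' \eqn{\exp\{(Total + \min_k bl_k)/r\}}. A case reading adds a marker at
#' each row's points value and dashed drop lines at the case totals.
#'
#' Row ticks carry `data-covariate`, `data-category`, `data-x` and
#' `data-points` attributes; ruler, total-axis and exp-axis ticks carry
#' `data-points`, `data-total` and `data-value` respectively.
#'
#' @param chart a [scoring_chart()].
#' @param case optionally, a [case_reading()] to overlay.
#' @param config a [render_config()].
#' @return The SVG document as a single character string.
#' @export
render_scoring_chart <- function(chart, case = NULL,
                                 config = render_config()) {
  cf <- config
  model <- chart$model
  cats <- rownames(chart$beta_star)
  J <- nrow(model$covariates)
  x0 <- cf$margin + cf$label_col
  x1 <- x0 + cf$chart_width
  pts2x <- function(p) x0 + p / 100 * cf$chart_width
  t_rng <- chart$total_range
  tot2x <- function(t) x0 + (t - t_rng[1]) / diff(t_rng) * cf$chart_width

  if (cf$row_order == "covariate") {
    rows <- expand.grid(k = cats, j = seq_len(J), stringsAsFactors = FALSE)
    rows <- rows[order(rows$j), ]
  } else {
    rows <- expand.grid(j = seq_len(J), k = cats, stringsAsFactors = FALSE)
    rows <- rows[order(match(rows$k, cats)), ]
  }
  n_rows <- nrow(rows)
  y_ruler <- cf$margin
  y_rows0 <- y_ruler + 2 * cf$row_height
  y_base <- y_rows0 + n_rows * cf$row_height + cf$row_height
  y_total <- y_base + length(cats) * cf$row_height + cf$row_height
  y_exp <- y_total + 1.8 * cf$row_height
  width <- x1 + cf$margin
  height <- y_exp + 2 * cf$margin
  out <- svg_header(width, height, cf$font_size)

  if (!is.null(case) && cf$integer_points)
    case <- case_reading(chart, case$profile, integer_points = TRUE)

  # points ruler, 0..100
  out <- c(out, '<g id="points-ruler">',
    svg_text(x0 - 10, y_ruler + 0.35 * cf$font_size, "Points",
             "axis-title", "end"),
    svg_line(x0, y_ruler, x1, y_ruler, "axis-line"))
  for (p in seq(0, 100, by = 10)) {
    xp <- pts2x(p)
    extra <- sprintf(' data-points="%s"', fmt_attr(p))
    out <- c(out,
      svg_line(xp, y_ruler, xp, y_ruler - cf$tick_length, "points-ruler",
               extra),
      svg_text(xp, y_ruler - cf$tick_length - 3, sprintf("%d", p),
               "tick-label", "middle", extra))
  }
  out <- c(out, '</g>', '<g id="rows">')

  for (i in seq_len(n_rows)) {
    j <- rows$j[i]; k <- rows$k[i]
    y <- y_rows0 + (i - 1) * cf$row_height
    cov <- model$covariates[j, ]
    out <- c(out, svg_text(cf$margin, y + 0.35 * cf$font_size,
                           sprintf("%s (%s)", cov$name, k), "row-label"))
    if (chart$span[k, j] == 0) {
      out <- c(out, svg_text(
        x0, y + 0.35 * cf$font_size, "0 points", "zero-points",
        "start", sprintf(' data-covariate="%s" data-category="%s"',
                         xml_escape(cov$name), xml_escape(k))))
      next
    }
    out <- c(out, svg_line(pts2x(0), y, pts2x(chart$span[k, j]), y,
                           "row-line"))
    vals <- if (cov$kind == "binary") c(0, 1) else {
      v <- pretty(c(cov$lower, cov$upper), n = 5)
      sort(unique(c(cov$lower, v[v > cov$lower & v < cov$upper],
                    cov$upper)))
    }
    for (v in vals) {
      pv <- covariate_points(chart, j, k, v)
      xv <- pts2x(pv)
      extra <- sprintf(
        ' data-covariate="%s" data-category="%s" data-x="%s" data-points="%s"',
        xml_escape(cov$name), xml_escape(k), fmt_attr(v), fmt_attr(pv))
      out <- c(out,
        svg_line(xv, y, xv, y + cf$tick_length, "row-tick", extra),
        svg_text(xv, y + cf$tick_length + cf$font_size, sprintf("%g", v),
                 "tick-label", "middle", extra))
    }
    if (!is.null(case)) {
      out <- c(out, sprintf(
        '<circle class="case-marker" cx="%s" cy="%s" r="3" data-covariate="%s" data-category="%s"/>',
        fmt_px(pts2x(case$points[k, j])), fmt_px(y),
        xml_escape(cov$name), xml_escape(k)))
    }
  }
  out <- c(out, '</g>', '<g id="baselines">')
  for (ki in seq_along(cats)) {
    k <- cats[ki]
    y <- y_base + (ki - 1) * cf$row_height
    out <- c(out, svg_text(
      cf$margin, y + 0.35 * cf$font_size,
      sprintf("Baseline points (%s): %g", k,
              round(chart$bl_star[k], 2)), "baseline", "start",
      sprintf(' data-category="%s" data-points="%s"', xml_escape(k),
              fmt_attr(chart$bl_star[k]))))
  }
  out <- c(out, '</g>', '<g id="total-axis">',
    svg_text(x0 - 10, y_total + 0.35 * cf$font_size, "Total Points",
             "axis-title", "end"),
    svg_line(x0, y_total, x1, y_total, "axis-line"))
  tv <- pretty(t_rng, n = 8)
  tv <- tv[tv >= t_rng[1] - 1e-9 & tv <= t_rng[2] + 1e-9]
  for (t in tv) {
    xt <- tot2x(t)
    extra <- sprintf(' data-total="%s"', fmt_attr(t))
    out <- c(out,
      svg_line(xt, y_total, xt, y_total + cf$tick_length, "total-tick",
               extra),
      svg_text(xt, y_total + cf$tick_length + cf$font_size,
               sprintf("%g", t), "tick-label", "middle", extra))
  }
  out <- c(out, '</g>', '<g id="exp-axis">',
    svg_text(x0 - 10, y_exp + 0.35 * cf$font_size, "Exp(lp)",
             "axis-title", "end"),
    svg_line(x0, y_exp, x1, y_exp, "axis-line"))
  ev <- thin_125(decade_125(max(chart$exp_range[1], 1e-12),
                            chart$exp_range[2]), max_n = 16)
  for (v in ev) {
    xt <- tot2x(total_label_for_l(chart, log(v)))
    extra <- sprintf(' data-value="%s"', fmt_attr(v))
    out <- c(out,
      svg_line(xt, y_exp, xt, y_exp + cf$tick_length, "exp-tick", extra),
      svg_text(xt, y_exp + cf$tick_length + cf$font_size,
               sprintf("%g", v), "tick-label", "middle", extra))
  }
  out <- c(out, '</g>')
  if (!is.null(case)) {
    out <- c(out, '<g id="case-totals">')
    for (k in cats) {
      xt <- tot2x(case$totals[[k]])
      out <- c(out, svg_line(xt, y_total - 0.6 * cf$row_height, xt, y_exp,
                             "case-line",
                             sprintf(' data-category="%s" data-total="%s"',
                                     xml_escape(k),
                                     fmt_attr(case$totals[[k]]))))
    }
    out <- c(out, '</g>')
  }
  paste(c(out, '</svg>'), collapse = "\n")
}
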