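# Static SVG rendering of display payloads. Rendering is a pure
# function of (payload, layout): identical input yields byte-identical
# output. All x transforms are affine per axis; the double-layer panel
# transforms its top and bottom coordinates independently.

#' Layout for the SVG renderer
#'
#' @param pixel_width Drawing width in pixels; must match the viewport
#'   used for the payload.
#' @param track_height Height of a sparse or dense lane.
#' @param interaction_height Height of the double-layer panel between
#'   the two axes.
#' @param ruler_height Height reserved for a coordinate ruler.
#' @param margin Outer margin.
#' @param font_size Label font size.
#' @param vmin,vmax Optional fixed intensity bounds for the interaction
#'   color scale; default is the range of the visible records.
#' @return A list of class `layout_spec`.
#' @export
layout_spec <- function(pixel_width, track_height = 60, interaction_height = 120,
                        ruler_height = 24, margin = 10, font_size = 10,
                        vmin = NULL, vmax = NULL) {
  structure(list(pixel_width = as.integer(pixel_width),
                 track_height = track_height,
                 interaction_height = interaction_height,
                 ruler_height = ruler_height, margin = margin,
                 font_size = font_size, vmin = vmin, vmax = vmax),
            class = "layout_spec")
}

#' Map an intensity to the red-green scale
#'
#' Linear interpolation in RGB from pure green (weakest) to pure red
#' (strongest); values are clamped into `[vmin, vmax]`, and the red
#' channel is monotone in the value. Degenerate bounds
#' (`vmin == vmax`) give the midpoint color.
#'
#' @param value Finite intensity.
#' @param vmin,vmax Scale endpoints (`vmin < vmax` normally).
#' @return Named integer vector `c(r, g, b)` in 0..255.
#' @export
color_scale <- function(value, vmin, vmax) {
  t <- if (vmax > vmin) min(1, max(0, (value - vmin) / (vmax - vmin))) else 0.5
  c(r = as.integer(round(255 * t)), g = as.integer(round(255 * (1 - t))),
    b = 0L)
}

color_hex <- function(rgb) sprintf("#%02x%02x%02x", rgb[1], rgb[2], rgb[3])

fmt <- function(x) sprintf("%.2f", x)

# Affine genomic -> pixel transform for one axis.
x_transform <- function(region, pixel_width) {
  res <- (region$end - region$start) / pixel_width
  function(pos) (pos - region$start) / res
}

svg_ruler <- function(region, pixel_width, x0, y0, height, font_size) {
  tx <- x_transform(region, pixel_width)
  ticks <- pretty(c(region$start, region$end), n = 6)
  ticks <- ticks[ticks >= region$start & ticks <= region$end]
  out <- sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black"/>',
                 fmt(x0), fmt(y0 + height - 6), fmt(x0 + pixel_width),
                 fmt(y0 + height - 6))
  for (t in ticks) {
    x <- x0 + tx(t)
    out <- c(out,
             sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black"/>',
                     fmt(x), fmt(y0 + height - 10), fmt(x), fmt(y0 + height - 6)),
             # axis labels are 1-based; internal coordinates stay 0-based
             sprintf('<text x="%s" y="%s" font-size="%s" text-anchor="middle">%s:%s</text>',
                     fmt(x), fmt(y0 + height - 12), fmt(font_size),
                     region$chrom, format(t + 1, scientific = FALSE,
                                          big.mark = ",")))
  }
  out
}

svg_sparse_lane <- function(records, region, pixel_width, x0, y0, height,
                            font_size) {
  tx <- x_transform(region, pixel_width)
  out <- character(0)
  box_h <- max(6, height - 2 * font_size)
  for (i in seq_len(nrow(records))) {
    xa <- max(0, tx(records$start[i]))
    xb <- min(pixel_width, tx(records$end[i]))
    if (xb <= xa) next
    out <- c(out, sprintf(
      '<rect x="%s" y="%s" width="%s" height="%s" fill="steelblue" stroke="none"/>',
      fmt(x0 + xa), fmt(y0 + 2), fmt(xb - xa), fmt(box_h)))
    nm <- records$name[i]
    if (nzchar(nm) && (xb - xa) >= 0.6 * font_size * nchar(nm)) {
      out <- c(out, sprintf(
        '<text x="%s" y="%s" font-size="%s" text-anchor="middle">%s</text>',
        fmt(x0 + (xa + xb) / 2), fmt(y0 + box_h + font_size), fmt(font_size), nm))
    }
  }
  out
}

svg_dense_lane <- function(profile, region, pixel_width, x0, y0, height) {
  vals <- profile$mean[!profile$gap]
  if (length(vals) == 0L) return(character(0))
  lo <- min(0, min(vals))
  hi <- max(vals)
  if (hi <= lo) hi <- lo + 1
  tx <- x_transform(region, pixel_width)
  out <- character(0)
  for (i in seq_len(nrow(profile))) {
    if (profile$gap[i]) next
    h <- height * (profile$mean[i] - lo) / (hi - lo)
    xa <- tx(profile$start[i]); xb <- tx(profile$end[i])
    out <- c(out, sprintf(
      '<rect x="%s" y="%s" width="%s" height="%s" fill="darkorange" stroke="none"/>',
      fmt(x0 + xa), fmt(y0 + height - h), fmt(max(xb - xa, 0.5)), fmt(h)))
  }
  out
}

#' Render a display payload to an SVG document
#'
#' One coordinate ruler, then one lane per track in payload order:
#' sparse records as boxes (named where space allows), dense profiles
#' as per-pixel bars of the mean, interaction tracks as a double-layer
#' panel via [render_interactions()] (using the payload's second
#' viewport for the bottom axis, or the main one if absent).
#'
#' @param payload A `display_payload` from [session_query()].
#' @param layout A [layout_spec()]; its `pixel_width` must match the
#'   payload viewport.
#' @return A single string: the SVG 1.1 document.
#' @export
render_tracks <- function(payload, layout) {
  view <- payload$view
  if (layout$pixel_width != view$pixel_width) {
    stop("layout pixel_width must match the payload viewport")
  }
  region <- view$region
  x0 <- layout$margin
  y <- layout$margin
  body <- svg_ruler(region, layout$pixel_width, x0, y, layout$ruler_height,
                    layout$font_size)
  y <- y + layout$ruler_height
  for (track_id in names(payload$tracks)) {
    tr <- payload$tracks[[track_id]]
    body <- c(body, sprintf(
      '<text x="%s" y="%s" font-size="%s">%s</text>',
      fmt(x0), fmt(y + layout$font_size), fmt(layout$font_size), track_id))
    if (tr$kind == "sparse") {
      body <- c(body, svg_sparse_lane(tr$records, region, layout$pixel_width,
                                      x0, y, layout$track_height,
                                      layout$font_size))
      y <- y + layout$track_height
    } else if (tr$kind == "dense") {
      body <- c(body, svg_dense_lane(tr$profile, region, layout$pixel_width,
                                     x0, y, layout$track_height))
      y <- y + layout$track_height
    } else if (tr$kind == "interaction") {
      bottom <- if (!is.null(payload$second_view)) payload$second_view else view
      frag <- render_interactions(view, bottom, tr$records, layout, x0, y)
      body <- c(body, frag)
      y <- y + layout$interaction_height + 2 * layout$ruler_height
    }
    y <- y + layout$margin
  }
  width <- layout$pixel_width + 2 * layout$margin
  height <- y + layout$margin
  paste(c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s">',
                  fmt(width), fmt(height)),
          body, "</svg>"), collapse = "\n")
}

#' Render the double-layer interaction panel
#'
#' Two independently scaled coordinate axes (anchor 1 on top, anchor 2
#' on the bottom unless `swap_axes`); every record whose top anchor is
#' visible in the top viewport and bottom anchor in the bottom viewport
#' is drawn as a straight-edged quadrilateral linking the two anchor
#' spans, filled by the red-green intensity scale. Off-view records are
#' omitted.
#'
#' @param top,bottom [viewport()]s for the two axes (they may cover
#'   different regions or chromosomes).
#' @param records Interaction record data.frame.
#' @param layout A [layout_spec()].
#' @param x0,y0 Panel origin inside the document.
#' @param swap_axes Plot anchor 2 on top instead.
#' @return Character vector of SVG fragment lines.
#' @export
render_interactions <- function(top, bottom, records, layout, x0 = 0, y0 = 0,
                                swap_axes = FALSE) {
  if (swap_axes && nrow(records) > 0L) {
    records <- data.frame(chrom1 = records$chrom2, start1 = records$start2,
                          end1 = records$end2, chrom2 = records$chrom1,
                          start2 = records$start1, end2 = records$end1,
                          intensity = records$intensity,
                          stringsAsFactors = FALSE)
  }
  vis <- records[records$chrom1 == top$region$chrom &
                   records$start1 < top$region$end &
                   top$region$start < records$end1 &
                   records$chrom2 == bottom$region$chrom &
                   records$start2 < bottom$region$end &
                   bottom$region$start < records$end2, , drop = FALSE]
  vmin <- if (!is.null(layout$vmin)) layout$vmin else
    if (nrow(vis)) min(vis$intensity) else 0
  vmax <- if (!is.null(layout$vmax)) layout$vmax else
    if (nrow(vis)) max(vis$intensity) else 1
  tx_top <- x_transform(top$region, layout$pixel_width)
  tx_bot <- x_transform(bottom$region, layout$pixel_width)
  y_top <- y0 + layout$ruler_height
  y_bot <- y_top + layout$interaction_height
  out <- svg_ruler(top$region, layout$pixel_width, x0, y0,
                   layout$ruler_height, layout$font_size)
  clampx <- function(x) min(layout$pixel_width, max(0, x))
  for (i in seq_len(nrow(vis))) {
    xa1 <- clampx(tx_top(vis$start1[i])); xb1 <- clampx(tx_top(vis$end1[i]))
    xa2 <- clampx(tx_bot(vis$start2[i])); xb2 <- clampx(tx_bot(vis$end2[i]))
    col <- color_hex(color_scale(vis$intensity[i], vmin, vmax))
    out <- c(out, sprintf(
      '<polygon points="%s,%s %s,%s %s,%s %s,%s" fill="%s" fill-opacity="0.65" stroke="%s"/>',
      fmt(x0 + xa1), fmt(y_top), fmt(x0 + xb1), fmt(y_top),
      fmt(x0 + xb2), fmt(y_bot), fmt(x0 + xa2), fmt(y_bot), col, col))
  }
  c(out, svg_ruler(bottom$region, layout$pixel_width, x0, y_bot,
                   layout$ruler_height, layout$font_size))
}
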