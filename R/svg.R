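# Deterministic SVG rendering of haplotype-block inheritance.
#
# One vertical bar per embryo x origin, y linear in bp. Block colors follow
# the field's convention for reference-anchored haplotypes: paternal blocks
# shared with / absent from the reference child are red / green, maternal
# blocks yellow / blue. The mutation position is a horizontal line across all
# tracks. Output is plain SVG 1.1 text with a stable element order and no
# timestamps, so identical input renders byte-identical files.

BLOCK_COLORS <- c(paternal.I = "red", paternal.D = "green",
                  maternal.I = "yellow", maternal.D = "blue",
                  none = "grey")

#' Plot specification for haplotype figures
#'
#' @param px_per_mb Vertical pixels per megabase. Default 3.
#' @param track_width Bar width in px. Default 18.
#' @param track_gap Gap between bars (including label room). Default 34.
#' @param margin Outer margin in px. Default 46.
#' @param colors Named fill colors for `paternal.I`, `paternal.D`,
#'   `maternal.I`, `maternal.D`, `none`. The four block colors must be
#'   distinct.
#' @param gene_label Label written at the mutation line. Default `"locus"`.
#' @return A `plot_spec` list.
#' @export
plot_spec <- function(px_per_mb = 3, track_width = 18, track_gap = 34,
                      margin = 46, colors = BLOCK_COLORS,
                      gene_label = "locus") {
  stopifnot(px_per_mb > 0, track_width > 0, track_gap >= 0, margin >= 0,
            all(names(BLOCK_COLORS) %in% names(colors)))
  if (anyDuplicated(colors[c("paternal.I", "paternal.D",
                             "maternal.I", "maternal.D")])) {
    stop("the four block colors must be distinct")
  }
  structure(list(px_per_mb = px_per_mb, track_width = track_width,
                 track_gap = track_gap, margin = margin, colors = colors,
                 gene_label = gene_label),
            class = "plot_spec")
}

fmt_px <- function(x) sprintf("%.2f", x)

svg_rect <- function(x, y, w, h, fill, stroke = "none", extra = "") {
  sprintf(
    '<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="%s"%s/>',
    fmt_px(x), fmt_px(y), fmt_px(w), fmt_px(h), fill, stroke, extra)
}

#' Render a family haplotype-block figure to SVG
#'
#' @param segmentations Named list per embryo of named lists per origin of
#'   `block_segmentation` objects, all on the chromosome of `locus`. A NULL or
#'   empty segmentation renders as a grey track with a warning glyph.
#' @param locus A [disease_locus()]; its midpoint is drawn as the mutation
#'   line.
#' @param path Output SVG path.
#' @param spec A [plot_spec()].
#' @param chrom_length_bp Drawn chromosome extent; defaults to the largest
#'   block end (or the locus end) rounded up to a whole Mb.
#' @return `path`, invisibly.
#' @export
render_family_svg <- function(segmentations, locus, path,
                              spec = plot_spec(), chrom_length_bp = NULL) {
  tracks <- list()
  for (id in names(segmentations)) {
    for (or in names(segmentations[[id]])) {
      tracks[[length(tracks) + 1L]] <- list(
        embryo = id, origin = or, seg = segmentations[[id]][[or]])
    }
  }
  if (length(tracks) == 0L) stop("no segmentations to render")

  max_end <- max(c(locus$end_pos, unlist(lapply(tracks, function(t) {
    if (is.null(t$seg) || nrow(t$seg$blocks) == 0L) NA_real_ else
      max(t$seg$blocks$end_pos)
  }))), na.rm = TRUE)
  if (is.null(chrom_length_bp)) chrom_length_bp <- ceiling(max_end / 1e6) * 1e6

  y_of <- function(bp) spec$margin + (bp - 1) / 1e6 * spec$px_per_mb
  chrom_px <- chrom_length_bp / 1e6 * spec$px_per_mb
  width <- 2 * spec$margin +
    length(tracks) * (spec$track_width + spec$track_gap) - spec$track_gap
  height <- 2 * spec$margin + chrom_px

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                   'width="%s" height="%s" viewBox="0 0 %s %s">'),
            fmt_px(width), fmt_px(height), fmt_px(width), fmt_px(height)))

  for (k in seq_along(tracks)) {
    tr <- tracks[[k]]
    x <- spec$margin + (k - 1) * (spec$track_width + spec$track_gap)
    seg <- tr$seg
    if (!is.null(seg)) {
      blocks <- seg$blocks[seg$blocks$chrom == locus$chrom, , drop = FALSE]
    } else {
      blocks <- NULL
    }
    if (is.null(blocks) || nrow(blocks) == 0L) {
      lines <- c(lines,
                 svg_rect(x, y_of(1), spec$track_width,
                          y_of(chrom_length_bp) - y_of(1),
                          spec$colors[["none"]]),
                 sprintf('<text x="%s" y="%s" font-size="12">!</text>',
                         fmt_px(x + spec$track_width / 2 - 3),
                         fmt_px(spec$margin - 22)))
    } else {
      for (b in seq_len(nrow(blocks))) {
        key <- paste0(tr$origin, ".", blocks$state[b])
        lines <- c(lines,
                   svg_rect(x, y_of(blocks$start_pos[b]), spec$track_width,
                            y_of(blocks$end_pos[b]) -
                              y_of(blocks$start_pos[b]),
                            spec$colors[[key]]))
      }
    }
    # track outline over the full chromosome extent
    lines <- c(lines,
               svg_rect(x, y_of(1), spec$track_width,
                        y_of(chrom_length_bp) - y_of(1),
                        "none", stroke = "black"))
    lines <- c(lines,
               sprintf('<text x="%s" y="%s" font-size="9">%s</text>',
                       fmt_px(x), fmt_px(spec$margin - 10),
                       paste0(tr$embryo, ":",
                              substr(tr$origin, 1, 3))))
  }

  mut_y <- y_of(floor((locus$start_pos + locus$end_pos) / 2))
  lines <- c(lines,
             sprintf(paste0('<line x1="%s" y1="%s" x2="%s" y2="%s" ',
                            'stroke="black" stroke-width="1.5"/>'),
                     fmt_px(spec$margin / 2), fmt_px(mut_y),
                     fmt_px(width - spec$margin / 2), fmt_px(mut_y)),
             sprintf('<text x="%s" y="%s" font-size="9">%s</text>',
                     fmt_px(2), fmt_px(mut_y - 3), spec$gene_label),
             '</svg>')
  writeLines(lines, path)
  invisible(path)
}
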