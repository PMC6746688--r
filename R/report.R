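fmt_num <- function(x, digits = 2) {
  # fixed-format, locale-independent numbers for deterministic SVG/HTML
  sprintf(paste0("%.", digits, "f"), x)
}

#' Render an SVG overlay of an annotation
#'
#' Draws every marker (circle + label), the medial line, the calibration
#' segment and the measurement lines of the computed panel onto an SVG
#' canvas at the raw annotation coordinates. If the annotation records an
#' image path it is referenced as the backdrop; otherwise a blank canvas of
#' the declared (or derived) size is used. Output is deterministic:
#' identical inputs give byte-identical SVG.
#'
#' @param annotation A [landmark_annotation()].
#' @param panel Optional [compute_panel()] result; measurement lines are
#'   drawn for the chord measurements present in it.
#' @param path Optional output file; when `NULL` the SVG text is returned.
#' @param image_size Optional `c(width, height)` overriding the canvas size.
#' @return The SVG document as a single character string (invisibly when
#'   written to `path`).
#' @export
render_overlay <- function(annotation, panel = NULL, path = NULL,
                           image_size = NULL) {
  stopifnot(inherits(annotation, "landmark_annotation"))
  lms <- annotation$landmarks
  size <- image_size %||% annotation$image_size
  if (is.null(size)) {
    xs <- vapply(lms, function(p) p$x, numeric(1))
    ys <- vapply(lms, function(p) p$y, numeric(1))
    size <- c(max(xs) + 50, max(ys) + 50)
  }
  if (!is.null(annotation$image_size) && !is.null(image_size) &&
      any(round(image_size) != round(annotation$image_size))) {
    stop("supplied image size disagrees with the annotation's declared size",
         call. = FALSE)
  }
  line_el <- function(a, b, colour, width = 1.5, dash = NULL) {
    sprintf(
      '  <line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"%s/>',
      fmt_num(a$x), fmt_num(a$y), fmt_num(b$x), fmt_num(b$y), colour,
      fmt_num(width, 1),
      if (is.null(dash)) "" else sprintf(' stroke-dasharray="%s"', dash))
  }
  out <- c(
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%s" ',
                   'height="%s" viewBox="0 0 %s %s">'),
            fmt_num(size[1], 0), fmt_num(size[2], 0),
            fmt_num(size[1], 0), fmt_num(size[2], 0)),
    if (is.null(annotation$image_path))
      sprintf('  <rect width="100%%" height="100%%" fill="#f5f5f5"/>')
    else
      sprintf('  <image href="%s" width="%s" height="%s"/>',
              annotation$image_path, fmt_num(size[1], 0), fmt_num(size[2], 0))
  )
  if (all(c("SN", "UMB") %in% names(lms))) {
    out <- c(out, line_el(lms$SN, lms$UMB, "#2166ac", 2, dash = "6,4"))
  }
  if (!is.null(panel)) {
    chords <- list(SNN_R = c("SN", "N_R"), SNN_L = c("SN", "N_L"),
                   IMFN_R = c("IMFA_R", "N_R"), IMFN_L = c("IMFA_L", "N_L"),
                   UPN_R = c("UPA_R", "N_R"), UPN_L = c("UPA_L", "N_L"))
    for (m in intersect(panel$measurement, names(chords))) {
      ends <- chords[[m]]
      if (all(ends %in% names(lms))) {
        out <- c(out, line_el(lms[[ends[1]]], lms[[ends[2]]], "#b2182b", 1.5))
      }
    }
  }
  cal <- annotation$calibration
  out <- c(out, line_el(cal$endpoint_a, cal$endpoint_b, "#1b7837", 3))
  for (nm in names(lms)) {
    p <- lms[[nm]]
    out <- c(out,
      sprintf('  <circle cx="%s" cy="%s" r="4" fill="#d73027" stroke="white"/>',
              fmt_num(p$x), fmt_num(p$y)),
      sprintf('  <text x="%s" y="%s" font-size="12" font-family="sans-serif">%s</text>',
              fmt_num(p$x + 6), fmt_num(p$y - 6), nm))
  }
  svg <- paste(c(out, "</svg>"), collapse = "\n")
  if (!is.null(path)) {
    writeLines(svg, path, useBytes = TRUE)
    return(invisible(svg))
  }
  svg
}

#' Assemble a measurement report
#'
#' Bundles the measurement panel (rounded to 0.1 cm, tape-measure
#' precision), the aesthetic ratios with their ideal references, value
#' provenance (one- vs two-photo) and subject metadata into a serializable
#' report. Regenerating the report from the same annotation is
#' bit-identical.
#'
#' @param annotation A [landmark_annotation()].
#' @return A list of class `measurement_report`.
#' @export
build_report <- function(annotation) {
  stopifnot(inherits(annotation, "landmark_annotation"))
  panel <- compute_panel(annotation)
  ratios <- ratio_set(annotation, panel)
  structure(
    list(
      subject = list(id = annotation$subject_id %||% NA_character_,
                     sex_type = annotation$sex_type %||% NA_character_,
                     notes = annotation$notes %||% NA_character_),
      two_photo = !is.null(annotation$secondary),
      panel = data.frame(measurement = panel$measurement,
                         value_cm = round(panel$value_cm, 1),
                         provenance = panel$provenance,
                         stringsAsFactors = FALSE),
      ratios = as.data.frame(ratios),
      ideal_ratios = ideal_ratios()),
    class = "measurement_report"
  )
}

#' Write a report as JSON or HTML
#'
#' @param report A [build_report()] result.
#' @param path Output file path.
#' @param format `"json"` or `"html"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "html")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "measurement_report"))
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null",
                         dataframe = "rows", na = "null")
  } else {
    rows <- apply(report$panel, 1, function(r) {
      sprintf("<tr><td>%s</td><td>%s</td><td>%s</td></tr>",
              r[["measurement"]], r[["value_cm"]], r[["provenance"]])
    })
    ratio_rows <- if (nrow(report$ratios)) {
      apply(report$ratios, 1, function(r) {
        sprintf("<tr><td>%s</td><td>%s</td><td>%s : %s</td><td>%s</td></tr>",
                r[["side"]], r[["ratio"]],
                fmt_num(as.numeric(r[["first_pct"]]), 1),
                fmt_num(as.numeric(r[["second_pct"]]), 1),
                fmt_num(as.numeric(r[["deviation_pp"]]), 1))
      })
    } else character()
    html <- c(
      "<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\"/>",
      "<title>Breast measurement report</title></head><body>",
      sprintf("<h1>Breast measurement report</h1>"),
      sprintf("<p>Subject: %s%s</p>",
              report$subject$id,
              if (report$two_photo) " (two-photo assessment)" else ""),
      "<h2>Measurements (cm)</h2>",
      "<table border=\"1\"><tr><th>Measurement</th><th>Value (cm)</th><th>Provenance</th></tr>",
      rows, "</table>",
      "<h2>Aesthetic ratios (ideals 45:55 vertical, 40:60 horizontal)</h2>",
      "<table border=\"1\"><tr><th>Side</th><th>Ratio</th><th>Value</th><th>Deviation (pp)</th></tr>",
      ratio_rows, "</table>",
      "</body></html>")
    writeLines(html, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Write the measurement panel as CSV
#'
#' One row per measurement: name, value in cm, provenance.
#'
#' @param panel A `measurement_panel`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(as.data.frame(panel)[, c("measurement", "value_cm",
                                            "provenance")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Bland-Altman plot
#'
#' Scatter of paired differences against paired means with the bias line
#' and the 1.96 SD limits of agreement, in the style used to assess
#' clinical interchangeability of a digital and a direct method.
#'
#' @param ba A [bland_altman()] result.
#' @param path Output file (PNG via [grDevices::png()], or SVG when the
#'   path ends in `.svg`).
#' @param main Plot title.
#' @return `path`, invisibly.
#' @export
plot_bland_altman <- function(ba, path, main = "Bland-Altman agreement") {
  stopifnot(inherits(ba, "bland_altman"))
  if (grepl("\\.svg$", path)) grDevices::svg(path, width = 6, height = 5)
  else grDevices::png(path, width = 720, height = 600)
  on.exit(grDevices::dev.off())
  plot(ba$data$mean, ba$data$difference,
       xlab = "Mean of digital and direct value (cm)",
       ylab = "Digital - direct difference (cm)",
       main = main, pch = 19, col = "#00000080")
  graphics::abline(h = ba$bias, col = "#2166ac", lwd = 2)
  graphics::abline(h = c(ba$loa_low, ba$loa_high), col = "#b2182b", lty = 2)
  invisible(path)
}
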