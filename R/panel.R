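#' Names of the 13 clinical measurements
#'
#' Level differences: `NLD` (nipples), `IMFLD` (inframammary fold apices),
#' `UPLD` (upper pole apices). Midline distances: `MLN` (medial line to
#' nipple), `IMFML` (inframammary fold apex to medial line). Chord
#' distances: `SNN` (sternal notch to nipple), `IMFN` (inframammary fold
#' apex to nipple), `UPN` (upper pole apex to nipple). Side-specific
#' measurements carry `_R`/`_L` suffixes.
#'
#' @return Character vector of the 13 measurement names.
#' @export
measurement_names <- function() {
  c("NLD", "MLN_R", "MLN_L", "SNN_R", "SNN_L", "IMFLD", "IMFML_R",
    "IMFML_L", "IMFN_R", "IMFN_L", "UPLD", "UPN_R", "UPN_L")
}

# landmarks each measurement needs (beyond SN/UMB, which are always required)
measurement_requirements <- function() {
  list(
    NLD     = c("N_R", "N_L"),
    MLN_R   = "N_R",     MLN_L   = "N_L",
    SNN_R   = "N_R",     SNN_L   = "N_L",
    IMFLD   = c("IMFA_R", "IMFA_L"),
    IMFML_R = "IMFA_R",  IMFML_L = "IMFA_L",
    IMFN_R  = c("IMFA_R", "N_R"), IMFN_L = c("IMFA_L", "N_L"),
    UPLD    = c("UPA_R", "UPA_L"),
    UPN_R   = c("UPA_R", "N_R"), UPN_L = c("UPA_L", "N_L")
  )
}

#' Compute the clinical measurement panel from an annotation
#'
#' Assembles the 13 named linear measurements (in cm) from a
#' [landmark_annotation()]. Level differences are magnitudes of the signed
#' projection difference onto the medial axis; midline distances are
#' perpendicular point-to-line distances; the rest are straight chord
#' distances. A measurement is present iff all landmarks it needs are
#' annotated; absent landmarks yield absent (not zero) rows.
#'
#' When a secondary (breasts-lifted) annotation is attached, the IMFA and
#' UPA landmarks are taken from it and mapped into the primary frame with
#' [bind_photos()] before any mixed-frame distance: nipples always come
#' from the primary (relaxed) photo, so e.g. IMFN pairs a primary-frame
#' nipple with a mapped fold apex. Such values are flagged `two-photo`.
#'
#' @param annotation A [landmark_annotation()].
#' @return A data frame of class `measurement_panel` with columns
#'   `measurement`, `value_cm`, `provenance` (`single-photo`/`two-photo`),
#'   and attribute `signed_cm` holding the signed level differences.
#' @export
compute_panel <- function(annotation) {
  stopifnot(inherits(annotation, "landmark_annotation"))
  scale <- compute_scale(annotation$calibration)
  ml <- annotation_midline(annotation)
  lms <- annotation$landmarks
  prov <- rep("single-photo", length(lms))
  names(prov) <- names(lms)

  sec <- annotation$secondary
  if (!is.null(sec)) {
    tf <- bind_photos(ml, annotation_midline(sec),
                      scale_primary = scale,
                      scale_secondary = compute_scale(sec$calibration))
    for (nm in intersect(c("IMFA_R", "IMFA_L", "UPA_R", "UPA_L"),
                         names(sec$landmarks))) {
      lms[[nm]] <- apply_transform(tf, sec$landmarks[[nm]])
      prov[nm] <- "two-photo"
    }
  }

  req <- measurement_requirements()
  rows <- list()
  signed <- c()
  for (m in measurement_names()) {
    need <- req[[m]]
    if (!all(need %in% names(lms))) next
    pv <- if (any(prov[need] == "two-photo")) "two-photo" else "single-photo"
    value <- switch(
      m,
      NLD   = , IMFLD = , UPLD = {
        ld <- level_difference_cm(lms[[need[1]]], lms[[need[2]]], ml, scale)
        signed[m] <- ld$signed_cm
        ld$magnitude_cm
      },
      MLN_R = , MLN_L = , IMFML_R = , IMFML_L =
        midline_distance_cm(lms[[need[1]]], ml, scale),
      SNN_R = , SNN_L = distance_cm(lms$SN, lms[[need[1]]], scale),
      IMFN_R = , IMFN_L = , UPN_R = , UPN_L =
        distance_cm(lms[[need[1]]], lms[[need[2]]], scale)
    )
    rows[[m]] <- data.frame(measurement = m, value_cm = value,
                            provenance = pv, stringsAsFactors = FALSE)
  }
  panel <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(measurement = character(), value_cm = numeric(),
               provenance = character(), stringsAsFactors = FALSE)
  }
  attr(panel, "signed_cm") <- signed
  attr(panel, "subject_id") <- annotation$subject_id
  class(panel) <- c("measurement_panel", class(panel))
  panel
}

#' @export
print.measurement_panel <- function(x, ...) {
  cat(sprintf("Measurement panel%s (%d of 13 measurements):\n",
              if (!is.null(attr(x, "subject_id")))
                sprintf(" for subject '%s'", attr(x, "subject_id")) else "",
              nrow(x)))
  out <- data.frame(measurement = x$measurement,
                    value_cm = sprintf("%.1f", round(x$value_cm, 1)),
                    provenance = x$provenance)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Extract one panel value
#'
#' @param panel A `measurement_panel`.
#' @param measurement One of [measurement_names()].
#' @return The value in cm, or `NA` if the measurement is absent.
#' @export
panel_value <- function(panel, measurement) {
  i <- match(measurement, panel$measurement)
  if (is.na(i)) NA_real_ else panel$value_cm[i]
}

ratio_of <- function(a, b, what) {
  if (!is.numeric(a) || !is.numeric(b) || a < 0 || b < 0) {
    stop(sprintf("%s components must be non-negative numbers", what),
         call. = FALSE)
  }
  if (a + b == 0) {
    stop(sprintf("undefined %s: both components are zero", what),
         call. = FALSE)
  }
  c(100 * a / (a + b), 100 * b / (a + b))
}

#' Vertical (upper:lower pole) aesthetic ratio
#'
#' Ratio of the upper-pole-apex-to-nipple distance to the inframammary-fold
#' -apex-to-nipple distance, expressed as percentages summing to 100. The
#' published "most appealing" reference is 45:55.
#'
#' @param upn Upper pole apex to nipple distance, cm.
#' @param imfn Inframammary fold apex to nipple distance, cm.
#' @return Named numeric `c(upper, lower)` in percent.
#' @examples
#' vertical_ratio(9, 11)  # the 45:55 ideal
#' @export
vertical_ratio <- function(upn, imfn) {
  r <- ratio_of(upn, imfn, "vertical ratio")
  c(upper = r[1], lower = r[2])
}

#' Horizontal (lateral:medial) aesthetic ratio
#'
#' Ratio of the lateral-breast-border-to-nipple distance to the
#' nipple-to-medial-border distance, as percentages summing to 100. The
#' published "most appealing" reference is 40:60.
#'
#' @param lateral_to_nipple,nipple_to_medial Distances in cm.
#' @return Named numeric `c(lateral, medial)` in percent.
#' @examples
#' horizontal_ratio(8, 12)  # the 40:60 ideal
#' @export
horizontal_ratio <- function(lateral_to_nipple, nipple_to_medial) {
  r <- ratio_of(lateral_to_nipple, nipple_to_medial, "horizontal ratio")
  c(lateral = r[1], medial = r[2])
}

#' Ideal aesthetic ratio references
#' @return List with `vertical` (45:55) and `horizontal` (40:60) ideals.
#' @export
ideal_ratios <- function() {
  list(vertical = c(upper = 45, lower = 55),
       horizontal = c(lateral = 40, medial = 60))
}

#' Per-breast aesthetic ratio set
#'
#' Computes, per breast, the vertical (upper:lower pole) ratio from the UPN
#' and IMFN panel values and -- when the optional LB/MB border landmarks are
#' annotated -- the horizontal (lateral:medial) ratio from border-to-nipple
#' distances, together with deviations from the 45:55 and 40:60 ideals in
#' percentage points.
#'
#' @param annotation A [landmark_annotation()].
#' @param panel Optional precomputed [compute_panel()] result.
#' @return Data frame of class `ratio_set` with columns `side`, `ratio`
#'   (`vertical`/`horizontal`), the two components in percent, and
#'   `deviation_pp` (absolute deviation of the first component from ideal).
#' @export
ratio_set <- function(annotation, panel = compute_panel(annotation)) {
  stopifnot(inherits(annotation, "landmark_annotation"))
  scale <- compute_scale(annotation$calibration)
  lms <- annotation$landmarks
  ideals <- ideal_ratios()
  rows <- list()
  for (side in c("R", "L")) {
    upn <- panel_value(panel, paste0("UPN_", side))
    imfn <- panel_value(panel, paste0("IMFN_", side))
    if (!is.na(upn) && !is.na(imfn) && upn + imfn > 0) {
      v <- vertical_ratio(upn, imfn)
      rows[[paste0("v", side)]] <- data.frame(
        side = side, ratio = "vertical",
        first_pct = v[["upper"]], second_pct = v[["lower"]],
        deviation_pp = abs(v[["upper"]] - ideals$vertical[["upper"]]),
        stringsAsFactors = FALSE)
    }
    lb <- lms[[paste0("LB_", side)]]; mb <- lms[[paste0("MB_", side)]]
    np <- lms[[paste0("N_", side)]]
    if (!is.null(lb) && !is.null(mb) && !is.null(np)) {
      lat <- distance_cm(lb, np, scale)
      med <- distance_cm(np, mb, scale)
      if (lat + med > 0) {
        h <- horizontal_ratio(lat, med)
        rows[[paste0("h", side)]] <- data.frame(
          side = side, ratio = "horizontal",
          first_pct = h[["lateral"]], second_pct = h[["medial"]],
          deviation_pp = abs(h[["lateral"]] - ideals$horizontal[["lateral"]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(side = character(), ratio = character(),
               first_pct = numeric(), second_pct = numeric(),
               deviation_pp = numeric(), stringsAsFactors = FALSE)
  }
  class(out) <- c("ratio_set", class(out))
  out
}
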