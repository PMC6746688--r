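#' Pixel-space point in a photo frame
#'
#' Points use raw image coordinates: origin at the top-left corner, x grows
#' rightward, y grows downward. Sub-pixel (continuous) values are allowed;
#' every point carries the identifier of the photo frame it lives in, so that
#' accidental mixing of frames is caught.
#'
#' @param x,y Continuous pixel coordinates (finite).
#' @param photo_id Identifier of the photo frame (character scalar).
#' @return An object of class `pixel_point`.
#' @examples
#' pixel_point(120.5, 340.25)
#' @export
pixel_point <- function(x, y, photo_id = "photo1") {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == 1L, length(y) == 1L)
  if (!is.finite(x) || !is.finite(y)) {
    stop("pixel_point coordinates must be finite", call. = FALSE)
  }
  structure(
    list(x = as.numeric(x), y = as.numeric(y),
         photo_id = as.character(photo_id)),
    class = "pixel_point"
  )
}

#' @export
print.pixel_point <- function(x, ...) {
  cat(sprintf("<pixel_point (%.3f, %.3f) @ %s>\n", x$x, x$y, x$photo_id))
  invisible(x)
}

as_xy <- function(p) c(p$x, p$y)

same_frame <- function(...) {
  ids <- vapply(list(...), function(p) p$photo_id, character(1))
  length(unique(ids)) == 1L
}

#' Calibration segment of known physical length
#'
#' An in-frame reference object (by protocol a 2 cm long unit placed flat on
#' the chest, perpendicular to the camera axis) marked by its two endpoints.
#' It anchors the pixel-to-centimetre scale of the photograph.
#'
#' @param endpoint_a,endpoint_b [pixel_point()] endpoints of the reference
#'   segment; must be distinct and in the same photo frame.
#' @param known_length_cm Physical length of the segment in cm (default 2).
#' @return An object of class `calibration_segment`.
#' @export
calibration_segment <- function(endpoint_a, endpoint_b, known_length_cm = 2) {
  stopifnot(inherits(endpoint_a, "pixel_point"),
            inherits(endpoint_b, "pixel_point"))
  if (!same_frame(endpoint_a, endpoint_b)) {
    stop("calibration endpoints lie in different photo frames", call. = FALSE)
  }
  if (!is.numeric(known_length_cm) || length(known_length_cm) != 1L ||
      !is.finite(known_length_cm) || known_length_cm <= 0) {
    stop("known_length_cm must be a positive finite number", call. = FALSE)
  }
  structure(
    list(endpoint_a = endpoint_a, endpoint_b = endpoint_b,
         known_length_cm = as.numeric(known_length_cm)),
    class = "calibration_segment"
  )
}

#' Pixel-to-centimetre scale of a photograph
#'
#' Derived from a [calibration_segment()]: the Euclidean pixel length of the
#' reference segment divided by its known physical length.
#'
#' @param calibration A [calibration_segment()].
#' @return An object of class `photo_scale` with field `pixels_per_cm`.
#' @examples
#' seg <- calibration_segment(pixel_point(0, 0), pixel_point(100, 0), 2)
#' compute_scale(seg)$pixels_per_cm  # 50
#' @export
compute_scale <- function(calibration) {
  stopifnot(inherits(calibration, "calibration_segment"))
  d <- sqrt(sum((as_xy(calibration$endpoint_a) -
                 as_xy(calibration$endpoint_b))^2))
  if (d == 0) {
    stop("degenerate calibration: reference segment endpoints coincide",
         call. = FALSE)
  }
  structure(
    list(pixels_per_cm = d / calibration$known_length_cm,
         photo_id = calibration$endpoint_a$photo_id),
    class = "photo_scale"
  )
}

#' @export
print.photo_scale <- function(x, ...) {
  cat(sprintf("<photo_scale %.4f px/cm @ %s>\n", x$pixels_per_cm, x$photo_id))
  invisible(x)
}

#' Euclidean distance between two landmarks, in centimetres
#'
#' Straight-line (chord) distance; the digital counterpart of a taut tape
#' measure that does not follow body curvature. Points must share a photo
#' frame, or a [similarity_transform] mapping `q`'s frame into `p`'s must be
#' supplied.
#'
#' @param p,q [pixel_point()]s.
#' @param scale A `photo_scale` for the frame the distance is measured in.
#' @param transform Optional [bind_photos()] transform applied to `q` first.
#' @return Non-negative length in cm.
#' @export
distance_cm <- function(p, q, scale, transform = NULL) {
  stopifnot(inherits(p, "pixel_point"), inherits(q, "pixel_point"),
            inherits(scale, "photo_scale"))
  if (!is.null(transform)) q <- apply_transform(transform, q)
  if (!same_frame(p, q)) {
    stop(sprintf(
      "frame mismatch: '%s' vs '%s' (supply a transform to bind them)",
      p$photo_id, q$photo_id), call. = FALSE)
  }
  sqrt(sum((as_xy(p) - as_xy(q))^2)) / scale$pixels_per_cm
}

#' The patient's medial line as an oriented axis
#'
#' Defined by exactly two landmarks: the sternal notch (superior anchor) and
#' the umbilicus (inferior anchor). It is treated as an infinite line for
#' perpendicular distances and as an oriented axis -- origin at the sternal
#' notch, unit direction towards the umbilicus -- for landmark levels.
#'
#' @param superior,inferior [pixel_point()]s marking the sternal notch and
#'   umbilicus; must be distinct and share a frame.
#' @return An object of class `midline` with the unit axis precomputed.
#' @export
midline <- function(superior, inferior) {
  stopifnot(inherits(superior, "pixel_point"), inherits(inferior, "pixel_point"))
  if (!same_frame(superior, inferior)) {
    stop("midline endpoints lie in different photo frames", call. = FALSE)
  }
  v <- as_xy(inferior) - as_xy(superior)
  len <- sqrt(sum(v^2))
  if (len == 0) {
    stop("degenerate midline: superior and inferior landmarks coincide",
         call. = FALSE)
  }
  structure(
    list(superior = superior, inferior = inferior, axis = v / len,
         length_px = len, photo_id = superior$photo_id),
    class = "midline"
  )
}

#' Level of a landmark along the medial axis
#'
#' Scalar projection of `p` (relative to the sternal notch) onto the unit
#' midline axis, in pixels. Values increase towards the umbilicus, i.e. a
#' larger level means a more inferior landmark. The projection is orthogonal
#' to the body axis, not parallel to the image x-axis, so levels are
#' invariant to camera roll.
#'
#' @param p A [pixel_point()] in the midline's frame.
#' @param ml A [midline()].
#' @return Level coordinate in pixels (signed scalar).
#' @export
level_of <- function(p, ml) {
  stopifnot(inherits(p, "pixel_point"), inherits(ml, "midline"))
  if (p$photo_id != ml$photo_id) {
    stop("frame mismatch between point and midline", call. = FALSE)
  }
  sum((as_xy(p) - as_xy(ml$superior)) * ml$axis)
}

#' Level difference between a right and a left landmark
#'
#' Both landmarks are projected orthogonally onto the medial axis and the
#' distance between the projections is converted to cm. The signed value is
#' right minus left (positive when the right-side landmark sits more
#' inferior); clinical panels report the magnitude.
#'
#' @param p_right,p_left [pixel_point()]s of the paired landmarks.
#' @param ml A [midline()].
#' @param scale A `photo_scale`.
#' @return List with `signed_cm` and `magnitude_cm`.
#' @export
level_difference_cm <- function(p_right, p_left, ml, scale) {
  stopifnot(inherits(scale, "photo_scale"))
  signed <- (level_of(p_right, ml) - level_of(p_left, ml)) / scale$pixels_per_cm
  list(signed_cm = signed, magnitude_cm = abs(signed))
}

#' Perpendicular distance from a landmark to the medial line
#'
#' Point-to-infinite-line distance, in cm; zero iff the point lies on the
#' line through the sternal notch and umbilicus.
#'
#' @inheritParams level_difference_cm
#' @param p A [pixel_point()].
#' @return Non-negative length in cm.
#' @export
midline_distance_cm <- function(p, ml, scale) {
  stopifnot(inherits(p, "pixel_point"), inherits(ml, "midline"),
            inherits(scale, "photo_scale"))
  if (p$photo_id != ml$photo_id) {
    stop("frame mismatch between point and midline", call. = FALSE)
  }
  rel <- as_xy(p) - as_xy(ml$superior)
  # 2-D cross product magnitude = distance to line x unit-axis length
  abs(rel[1] * ml$axis[2] - rel[2] * ml$axis[1]) / scale$pixels_per_cm
}

#' Bind two photographs of the same subject via their medial lines
#'
#' Estimates the unique 2-D similarity transform (rotation, isotropic scale,
#' translation) that maps the secondary photo's two midline endpoints onto
#' the primary photo's. The two marked endpoints must correspond
#' anatomically: sternal notch to sternal notch, umbilicus to umbilicus.
#' With the transform, any landmark marked on the secondary (breasts-lifted)
#' photo can be expressed in the primary frame.
#'
#' If both photos carry their own calibration, the transform's implied scale
#' ratio is checked against the ratio of the two calibrated `pixels_per_cm`;
#' a relative disagreement above `tolerance` raises a warning (not an
#' error -- lifting the breasts may slightly change camera distance).
#'
#' @param midline_primary,midline_secondary [midline()]s marked on the two
#'   photos.
#' @param scale_primary,scale_secondary Optional `photo_scale`s used for the
#'   calibration-consistency check.
#' @param tolerance Relative tolerance of that check (default 0.05).
#' @return An object of class `similarity_transform` mapping
#'   secondary-frame points into the primary frame.
#' @export
bind_photos <- function(midline_primary, midline_secondary,
                        scale_primary = NULL, scale_secondary = NULL,
                        tolerance = 0.05) {
  stopifnot(inherits(midline_primary, "midline"),
            inherits(midline_secondary, "midline"))
  # Two point correspondences determine a similarity exactly; solve in the
  # complex plane: z_target = a * z_source + b.
  s1 <- complex(real = midline_secondary$superior$x,
                imaginary = midline_secondary$superior$y)
  s2 <- complex(real = midline_secondary$inferior$x,
                imaginary = midline_secondary$inferior$y)
  t1 <- complex(real = midline_primary$superior$x,
                imaginary = midline_primary$superior$y)
  t2 <- complex(real = midline_primary$inferior$x,
                imaginary = midline_primary$inferior$y)
  a <- (t2 - t1) / (s2 - s1)
  b <- t1 - a * s1
  tf <- structure(
    list(rotation_rad = Arg(a), scale_factor = Mod(a),
         translation_px = c(Re(b), Im(b)),
         source_photo_id = midline_secondary$photo_id,
         target_photo_id = midline_primary$photo_id),
    class = "similarity_transform"
  )
  if (!is.null(scale_primary) && !is.null(scale_secondary)) {
    implied <- scale_primary$pixels_per_cm / scale_secondary$pixels_per_cm
    if (abs(tf$scale_factor / implied - 1) > tolerance) {
      warning(sprintf(
        paste0("calibration inconsistency between bound photos: midline-",
               "implied scale ratio %.4f vs calibrated ratio %.4f ",
               "(tolerance %.0f%%)"),
        tf$scale_factor, implied, 100 * tolerance), call. = FALSE)
    }
  }
  tf
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf(
    "<similarity_transform %s -> %s: rot %.4f rad, scale %.4f, t (%.2f, %.2f)>\n",
    x$source_photo_id, x$target_photo_id, x$rotation_rad, x$scale_factor,
    x$translation_px[1], x$translation_px[2]))
  invisible(x)
}

#' Apply a similarity transform to a landmark
#'
#' @param t A `similarity_transform` from [bind_photos()].
#' @param p A [pixel_point()] in the transform's source frame.
#' @return The point expressed in the target frame.
#' @export
apply_transform <- function(t, p) {
  stopifnot(inherits(t, "similarity_transform"), inherits(p, "pixel_point"))
  if (p$photo_id != t$source_photo_id) {
    stop(sprintf("frame mismatch: point in '%s', transform expects '%s'",
                 p$photo_id, t$source_photo_id), call. = FALSE)
  }
  co <- cos(t$rotation_rad); si <- sin(t$rotation_rad)
  s <- t$scale_factor
  x <- s * (co * p$x - si * p$y) + t$translation_px[1]
  y <- s * (si * p$x + co * p$y) + t$translation_px[2]
  pixel_point(x, y, t$target_photo_id)
}

#' Invert a similarity transform
#'
#' @param t A `similarity_transform`.
#' @return The inverse transform (target frame back to source frame).
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "similarity_transform"))
  co <- cos(-t$rotation_rad); si <- sin(-t$rotation_rad)
  s <- 1 / t$scale_factor
  tx <- -(s * (co * t$translation_px[1] - si * t$translation_px[2]))
  ty <- -(s * (si * t$translation_px[1] + co * t$translation_px[2]))
  structure(
    list(rotation_rad = -t$rotation_rad, scale_factor = s,
         translation_px = c(tx, ty),
         source_photo_id = t$target_photo_id,
         target_photo_id = t$source_photo_id),
    class = "similarity_transform"
  )
}
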