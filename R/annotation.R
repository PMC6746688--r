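#' Landmark vocabulary
#'
#' The named anatomical landmarks an annotation may carry. `SN` sternal
#' notch and `UMB` umbilicus anchor the medial line; `N` nipple, `IMFA`
#' inframammary fold apex and `UPA` upper pole apex come in right/left
#' pairs and drive the 13 clinical measurements. `LB`/`MB` (lateral and
#' medial breast border) are optional and used only for the horizontal
#' aesthetic ratio.
#'
#' @return Character vector of valid landmark names.
#' @export
landmark_vocabulary <- function() {
  c("SN", "UMB", "N_R", "N_L", "IMFA_R", "IMFA_L", "UPA_R", "UPA_L",
    "LB_R", "LB_L", "MB_R", "MB_L")
}

#' Landmark annotation of one photograph
#'
#' The raw input of the measurement pipeline: named pixel landmarks plus the
#' calibration segment of one photo, optionally bundled with a secondary
#' (breasts-lifted) annotation for ptotic subjects. `SN` and `UMB` are
#' mandatory (they define the medial line); every other landmark is
#' optional, and measurements that need an absent landmark are simply not
#' produced.
#'
#' @param photo_id Identifier of the photo frame.
#' @param calibration A [calibration_segment()] in this frame.
#' @param landmarks Named list of [pixel_point()]s; names restricted to
#'   [landmark_vocabulary()], each present at most once.
#' @param secondary Optional `landmark_annotation` of the breasts-lifted
#'   photo (must itself contain SN and UMB); its IMFA/UPA landmarks take
#'   precedence in panel computation.
#' @param image_path Optional path of the underlying photograph (used only
#'   for overlays).
#' @param image_size Optional `c(width, height)` in pixels.
#' @param subject_id,sex_type,notes Optional subject metadata.
#' @return An object of class `landmark_annotation`.
#' @export
landmark_annotation <- function(photo_id, calibration, landmarks,
                                secondary = NULL, image_path = NULL,
                                image_size = NULL, subject_id = NULL,
                                sex_type = NULL, notes = NULL) {
  stopifnot(inherits(calibration, "calibration_segment"), is.list(landmarks))
  nm <- names(landmarks)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("landmarks must be a uniquely named list", call. = FALSE)
  }
  bad <- setdiff(nm, landmark_vocabulary())
  if (length(bad)) {
    stop(sprintf("unknown landmark name(s): %s (valid: %s)",
                 paste(bad, collapse = ", "),
                 paste(landmark_vocabulary(), collapse = ", ")),
         call. = FALSE)
  }
  if (!all(c("SN", "UMB") %in% nm)) {
    stop("annotation must contain SN and UMB (they define the medial line)",
         call. = FALSE)
  }
  for (p in landmarks) {
    stopifnot(inherits(p, "pixel_point"))
    if (p$photo_id != photo_id) {
      stop("all landmarks must lie in the annotation's photo frame",
           call. = FALSE)
    }
  }
  if (calibration$endpoint_a$photo_id != photo_id) {
    stop("calibration segment must lie in the annotation's photo frame",
         call. = FALSE)
  }
  if (!is.null(secondary)) {
    stopifnot(inherits(secondary, "landmark_annotation"))
    if (!is.null(secondary$secondary)) {
      stop("a secondary annotation cannot itself carry a secondary photo",
           call. = FALSE)
    }
  }
  structure(
    list(photo_id = as.character(photo_id), calibration = calibration,
         landmarks = landmarks, secondary = secondary,
         image_path = image_path, image_size = image_size,
         subject_id = subject_id, sex_type = sex_type, notes = notes),
    class = "landmark_annotation"
  )
}

#' @export
print.landmark_annotation <- function(x, ...) {
  cat(sprintf("<landmark_annotation '%s': %d landmark(s)%s>\n",
              x$photo_id, length(x$landmarks),
              if (!is.null(x$secondary)) " + secondary (lifted) photo" else ""))
  invisible(x)
}

#' Medial line of an annotation
#'
#' @param annotation A [landmark_annotation()].
#' @return The [midline()] through the annotation's SN and UMB landmarks.
#' @export
annotation_midline <- function(annotation) {
  stopifnot(inherits(annotation, "landmark_annotation"))
  midline(annotation$landmarks$SN, annotation$landmarks$UMB)
}

annotation_schema_version <- "1.0"

photo_block_to_list <- function(ann) {
  pt <- function(p) list(x = p$x, y = p$y)
  list(
    photo_id = ann$photo_id,
    image_path = ann$image_path,
    image_size = ann$image_size,
    calibration = list(
      endpoint_a = pt(ann$calibration$endpoint_a),
      endpoint_b = pt(ann$calibration$endpoint_b),
      known_length_cm = ann$calibration$known_length_cm
    ),
    landmarks = lapply(ann$landmarks, pt)
  )
}

photo_block_from_list <- function(blk, what = "photo block") {
  need <- c("photo_id", "calibration", "landmarks")
  miss <- setdiff(need, names(blk))
  if (length(miss)) {
    stop(sprintf("invalid %s: missing field(s) %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  pid <- blk$photo_id
  cal <- blk$calibration
  if (!all(c("endpoint_a", "endpoint_b", "known_length_cm") %in% names(cal))) {
    stop(sprintf("invalid %s: incomplete calibration block", what),
         call. = FALSE)
  }
  to_pt <- function(v) pixel_point(as.numeric(v[["x"]]), as.numeric(v[["y"]]), pid)
  landmarks <- lapply(blk$landmarks, to_pt)
  names(landmarks) <- names(blk$landmarks)
  list(
    photo_id = pid,
    calibration = calibration_segment(to_pt(cal$endpoint_a),
                                      to_pt(cal$endpoint_b),
                                      as.numeric(cal$known_length_cm)),
    landmarks = landmarks,
    image_path = blk$image_path,
    image_size = if (!is.null(blk$image_size)) as.numeric(blk$image_size)
  )
}

#' Write an annotation to a JSON file
#'
#' The file layout (schema shipped at
#' `system.file("extdata", "annotation-schema.json", package = "photanthro")`)
#' stores a schema version, subject metadata and one or two photo blocks,
#' each with photo id, optional image reference, calibration segment and
#' landmark map. Raw click coordinates are stored untransformed.
#'
#' @param annotation A [landmark_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "landmark_annotation"))
  doc <- list(
    schema_version = annotation_schema_version,
    subject = list(id = annotation$subject_id,
                   sex_type = annotation$sex_type,
                   notes = annotation$notes),
    primary = photo_block_to_list(annotation)
  )
  if (!is.null(annotation$secondary)) {
    doc$secondary <- photo_block_to_list(annotation$secondary)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read an annotation from a JSON file
#'
#' Validates the file against the shipped schema contract: schema version,
#' exactly one primary photo block, landmark names restricted to
#' [landmark_vocabulary()], calibration present, SN and UMB present.
#'
#' @param path Path to an annotation JSON file.
#' @return A [landmark_annotation()].
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$schema_version)) {
    stop("invalid annotation file: missing schema_version", call. = FALSE)
  }
  if (is.null(doc$primary)) {
    stop("invalid annotation file: missing primary photo block", call. = FALSE)
  }
  sec <- NULL
  if (!is.null(doc$secondary)) {
    sb <- photo_block_from_list(doc$secondary, "secondary photo block")
    sec <- landmark_annotation(sb$photo_id, sb$calibration, sb$landmarks,
                               image_path = sb$image_path,
                               image_size = sb$image_size)
  }
  pb <- photo_block_from_list(doc$primary, "primary photo block")
  landmark_annotation(pb$photo_id, pb$calibration, pb$landmarks,
                      secondary = sec, image_path = pb$image_path,
                      image_size = pb$image_size,
                      subject_id = doc$subject$id,
                      sex_type = doc$subject$sex_type,
                      notes = doc$subject$notes)
}
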