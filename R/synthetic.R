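# Seeds derived from a master seed stay below 2^31 - 1.
derive_seed <- function(master, ...) {
  parts <- c(master, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + as.numeric(p) + 1) %% 2147483629
  as.integer(s)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Body-frame landmark presets
#'
#' Mean landmark coordinates in a body-fixed frame, in cm, with the sternal
#' notch at the origin, x to the subject's anatomical left as seen on the
#' photo (image-right) and y increasing towards the feet (matching image
#' convention). Magnitudes follow typical adult torso anthropometry:
#' sternal notch to umbilicus about 25 cm, sternal-notch-to-nipple about
#' 19-21 cm in women and about 15 cm in men.
#'
#' @param preset `"female"` or `"male"`.
#' @return Named list of `c(x, y)` landmark positions in cm.
#' @export
subject_preset <- function(preset = c("female", "male")) {
  preset <- match.arg(preset)
  if (preset == "female") {
    # N-UPA ~6.2 cm, N-IMFA ~7.3 cm: vertical pole ratio near the
    # published 45:55 aesthetic reference for a natural breast
    list(SN = c(0, 0), UMB = c(0, 25),
         N_R = c(-9.5, 17), N_L = c(9.5, 17),
         UPA_R = c(-8, 11), UPA_L = c(8, 11),
         IMFA_R = c(-7.5, 24), IMFA_L = c(7.5, 24),
         LB_R = c(-16, 16.5), LB_L = c(16, 16.5),
         MB_R = c(-2.5, 16.5), MB_L = c(2.5, 16.5))
  } else {
    list(SN = c(0, 0), UMB = c(0, 24),
         N_R = c(-10, 12), N_L = c(10, 12),
         UPA_R = c(-9, 8), UPA_L = c(9, 8),
         IMFA_R = c(-8.5, 15), IMFA_L = c(8.5, 15),
         LB_R = c(-15, 12), LB_L = c(15, 12),
         MB_R = c(-4, 12), MB_L = c(4, 12))
  }
}

#' Generate a synthetic subject
#'
#' Draws a subject around a sex-type preset: each non-anchor landmark gets
#' an independent Gaussian anatomical variation (SD `variation_cm`, default
#' 1 cm), then the named `asymmetry_cm` offsets are added -- e.g.
#' `list(N_L = c(0, 0.6))` lowers the left nipple by 0.6 cm, creating a
#' ground-truth nipple level difference of 0.6 cm. The ground-truth
#' measurement panel is computable in closed form from the body frame (see
#' [true_panel()]).
#'
#' @param preset `"female"` or `"male"`.
#' @param asymmetry_cm Named list of `c(dx, dy)` cm offsets per landmark.
#' @param ptosis If `TRUE`, the inframammary folds and upper poles are
#'   treated as hidden on a relaxed photo, so [photograph_subject()] needs a
#'   lifted secondary photo to expose them. Default `FALSE`.
#' @param variation_cm SD of the per-landmark anatomical variation (cm);
#'   0 gives the preset geometry exactly.
#' @param seed Integer seed; fixed seed gives an identical subject.
#' @return Object of class `subject_template` with the landmark list
#'   `landmarks_cm`, `preset` and `ptosis`.
#' @export
make_subject <- function(preset = c("female", "male"), asymmetry_cm = list(),
                         ptosis = FALSE, variation_cm = 1, seed = 1) {
  preset <- match.arg(preset)
  base <- subject_preset(preset)
  bad <- setdiff(names(asymmetry_cm), names(base))
  if (length(bad)) {
    stop(sprintf("asymmetry for unknown landmark(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  lms <- with_seed(derive_seed(seed, 101), {
    out <- base
    for (nm in names(out)) {
      if (nm %in% c("SN", "UMB")) next    # anchors stay on the midline
      out[[nm]] <- out[[nm]] + stats::rnorm(2, 0, variation_cm)
    }
    out
  })
  for (nm in names(asymmetry_cm)) {
    lms[[nm]] <- lms[[nm]] + as.numeric(asymmetry_cm[[nm]])
  }
  structure(list(landmarks_cm = lms, preset = preset, ptosis = ptosis,
                 seed = seed),
            class = "subject_template")
}

#' @export
print.subject_template <- function(x, ...) {
  cat(sprintf("<subject_template %s%s, %d landmarks>\n", x$preset,
              if (x$ptosis) " (ptotic)" else "", length(x$landmarks_cm)))
  invisible(x)
}

#' Photo framing model
#'
#' Forward model of taking one photograph: an isotropic pixel scale, a
#' camera roll angle, a pixel translation, and an optional perspective
#' foreshortening coefficient. The 2 cm reference unit is placed flat on
#' the upper chest (`reference_cm`, two body-frame points 2 cm apart).
#'
#' The skew model divides body coordinates by `1 + skew * y_cm`, a linear
#' foreshortening with depth -- enough to probe sensitivity to a
#' non-perpendicular camera without a full projective model. `skew` is
#' limited to \[0, 0.05\] per cm.
#'
#' @param pixels_per_cm Image resolution at the chest plane (default 35).
#' @param roll_deg Camera roll angle in degrees (default 0).
#' @param translation_px Pixel offset `c(tx, ty)` of the frame.
#' @param skew Foreshortening coefficient per cm (default 0).
#' @param reference_cm 2 x 2 matrix of body-frame reference endpoints (rows),
#'   default a horizontal 2 cm unit below the right clavicle.
#' @param photo_id Frame identifier.
#' @return Object of class `photo_model`.
#' @export
photo_model <- function(pixels_per_cm = 35, roll_deg = 0,
                        translation_px = c(500, 300), skew = 0,
                        reference_cm = rbind(c(-5, 2), c(-3, 2)),
                        photo_id = "photo1") {
  if (pixels_per_cm <= 0) stop("pixels_per_cm must be positive", call. = FALSE)
  if (skew < 0 || skew > 0.05) {
    stop("skew coefficient must lie in [0, 0.05]", call. = FALSE)
  }
  structure(list(pixels_per_cm = pixels_per_cm, roll_deg = roll_deg,
                 translation_px = as.numeric(translation_px), skew = skew,
                 reference_cm = reference_cm, photo_id = photo_id),
            class = "photo_model")
}

project_point <- function(xy_cm, photo) {
  if (photo$skew > 0) xy_cm <- xy_cm / (1 + photo$skew * xy_cm[2])
  th <- photo$roll_deg * pi / 180
  r <- c(cos(th) * xy_cm[1] - sin(th) * xy_cm[2],
         sin(th) * xy_cm[1] + cos(th) * xy_cm[2])
  r * photo$pixels_per_cm + photo$translation_px
}

#' Photograph a synthetic subject (noise-free annotation)
#'
#' Applies the photo model's scale, roll, translation (and optional skew)
#' to the subject's body-frame landmarks and emits a noise-free
#' [landmark_annotation()], including the transformed 2 cm reference
#' segment. With zero skew, [compute_panel()] on the result reproduces the
#' subject's ground truth exactly (up to floating point).
#'
#' @param subject A [make_subject()] template.
#' @param photo A [photo_model()].
#' @param lifted If `TRUE`, render the breasts-lifted pose: the relaxed
#'   photo of a ptotic subject omits IMFA/UPA, the lifted one exposes them.
#' @return A [landmark_annotation()].
#' @export
photograph <- function(subject, photo = photo_model(), lifted = FALSE) {
  stopifnot(inherits(subject, "subject_template"),
            inherits(photo, "photo_model"))
  lms <- subject$landmarks_cm
  if (subject$ptosis && !lifted) {
    lms <- lms[setdiff(names(lms), c("IMFA_R", "IMFA_L", "UPA_R", "UPA_L"))]
  }
  pts <- lapply(lms, function(xy) {
    p <- project_point(xy, photo)
    pixel_point(p[1], p[2], photo$photo_id)
  })
  ra <- project_point(photo$reference_cm[1, ], photo)
  rb <- project_point(photo$reference_cm[2, ], photo)
  ref_len <- sqrt(sum((photo$reference_cm[1, ] - photo$reference_cm[2, ])^2))
  landmark_annotation(
    photo$photo_id,
    calibration_segment(pixel_point(ra[1], ra[2], photo$photo_id),
                        pixel_point(rb[1], rb[2], photo$photo_id),
                        known_length_cm = ref_len),
    pts)
}

#' Photograph a subject with an optional lifted secondary photo
#'
#' For ptotic subjects, produces the primary (relaxed) annotation with the
#' lifted secondary photo attached, ready for the two-photo measurement
#' path. Non-ptotic subjects get a single-photo annotation.
#'
#' @param subject A [make_subject()] template.
#' @param primary_photo,secondary_photo [photo_model()]s for the two frames
#'   (the secondary defaults to a differently framed shot).
#' @return A [landmark_annotation()], with `secondary` attached when the
#'   subject is ptotic.
#' @export
photograph_subject <- function(subject, primary_photo = photo_model(),
                               secondary_photo = photo_model(
                                 pixels_per_cm = primary_photo$pixels_per_cm,
                                 roll_deg = primary_photo$roll_deg + 4,
                                 translation_px = primary_photo$translation_px +
                                   c(60, -40),
                                 photo_id = "photo2")) {
  ann <- photograph(subject, primary_photo)
  if (!subject$ptosis) return(ann)
  sec <- photograph(subject, secondary_photo, lifted = TRUE)
  landmark_annotation(ann$photo_id, ann$calibration, ann$landmarks,
                      secondary = sec)
}

#' Ground-truth measurement panel of a synthetic subject
#'
#' Computed directly in the body frame (identity photograph at 1 px/cm, no
#' noise), so values are exact by construction.
#'
#' @param subject A [make_subject()] template.
#' @return A `measurement_panel` of the true values in cm.
#' @export
true_panel <- function(subject) {
  stopifnot(inherits(subject, "subject_template"))
  relaxed <- subject
  relaxed$ptosis <- FALSE   # the body frame always shows every landmark
  compute_panel(photograph(
    relaxed,
    photo_model(pixels_per_cm = 1, roll_deg = 0, translation_px = c(0, 0),
                photo_id = "body")))
}

#' Observer marking-noise model
#'
#' Each observer has a per-landmark systematic bias (drawn once per
#' observer, SD `bias_sd_px` per axis) plus independent isotropic Gaussian
#' session jitter (SD `jitter_sd_px` per axis) on every click. The
#' calibration endpoints are clicked too, so they receive the same noise
#' and calibration error propagates realistically.
#'
#' @param jitter_sd_px Per-axis jitter SD in pixels (default 2).
#' @param bias_sd_px Per-axis SD of the observer's systematic bias (default 1).
#' @param seed Observer seed; the bias field is deterministic in it.
#' @return Object of class `observer_model`.
#' @export
observer_model <- function(jitter_sd_px = 2, bias_sd_px = 1, seed = 1) {
  if (jitter_sd_px < 0 || bias_sd_px < 0) {
    stop("noise SDs must be non-negative", call. = FALSE)
  }
  bias_names <- c(landmark_vocabulary(), "CAL_A", "CAL_B")
  bias <- with_seed(derive_seed(seed, 202), {
    b <- lapply(bias_names, function(nm) stats::rnorm(2, 0, bias_sd_px))
    names(b) <- bias_names
    b
  })
  structure(list(jitter_sd_px = jitter_sd_px, bias_px = bias, seed = seed),
            class = "observer_model")
}

perturb_point <- function(p, bias, sd) {
  pixel_point(p$x + bias[1] + stats::rnorm(1, 0, sd),
              p$y + bias[2] + stats::rnorm(1, 0, sd),
              p$photo_id)
}

#' Simulate one observer's marking of an annotation
#'
#' Adds the observer's systematic bias plus session jitter to every
#' landmark and to the calibration endpoints (of the secondary photo too,
#' if present). Deterministic for a fixed (observer seed, session seed)
#' pair.
#'
#' @param annotation A noise-free [landmark_annotation()].
#' @param observer An [observer_model()].
#' @param session_seed Integer distinguishing marking sessions.
#' @return A perturbed [landmark_annotation()].
#' @export
perturb <- function(annotation, observer, session_seed = 1) {
  stopifnot(inherits(annotation, "landmark_annotation"),
            inherits(observer, "observer_model"))
  jitter_one <- function(ann, salt) {
    with_seed(derive_seed(observer$seed, session_seed, salt), {
      lms <- ann$landmarks
      for (nm in names(lms)) {
        lms[[nm]] <- perturb_point(lms[[nm]], observer$bias_px[[nm]],
                                   observer$jitter_sd_px)
      }
      cal <- calibration_segment(
        perturb_point(ann$calibration$endpoint_a, observer$bias_px$CAL_A,
                      observer$jitter_sd_px),
        perturb_point(ann$calibration$endpoint_b, observer$bias_px$CAL_B,
                      observer$jitter_sd_px),
        ann$calibration$known_length_cm)
      list(landmarks = lms, calibration = cal)
    })
  }
  pri <- jitter_one(annotation, 1)
  sec <- NULL
  if (!is.null(annotation$secondary)) {
    s <- jitter_one(annotation$secondary, 2)
    sec <- landmark_annotation(annotation$secondary$photo_id, s$calibration,
                               s$landmarks)
  }
  landmark_annotation(annotation$photo_id, pri$calibration, pri$landmarks,
                      secondary = sec, subject_id = annotation$subject_id,
                      sex_type = annotation$sex_type)
}

#' Simulate a full repeated-measures validation study
#'
#' Replays the validation design: `n_subjects` synthetic subjects, each
#' photographed once, then marked independently by `n_observers` observers
#' in `n_sessions` sessions; every marking is pushed through
#' [compute_panel()] into a long-format table ready for the reliability
#' battery. References emulate direct anthropometry: the ground-truth
#' panels, optionally perturbed by a tape-measure noise SD.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_observers,n_sessions Study design (defaults 2 and 3).
#' @param preset Sex-type preset passed to [make_subject()].
#' @param ptosis_rate Share of subjects rendered ptotic (two-photo path);
#'   default 0.
#' @param variation_cm Between-subject anatomical SD in cm (default 1).
#' @param jitter_sd_px,bias_sd_px Observer noise, see [observer_model()].
#' @param reference_noise_sd_cm SD of tape-measure noise on the references
#'   (default 0 = references are exact ground truth).
#' @param photo A [photo_model()] shared by all subjects.
#' @param master_seed Master seed; all randomness derives from it.
#' @return A [repeated_measures_table()] whose `measurements` hold
#'   `n_subjects * n_observers * n_sessions * 13` rows for fully annotated
#'   subjects and whose `references` hold the ground truth.
#' @export
batch_study <- function(n_subjects = 10, n_observers = 2, n_sessions = 3,
                        preset = "female", ptosis_rate = 0, variation_cm = 1,
                        jitter_sd_px = 2, bias_sd_px = 1,
                        reference_noise_sd_cm = 0,
                        photo = photo_model(), master_seed = 1) {
  if (n_subjects < 2) stop("need at least 2 subjects", call. = FALSE)
  if (n_observers < 1 || n_sessions < 1) {
    stop("need at least 1 observer and 1 session", call. = FALSE)
  }
  observers <- lapply(seq_len(n_observers), function(o) {
    observer_model(jitter_sd_px, bias_sd_px, seed = derive_seed(master_seed, 3, o))
  })
  ptotic <- with_seed(derive_seed(master_seed, 4), {
    stats::runif(n_subjects) < ptosis_rate
  })
  meas <- list(); refs <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%03d", s)
    subj <- make_subject(preset, ptosis = ptotic[s],
                         variation_cm = variation_cm,
                         seed = derive_seed(master_seed, 5, s))
    ann <- photograph_subject(subj, photo)
    truth <- true_panel(subj)
    ref_val <- truth$value_cm
    if (reference_noise_sd_cm > 0) {
      ref_val <- ref_val + with_seed(derive_seed(master_seed, 6, s), {
        stats::rnorm(length(ref_val), 0, reference_noise_sd_cm)
      })
    }
    refs[[sid]] <- data.frame(subject_id = sid,
                              measurement = truth$measurement,
                              reference_cm = ref_val,
                              stringsAsFactors = FALSE)
    for (o in seq_len(n_observers)) {
      for (ses in seq_len(n_sessions)) {
        marked <- perturb(ann, observers[[o]],
                          session_seed = derive_seed(master_seed, 7, s, ses))
        panel <- compute_panel(marked)
        meas[[paste(sid, o, ses)]] <- data.frame(
          subject_id = sid, observer_id = sprintf("Obs%d", o),
          session = ses, measurement = panel$measurement,
          value_cm = panel$value_cm, stringsAsFactors = FALSE)
      }
    }
  }
  repeated_measures_table(
    do.call(rbind, c(meas, list(make.row.names = FALSE))),
    do.call(rbind, c(refs, list(make.row.names = FALSE))))
}
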