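# Shared fixtures and independent oracles for the test suite.

# Apply a similarity motion (rotation deg, isotropic scale, pixel shift) to
# every pixel coordinate of an annotation, calibration included. Used to
# assert invariance of cm-valued outputs: rigid motion keeps the calibration
# consistent automatically, and rescaling keeps it consistent because the
# reference segment is rescaled with everything else.
move_annotation <- function(ann, angle_deg = 0, scale = 1, shift = c(0, 0)) {
  th <- angle_deg * pi / 180
  mv <- function(p) {
    x <- scale * (cos(th) * p$x - sin(th) * p$y) + shift[1]
    y <- scale * (sin(th) * p$x + cos(th) * p$y) + shift[2]
    pixel_point(x, y, p$photo_id)
  }
  sec <- if (!is.null(ann$secondary)) {
    move_annotation(ann$secondary, angle_deg, scale, shift)
  }
  landmark_annotation(
    ann$photo_id,
    calibration_segment(mv(ann$calibration$endpoint_a),
                        mv(ann$calibration$endpoint_b),
                        ann$calibration$known_length_cm),
    lapply(ann$landmarks, mv),
    secondary = sec)
}

# A minimal hand-built annotation on a vertical midline: 10 px/cm, torso
# drawn directly in pixel space so every expected value is hand arithmetic.
vertical_annotation <- function(photo_id = "photo1") {
  pt <- function(x, y) pixel_point(x, y, photo_id)
  landmark_annotation(
    photo_id,
    calibration_segment(pt(200, 10), pt(220, 10), known_length_cm = 2),
    list(SN = pt(0, 0), UMB = pt(0, 250),
         N_R = pt(-95, 170), N_L = pt(95, 170),
         IMFA_R = pt(-75, 210), IMFA_L = pt(75, 210),
         UPA_R = pt(-80, 70), UPA_L = pt(80, 70)))
}

# Frozen independent oracle (two-way ANOVA ICC computed with pingouin
# 0.6.1, an implementation unrelated to this package) for this fixed
# 5 subjects x 3 raters matrix.
oracle_icc_matrix <- function() {
  matrix(c(9.1, 9.4, 9.0,
           11.2, 11.0, 11.5,
           10.0, 10.2, 9.8,
           12.3, 12.5, 12.9,
           8.7, 8.5, 8.4), nrow = 5, byrow = TRUE)
}
oracle_icc_expected <- list(
  icc21 = 0.9801806322, icc31 = 0.9758960909,
  ci21 = c(0.91, 1.00), ci31 = c(0.89, 1.00),
  msr = 7.878333333333342, msc = 0.006, mse = 0.06433333333332988)
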