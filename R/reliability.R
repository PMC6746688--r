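#' Validate a long-format repeated-measures table
#'
#' The validation battery consumes long-format records of digital
#' measurements -- columns `subject_id`, `observer_id`, `session`,
#' `measurement`, `value_cm` -- plus optional reference records from direct
#' anthropometry -- columns `subject_id`, `measurement`, `reference_cm`.
#' Keys (subject, observer, session, measurement) must be unique and values
#' finite; any ICC needs at least two subjects.
#'
#' @param measurements Data frame of digital measurement records.
#' @param references Optional data frame of direct-measurement references.
#' @return A list of class `repeated_measures_table` with elements
#'   `measurements` and `references`.
#' @export
repeated_measures_table <- function(measurements, references = NULL) {
  need <- c("subject_id", "observer_id", "session", "measurement", "value_cm")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) {
    stop(sprintf("measurements table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!all(is.finite(measurements$value_cm))) {
    stop("non-finite value_cm in measurements table", call. = FALSE)
  }
  key <- with(measurements,
              paste(subject_id, observer_id, session, measurement, sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate (subject, observer, session, measurement) keys",
         call. = FALSE)
  }
  if (!is.null(references)) {
    rneed <- c("subject_id", "measurement", "reference_cm")
    rmiss <- setdiff(rneed, names(references))
    if (length(rmiss)) {
      stop(sprintf("references table lacks column(s): %s",
                   paste(rmiss, collapse = ", ")), call. = FALSE)
    }
    if (!all(is.finite(references$reference_cm))) {
      stop("non-finite reference_cm in references table", call. = FALSE)
    }
  }
  structure(list(measurements = measurements, references = references),
            class = "repeated_measures_table")
}

as_rm_table <- function(x) {
  if (inherits(x, "repeated_measures_table")) x
  else repeated_measures_table(x)
}

#' Accuracy summary: mean absolute difference against direct references
#'
#' For each (measurement, observer), forms the signed differences
#' d = digital value - direct reference over all (subject, session) records
#' and reports `mad_cm = mean(|d|)` with `sd_cm` the sample standard
#' deviation of the signed differences (the default; set
#' `sd_of = "absolute"` for the SD of |d| instead -- the published summary
#' tables are ambiguous on this point and the signed reading is the only
#' internally consistent one).
#'
#' @param table A [repeated_measures_table()] (references required).
#' @param sd_of `"signed"` (default) or `"absolute"`.
#' @return Data frame with columns `measurement`, `observer_id`, `mad_cm`,
#'   `sd_cm`, `n`.
#' @export
accuracy_summary <- function(table, sd_of = c("signed", "absolute")) {
  sd_of <- match.arg(sd_of)
  table <- as_rm_table(table)
  if (is.null(table$references)) {
    stop("accuracy_summary needs direct-measurement references", call. = FALSE)
  }
  m <- table$measurements
  refs <- table$references
  i <- match(paste(m$subject_id, m$measurement, sep = "\r"),
             paste(refs$subject_id, refs$measurement, sep = "\r"))
  if (anyNA(i)) {
    bad <- m[is.na(i), c("subject_id", "measurement")][1, ]
    stop(sprintf("missing reference for subject '%s', measurement '%s'",
                 bad$subject_id, bad$measurement), call. = FALSE)
  }
  d <- m$value_cm - refs$reference_cm[i]
  grp <- interaction(m$measurement, m$observer_id, drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(split(seq_along(d), grp), function(idx) {
    di <- d[idx]
    data.frame(
      measurement = m$measurement[idx[1]],
      observer_id = m$observer_id[idx[1]],
      mad_cm = mean(abs(di)),
      sd_cm = if (length(di) > 1) {
        if (sd_of == "signed") stats::sd(di) else stats::sd(abs(di))
      } else 0,
      n = length(di), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Intraclass correlation coefficient with F-based 95% confidence interval
#'
#' Single-measurement ICC from the two-way ANOVA mean squares of a complete
#' subjects x raters (or subjects x sessions) design. Two forms:
#'
#' * `"two-way-random-absolute"` -- ICC(2,1), two-way random effects,
#'   absolute agreement: raters are a random sample and systematic rater
#'   offsets count as disagreement. The default, as clinical
#'   interchangeability requires absolute agreement. CI by the
#'   McGraw-Wong F bounds with a Satterthwaite denominator df.
#' * `"two-way-mixed-consistency"` -- ICC(3,1), two-way mixed effects,
#'   consistency: rater offsets are ignored. Exact F-based CI.
#'
#' @param x Numeric matrix (rows = subjects, columns = raters/sessions) or a
#'   long data frame with columns `subject_id`, a rater column named by
#'   `rater_col`, and `value_cm`.
#' @param model ICC form, see above.
#' @param conf_level Confidence level (default 0.95).
#' @param rater_col Column holding the repeated facet when `x` is long
#'   format (default `"session"`).
#' @return List of class `icc_result`: `icc`, `ci_low`, `ci_high`, `model`,
#'   `n_subjects`, `n_raters`, and the mean squares `msr`, `msc`, `mse`.
#' @export
icc <- function(x,
                model = c("two-way-random-absolute", "two-way-mixed-consistency"),
                conf_level = 0.95, rater_col = "session") {
  model <- match.arg(model)
  if (is.data.frame(x)) x <- long_to_matrix(x, rater_col)
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2) stop("ICC needs at least 2 subjects", call. = FALSE)
  if (k < 2) stop("ICC needs at least 2 raters/sessions", call. = FALSE)
  if (anyNA(x)) stop("incomplete design: missing cells", call. = FALSE)

  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  if (sst == 0) stop("degenerate data: zero total variance", call. = FALSE)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  # SSE is non-negative by construction; tiny negatives are floating point
  mse <- max(sse, 0) / ((n - 1) * (k - 1))
  alpha <- 1 - conf_level

  if (model == "two-way-random-absolute") {
    denom <- msr + (k - 1) * mse + k * (msc - mse) / n
    est <- if (denom == 0) 1 else (msr - mse) / denom
    # Satterthwaite df for the MSC/MSE mixture (McGraw & Wong 1996)
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    if (!is.finite(a) || !is.finite(b)) {        # est == 1 exactly
      lo <- hi <- 1
    } else {
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      fl <- stats::qf(1 - alpha / 2, n - 1, v)
      fu <- stats::qf(1 - alpha / 2, v, n - 1)
      lo <- n * (msr - fl * mse) /
        (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
      hi <- n * (fu * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * fu * msr)
    }
  } else {
    denom <- msr + (k - 1) * mse
    est <- if (denom == 0) 1 else (msr - mse) / denom
    if (mse == 0) {
      lo <- hi <- 1
    } else {
      fo <- msr / mse
      fl <- fo / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      fu <- fo * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      lo <- (fl - 1) / (fl + k - 1)
      hi <- (fu - 1) / (fu + k - 1)
    }
  }
  structure(
    list(icc = est, ci_low = min(lo, est), ci_high = max(hi, est),
         model = model, conf_level = conf_level,
         n_subjects = n, n_raters = k, msr = msr, msc = msc, mse = mse),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (%s, single): %.3f, %d%% CI %.3f-%.3f (n=%d, k=%d)\n",
              x$model, x$icc, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$n_subjects, x$n_raters))
  invisible(x)
}

#' Standard error of measurement
#'
#' `SEM = SD * sqrt(1 - ICC)`: the standard deviation of the measurement
#' errors, in the measurement's own units.
#'
#' @param sd_cm Standard deviation of the measurements (cm), non-negative.
#' @param icc Intraclass correlation coefficient, at most 1.
#' @return SEM in cm.
#' @examples
#' sem_cm(0.29, 0.944)  # 0.07 after 2-decimal rounding
#' @export
sem_cm <- function(sd_cm, icc) {
  if (any(!is.finite(sd_cm)) || any(sd_cm < 0)) {
    stop("sd_cm must be non-negative and finite", call. = FALSE)
  }
  if (any(!is.finite(icc)) || any(icc > 1)) {
    stop("icc must be finite and at most 1", call. = FALSE)
  }
  sd_cm * sqrt(1 - icc)
}

#' Coefficient of variation of repeated measurements, in percent
#'
#' Per subject, `CV = 100 * sd / mean` over that subject's repeated values;
#' the reported figure is the mean of the per-subject CVs (default) or the
#' pooled root-mean-square CV (`aggregate = "pooled"`).
#'
#' @param x Numeric matrix (rows = subjects, columns = repeats) or a long
#'   data frame with columns `subject_id` and `value_cm`.
#' @param aggregate `"mean"` (default) or `"pooled"`.
#' @return CV in percent.
#' @export
cv_percent <- function(x, aggregate = c("mean", "pooled")) {
  aggregate <- match.arg(aggregate)
  vals <- if (is.data.frame(x)) split(x$value_cm, x$subject_id)
          else split(as.matrix(x), row(as.matrix(x)))
  per <- vapply(seq_along(vals), function(i) {
    v <- vals[[i]]
    m <- mean(v)
    if (m == 0) {
      stop(sprintf("zero mean for subject '%s': CV undefined",
                   names(vals)[i] %||% i), call. = FALSE)
    }
    100 * stats::sd(v) / m
  }, numeric(1))
  if (aggregate == "mean") mean(per) else sqrt(mean(per^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bland-Altman agreement analysis
#'
#' Juxtaposes paired differences (digital minus reference) against pair
#' means; the bias is the mean difference and the limits of agreement are
#' bias +/- 1.96 times the SD of the differences.
#'
#' @param reference Numeric vector of reference (direct) values.
#' @param digital Numeric vector of digital values (same length, >= 2).
#' @return List of class `bland_altman`: `data` (a data frame of `mean` and
#'   `difference` per pair), `bias`, `sd_diff`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(reference, digital) {
  if (length(reference) != length(digital)) {
    stop("reference and digital vectors differ in length", call. = FALSE)
  }
  if (length(reference) < 2) {
    stop("Bland-Altman needs at least 2 pairs", call. = FALSE)
  }
  d <- digital - reference
  m <- (digital + reference) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  structure(
    list(data = data.frame(mean = m, difference = d),
         bias = bias, sd_diff = s,
         loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f, LoA [%.3f, %.3f] (n=%d)\n",
              x$bias, x$loa_low, x$loa_high, nrow(x$data)))
  invisible(x)
}

#' Effectiveness: share of measurements with satisfactory accuracy
#'
#' Proportion (in percent) of mean-absolute-difference values strictly below
#' the accepted deviation threshold for the thoracic region (1 cm).
#'
#' @param mads Numeric vector of MAD values in cm (non-empty).
#' @param threshold_cm Acceptance threshold (default 1).
#' @return Percentage in \[0, 100\].
#' @export
effectiveness <- function(mads, threshold_cm = 1) {
  if (length(mads) == 0) stop("empty MAD list", call. = FALSE)
  if (threshold_cm <= 0) stop("threshold must be positive", call. = FALSE)
  100 * sum(mads < threshold_cm) / length(mads)
}

#' Interpret an ICC value
#'
#' Two published interpretation scales: Cicchetti's bands (poor < 0.40,
#' fair 0.40-0.59, good 0.60-0.74, excellent 0.75-1.00) and a clinically
#' oriented scale (poor-to-moderate < 0.75, good 0.75-0.87, above 0.87
#' high enough to be regarded as a clinical measure). Band edges are
#' inclusive on the lower edge of each stated range.
#'
#' @param icc ICC value in \[-1, 1\].
#' @return List with `cicchetti` and `clinical` labels.
#' @export
classify_icc <- function(icc) {
  if (!is.finite(icc) || icc < -1 || icc > 1) {
    stop("icc must lie in [-1, 1]", call. = FALSE)
  }
  cic <- if (icc < 0.40) "poor" else if (icc < 0.60) "fair"
         else if (icc < 0.75) "good" else "excellent"
  cli <- if (icc < 0.75) "poor-to-moderate" else if (icc < 0.87) "good"
         else "clinical"
  list(cicchetti = cic, clinical = cli)
}

#' Sample variance of a set of ICC values
#'
#' Used to compare the spread of reliability across measurement sets (e.g.
#' female vs male panels); plain sample variance with denominator n - 1.
#'
#' @param iccs Numeric vector of at least two ICC values.
#' @return Sample variance.
#' @export
icc_variance <- function(iccs) {
  if (length(iccs) < 2) stop("need at least 2 ICC values", call. = FALSE)
  stats::var(iccs)
}

# subjects x facet matrix from long records; unique keys enforced upstream
long_to_matrix <- function(df, facet_col) {
  tapply(df$value_cm,
         list(as.character(df$subject_id), as.character(df[[facet_col]])),
         mean)
}

#' Full validation summary in the published table layout
#'
#' Reproduces the layout of a three-session, two-observer validation study:
#'
#' * `per_observer` -- one row per (measurement, observer): accuracy (MAD
#'   and SD against direct references, if supplied) and precision (ICC
#'   across sessions with 95% CI, and SEM from that SD and ICC).
#' * `inter_rater` -- one row per measurement: CV across all repeated
#'   values, and inter-rater ICC (95% CI, SEM) computed on the subjects x
#'   observers matrix of session-averaged values.
#'
#' @param table A [repeated_measures_table()] (or bare measurements data
#'   frame; accuracy columns then absent).
#' @param model ICC form passed to [icc()].
#' @param round_output Round cm to 2 decimals, ICC to 3, CV to 1 (the
#'   published format). Default `FALSE` (full precision).
#' @return List of class `agreement_summary` with data frames
#'   `per_observer` and `inter_rater`.
#' @export
summary_tables <- function(table,
                           model = "two-way-random-absolute",
                           round_output = FALSE) {
  table <- as_rm_table(table)
  m <- table$measurements
  acc <- if (!is.null(table$references)) accuracy_summary(table) else NULL

  per_obs <- list()
  for (meas in unique(m$measurement)) {
    for (obs in unique(m$observer_id)) {
      slice <- m[m$measurement == meas & m$observer_id == obs, ]
      mat <- long_to_matrix(slice, "session")
      fit <- icc(mat, model = model)
      sdv <- stats::sd(as.vector(mat))
      row <- data.frame(
        measurement = meas, observer_id = obs,
        icc = fit$icc, ci_low = fit$ci_low, ci_high = fit$ci_high,
        sd_cm = sdv, sem_cm = sem_cm(sdv, fit$icc),
        stringsAsFactors = FALSE)
      if (!is.null(acc)) {
        ai <- acc[acc$measurement == meas & acc$observer_id == obs, ]
        row$mad_cm <- ai$mad_cm
        row$mad_sd_cm <- ai$sd_cm
      }
      per_obs[[paste(meas, obs)]] <- row
    }
  }
  per_obs <- do.call(rbind, c(per_obs, list(make.row.names = FALSE)))

  inter <- list()
  for (meas in unique(m$measurement)) {
    slice <- m[m$measurement == meas, ]
    # session-averaged value per subject x observer
    agg <- stats::aggregate(value_cm ~ subject_id + observer_id, data = slice,
                            FUN = mean)
    mat <- long_to_matrix(agg, "observer_id")
    fit <- icc(mat, model = model)
    sdv <- stats::sd(as.vector(mat))
    inter[[meas]] <- data.frame(
      measurement = meas,
      cv_percent = cv_percent(slice),
      icc = fit$icc, ci_low = fit$ci_low, ci_high = fit$ci_high,
      sem_cm = sem_cm(sdv, fit$icc),
      stringsAsFactors = FALSE)
  }
  inter <- do.call(rbind, c(inter, list(make.row.names = FALSE)))

  if (round_output) {
    for (col in c("sd_cm", "sem_cm", "mad_cm", "mad_sd_cm")) {
      if (col %in% names(per_obs)) per_obs[[col]] <- round(per_obs[[col]], 2)
    }
    for (col in c("icc", "ci_low", "ci_high")) {
      per_obs[[col]] <- round(per_obs[[col]], 3)
      inter[[col]] <- round(inter[[col]], 3)
    }
    inter$sem_cm <- round(inter$sem_cm, 2)
    inter$cv_percent <- round(inter$cv_percent, 1)
  }
  structure(list(per_observer = per_obs, inter_rater = inter),
            class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat("Per-observer accuracy and precision:\n")
  print(x$per_observer, row.names = FALSE, digits = 4)
  cat("\nInter-rater reliability:\n")
  print(x$inter_rater, row.names = FALSE, digits = 4)
  invisible(x)
}
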