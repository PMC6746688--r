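#' Published validation summaries of the original tool
#'
#' The clinical validation study of the original web-based implementation
#' of this measurement protocol (10 female and 10 male subjects, direct
#' tape-measure references, two observers, three weekly sessions) published
#' per-observer accuracy/precision summaries and an inter-rater reliability
#' summary. Those printed values are shipped with the package as a
#' plain-text CSV and serve as numeric anchors for the statistics battery
#' (SEM recomputation, ICC-variance and CV summaries).
#'
#' @param table `"per_observer"` (accuracy MAD/SD plus within-observer ICC,
#'   CI and SEM, by sex group and observer) or `"inter_rater"` (CV,
#'   between-observer ICC, CI and SEM by sex group).
#' @return Data frame of the requested published table.
#' @export
published_validation_tables <- function(table = c("per_observer",
                                                  "inter_rater")) {
  table <- match.arg(table)
  path <- system.file("extdata", "published_validation_tables.csv",
                      package = "photanthro", mustWork = TRUE)
  all <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- all[all$table == table, setdiff(names(all), "table")]
  if (table == "inter_rater") {
    out <- out[, setdiff(names(out), c("observer", "mad_cm", "sd_cm"))]
  } else {
    out <- out[, setdiff(names(out), "cv_percent")]
  }
  rownames(out) <- NULL
  out
}
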