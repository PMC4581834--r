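#' Write carrier predictions to TSV or JSON
#'
#' Writes the per-haplotype table of a [predict_carriers()] result
#' (`sample_id`, `score`, `percentile`, `posterior_carrier`, `label`, and
#' `carrier_truth` when present), preceded by `#`-comment header lines
#' recording `ell` and the mixture parameters. JSON output mirrors the TSV
#' with an explicit `evaluation` block.
#'
#' @param prediction A `precioss` tibble from [predict_carriers()].
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param evaluation Optional one-row tibble from [evaluate_prediction()],
#'   appended to the header / JSON.
#' @return `path`, invisibly.
#' @export
write_scores <- function(prediction, path, format = c("tsv", "json"),
                         evaluation = NULL) {
  format <- match.arg(format)
  fit <- attr(prediction, "fit")
  meta <- list(ell = attr(prediction, "ell"),
               low_confidence = isTRUE(attr(prediction, "low_confidence")))
  if (!is.null(fit)) {
    meta$component_means <- fit$means
    meta$component_sds <- sqrt(fit$variances)
    meta$weights <- fit$weights
  }
  df <- as.data.frame(prediction)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ell=", meta$ell,
                      " low_confidence=", meta$low_confidence), con)
    if (!is.null(fit)) {
      writeLines(sprintf("# means=%.6g,%.6g sds=%.6g,%.6g weights=%.4f,%.4f",
                         fit$means[1], fit$means[2],
                         sqrt(fit$variances[1]), sqrt(fit$variances[2]),
                         fit$weights[1], fit$weights[2]), con)
    }
    if (!is.null(evaluation)) {
      writeLines(sprintf("# balanced_accuracy=%.4f wilcoxon_p=%.4g",
                         evaluation$balanced_accuracy,
                         evaluation$wilcoxon_p), con)
    }
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    payload <- list(meta = meta, haplotypes = df)
    if (!is.null(evaluation)) payload$evaluation <- as.list(evaluation)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read back a JSON score file
#'
#' @param path Path written by [write_scores()] with `format = "json"`.
#' @return A list with `meta`, `haplotypes` (tibble) and optionally
#'   `evaluation`.
#' @export
read_scores_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$haplotypes <- tibble::as_tibble(x$haplotypes)
  x
}
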