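#' Published STAMPEDE comparison p-values
#'
#' The seven reported (multiplicity-unadjusted) one-sided p-values from
#' the STAMPEDE prostate-cancer platform trial, comparing experimental
#' arms B-H against the standard-of-care control arm A, in reporting
#' order with the trial's four reporting batches: \{B, C, E\}, \{D, F\},
#' \{G\}, \{H\}.
#'
#' @return a \code{\link{pvalue_stream}} of 7 records: arm label,
#'   p-value, batch.
#' @examples
#' stampede_pvalues()
#' @export
stampede_pvalues <- function() {
  pvalue_stream(
    p = c(0.450, 0.006, 0.022, 0.847, 0.130, 0.001, 0.266),
    id = c("B", "C", "E", "D", "F", "G", "H"),
    batch = c(1L, 1L, 1L, 2L, 2L, 3L, 4L)
  )
}

#' Re-analysis of the STAMPEDE p-values under online error control
#'
#' Applies a set of procedures to the seven STAMPEDE p-values at several
#' overall levels \eqn{\alpha}, reporting for each the rejected arms and
#' the testing level \eqn{\alpha_8} that would apply to the next (8th)
#' experimental arm. Fully online procedures consume the stream in
#' reporting order, ignoring batches; batched procedures use the 4-batch
#' structure; offline BH/Storey-BH/Holm see all seven p-values at once
#' (and have no meaningful next-arm level, reported as \code{NA}).
#'
#' @param alphas overall levels to evaluate (default 0.025, 0.05, 0.1).
#' @param Nbound assumed bound on the number of arms (default 20).
#' @param which procedure names (see \code{\link{procedure_set}}).
#' @param stream the p-value stream (default
#'   \code{\link{stampede_pvalues}}; override to run the sensitivity
#'   analysis with a permuted first batch).
#' @param digits decimal places for the reported \code{alpha_next}
#'   (rounded half up, as levels are conventionally printed); \code{NULL}
#'   for no rounding.
#' @param ... hyperparameter overrides for \code{\link{procedure_set}}.
#' @return data frame: \code{procedure}, \code{alpha}, \code{rejected}
#'   (comma-separated arm labels), \code{n_rejected}, \code{alpha_next}.
#' @examples
#' reproduce_case_study(which = c("uncorrected", "bonferroni", "lond"))
#' @export
reproduce_case_study <- function(alphas = c(0.025, 0.05, 0.1), Nbound = 20,
                                 which = c("uncorrected", "bonferroni",
                                           "addis-spending", "bh", "addis",
                                           "saffron", "lord", "lond",
                                           "batch-bh", "batch-prds",
                                           "batch-stbh"),
                                 stream = stampede_pvalues(), digits = 4,
                                 ...) {
  out <- list()
  for (a in alphas) {
    procs <- procedure_set(a, Nbound, which = which, ...)
    for (nm in names(procs)) {
      dec <- procs[[nm]](stream)
      an <- attr(dec, "alpha_next")
      if (!is.null(digits) && !is.na(an)) an <- round_half_up(an, digits)
      out[[length(out) + 1L]] <- data.frame(
        procedure = nm, alpha = a,
        rejected = paste(rejected_ids(dec), collapse = ", "),
        n_rejected = sum(dec$rejected),
        alpha_next = an
      )
    }
  }
  res <- do.call(rbind, out)
  res[order(match(res$procedure, which), res$alpha), , drop = FALSE]
}
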