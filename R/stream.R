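#' P-value streams and test decisions
#'
#' Online procedures consume an ordered stream of hypotheses. A stream is
#' a data frame with columns \code{p} (the one-sided p-values in testing
#' order), \code{id} (hypothesis labels) and \code{batch} (positive
#' integers, non-decreasing, grouping hypotheses that become available
#' together). \code{pvalue_stream} builds one from vectors; bare numeric
#' vectors are accepted by every procedure and coerced (one hypothesis per
#' batch).
#'
#' @param p numeric vector of p-values in testing order.
#' @param id optional labels (default \code{"H1"}, \code{"H2"}, ...).
#' @param batch optional non-decreasing batch labels (default
#'   \code{1:length(p)}).
#' @return data frame with columns \code{id}, \code{p}, \code{batch}.
#' @examples
#' pvalue_stream(c(0.01, 0.2), id = c("A", "B"))
#' @export
pvalue_stream <- function(p, id = NULL, batch = NULL) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1))
  if (is.null(id)) {
    id <- if (length(p)) paste0("H", seq_along(p)) else character(0)
  }
  if (is.null(batch)) batch <- seq_along(p)
  batch <- match(batch, unique(batch))  # normalize to 1,2,...
  if (is.unsorted(batch)) stop("batch labels must be non-decreasing along the stream")
  data.frame(id = as.character(id), p = as.numeric(p),
             batch = as.integer(batch))
}

as_pstream <- function(stream) {
  if (is.numeric(stream)) return(pvalue_stream(stream))
  stopifnot(is.data.frame(stream), "p" %in% names(stream))
  pvalue_stream(stream$p,
                id = if ("id" %in% names(stream)) stream$id,
                batch = if ("batch" %in% names(stream)) stream$batch)
}

# Assemble the uniform decision record: one row per hypothesis with its
# testing level, decision (weak inequality p <= alpha_i), and the level
# that would apply to the next hypothesis as attribute "alpha_next".
make_decisions <- function(stream, alphai, alpha_next = NA_real_,
                           rejected = stream$p <= alphai) {
  stopifnot(length(alphai) == nrow(stream), all(alphai >= 0 & alphai <= 1))
  out <- data.frame(i = seq_len(nrow(stream)), id = stream$id,
                    batch = stream$batch, p = stream$p,
                    alphai = alphai, rejected = rejected)
  attr(out, "alpha_next") <- alpha_next
  class(out) <- c("otl_decisions", "data.frame")
  out
}

#' @export
print.otl_decisions <- function(x, ...) {
  cat("Online testing decisions (", sum(x$rejected), " rejection",
      if (sum(x$rejected) != 1) "s", " of ", nrow(x), ")\n", sep = "")
  print.data.frame(x, ...)
  an <- attr(x, "alpha_next")
  if (!is.na(an)) cat("next testing level:", format(an), "\n")
  invisible(x)
}

#' Rejected hypothesis labels
#' @param decisions a decision record from any \code{run_*} procedure.
#' @return character vector of rejected \code{id}s, in stream order.
#' @export
rejected_ids <- function(decisions) decisions$id[decisions$rejected]
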