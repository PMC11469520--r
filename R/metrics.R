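#' Confusion counts from a screening run
#'
#' @param tp,fp,fn,tn Non-negative integer counts of matched actives, matched
#'   decoys, unmatched actives and unmatched decoys.
#' @return An object of class `screen_counts`.
#' @export
screen_counts <- function(tp, fp, fn, tn) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 n_total = as.integer(tp + fp + fn + tn),
                 n_active = as.integer(tp + fn)),
            class = "screen_counts")
}

#' @export
print.screen_counts <- function(x, ...) {
  cat("<screen_counts> tp=", x$tp, " fp=", x$fp, " fn=", x$fn, " tn=", x$tn,
      " (", x$n_active, "/", x$n_total, " active)\n", sep = "")
  invisible(x)
}

#' Screening metrics from confusion counts
#'
#' Precision, recall and F1 use the usual definitions, with 0/0 defined as 0
#' so that a pharmacophore retrieving nothing earns a zero reward rather than
#' an error. The enrichment factor is precision divided by the library's
#' active fraction (EF > 1 beats random retrieval). When `max_reference_f1`
#' is supplied (the best F1 achievable from reference ligand features), the
#' normalized F1 `f1 / max_reference_f1` is reported as well.
#'
#' @param counts A [screen_counts()] object.
#' @param max_reference_f1 Optional positive reference F1 for normalization.
#' @return A one-row tibble of class `screen_metrics` with columns
#'   `precision`, `recall`, `f1`, `enrichment_factor`, `normalized_f1`.
#' @export
compute_metrics <- function(counts, max_reference_f1 = NULL) {
  stopifnot(inherits(counts, "screen_counts"))
  prec <- if (counts$tp + counts$fp > 0) counts$tp / (counts$tp + counts$fp) else 0
  rec <- if (counts$n_active > 0) counts$tp / counts$n_active else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  ef <- if (counts$n_active > 0 && counts$n_total > 0) {
    prec / (counts$n_active / counts$n_total)
  } else 0
  nf1 <- NA_real_
  if (!is.null(max_reference_f1)) {
    if (max_reference_f1 == 0) stop("max_reference_f1 = 0: normalization undefined")
    nf1 <- f1 / max_reference_f1
  }
  out <- tibble::tibble(precision = prec, recall = rec, f1 = f1,
                        enrichment_factor = ef, normalized_f1 = nf1)
  class(out) <- c("screen_metrics", class(out))
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.screen_result <- function(x, ...) {
  x$per_molecule
}

#' @export
glance.screen_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(tp = x$counts$tp, fp = x$counts$fp,
                   fn = x$counts$fn, tn = x$counts$tn),
    tibble::as_tibble(x$metrics)
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> ", x$counts$n_total, " molecules, ",
      x$counts$n_active, " active\n", sep = "")
  cat(sprintf("  precision %.3f  recall %.3f  F1 %.3f  EF %.2f\n",
              x$metrics$precision, x$metrics$recall, x$metrics$f1,
              x$metrics$enrichment_factor))
  invisible(x)
}
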