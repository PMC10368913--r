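#' Confusion matrix from reference and mapped labels
#'
#' Entry (i, j) counts the reference points whose true class is i and
#' whose mapped class is j; points with `NA` in either vector (e.g.
#' falling on nodata under either raster) are dropped with a message.
#'
#' @param reference,mapped equal-length label vectors.
#' @param labels optional label alphabet fixing row/column order;
#'   defaults to the sorted union of both vectors.
#' @return square integer matrix, rows = reference, columns = mapped.
#' @examples
#' confusionMatrix(c(1, 1, 2, 2, 2, 1), c(1, 2, 2, 2, 1, 1))
#' @export
confusionMatrix <- function(reference, mapped, labels = NULL) {
  if (length(reference) != length(mapped))
    stop("reference and mapped must have equal length")
  keep <- !is.na(reference) & !is.na(mapped)
  if (sum(!keep))
    message(sum(!keep), " point(s) with missing labels dropped")
  reference <- reference[keep]; mapped <- mapped[keep]
  if (!length(reference)) stop("no valid points")
  if (is.null(labels)) labels <- sort(unique(c(reference, mapped)))
  cm <- table(factor(reference, levels = labels),
              factor(mapped, levels = labels))
  m <- matrix(as.integer(cm), nrow(cm), ncol(cm),
              dimnames = list(reference = labels, mapped = labels))
  m
}

.checkCM <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm))
    stop("confusion matrix must be square")
  if (any(cm < 0) || sum(cm) == 0)
    stop("confusion matrix must be non-negative with a positive total")
}

#' Overall accuracy
#'
#' Fraction of points on the diagonal of the confusion matrix:
#' \eqn{OA = \mathrm{trace}(C)/n}.
#' @param cm square confusion-count matrix.
#' @return fraction in [0, 1].
#' @export
overallAccuracy <- function(cm) {
  .checkCM(cm)
  sum(diag(cm)) / sum(cm)
}

#' Cohen's kappa coefficient
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' observed agreement \eqn{p_o = \mathrm{trace}(C)/n} and expected
#' agreement \eqn{p_e = \sum_i r_i c_i / n^2} from the marginals. The
#' degenerate case \eqn{p_e = 1} (all mass in a single class on both
#' sides) is an error, not a silent zero.
#'
#' @param cm square confusion-count matrix.
#' @return kappa, at most 1.
#' @export
kappaCoefficient <- function(cm) {
  .checkCM(cm)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-12)
    stop("kappa undefined: expected agreement is 1 (single-class matrix)")
  (po - pe) / (1 - pe)
}

#' Producer's and user's accuracy per class
#'
#' Producer's accuracy is the diagonal over the reference-row total
#' (omission view); user's accuracy is the diagonal over the mapped-
#' column total (commission view). Classes with an empty marginal get
#' `NA`, never a fake 0.
#'
#' @param cm square confusion-count matrix.
#' @return data.frame with columns `class`, `producers`, `users`.
#' @export
perClassAccuracy <- function(cm) {
  .checkCM(cm)
  rs <- rowSums(cm); cs <- colSums(cm); d <- diag(cm)
  data.frame(
    class = if (!is.null(rownames(cm))) rownames(cm)
            else as.character(seq_len(nrow(cm))),
    producers = ifelse(rs > 0, d / rs, NA_real_),
    users = ifelse(cs > 0, d / cs, NA_real_),
    row.names = NULL)
}

#' Accuracy assessment from a reference-point table
#'
#' Convenience wrapper chaining [confusionMatrix()] with the summary
#' metrics, as used to rank competing classified maps.
#'
#' @param points data.frame with `true_code` and `mapped_code` columns
#'   (the output of [generateReferencePoints()], or any point file with
#'   those columns).
#' @param useSplit if non-NULL, restrict to rows whose `split` column
#'   equals this tag (e.g. `"test"`).
#' @return list with `confusion`, `overall_accuracy`, `kappa`,
#'   `per_class`, `n`.
#' @export
assessAccuracy <- function(points, useSplit = NULL) {
  if (!is.null(useSplit)) points <- points[points$split == useSplit, ]
  cm <- confusionMatrix(points$true_code, points$mapped_code)
  list(confusion = cm,
       overall_accuracy = overallAccuracy(cm),
       kappa = kappaCoefficient(cm),
       per_class = perClassAccuracy(cm),
       n = sum(cm))
}
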