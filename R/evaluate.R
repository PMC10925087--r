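#' Precision, recall and F1 for somatic-site detection
#'
#' Compares predicted site labels to truth labels, treating the somatic class
#' as positive.
#'
#' Degenerate cases follow fixed conventions: with no somatic sites in the
#' truth and no somatic predictions, all three metrics are reported as 1
#' (nothing to find, nothing falsely found); with somatic truth sites but no
#' somatic predictions, precision is reported as 0 and F1 is 0.
#'
#' @param truth,pred equal-length vectors (character or factor) of site
#'   classes; any label other than \code{"somatic"} counts as negative.
#' @return A named list with \code{precision}, \code{recall}, \code{f1} and
#'   the confusion counts \code{tp}, \code{fp}, \code{fn}.
#' @examples
#' evaluateCalls(c("somatic", "somatic", "het", "somatic"),
#'               c("somatic", "somatic", "somatic", "reference"))
#' @export
evaluateCalls <- function(truth, pred) {
    if (length(truth) != length(pred))
        stop("'truth' and 'pred' must have equal length")
    t <- as.character(truth) == "somatic"
    p <- as.character(pred) == "somatic"
    .prf(sum(t & p), sum(!t & p), sum(t & !p))
}

## metrics from confusion counts, with the documented degenerate conventions
.prf <- function(tp, fp, fn) {
    if (tp + fn == 0L && tp + fp == 0L)
        return(list(precision = 1, recall = 1, f1 = 1, tp = tp, fp = fp, fn = fn))
    precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0L) tp / (tp + fn) else 1
    f1 <- if (tp == 0L) 0 else 2 * precision * recall / (precision + recall)
    list(precision = precision, recall = recall, f1 = f1,
         tp = tp, fp = fp, fn = fn)
}
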