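# Benchmarking predicted networks against a reference.
#
# Matching is on unordered gene pairs ("a matched link regardless of its
# direction"); the negative universe for ranking metrics is every unordered
# gene pair absent from the reference.

canonical_pairs <- function(edges) {
  if (!nrow(edges)) return(character())
  unique(paste(pmin(edges$gene_a, edges$gene_b),
               pmax(edges$gene_a, edges$gene_b), sep = "\r"))
}

#' Confusion counts with undirected matching
#'
#' Both edge sets are collapsed to unordered pairs (duplicates removed); a
#' predicted edge matching a reference edge in either direction counts as one
#' true positive.
#'
#' @param predicted,truth [edge_list()]s (or data frames with `gene_a`,
#'   `gene_b`).
#' @return named integer vector `c(TP, FP, FN)`.
#' @export
confusion_counts <- function(predicted, truth) {
  p <- canonical_pairs(predicted)
  t <- canonical_pairs(truth)
  c(TP = length(intersect(p, t)),
    FP = length(setdiff(p, t)),
    FN = length(setdiff(t, p)))
}

#' Precision, recall and F1 from confusion counts
#'
#' Zero denominators yield 0 with a warning.
#'
#' @param TP,FP,FN nonnegative counts. `TP` may also be the named vector
#'   returned by [confusion_counts()].
#' @return named numeric vector `c(precision, recall, f1)`.
#' @export
prf1 <- function(TP, FP = NULL, FN = NULL) {
  if (is.null(FP) && length(TP) == 3) {
    FP <- TP[["FP"]]; FN <- TP[["FN"]]; TP <- TP[["TP"]]
  }
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  precision <- if (TP + FP > 0) TP / (TP + FP) else {
    warning("prf1: no predicted positives; precision set to 0"); 0
  }
  recall <- if (TP + FN > 0) TP / (TP + FN) else {
    warning("prf1: no reference positives; recall set to 0"); 0
  }
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' AUROC and AUPR of a score matrix against a reference network
#'
#' All unordered gene pairs form the ranking universe; pairs present in the
#' reference are positives, every other pair is a negative (self-pairs
#' excluded). AUROC uses the rank-statistic (Mann-Whitney) formulation with
#' midrank tie correction; AUPR is the step-interpolated area (average
#' precision) over the ranking, ties broken by stable pair order.
#'
#' @param scores symmetric [scored_network()].
#' @param truth reference [edge_list()].
#' @param exclude optional [edge_list()] of pairs removed from the universe.
#' @return named numeric vector `c(auroc, aupr)`.
#' @export
ranking_curves <- function(scores, truth, exclude = NULL) {
  stopifnot(inherits(scores, "scored_network"), scores$symmetric)
  genes <- scores$gene_ids
  s <- scores$scores
  ut <- upper.tri(s)
  idx <- which(ut, arr.ind = TRUE)
  key <- paste(pmin(genes[idx[, 1]], genes[idx[, 2]]),
               pmax(genes[idx[, 1]], genes[idx[, 2]]), sep = "\r")
  score <- s[ut]
  pos <- key %in% canonical_pairs(truth)
  if (!is.null(exclude)) {
    drop <- key %in% canonical_pairs(exclude)
    score <- score[!drop]; pos <- pos[!drop]
  }
  P <- sum(pos); N <- sum(!pos)
  if (P == 0 || N == 0)
    stop("ranking_curves: reference must induce both positive and negative pairs")
  r <- rank(score, ties.method = "average")
  auroc <- (sum(r[pos]) - P * (P + 1) / 2) / (P * N)
  o <- order(-score)  # stable: ties keep pair order
  hits <- cumsum(pos[o])
  prec_at <- hits / seq_along(hits)
  aupr <- sum(prec_at[pos[o]]) / P
  c(auroc = auroc, aupr = aupr)
}

#' Evaluate a predicted network against a reference
#'
#' Convenience wrapper: confusion counts, precision/recall/F1 and (when a
#' score matrix is supplied) AUROC/AUPR.
#'
#' @param predicted predicted [edge_list()].
#' @param truth reference [edge_list()].
#' @param scores optional symmetric [scored_network()] enabling AUROC/AUPR.
#' @return named list (class `evaluation_report`) with `TP`, `FP`, `FN`,
#'   `precision`, `recall`, `f1` and, if scores given, `auroc`, `aupr`.
#' @export
evaluate_network <- function(predicted, truth, scores = NULL) {
  cc <- confusion_counts(predicted, truth)
  m <- suppressWarnings(prf1(cc))
  out <- c(as.list(cc), as.list(m))
  if (!is.null(scores)) out <- c(out, as.list(ranking_curves(scores, truth)))
  structure(out, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d | precision %.4f  recall %.4f  F1 %.4f",
              x$TP, x$FP, x$FN, x$precision, x$recall, x$f1))
  if (!is.null(x$auroc))
    cat(sprintf(" | AUROC %.4f  AUPR %.4f", x$auroc, x$aupr))
  cat("\n")
  invisible(x)
}

#' Group methods by significance of their metric samples
#'
#' Orders methods by mean metric; the best method seeds the top group, and
#' next-best methods are pooled into it while the classic (pooled-variance)
#' unpaired t-test between the current top group and the next method is not
#' significant at `alpha`. Degenerate zero-variance comparisons fall back to
#' exact-equality grouping.
#'
#' @param metric_samples named list of numeric vectors (>= 2 values each), one
#'   per method.
#' @param alpha significance level (default 0.05).
#' @return list with `groups` (named vector: `"top"` / `"other"`), `means`,
#'   and `p_value` (the boundary test; `NA` if all methods pooled).
#' @export
significance_group <- function(metric_samples, alpha = 0.05) {
  stopifnot(is.list(metric_samples), length(metric_samples) >= 2,
            all(lengths(metric_samples) >= 2))
  means <- vapply(metric_samples, mean, 0)
  ord <- order(-means)
  nm <- names(metric_samples)[ord]
  top <- nm[1]
  pooled <- metric_samples[[top]]
  p_val <- NA_real_
  for (m in nm[-1]) {
    xs <- metric_samples[[m]]
    if (stats::var(pooled) == 0 && stats::var(xs) == 0) {
      same <- mean(pooled) == mean(xs)
      p_val <- if (same) 1 else 0
    } else {
      p_val <- stats::t.test(pooled, xs, var.equal = TRUE)$p.value
    }
    if (p_val < alpha) break
    top <- c(top, m)
    pooled <- c(pooled, xs)
  }
  groups <- stats::setNames(
    ifelse(names(metric_samples) %in% top, "top", "other"),
    names(metric_samples))
  list(groups = groups, means = means, p_value = p_val)
}
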