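#' Confusion counts and rates for one validation run
#'
#' Computes the standard rates from confusion counts:
#' `TPR = TP/P`, `FPR = FP/N`, `F1 = 2 TP / (2 TP + FP + FN)`,
#' `precision = TP / (TP + FP)` and the confirmation rate `TP / n_predicted`
#' (the fraction of all predicted interactions that are validated positives,
#' a proxy for expected experimental success). Rates with zero denominator
#' are 0 by convention. `FN = P - TP` always.
#'
#' @param tp,fp True/false positive counts.
#' @param n_positives Number of positives `P` (`tp <= P` required).
#' @param n_negatives Number of negatives `N` (`fp <= N` required).
#' @param n_predicted Total number of predicted interactions, including those
#'   matching neither validation set (default `tp + fp`).
#' @return An object of class `cpi_metrics` (named list with fields `tp`,
#'   `fp`, `fn`, `n_positives`, `n_negatives`, `n_predicted`, `tpr`, `fpr`,
#'   `f1`, `precision`, `confirmation_rate`).
#' @export
metrics_from_counts <- function(tp, fp, n_positives, n_negatives,
                                n_predicted = tp + fp) {
  tp <- as.integer(tp); fp <- as.integer(fp)
  P <- as.integer(n_positives); N <- as.integer(n_negatives)
  n_predicted <- as.integer(n_predicted)
  if (tp < 0 || fp < 0 || P < 0 || N < 0) stop("negative counts")
  if (tp > P) stop("tp exceeds number of positives")
  if (fp > N) stop("fp exceeds number of negatives")
  fn <- P - tp
  rate <- function(num, den) if (den > 0) num / den else 0
  structure(list(tp = tp, fp = fp, fn = fn,
                 n_positives = P, n_negatives = N, n_predicted = n_predicted,
                 tpr = rate(tp, P), fpr = rate(fp, N),
                 f1 = rate(2 * tp, 2 * tp + fp + fn),
                 precision = rate(tp, tp + fp),
                 confirmation_rate = rate(tp, n_predicted)),
            class = "cpi_metrics")
}

#' @export
print.cpi_metrics <- function(x, ...) {
  cat(sprintf("TP %d / P %d, FP %d / N %d, predicted %d\n",
              x$tp, x$n_positives, x$fp, x$n_negatives, x$n_predicted))
  cat(sprintf("TPR %.3f  FPR %.3f  F1 %.3f  precision %.3f  TP/PI %.3f\n",
              x$tpr, x$fpr, x$f1, x$precision, x$confirmation_rate))
  invisible(x)
}

#' Split a network into a training network and hold-out positives
#'
#' Removes `round(fraction * |E|)` uniformly sampled edges (rounding half
#' away from zero) and returns them as the positive validation pairs. Node
#' records are kept even if an endpoint loses its last edge, and no re-pruning
#' is applied: a held-out positive whose endpoint became edge-free simply
#' stays unpredictable and still counts in `P` after the predictable-pair
#' restriction is applied against the training network.
#'
#' @param net A `cpi_network`.
#' @param fraction Fraction of edges to hold out, in (0, 1).
#' @param seed Integer seed; same seed, same split.
#' @return A list with `train` (`cpi_network`) and `positives` (pair data
#'   frame); train edges and positives partition the input edge set.
#' @export
holdout_split <- function(net, fraction, seed) {
  stopifnot(inherits(net, "cpi_network"), fraction > 0, fraction < 1)
  m <- nrow(net$edges)
  k <- as.integer(round_half_up(fraction * m))
  if (k >= m) stop("hold-out fraction would remove all edges")
  idx <- with_seed(seed, sample.int(m, k))
  positives <- pairs_df(net$edges$compound[idx], net$edges$protein[idx])
  train <- set_edges(net, net$edges[-idx, , drop = FALSE],
                     drop_isolated = FALSE)
  list(train = train, positives = positives)
}

#' Restrict validation pairs to predictable ones
#'
#' A pair is predictable if both its compound and its protein occur with at
#' least one edge in the (training) network; only such pairs can in principle
#' be produced by biclique extension.
#'
#' @param pairs Pair data frame (`compound`, `protein`).
#' @param net A `cpi_network`.
#' @return The restricted pair data frame.
#' @export
restrict_to_predictable <- function(pairs, net) {
  stopifnot(inherits(net, "cpi_network"))
  keep <- pairs$compound %in% unique(net$edges$compound) &
    pairs$protein %in% unique(net$edges$protein)
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score predictions against positive and negative validation pairs
#'
#' `tp` counts predictions that are validation positives, `fp` those that are
#' validation negatives; predictions matching neither set have unknown status
#' and only contribute to `n_predicted`. Positives and negatives must be
#' disjoint and already restricted to predictable pairs.
#'
#' @param predictions Prediction data frame (or any data frame with
#'   `compound` and `protein` columns).
#' @param positives,negatives Pair data frames.
#' @return A `cpi_metrics` object.
#' @export
score_predictions <- function(predictions, positives, negatives) {
  pred_k <- unique(edge_key(predictions$compound, predictions$protein))
  pos_k <- unique(edge_key(positives$compound, positives$protein))
  neg_k <- unique(edge_key(negatives$compound, negatives$protein))
  if (length(intersect(pos_k, neg_k)))
    stop("positive and negative validation sets overlap")
  metrics_from_counts(tp = sum(pred_k %in% pos_k),
                      fp = sum(pred_k %in% neg_k),
                      n_positives = length(pos_k),
                      n_negatives = length(neg_k),
                      n_predicted = length(pred_k))
}

normalize_thresholds <- function(thresholds) {
  if (is.data.frame(thresholds)) {
    stopifnot(all(c("c_min", "p_min") %in% names(thresholds)))
    out <- thresholds[c("c_min", "p_min")]
  } else if (is.list(thresholds)) {
    out <- data.frame(c_min = vapply(thresholds, `[`, numeric(1), 1),
                      p_min = vapply(thresholds, `[`, numeric(1), 2))
  } else if (is.numeric(thresholds) && length(thresholds) == 2) {
    out <- data.frame(c_min = thresholds[1], p_min = thresholds[2])
  } else stop("thresholds must be a list of c(c_min, p_min) pairs or a data frame")
  if (nrow(out) == 0) stop("no thresholds given")
  out$c_min <- as.integer(out$c_min); out$p_min <- as.integer(out$p_min)
  out
}

#' Hold-out validation sweep over biclique-size thresholds
#'
#' For each repeat, one split is drawn with seed `base_seed + r` and reused
#' for every threshold (so threshold rows differ only by threshold, not by
#' split). Per repeat, maximal bicliques are enumerated once at the loosest
#' threshold of the sweep and re-filtered per threshold -- which is exact,
#' because maximality is judged against the network, never against the
#' threshold. Negatives found among the reference network's edges are
#' excluded from `N` (they are not non-interactions there, and a held-out
#' edge could otherwise land in both truth sets); the exclusion is reported
#' via a message once per sweep.
#'
#' @param net A `cpi_network`.
#' @param negatives Pair data frame of validated non-interactions.
#' @param fraction Hold-out fraction passed to [holdout_split()].
#' @param thresholds List of `c(c_min, p_min)` pairs (or a data frame with
#'   those columns).
#' @param n_repeats Number of random hold-out repetitions.
#' @param base_seed Integer; repeat `r` uses seed `base_seed + r`.
#' @param max_missing,two_edge_min_side Passed to [extend_bicliques()].
#' @return An object of class `cpi_sweep`: a data frame with one row per
#'   threshold carrying `mean_*` and `sd_*` columns for every metric field,
#'   plus attributes `runs` (the long per-repeat results) and
#'   `best_threshold` (the row index with maximal mean F1).
#' @export
run_validation <- function(net, negatives, fraction, thresholds,
                           n_repeats = 10, base_seed = 1, max_missing = 1,
                           two_edge_min_side = 4) {
  stopifnot(n_repeats >= 1)
  thr <- normalize_thresholds(thresholds)
  loose_c <- min(thr$c_min); loose_p <- min(thr$p_min)

  # negatives that are edges of the reference network are not
  # non-interactions there (they would also collide with held-out positives);
  # drop them up front, as validated negative sets are cleaned against the
  # source database
  net_k <- edge_key(net$edges$compound, net$edges$protein)
  in_net <- edge_key(negatives$compound, negatives$protein) %in% net_k
  n_neg_excluded <- sum(in_net)
  negatives <- negatives[!in_net, , drop = FALSE]

  runs <- list()
  for (r in seq_len(n_repeats)) {
    sp <- holdout_split(net, fraction, seed = base_seed + r)
    pos <- restrict_to_predictable(sp$positives, sp$train)
    neg <- restrict_to_predictable(negatives, sp$train)

    bic <- maximal_bicliques(sp$train, loose_c, loose_p)
    for (t in seq_len(nrow(thr))) {
      preds <- extend_bicliques(sp$train, thr$c_min[t], thr$p_min[t],
                                max_missing = max_missing,
                                two_edge_min_side = two_edge_min_side,
                                bicliques = bic)
      m <- score_predictions(preds, pos, neg)
      runs[[length(runs) + 1L]] <-
        cbind(data.frame(repeat_id = r, seed = base_seed + r,
                         c_min = thr$c_min[t], p_min = thr$p_min[t]),
              as.data.frame(unclass(m)))
    }
  }
  if (n_neg_excluded > 0)
    message("run_validation: excluded ", n_neg_excluded,
            " negative pair(s) present as reference-network edges")
  runs <- do.call(rbind, runs)

  fields <- c("tp", "fp", "fn", "n_predicted", "tpr", "fpr", "f1",
              "precision", "confirmation_rate")
  out <- thr
  grp <- interaction(runs$c_min, runs$p_min, drop = FALSE)
  key <- interaction(thr$c_min, thr$p_min)
  for (f in fields) {
    mu <- tapply(runs[[f]], grp, mean)
    sdv <- tapply(runs[[f]], grp, function(v) if (length(v) > 1) stats::sd(v) else 0)
    out[[paste0("mean_", f)]] <- as.numeric(mu[match(key, names(mu))])
    out[[paste0("sd_", f)]] <- as.numeric(sdv[match(key, names(sdv))])
  }
  structure(out, class = c("cpi_sweep", "data.frame"),
            runs = runs,
            best_threshold = which.max(out$mean_f1))
}

#' @export
print.cpi_sweep <- function(x, ...) {
  cat("Validation sweep over", nrow(x), "threshold(s)\n")
  print.data.frame(x, digits = 3)
  b <- attr(x, "best_threshold")
  cat(sprintf("best threshold by mean F1: c_min=%d, p_min=%d (F1=%.3f)\n",
              x$c_min[b], x$p_min[b], x$mean_f1[b]))
  invisible(x)
}
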