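#' Specification for a synthetic planted-biclique CPI network
#'
#' Describes a bipartite network with node-disjoint planted complete
#' bicliques, optional background noise, a per-biclique hold-out of removed
#' edges (the recoverable ground truth), and a sampled set of true-negative
#' pairs. Planted bicliques are node-disjoint so that the recovery guarantee
#' of single-edge extension is provable; `overlap = TRUE` lifts that
#' restriction for stress testing (no guarantee then holds).
#'
#' @param n_compounds,n_proteins Partition sizes.
#' @param planted List of `c(c_i, p_i)` biclique sizes; they must fit in the
#'   node budget (when disjoint).
#' @param background_edge_prob Probability of a background edge between pairs
#'   not joined by a planted biclique, in `[0, 1)`.
#' @param holdout_per_biclique Number of edges removed from each planted
#'   biclique (at most 1 unless `stress = TRUE`; single-edge removal is what
#'   the one-edge extension rule provably recovers).
#' @param n_negatives Number of never-edge, never-removed pairs to sample as
#'   true negatives.
#' @param degree_model `"uniform"` or `"heavy_tail"`: heavy-tail draws
#'   per-compound background propensities from a power law (Pareto shape 2.5)
#'   to mimic the heavy-tailed compound degree distributions of real CPI
#'   networks, rescaled so the mean background edge probability is
#'   `background_edge_prob`.
#' @param seed Integer seed; generation is fully deterministic given the spec.
#' @param overlap Allow planted bicliques to share nodes (stress mode).
#' @param stress Allow `holdout_per_biclique > 1`.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds, n_proteins, planted,
                           background_edge_prob = 0,
                           holdout_per_biclique = 0, n_negatives = 100,
                           degree_model = c("uniform", "heavy_tail"),
                           seed = 1, overlap = FALSE, stress = FALSE) {
  degree_model <- match.arg(degree_model)
  stopifnot(n_compounds >= 1, n_proteins >= 1,
            background_edge_prob >= 0, background_edge_prob < 1,
            holdout_per_biclique >= 0, n_negatives >= 0)
  planted <- lapply(planted, function(s) {
    s <- as.integer(s)
    if (length(s) != 2 || any(s < 1)) stop("planted sizes must be c(c_i, p_i)")
    s
  })
  if (!overlap && length(planted)) {
    if (sum(vapply(planted, `[`, integer(1), 1)) > n_compounds)
      stop("planted compound sets exceed n_compounds")
    if (sum(vapply(planted, `[`, integer(1), 2)) > n_proteins)
      stop("planted protein sets exceed n_proteins")
  }
  if (holdout_per_biclique > 1 && !stress)
    stop("holdout_per_biclique > 1 requires stress = TRUE ",
         "(single removal is the guaranteed-recovery regime)")
  if (holdout_per_biclique > 0 && length(planted)) {
    too_small <- vapply(planted, function(s) prod(s) <= holdout_per_biclique,
                        logical(1))
    if (any(too_small))
      stop("holdout_per_biclique would empty a planted biclique")
  }
  structure(list(n_compounds = as.integer(n_compounds),
                 n_proteins = as.integer(n_proteins), planted = planted,
                 background_edge_prob = background_edge_prob,
                 holdout_per_biclique = as.integer(holdout_per_biclique),
                 n_negatives = as.integer(n_negatives),
                 degree_model = degree_model, seed = as.integer(seed),
                 overlap = overlap, stress = stress),
            class = "synthetic_spec")
}

#' Generate a synthetic planted-biclique CPI network with ground truth
#'
#' Plants each requested complete biclique on (by default) disjoint node
#' blocks, adds background edges between non-planted pairs, removes
#' `holdout_per_biclique` edges uniformly from each planted biclique
#' (recording them as recoverable ground truth), and samples a set of
#' negative pairs disjoint from all edges and removed edges. All randomness
#' derives from `spec$seed`; the same spec yields an identical result.
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `synthetic_truth`: list with `network`
#'   (`cpi_network`, all scores 1), `removed_edges` (pair data frame),
#'   `planted_bicliques` (`biclique_set`), `negatives` (pair data frame) and
#'   `spec`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  comp_ids <- sprintf("c%03d", seq_len(spec$n_compounds))
  prot_ids <- sprintf("p%03d", seq_len(spec$n_proteins))

  with_seed(spec$seed, {
    # assign planted blocks
    planted <- list()
    next_c <- 1L; next_p <- 1L
    for (i in seq_along(spec$planted)) {
      s <- spec$planted[[i]]
      if (!spec$overlap) {
        cs <- comp_ids[next_c:(next_c + s[1] - 1L)]
        ps <- prot_ids[next_p:(next_p + s[2] - 1L)]
        next_c <- next_c + s[1]; next_p <- next_p + s[2]
      } else {
        cs <- sample(comp_ids, s[1])
        ps <- sample(prot_ids, s[2])
      }
      planted[[i]] <- list(compounds = sort(cs), proteins = sort(ps))
    }

    in_planted <- new.env(hash = TRUE, parent = emptyenv())
    planted_edges <- list()
    for (i in seq_along(planted)) {
      g <- expand.grid(compound = planted[[i]]$compounds,
                       protein = planted[[i]]$proteins,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      g$biclique <- i
      planted_edges[[i]] <- g
      for (k in edge_key(g$compound, g$protein))
        assign(k, TRUE, envir = in_planted)
    }
    planted_edges <- if (length(planted_edges)) do.call(rbind, planted_edges)
    else cbind(pairs_df(), biclique = integer())

    # background edges between pairs not covered by a planted biclique
    prob <- matrix(spec$background_edge_prob, spec$n_compounds, spec$n_proteins)
    if (spec$degree_model == "heavy_tail" && spec$background_edge_prob > 0) {
      w <- (1 - stats::runif(spec$n_compounds))^(-1 / 2.5)  # Pareto, shape 2.5
      prob <- pmin(outer(w / mean(w), rep(1, spec$n_proteins)) *
                     spec$background_edge_prob, 0.9)
    }
    draw <- matrix(stats::runif(spec$n_compounds * spec$n_proteins),
                   spec$n_compounds, spec$n_proteins) < prob
    bg_idx <- which(draw, arr.ind = TRUE)
    bg <- pairs_df(comp_ids[bg_idx[, 1]], prot_ids[bg_idx[, 2]])
    bg <- bg[!vapply(edge_key(bg$compound, bg$protein), exists,
                     logical(1), envir = in_planted, inherits = FALSE), ,
             drop = FALSE]

    # per-biclique hold-out
    removed <- pairs_df()
    keep_planted <- rep(TRUE, nrow(planted_edges))
    if (spec$holdout_per_biclique > 0) {
      for (i in seq_along(planted)) {
        rows <- which(planted_edges$biclique == i)
        out <- sample(rows, spec$holdout_per_biclique)
        keep_planted[out] <- FALSE
        removed <- rbind(removed, planted_edges[out, c("compound", "protein")])
      }
    }

    edges <- rbind(planted_edges[keep_planted, c("compound", "protein")], bg)
    edges <- dedup_pairs(edges)
    edges$experimental <- 1

    # negatives: uniformly from pairs with no edge and no removed edge
    taken <- new.env(hash = TRUE, parent = emptyenv())
    for (k in edge_key(edges$compound, edges$protein))
      assign(k, TRUE, envir = taken)
    for (k in edge_key(removed$compound, removed$protein))
      assign(k, TRUE, envir = taken)
    n_free <- spec$n_compounds * spec$n_proteins -
      nrow(edges) - nrow(removed)
    if (spec$n_negatives > n_free)
      stop("cannot sample ", spec$n_negatives, " negatives: only ", n_free,
           " free pairs")
    negatives <- pairs_df()
    guard <- 0L
    while (nrow(negatives) < spec$n_negatives) {
      need <- spec$n_negatives - nrow(negatives)
      ci <- sample.int(spec$n_compounds, need * 2L, replace = TRUE)
      pj <- sample.int(spec$n_proteins, need * 2L, replace = TRUE)
      cand <- dedup_pairs(pairs_df(comp_ids[ci], prot_ids[pj]))
      free <- !vapply(edge_key(cand$compound, cand$protein), exists,
                      logical(1), envir = taken, inherits = FALSE)
      cand <- cand[free, , drop = FALSE]
      if (nrow(cand) > need) cand <- cand[seq_len(need), , drop = FALSE]
      for (k in edge_key(cand$compound, cand$protein))
        assign(k, TRUE, envir = taken)
      negatives <- rbind(negatives, cand)
      guard <- guard + 1L
      if (guard > 1000L) stop("negative sampling did not converge")
    }

    net <- cpi_network(comp_ids, prot_ids, edges,
                       provenance = "synthetic:planted_biclique")
    rownames(removed) <- rownames(negatives) <- NULL
    structure(list(network = net, removed_edges = removed,
                   planted_bicliques = structure(planted,
                                                 class = "biclique_set"),
                   negatives = negatives, spec = spec),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic planted-biclique network (seed ", x$spec$seed, ")\n", sep = "")
  print(x$network)
  cat(sprintf("  %d planted biclique(s), %d removed edge(s), %d negative pair(s)\n",
              length(x$planted_bicliques), nrow(x$removed_edges),
              nrow(x$negatives)))
  invisible(x)
}

#' Write a synthetic truth bundle as TSV files
#'
#' Serializes the network edge list (via [write_network()], readable by
#' [read_stitch_links()] and [read_network()]) and the removed-edge and
#' negative pair lists (readable by [read_pair_list()]), so that synthetic
#' benchmarks exercise the same I/O paths as real data.
#'
#' @param truth A `synthetic_truth`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_synthetic_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(network = file.path(dir, "network.tsv"),
             positives = file.path(dir, "removed_edges.tsv"),
             negatives = file.path(dir, "negatives.tsv"))
  write_network(truth$network, paths["network"])
  utils::write.table(truth$removed_edges, paths["positives"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth$negatives, paths["negatives"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Benchmark biclique extension over a grid of synthetic networks
#'
#' Generates each spec, predicts at each threshold on the generated network,
#' and scores the predictions against the generated ground truth: the removed
#' planted edges act as the positives (they are the hold-out by
#' construction), the generated negative pairs as the negatives (restricted
#' to predictable pairs first).
#'
#' @param spec_grid List of [synthetic_spec()] objects.
#' @param thresholds List of `c(c_min, p_min)` pairs.
#' @param max_missing,two_edge_min_side Passed to [extend_bicliques()].
#' @return Data frame with one row per (spec, threshold) carrying the spec
#'   index, threshold and all metric fields.
#' @export
benchmark_suite <- function(spec_grid, thresholds, max_missing = 1,
                            two_edge_min_side = 4) {
  thr <- normalize_thresholds(thresholds)
  rows <- list()
  for (i in seq_along(spec_grid)) {
    truth <- generate_synthetic(spec_grid[[i]])
    pos <- restrict_to_predictable(truth$removed_edges, truth$network)
    neg <- restrict_to_predictable(truth$negatives, truth$network)
    bic <- maximal_bicliques(truth$network, min(thr$c_min), min(thr$p_min))
    for (t in seq_len(nrow(thr))) {
      preds <- extend_bicliques(truth$network, thr$c_min[t], thr$p_min[t],
                                max_missing = max_missing,
                                two_edge_min_side = two_edge_min_side,
                                bicliques = bic)
      m <- score_predictions(preds, pos, neg)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(spec_id = i, seed = spec_grid[[i]]$seed,
                         c_min = thr$c_min[t], p_min = thr$p_min[t]),
              as.data.frame(unclass(m)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
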