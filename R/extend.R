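#' Predict missing edges by biclique extension
#'
#' For every maximal biclique `B = (C, P)` passing the size threshold, an
#' external compound adjacent to all but one protein of `P` is predicted to
#' interact with the one remaining protein (and symmetrically for proteins
#' joining the compound side). Such a candidate lacks exactly one edge to
#' become a full member of `B`; inserting it extends the biclique. With
#' `max_missing = 2`, candidates lacking exactly two edges to a side with at
#' least `two_edge_min_side` members additionally yield both missing edges
#' (multiplicity 2). Predictions are deduplicated per edge; `support` counts
#' the number of distinct (biclique, candidate) derivations that produced the
#' edge, and `missing_multiplicity` reports the smallest number of edges any
#' single derivation had to insert. No prediction duplicates an existing edge.
#'
#' @param net A `cpi_network`.
#' @param c_min,p_min Size threshold a maximal biclique must pass for its
#'   extensions to be emitted.
#' @param max_missing 1 (default) or 2: maximum number of edges a candidate
#'   may lack.
#' @param two_edge_min_side Minimum size of the side a two-edge candidate
#'   joins (default 4); ignored for `max_missing = 1`.
#' @param bicliques Optional pre-computed `biclique_set` for `net` (it is
#'   re-filtered by the threshold); when `NULL` the maximal bicliques are
#'   enumerated internally.
#' @return Data frame with columns `compound`, `protein`, `support`,
#'   `missing_multiplicity`.
#' @export
extend_bicliques <- function(net, c_min = 2, p_min = 2, max_missing = 1,
                             two_edge_min_side = 4, bicliques = NULL) {
  stopifnot(inherits(net, "cpi_network"), max_missing %in% c(1, 2))
  if (is.null(bicliques)) bicliques <- maximal_bicliques(net, c_min, p_min)
  else bicliques <- filter_bicliques(bicliques, c_min, p_min)

  empty <- data.frame(compound = character(), protein = character(),
                      support = integer(), missing_multiplicity = integer())
  if (!length(bicliques)) return(empty)

  adj_c <- split(net$edges$protein, net$edges$compound)   # compound -> proteins
  adj_p <- split(net$edges$compound, net$edges$protein)   # protein -> compounds

  acc <- new.env(hash = TRUE, parent = emptyenv())
  add <- function(compound, protein, mult) {
    k <- edge_key(compound, protein)
    cur <- if (exists(k, envir = acc, inherits = FALSE))
      get(k, envir = acc) else list(compound = compound, protein = protein,
                                    support = 0L, mult = mult)
    cur$support <- cur$support + 1L
    cur$mult <- min(cur$mult, mult)
    assign(k, cur, envir = acc)
  }

  # one side of a biclique: members of `side_in` are joined by candidates
  # drawn from the opposite partition; `adj_in` maps side_in members to their
  # neighbors (the candidates), `adj_out` maps candidates to side_in ids
  scan_side <- function(side_in, members_out, adj_in, adj_out, flip) {
    n <- length(side_in)
    cnt <- table(unlist(adj_in[side_in], use.names = FALSE))
    cand <- setdiff(names(cnt), members_out)
    for (x in cand) {
      k <- cnt[[x]]
      if (k == n - 1L) {
        miss <- setdiff(side_in, adj_out[[x]])
        if (flip) add(miss, x, 1L) else add(x, miss, 1L)
      } else if (max_missing == 2 && n >= two_edge_min_side && k == n - 2L) {
        miss <- setdiff(side_in, adj_out[[x]])
        for (m in miss) if (flip) add(m, x, 2L) else add(x, m, 2L)
      }
    }
  }

  for (b in bicliques) {
    # compound candidates joining the protein side P
    scan_side(b$proteins, b$compounds, adj_p, adj_c, flip = FALSE)
    # protein candidates joining the compound side C
    scan_side(b$compounds, b$proteins, adj_c, adj_p, flip = TRUE)
  }

  keys <- ls(acc)
  if (!length(keys)) return(empty)
  rows <- lapply(keys, get, envir = acc)
  data.frame(compound = vapply(rows, `[[`, character(1), "compound"),
             protein = vapply(rows, `[[`, character(1), "protein"),
             support = vapply(rows, `[[`, integer(1), "support"),
             missing_multiplicity = vapply(rows, `[[`, integer(1), "mult"),
             stringsAsFactors = FALSE)
}

#' Predict missing compound-protein interactions
#'
#' Convenience wrapper around [maximal_bicliques()] and [extend_bicliques()].
#' Output is sorted by decreasing support, then compound id, then protein id,
#' for deterministic downstream use, and carries an `iteration` column (1 for
#' a single-pass prediction; see [iterate_extension()]).
#'
#' @inheritParams extend_bicliques
#' @return Data frame with columns `compound`, `protein`, `support`,
#'   `missing_multiplicity`, `iteration`.
#' @examples
#' # a 3x2 biclique plus an external compound touching one of its proteins
#' net <- cpi_network(paste0("c", 1:4), paste0("p", 1:2),
#'   data.frame(compound = c("c1","c1","c2","c2","c3","c3","c4"),
#'              protein  = c("p1","p2","p1","p2","p1","p2","p1")))
#' predict_interactions(net)  # predicts (c4, p2)
#' @export
predict_interactions <- function(net, c_min = 2, p_min = 2, max_missing = 1,
                                 two_edge_min_side = 4, bicliques = NULL) {
  preds <- extend_bicliques(net, c_min = c_min, p_min = p_min,
                            max_missing = max_missing,
                            two_edge_min_side = two_edge_min_side,
                            bicliques = bicliques)
  preds <- preds[order(-preds$support, preds$compound, preds$protein), ,
                 drop = FALSE]
  preds$iteration <- rep(1L, nrow(preds))
  rownames(preds) <- NULL
  preds
}

#' Apply biclique extension iteratively until convergence
#'
#' Each iteration predicts all missing edges against the iteration-start
#' network (batch semantics, so the result does not depend on any edge
#' ordering), inserts them, and repeats. The loop stops when the number of
#' newly predicted edges falls below `stop_new_below`, or after `max_iter`
#' iterations. Since edges are only ever added between existing nodes, the
#' density history is non-decreasing and bounded by 1.
#'
#' @inheritParams extend_bicliques
#' @param stop_new_below Stop once an iteration predicts fewer than this many
#'   new edges (default 1: strict convergence; the looser "fewer than 10"
#'   stopping sometimes used for large networks is available by flag).
#' @param max_iter Iteration cap.
#' @return A list with `network` (the final `cpi_network`; inserted edges
#'   score 1 on every channel) and `history`, a data frame with one row per
#'   iteration: `iteration`, `n_new`, `density`.
#' @export
iterate_extension <- function(net, c_min = 2, p_min = 2, max_missing = 1,
                              two_edge_min_side = 4, stop_new_below = 1,
                              max_iter = 50) {
  stopifnot(stop_new_below >= 1, max_iter >= 1)
  cur <- net
  hist <- data.frame(iteration = integer(), n_new = integer(),
                     density = numeric())
  for (it in seq_len(max_iter)) {
    preds <- extend_bicliques(cur, c_min = c_min, p_min = p_min,
                              max_missing = max_missing,
                              two_edge_min_side = two_edge_min_side)
    n_new <- nrow(preds)
    if (n_new > 0) {
      new_edges <- preds[, c("compound", "protein"), drop = FALSE]
      for (ch in cur$channels) new_edges[[ch]] <- 1
      cur <- set_edges(cur, rbind(cur$edges, new_edges))
    }
    hist <- rbind(hist, data.frame(iteration = it, n_new = n_new,
                                   density = density_summary(cur)$density))
    if (n_new < stop_new_below) break
  }
  list(network = cur, history = hist)
}

#' Write predictions as TSV
#'
#' @param predictions Prediction data frame from [predict_interactions()] or
#'   [extend_bicliques()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  if (is.null(predictions$iteration))
    predictions$iteration <- rep(1L, nrow(predictions))
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
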