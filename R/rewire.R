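#' Degree-preserving edge-switch randomization
#'
#' Repeatedly draws two distinct edges `(c1, p1)`, `(c2, p2)` with
#' `c1 != c2`, `p1 != p2` and replaces them by `(c1, p2)`, `(c2, p1)` iff
#' neither target edge already exists. Each attempted draw counts toward the
#' swap budget whether or not it is accepted (Markov-chain semantics), so the
#' runtime is bounded. The degree of every node, the edge count and
#' bipartiteness are exactly preserved; on a complete bipartite network every
#' swap is rejected and the input is returned unchanged. Per-edge score
#' channels travel with the rewired rows (only the topology is randomized).
#'
#' @param net A `cpi_network` with at least two edges.
#' @param n_swaps Number of attempted swaps. Default
#'   `ceiling(|E| * log(1/eps))` with `eps = 1e-3` (about `6.9 |E|`), the
#'   usual switching-chain mixing heuristic.
#' @param seed Integer seed; the same seed reproduces the same randomized
#'   network.
#' @return A list with `network` (the randomized `cpi_network`) and `report`
#'   (`attempted_swaps`, `accepted_swaps`, `seed`).
#' @export
edge_switch_randomize <- function(net, n_swaps = NULL, seed) {
  stopifnot(inherits(net, "cpi_network"))
  m <- nrow(net$edges)
  if (m < 2) stop("edge-switch randomization needs at least 2 edges")
  if (is.null(n_swaps)) n_swaps <- ceiling(m * log(1 / 1e-3))
  comp <- net$edges$compound
  prot <- net$edges$protein

  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(m)) assign(edge_key(comp[i], prot[i]), TRUE, envir = seen)

  accepted <- 0L
  with_seed(seed, {
    for (s in seq_len(n_swaps)) {
      ij <- sample.int(m, 2L)
      i <- ij[1L]; j <- ij[2L]
      c1 <- comp[i]; p1 <- prot[i]; c2 <- comp[j]; p2 <- prot[j]
      if (c1 == c2 || p1 == p2) next
      k1 <- edge_key(c1, p2); k2 <- edge_key(c2, p1)
      if (exists(k1, envir = seen, inherits = FALSE) ||
          exists(k2, envir = seen, inherits = FALSE)) next
      rm(list = c(edge_key(c1, p1), edge_key(c2, p2)), envir = seen)
      assign(k1, TRUE, envir = seen)
      assign(k2, TRUE, envir = seen)
      prot[i] <- p2; prot[j] <- p1
      accepted <- accepted + 1L
    }
  })

  edges <- net$edges
  edges$compound <- comp
  edges$protein <- prot
  out <- set_edges(net, edges, drop_isolated = FALSE)
  out$provenance <- paste0(net$provenance,
                           if (nzchar(net$provenance)) "+", "edge_switch")
  list(network = out,
       report = list(attempted_swaps = as.integer(n_swaps),
                     accepted_swaps = accepted, seed = as.integer(seed)))
}
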