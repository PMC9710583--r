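#' Enumerate maximal bicliques of a bipartite CPI network
#'
#' A biclique is a pair of node sets (compounds `C`, proteins `P`) such that
#' every cross pair is an edge; it is maximal when no strict superset on
#' either side stays complete. Enumeration is exact, using a branch-and-bound
#' consensus algorithm over the neighborhoods of the smaller partition
#' (iMBEA-family): candidates on one side are added one at a time, the common
#' neighborhood on the other side is intersected, fully-connected candidates
#' are absorbed, and a check against previously processed candidates prunes
#' non-maximal branches. Size thresholds prune the search (the compound side
#' only shrinks along a branch) but never affect maximality, which is always
#' judged against the full network. Overlapping maximal bicliques are
#' expected and returned; an edge can belong to several.
#'
#' @param net A `cpi_network`.
#' @param c_min,p_min Minimum number of compounds / proteins a biclique must
#'   have to be returned (defaults 2 and 2, the smallest size that carries
#'   extension information).
#' @return A list of class `biclique_set`; each element is a list with sorted
#'   character vectors `compounds` and `proteins`.
#' @examples
#' net <- cpi_network(c("c1", "c2", "c3"), c("p1", "p2"),
#'   expand.grid(compound = c("c1", "c2", "c3"), protein = c("p1", "p2"),
#'               stringsAsFactors = FALSE))
#' length(maximal_bicliques(net))  # 1: the whole 3x2 graph
#' @export
maximal_bicliques <- function(net, c_min = 2, p_min = 2) {
  stopifnot(inherits(net, "cpi_network"), c_min >= 1, p_min >= 1)
  comp_ids <- sort(unique(net$edges$compound))
  prot_ids <- sort(unique(net$edges$protein))
  nc <- length(comp_ids); np <- length(prot_ids)
  empty <- structure(list(), class = "biclique_set")
  if (nc < c_min || np < p_min || nrow(net$edges) == 0) return(empty)

  ci <- match(net$edges$compound, comp_ids)
  pi <- match(net$edges$protein, prot_ids)
  adj_c <- split(pi, factor(ci, levels = seq_len(nc)))   # compound -> proteins
  adj_p <- split(ci, factor(pi, levels = seq_len(np)))   # protein -> compounds
  adj_c <- lapply(adj_c, sort); adj_p <- lapply(adj_p, sort)

  # expand along the smaller side: its subsets drive the recursion
  if (np <= nc) {
    raw <- mbea_core(nc, adj_p, l_min = c_min, r_min = p_min)
    bc <- lapply(raw, function(b) list(compounds = comp_ids[b$L],
                                       proteins = prot_ids[b$R]))
  } else {
    raw <- mbea_core(np, adj_c, l_min = p_min, r_min = c_min)
    bc <- lapply(raw, function(b) list(compounds = comp_ids[b$R],
                                       proteins = prot_ids[b$L]))
  }
  key <- vapply(bc, function(b)
    paste(paste(b$compounds, collapse = ","), paste(b$proteins, collapse = ","),
          sep = ";"), character(1))
  structure(bc[!duplicated(key)], class = "biclique_set")
}

# Branch-and-bound maximal biclique enumeration.
# L side: 1..n_l (implicit, via the candidate neighborhoods); candidates
# (R side) indexed by adj_cand: candidate -> sorted L-neighbors.
# Returns list of list(L = sorted L indices, R = sorted candidate indices);
# every maximal biclique with non-empty R and |L| >= l_min, |R'|+|P'|
# reachable >= r_min is reported (others are pruned).
mbea_core <- function(n_l, adj_cand, l_min, r_min) {
  res <- list(); n_res <- 0L
  report <- function(L, R) {
    if (length(L) >= l_min && length(R) >= r_min) {
      n_res <<- n_res + 1L
      res[[n_res]] <<- list(L = L, R = sort(R))
    }
  }
  find <- function(L, R, P, Q) {
    while (length(P)) {
      x <- P[1]; P <- P[-1]
      L2 <- intersect_sorted(L, adj_cand[[x]])
      if (length(L2) >= l_min) {
        R2 <- c(R, x)
        is_max <- TRUE
        Q2 <- integer()
        for (q in Q) {
          common <- sum(adj_cand[[q]] %in% L2)
          if (common == length(L2)) { is_max <- FALSE; break }
          if (common > 0L) Q2 <- c(Q2, q)
        }
        if (is_max) {
          P2 <- integer()
          for (p in P) {
            common <- sum(adj_cand[[p]] %in% L2)
            if (common == length(L2)) R2 <- c(R2, p)
            else if (common > 0L) P2 <- c(P2, p)
          }
          report(L2, R2)
          if (length(P2) && length(R2) + length(P2) >= r_min)
            find(L2, R2, P2, Q2)
        }
      }
      Q <- c(Q, x)
    }
  }
  cand <- which(lengths(adj_cand) > 0L)
  cand <- cand[order(lengths(adj_cand)[cand])]  # low-degree first
  find(seq_len(n_l), integer(), cand, integer())
  res[seq_len(n_res)]
}

#' @export
print.biclique_set <- function(x, ...) {
  cat(length(x), "maximal biclique(s)\n")
  if (length(x)) {
    cen <- biclique_census(x)
    print(utils::head(cen[order(-cen$count), ], 10), row.names = FALSE)
  }
  invisible(x)
}

#' Tabulate biclique frequencies by size
#'
#' Counts bicliques per (compounds, proteins) size class and reports the
#' scalar size `sqrt(c * p)` used to compare size spectra across networks on
#' a single axis.
#'
#' @param bicliques A `biclique_set` (or plain list of bicliques).
#' @return Data frame with columns `c`, `p`, `count`, `size` (= `sqrt(c*p)`),
#'   whose `count` column sums to `length(bicliques)`.
#' @export
biclique_census <- function(bicliques) {
  if (!length(bicliques))
    return(data.frame(c = integer(), p = integer(), count = integer(),
                      size = numeric()))
  cc <- vapply(bicliques, function(b) length(b$compounds), integer(1))
  pp <- vapply(bicliques, function(b) length(b$proteins), integer(1))
  tab <- as.data.frame(table(c = cc, p = pp), stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  out <- data.frame(c = as.integer(tab$c), p = as.integer(tab$p),
                    count = as.integer(tab$Freq))
  out <- out[order(out$c, out$p), , drop = FALSE]
  out$size <- sqrt(out$c * out$p)
  rownames(out) <- NULL
  out
}

# keep bicliques passing (c_min, p_min)
filter_bicliques <- function(bicliques, c_min, p_min) {
  keep <- vapply(bicliques, function(b)
    length(b$compounds) >= c_min && length(b$proteins) >= p_min, logical(1))
  structure(bicliques[keep], class = "biclique_set")
}

#' Write bicliques as a long-format TSV
#'
#' One row per biclique member: `biclique_id`, `side` (compound/protein),
#' `member_id`.
#'
#' @param bicliques A `biclique_set`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_bicliques <- function(bicliques, path) {
  rows <- lapply(seq_along(bicliques), function(i) {
    b <- bicliques[[i]]
    data.frame(biclique_id = i,
               side = rep(c("compound", "protein"),
                          c(length(b$compounds), length(b$proteins))),
               member_id = c(b$compounds, b$proteins),
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows)
  else data.frame(biclique_id = integer(), side = character(),
                  member_id = character())
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
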