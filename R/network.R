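#' Construct a bipartite compound-protein interaction network
#'
#' Builds a `cpi_network` object from compound records, protein records and an
#' edge table. Compounds and proteins form the two disjoint partitions of a
#' bipartite graph; edges connect one compound to one protein and carry one or
#' more confidence score channels in `[0, 1]` (e.g. `experimental`,
#' `combined`). Duplicate rows in the edge table collapse to a single edge
#' keeping the maximum score per channel.
#'
#' @param compounds Either a character vector of compound ids or a data frame
#'   with column `id` and optional columns `smiles`, `kegg_c`, `kegg_d`,
#'   `flags` (pipe-separated multi-valued fields) and `heavy_atoms`.
#' @param proteins Either a character vector of protein ids or a data frame
#'   with column `id` and optional columns `sequence` and `pathways`.
#' @param edges Data frame with columns `compound`, `protein` and one numeric
#'   column per score channel (at least one). Scores must lie in `[0, 1]`.
#' @param provenance Free-text source label stored on the network.
#' @param drop_isolated Drop nodes that end up with no incident edge
#'   (default). The hold-out machinery disables this so that removed edges do
#'   not silently remove their endpoints.
#'
#' @return An object of class `cpi_network`: a list with elements `compounds`,
#'   `proteins` (record data frames), `edges` (collapsed edge table),
#'   `channels` (score channel names) and `provenance`.
#'
#' @examples
#' net <- cpi_network(c("c1", "c2"), c("p1", "p2"),
#'   data.frame(compound = c("c1", "c1", "c2", "c2"),
#'              protein  = c("p1", "p2", "p1", "p2"),
#'              experimental = 1))
#' density_summary(net)$density  # 1: complete bipartite
#' @export
cpi_network <- function(compounds, proteins, edges, provenance = "",
                        drop_isolated = TRUE) {
  compounds <- as_compound_records(compounds)
  proteins <- as_protein_records(proteins)
  if (anyDuplicated(compounds$id))
    stop("duplicate compound ids: ",
         paste(unique(compounds$id[duplicated(compounds$id)]), collapse = ", "))
  if (anyDuplicated(proteins$id))
    stop("duplicate protein ids: ",
         paste(unique(proteins$id[duplicated(proteins$id)]), collapse = ", "))
  clash <- intersect(compounds$id, proteins$id)
  if (length(clash))
    stop("compound/protein id collision: ", paste(clash, collapse = ", "))

  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("compound", "protein") %in% names(edges)))
    stop("edge table needs 'compound' and 'protein' columns")
  channels <- setdiff(names(edges), c("compound", "protein"))
  if (!length(channels)) {
    edges$experimental <- rep(1, nrow(edges))
    channels <- "experimental"
  }
  edges$compound <- as.character(edges$compound)
  edges$protein <- as.character(edges$protein)

  bad_c <- which(!(edges$compound %in% compounds$id))
  if (length(bad_c))
    stop("edge row ", bad_c[1], " references unknown compound id '",
         edges$compound[bad_c[1]], "'")
  bad_p <- which(!(edges$protein %in% proteins$id))
  if (length(bad_p))
    stop("edge row ", bad_p[1], " references unknown protein id '",
         edges$protein[bad_p[1]], "'")
  for (ch in channels) {
    v <- edges[[ch]]
    if (!is.numeric(v)) stop("score channel '", ch, "' is not numeric")
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop("score channel '", ch, "' has values outside [0, 1]")
  }

  # collapse duplicate (compound, protein) rows, keeping max per channel
  key <- edge_key(edges$compound, edges$protein)
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    out <- edges[first, c("compound", "protein"), drop = FALSE]
    f <- factor(key, levels = key[first])
    for (ch in channels)
      out[[ch]] <- as.numeric(tapply(edges[[ch]], f, max, na.rm = TRUE))
    edges <- out
  }
  rownames(edges) <- NULL

  net <- structure(list(compounds = compounds, proteins = proteins,
                        edges = edges, channels = channels,
                        provenance = as.character(provenance)),
                   class = "cpi_network")
  if (drop_isolated) net <- drop_isolated_nodes(net)
  net
}

as_compound_records <- function(x) {
  if (is.character(x)) x <- data.frame(id = x, stringsAsFactors = FALSE)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!"id" %in% names(x)) stop("compound records need an 'id' column")
  x$id <- as.character(x$id)
  for (col in c("smiles", "kegg_c", "kegg_d", "flags"))
    if (is.null(x[[col]])) x[[col]] <- rep(NA_character_, nrow(x))
    else x[[col]] <- as.character(x[[col]])
  if (is.null(x[["heavy_atoms"]])) x$heavy_atoms <- rep(NA_integer_, nrow(x))
  x$heavy_atoms <- as.integer(x$heavy_atoms)
  rownames(x) <- NULL
  x[c("id", "smiles", "kegg_c", "kegg_d", "flags", "heavy_atoms")]
}

as_protein_records <- function(x) {
  if (is.character(x)) x <- data.frame(id = x, stringsAsFactors = FALSE)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!"id" %in% names(x)) stop("protein records need an 'id' column")
  x$id <- as.character(x$id)
  for (col in c("sequence", "pathways"))
    if (is.null(x[[col]])) x[[col]] <- rep(NA_character_, nrow(x))
    else x[[col]] <- as.character(x[[col]])
  rownames(x) <- NULL
  x[c("id", "sequence", "pathways")]
}

drop_isolated_nodes <- function(net) {
  net$compounds <- net$compounds[net$compounds$id %in% net$edges$compound, , drop = FALSE]
  net$proteins <- net$proteins[net$proteins$id %in% net$edges$protein, , drop = FALSE]
  rownames(net$compounds) <- rownames(net$proteins) <- NULL
  net
}

# replace the edge table of a network, keeping node records
set_edges <- function(net, edges, drop_isolated = TRUE) {
  net$edges <- edges
  rownames(net$edges) <- NULL
  if (drop_isolated) net <- drop_isolated_nodes(net)
  net
}

#' @export
print.cpi_network <- function(x, ...) {
  d <- density_summary(x)
  cat("Bipartite CPI network", if (nzchar(x$provenance)) paste0("[", x$provenance, "]"), "\n")
  cat(sprintf("  %d interactions between %d compounds and %d proteins (density %.3g)\n",
              d$n_interactions, d$n_compounds, d$n_proteins, d$density))
  cat("  score channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' Check the structural invariants of a CPI network
#'
#' Asserts strict bipartiteness (disjoint id spaces, every edge endpoint
#' known), edge uniqueness and score bounds. Used defensively in tests; errors
#' describe the first violated invariant.
#'
#' @param net A `cpi_network`.
#' @return `net`, invisibly.
#' @export
validate_cpi_network <- function(net) {
  stopifnot(inherits(net, "cpi_network"))
  if (length(intersect(net$compounds$id, net$proteins$id)))
    stop("compound and protein id spaces overlap")
  if (!all(net$edges$compound %in% net$compounds$id))
    stop("edge references unknown compound")
  if (!all(net$edges$protein %in% net$proteins$id))
    stop("edge references unknown protein")
  if (anyDuplicated(edge_key(net$edges$compound, net$edges$protein)))
    stop("duplicate edges present")
  for (ch in net$channels) {
    v <- net$edges[[ch]]
    if (any(!is.na(v) & (v < 0 | v > 1))) stop("score out of [0,1] in ", ch)
  }
  invisible(net)
}

#' Filter network edges by a confidence score channel
#'
#' Retains edges whose score on `channel` is at least `threshold` (inclusive
#' boundary, so a "medium" STITCH cutoff of 0.4 keeps edges scored exactly
#' 0.4). Nodes left without any edge are dropped.
#'
#' @param net A `cpi_network`.
#' @param channel Score channel name (must exist on the network).
#' @param threshold Numeric cutoff in `[0, 1]`.
#' @return The filtered `cpi_network`.
#' @export
filter_by_confidence <- function(net, channel, threshold) {
  stopifnot(inherits(net, "cpi_network"), threshold >= 0, threshold <= 1)
  if (!channel %in% net$channels)
    stop("unknown score channel '", channel, "'; available: ",
         paste(net$channels, collapse = ", "))
  keep <- !is.na(net$edges[[channel]]) & net$edges[[channel]] >= threshold
  set_edges(net, net$edges[keep, , drop = FALSE])
}

#' Count heavy (non-hydrogen) atoms of SMILES strings
#'
#' Parses each SMILES string and returns the number of non-hydrogen atoms.
#' Unparseable strings yield `NA` with a warning; downstream, the size filter
#' only removes compounds with a *known* small heavy-atom count, so a parse
#' failure never removes a compound.
#'
#' @param smiles Character vector of SMILES strings (`NA` allowed).
#' @return Integer vector of heavy-atom counts (`NA` where unknown).
#' @examples
#' \donttest{
#' heavy_atom_count(c("O", "C1CCCCC1"))  # 1, 6
#' }
#' @export
heavy_atom_count <- function(smiles) {
  n_fail <- 0L
  out <- vapply(as.character(smiles), function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_integer_)
    names(s) <- "x"
    sdf <- try(suppressWarnings(ChemmineR::smiles2sdf(s)), silent = TRUE)
    if (inherits(sdf, "try-error")) { n_fail <<- n_fail + 1L; return(NA_integer_) }
    counts <- ChemmineR::atomcount(sdf)[[1]]
    as.integer(sum(counts[names(counts) != "H"]))
  }, integer(1), USE.NAMES = FALSE)
  if (n_fail > 0)
    warning(n_fail, " SMILES string(s) could not be parsed; heavy-atom count set to NA")
  out
}

#' Remove non-metabolic and uninformative compounds from a CPI network
#'
#' Applies the standard cleanup used to confine a chemical-protein network to
#' naturally occurring metabolites: (a) compounds with fewer than
#' `min_heavy_atoms` heavy atoms (ions and other very small species) are
#' removed, judged from their SMILES where a heavy-atom count is not already
#' recorded; (b) compounds flagged with any category in `drop_categories`
#' (antibiotics; and, for bacterial networks, hormones/transmitters and
#' steroids) are removed; (c) with `require_c_number`, compounds without a
#' KEGG compound ('C') number are removed -- drugs carrying only a 'D' number
#' go, compounds holding both a 'D' and a 'C' number stay. All incident edges
#' are removed with their compounds. The three filters are independent node
#' predicates, so their order is irrelevant and the operation is idempotent.
#'
#' @param net A `cpi_network`.
#' @param min_heavy_atoms Minimum heavy-atom count to keep a compound
#'   (default 5, i.e. compounds with fewer than five heavy atoms go).
#' @param drop_categories Character vector of category flags to remove.
#' @param require_c_number Drop compounds lacking a KEGG 'C' number.
#' @return The cleaned `cpi_network`.
#' @export
cleanup_network <- function(net, min_heavy_atoms = 5,
                            drop_categories = c("antibiotic",
                                                "hormone_transmitter",
                                                "steroid"),
                            require_c_number = TRUE) {
  stopifnot(inherits(net, "cpi_network"))
  cmp <- net$compounds
  if (nrow(cmp) == 0) return(net)

  ha <- cmp$heavy_atoms
  need <- is.na(ha) & !is.na(cmp$smiles) & nzchar(cmp$smiles)
  if (any(need)) ha[need] <- heavy_atom_count(cmp$smiles[need])
  drop_small <- !is.na(ha) & ha < min_heavy_atoms

  flags <- split_multi(cmp$flags)
  drop_flag <- vapply(flags, function(f) any(f %in% drop_categories), logical(1))

  drop_kegg <- rep(FALSE, nrow(cmp))
  if (require_c_number) {
    has_c <- lengths(split_multi(cmp$kegg_c)) > 0
    drop_kegg <- !has_c
  }

  drop <- drop_small | drop_flag | drop_kegg
  keep_ids <- cmp$id[!drop]
  net$compounds <- cmp[!drop, , drop = FALSE]
  net$compounds$heavy_atoms <- as.integer(ha[!drop])
  set_edges(net, net$edges[net$edges$compound %in% keep_ids, , drop = FALSE])
}

#' Remove degree-one nodes from a CPI network
#'
#' Interactions involving a compound or protein with only a single reported
#' interaction cannot take part in any biclique of minimum side two, so they
#' are pruned before enumeration. `single_pass` removes, simultaneously, all
#' nodes whose degree in the input network is one; `fixpoint` repeats the pass
#' until no degree-one node remains; `off` returns the input unchanged.
#'
#' @param net A `cpi_network`.
#' @param mode One of `"single_pass"` (default), `"fixpoint"`, `"off"`.
#' @return The pruned `cpi_network`.
#' @export
prune_degree_one <- function(net, mode = c("single_pass", "fixpoint", "off")) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "cpi_network"))
  if (mode == "off") return(net)
  pass <- function(net) {
    dc <- table(net$edges$compound)
    dp <- table(net$edges$protein)
    bad_c <- names(dc)[dc == 1]
    bad_p <- names(dp)[dp == 1]
    if (!length(bad_c) && !length(bad_p)) return(list(net = net, changed = FALSE))
    keep <- !(net$edges$compound %in% bad_c) & !(net$edges$protein %in% bad_p)
    list(net = set_edges(net, net$edges[keep, , drop = FALSE]), changed = TRUE)
  }
  res <- pass(net)
  if (mode == "fixpoint") {
    while (res$changed) res <- pass(res$net)
  }
  res$net
}

#' Summarize network size and density
#'
#' Density is defined as `D = N_i / (c * p)` where `N_i` is the number of
#' interactions and `c`, `p` the number of compounds and proteins carrying at
#' least one interaction; it is 0 for an empty network by convention.
#'
#' @param net A `cpi_network`.
#' @return A list with `n_interactions`, `n_compounds`, `n_proteins`,
#'   `density`.
#' @export
density_summary <- function(net) {
  stopifnot(inherits(net, "cpi_network"))
  ni <- nrow(net$edges)
  nc <- length(unique(net$edges$compound))
  np <- length(unique(net$edges$protein))
  d <- if (nc == 0 || np == 0) 0 else ni / (nc * np)
  list(n_interactions = ni, n_compounds = nc, n_proteins = np, density = d)
}

#' Degree distribution of one network side
#'
#' @param net A `cpi_network`.
#' @param side `"compound"` or `"protein"`.
#' @return Data frame with columns `degree` and `frequency`; frequencies sum
#'   to the number of nodes on the requested side (stored isolated nodes, if
#'   any, appear as degree 0).
#' @export
degree_distribution <- function(net, side = c("compound", "protein")) {
  side <- match.arg(side)
  stopifnot(inherits(net, "cpi_network"))
  ids <- if (side == "compound") net$compounds$id else net$proteins$id
  inc <- if (side == "compound") net$edges$compound else net$edges$protein
  deg <- table(factor(inc, levels = ids))
  tab <- table(as.integer(deg))
  data.frame(degree = as.integer(names(tab)), frequency = as.integer(tab))
}
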