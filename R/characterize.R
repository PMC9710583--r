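#' Tanimoto similarity of two structural feature sets
#'
#' `|A n B| / |A u B|` over feature sets, the standard chemical similarity
#' index. Accepts character/integer feature vectors (treated as sets) or
#' logical bit vectors of equal length. Two empty fingerprints have
#' similarity 0 by convention.
#'
#' @param a,b Feature sets (vectors) or logical bit vectors.
#' @return Similarity in `[0, 1]`; 1 iff the non-empty fingerprints are
#'   identical.
#' @examples
#' tanimoto_similarity(c(1, 2, 3), c(2, 3, 4))  # 0.5
#' @export
tanimoto_similarity <- function(a, b) {
  if (is.logical(a) && is.logical(b)) {
    if (length(a) != length(b)) stop("bit vectors differ in length")
    inter <- sum(a & b); uni <- sum(a | b)
  } else {
    a <- unique(a); b <- unique(b)
    inter <- length(intersect(a, b)); uni <- length(union(a, b))
  }
  if (uni == 0) 0 else inter / uni
}

#' Structural feature sets for compounds from SMILES
#'
#' Computes per-compound structural feature sets used by
#' [tanimoto_similarity()]. The default `"atompair"` features are ChemmineR
#' atom-pair descriptors (each feature encodes an atom-type pair and its
#' topological distance); `"fp2"`-style hashed path features are available
#' through the `type` flag where ChemmineOB is usable. Unparseable SMILES
#' yield `NULL` entries with a warning; similarity pairs involving them are
#' skipped upstream.
#'
#' @param smiles Named character vector of SMILES (names are compound ids).
#' @param type Feature set type; currently `"atompair"`.
#' @return Named list of feature vectors (`NULL` where parsing failed).
#' @export
compound_fingerprints <- function(smiles, type = c("atompair")) {
  type <- match.arg(type)
  if (is.null(names(smiles)) || any(!nzchar(names(smiles))))
    stop("smiles must be a named vector (names = compound ids)")
  out <- stats::setNames(vector("list", length(smiles)), names(smiles))
  n_fail <- 0L
  for (i in seq_along(smiles)) {
    s <- smiles[[i]]
    if (is.na(s) || !nzchar(s)) { n_fail <- n_fail + 1L; next }
    names(s) <- names(smiles)[i]
    ap <- try(suppressWarnings(
      ChemmineR::sdf2ap(ChemmineR::smiles2sdf(s))), silent = TRUE)
    if (inherits(ap, "try-error")) { n_fail <- n_fail + 1L; next }
    feats <- ChemmineR::ap(ap)[[1]]
    if (length(feats) == 1 && feats[1] == 0) { n_fail <- n_fail + 1L; next }
    out[[i]] <- feats
  }
  if (n_fail)
    warning(n_fail, " compound(s) without usable fingerprint (missing or unparseable SMILES)")
  out
}

#' Local alignment similarity score of two protein sequences
#'
#' Best local alignment score under BLOSUM62 with affine gap penalties
#' (opening 11, extension 1 -- the blastp defaults), computed with
#' Biostrings. The score is symmetric in its arguments; it is a raw alignment
#' score, not an E-value.
#'
#' @param seq_a,seq_b Amino-acid sequence strings.
#' @return Numeric alignment score.
#' @export
protein_similarity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty protein sequence")
  aln <- Biostrings::pairwiseAlignment(Biostrings::AAString(seq_a),
                                       Biostrings::AAString(seq_b),
                                       type = "local",
                                       substitutionMatrix = blosum62(),
                                       gapOpening = 11, gapExtension = 1,
                                       scoreOnly = TRUE)
  as.numeric(aln)
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- get("BLOSUM62", envir = e)
    }
    cache
  }
})

#' Cohen's d standardized effect size
#'
#' `(mean(x) - mean(y)) / s_pooled`, with
#' `s_pooled = sqrt(((n_x - 1) var(x) + (n_y - 1) var(y)) / (n_x + n_y - 2))`.
#'
#' @param x,y Numeric samples of size >= 2 each.
#' @return The effect size; `NaN` with a warning when the pooled standard
#'   deviation is 0.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each group needs at least 2 values")
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  if (sp == 0) {
    if (mean(x) == mean(y)) return(0)
    warning("zero pooled standard deviation; effect size undefined")
    return(NaN)
  }
  (mean(x) - mean(y)) / sp
}

#' Molecular similarity within versus between bicliques
#'
#' Samples `n_pairs` node pairs that share at least one biclique ("within")
#' and `n_pairs` pairs of biclique members that share none ("between"),
#' computes the side-appropriate similarity (Tanimoto over compound feature
#' sets; local alignment score for proteins), and summarizes the contrast
#' with Cohen's d and a two-sided Wilcoxon rank-sum test. Pairs are sampled
#' without replacement and never include self-pairs. The rank-sum p-value
#' uses exact enumeration for group sizes below 50 and the normal
#' approximation with tie correction otherwise.
#'
#' @param net A `cpi_network` whose records carry SMILES (compound side) or
#'   sequences (protein side), unless `features` is given.
#' @param bicliques A `biclique_set` for `net`.
#' @param side `"compound"` or `"protein"`.
#' @param n_pairs Number of pairs per stratum.
#' @param seed Integer seed for the pair sampling.
#' @param features Optional named list overriding the per-node data: feature
#'   sets (compound side) or sequence strings (protein side).
#' @param sim_fun Optional custom similarity `function(feat_a, feat_b)`.
#' @return A list of class `similarity_stats`: `within_values`,
#'   `between_values`, `cohens_d`, `ranksum_p`, `n_pairs`, `n_skipped`.
#' @export
within_between_similarity <- function(net, bicliques,
                                      side = c("compound", "protein"),
                                      n_pairs = 1000, seed = 1,
                                      features = NULL, sim_fun = NULL) {
  side <- match.arg(side)
  stopifnot(inherits(net, "cpi_network"), n_pairs >= 2)
  members <- lapply(bicliques, `[[`,
                    if (side == "compound") "compounds" else "proteins")
  nodes <- sort(unique(unlist(members)))
  if (length(nodes) < 3) stop("too few biclique members on the ", side, " side")

  # node -> set of biclique indices
  idx <- stats::setNames(vector("list", length(nodes)), nodes)
  for (b in seq_along(members))
    for (v in members[[b]]) idx[[v]] <- c(idx[[v]], b)

  all_pairs <- utils::combn(nodes, 2)
  shares <- vapply(seq_len(ncol(all_pairs)), function(j)
    length(intersect(idx[[all_pairs[1, j]]], idx[[all_pairs[2, j]]])) > 0,
    logical(1))
  within_pool <- which(shares)
  between_pool <- which(!shares)
  if (!length(within_pool)) stop("no pair shares a biclique")
  if (!length(between_pool)) stop("no biclique-member pair lies across bicliques")
  if (length(within_pool) < n_pairs || length(between_pool) < n_pairs)
    stop("fewer than n_pairs = ", n_pairs, " admissible pairs ",
         "(within: ", length(within_pool), ", between: ", length(between_pool),
         "); lower n_pairs")

  if (is.null(features)) {
    if (side == "compound") {
      sm <- stats::setNames(net$compounds$smiles, net$compounds$id)[nodes]
      features <- suppressWarnings(compound_fingerprints(sm))
    } else {
      features <- stats::setNames(as.list(net$proteins$sequence),
                                  net$proteins$id)[nodes]
    }
  }
  if (is.null(sim_fun))
    sim_fun <- if (side == "compound") tanimoto_similarity
  else protein_similarity

  sampled <- with_seed(seed, list(within = sample(within_pool, n_pairs),
                                  between = sample(between_pool, n_pairs)))
  n_skipped <- 0L
  eval_pairs <- function(js) {
    vals <- numeric(0)
    for (j in js) {
      fa <- features[[all_pairs[1, j]]]; fb <- features[[all_pairs[2, j]]]
      if (is.null(fa) || is.null(fb) ||
          (length(fa) == 1 && is.na(fa)) || (length(fb) == 1 && is.na(fb))) {
        n_skipped <<- n_skipped + 1L
        next
      }
      vals <- c(vals, sim_fun(fa, fb))
    }
    vals
  }
  within_values <- eval_pairs(sampled$within)
  between_values <- eval_pairs(sampled$between)
  if (length(within_values) < 2 || length(between_values) < 2)
    stop("too few computable similarity pairs after skipping")

  if (length(unique(c(within_values, between_values))) == 1) {
    p <- 1  # fully degenerate: a single tied value in both strata
  } else {
    exact <- min(length(within_values), length(between_values)) < 50
    wt <- suppressWarnings(stats::wilcox.test(within_values, between_values,
                                              alternative = "two.sided",
                                              exact = exact, correct = TRUE))
    p <- wt$p.value
  }
  structure(list(within_values = within_values,
                 between_values = between_values,
                 cohens_d = cohens_d(within_values, between_values),
                 ranksum_p = p,
                 n_pairs = n_pairs, n_skipped = n_skipped),
            class = "similarity_stats")
}

#' @export
print.similarity_stats <- function(x, ...) {
  cat(sprintf("within: n=%d mean=%.3g | between: n=%d mean=%.3g\n",
              length(x$within_values), mean(x$within_values),
              length(x$between_values), mean(x$between_values)))
  cat(sprintf("Cohen's d = %.3f, rank-sum p = %.3g (%d pair(s) skipped)\n",
              x$cohens_d, x$ranksum_p, x$n_skipped))
  invisible(x)
}

#' Hypergeometric pathway over-representation analysis
#'
#' For each pathway with `K` annotated members in a universe of `N`, the
#' upper-tail hypergeometric probability of drawing at least `k` annotated
#' members in a query of size `n` is computed; p-values are adjusted across
#' all tested pathways by Benjamini-Hochberg, and pathways with
#' `p_adjust < alpha` are returned ordered by decreasing fold enrichment
#' `(k/n) / (K/N)`.
#'
#' @param query_proteins Character vector of query protein ids.
#' @param annotation_map Named list: protein id -> character vector of
#'   pathway ids (or a two-column data frame protein/pathway).
#' @param universe Character vector of universe protein ids; defaults to all
#'   annotated proteins in `annotation_map`.
#' @param alpha Adjusted-p cutoff for the returned rows (default 0.01).
#' @return Data frame with columns `pathway_id`, `k`, `n`, `K`, `N_univ`,
#'   `fold_enrichment`, `p_value`, `p_adjust`. The attribute `"full"` holds
#'   the unfiltered table for all tested pathways.
#' @export
hypergeometric_enrichment <- function(query_proteins, annotation_map,
                                      universe = NULL, alpha = 0.01) {
  if (is.data.frame(annotation_map)) {
    annotation_map <- split(as.character(annotation_map[[2]]),
                            as.character(annotation_map[[1]]))
  }
  if (is.null(universe)) universe <- names(annotation_map)
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  query <- intersect(unique(as.character(query_proteins)), universe)

  ann <- annotation_map[intersect(names(annotation_map), universe)]
  pathways <- sort(unique(unlist(ann)))
  if (!length(pathways))
    return(data.frame(pathway_id = character(), k = integer(), n = integer(),
                      K = integer(), N_univ = integer(),
                      fold_enrichment = numeric(), p_value = numeric(),
                      p_adjust = numeric()))
  N <- length(universe)
  n <- length(query)
  rows <- lapply(pathways, function(pw) {
    annotated <- names(ann)[vapply(ann, function(v) pw %in% v, logical(1))]
    K <- length(annotated)
    k <- length(intersect(query, annotated))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fold <- if (n > 0 && K > 0) (k / n) / (K / N) else 0
    data.frame(pathway_id = pw, k = k, n = n, K = K, N_univ = N,
               fold_enrichment = fold, p_value = p, stringsAsFactors = FALSE)
  })
  full <- do.call(rbind, rows)
  full$p_adjust <- stats::p.adjust(full$p_value, method = "BH")
  out <- full[full$p_adjust < alpha, , drop = FALSE]
  out <- out[order(-out$fold_enrichment), , drop = FALSE]
  rownames(out) <- rownames(full) <- NULL
  attr(out, "full") <- full
  out
}
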