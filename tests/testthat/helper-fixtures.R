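# Shared fixtures and independent brute-force oracles.
# The oracles work from the adjacency matrix by exhaustive subset closure and
# by direct application of the extension rule to every non-edge; they share no
# code with the package's enumeration/extension path.

cid <- function(i) sprintf("c%02d", i)
pid <- function(j) sprintf("p%02d", j)

net_from_matrix <- function(M, score = 1) {
  idx <- which(M, arr.ind = TRUE)
  cpi_network(cid(seq_len(nrow(M))), pid(seq_len(ncol(M))),
              data.frame(compound = cid(idx[, 1]), protein = pid(idx[, 2]),
                         experimental = score, stringsAsFactors = FALSE))
}

random_matrix <- function(nc, np, prob, seed) {
  set.seed(seed)
  M <- matrix(runif(nc * np) < prob, nc, np)
  # ensure at least 2 edges so every op is applicable
  while (sum(M) < 2) M[sample(length(M), 1)] <- TRUE
  M
}

random_net <- function(nc, np, prob, seed) net_from_matrix(random_matrix(nc, np, prob, seed))

net_from_edges <- function(compound, protein) {
  cpi_network(unique(compound), unique(protein),
              data.frame(compound = compound, protein = protein,
                         experimental = rep(1, length(compound)),
                         stringsAsFactors = FALSE))
}

# exhaustive maximal biclique oracle: closure of every compound subset
oracle_bicliques <- function(M, c_min = 2, p_min = 2) {
  nc <- nrow(M)
  out <- list(); seen <- character()
  for (mask in seq_len(2^nc - 1)) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, 0:(nc - 1))) > 0)
    P <- which(colSums(M[S, , drop = FALSE]) == length(S))
    if (!length(P)) next
    C <- which(rowSums(M[, P, drop = FALSE]) == length(P))
    key <- paste(paste(C, collapse = ","), paste(P, collapse = ","), sep = ";")
    if (key %in% seen) next
    seen <- c(seen, key)
    if (length(C) >= c_min && length(P) >= p_min)
      out[[length(out) + 1L]] <- list(C = C, P = P)
  }
  out
}

biclique_keys <- function(bicliques) {
  sort(vapply(bicliques, function(b)
    paste(paste(sort(b$compounds), collapse = ","),
          paste(sort(b$proteins), collapse = ","), sep = ";"), character(1)))
}

oracle_biclique_keys <- function(M, c_min = 2, p_min = 2) {
  sort(vapply(oracle_bicliques(M, c_min, p_min), function(b)
    paste(paste(cid(b$C), collapse = ","), paste(pid(b$P), collapse = ","),
          sep = ";"), character(1)))
}

# extension-rule oracle applied to every non-edge of M
oracle_extension_keys <- function(M, c_min = 2, p_min = 2, max_missing = 1,
                                  two_edge_min_side = 4) {
  bcs <- oracle_bicliques(M, c_min, p_min)
  hits <- character()
  non_edges <- which(!M, arr.ind = TRUE)
  for (r in seq_len(nrow(non_edges))) {
    x <- non_edges[r, 1]; q <- non_edges[r, 2]
    for (b in bcs) {
      # compound x joins the protein side, q the missing protein
      if (q %in% b$P && !(x %in% b$C)) {
        n_adj <- sum(M[x, b$P])
        if (n_adj == length(b$P) - 1 && !M[x, q]) {
          hits <- c(hits, paste(cid(x), pid(q))); break
        }
        if (max_missing == 2 && length(b$P) >= two_edge_min_side &&
            n_adj == length(b$P) - 2 && !M[x, q]) {
          hits <- c(hits, paste(cid(x), pid(q))); break
        }
      }
      # protein q joins the compound side, x the missing compound
      if (x %in% b$C && !(q %in% b$P)) {
        n_adj <- sum(M[b$C, q])
        if (n_adj == length(b$C) - 1) {
          hits <- c(hits, paste(cid(x), pid(q))); break
        }
        if (max_missing == 2 && length(b$C) >= two_edge_min_side &&
            n_adj == length(b$C) - 2) {
          hits <- c(hits, paste(cid(x), pid(q))); break
        }
      }
    }
  }
  sort(unique(hits))
}

prediction_keys <- function(preds) sort(unique(paste(preds$compound, preds$protein)))

# two-stage fixture: iteration 1 predicts (c03,p02),(c04,p01); only after
# inserting them does the biclique {c03,c04}x{p01,p02,p03} exist, whose
# extension predicts (c01,p03),(c02,p03); iteration 3 finds nothing.
two_stage_net <- function() {
  net_from_edges(
    compound = cid(c(1, 1, 2, 2, 3, 3, 4, 4)),
    protein = pid(c(1, 2, 1, 2, 1, 3, 2, 3)))
}

# minimal STITCH-dialect fixture file; returns the path
write_stitch_fixture <- function(path, rows) {
  writeLines(c("chemical\tprotein\texperimental\tcombined_score", rows), path)
  path
}

# small KGML pathway document builder
kgml_doc <- function(entries, reactions) {
  ent <- vapply(entries, function(e) {
    sprintf('  <entry id="%s" name="%s" type="%s"%s/>',
            e$id, e$name, e$type,
            if (!is.null(e$reaction)) sprintf(' reaction="%s"', e$reaction) else "")
  }, character(1))
  rx <- vapply(reactions, function(r) {
    subs <- paste(sprintf('    <substrate id="%s" name="x"/>', r$substrates),
                  collapse = "\n")
    prods <- paste(sprintf('    <product id="%s" name="x"/>', r$products),
                   collapse = "\n")
    sprintf('  <reaction id="%s" name="%s" type="irreversible">\n%s\n%s\n  </reaction>',
            r$id, r$name, subs, prods)
  }, character(1))
  paste(c('<?xml version="1.0"?>',
          '<pathway name="path:test" org="test" number="1">',
          ent, rx, "</pathway>"), collapse = "\n")
}

write_kgml_fixture <- function(path, entries, reactions) {
  writeLines(kgml_doc(entries, reactions), path)
  path
}
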