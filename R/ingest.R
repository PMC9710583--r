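#' Create an identifier map
#'
#' Many-to-one mapping from source identifiers (e.g. KEGG 'C' numbers or gene
#' ids) to target identifiers (e.g. STITCH ids). Source ids listed in
#' `unmapped` have no known target; rows referencing them are dropped during
#' ingest and counted.
#'
#' @param entries Named character vector: `names(entries)` are source ids,
#'   values the targets.
#' @param unmapped Character vector of source ids without a target.
#' @return An object of class `id_map`.
#' @export
id_map <- function(entries = character(), unmapped = character()) {
  entries <- entries[nzchar(names(entries))]
  clash <- intersect(names(entries), unmapped)
  if (length(clash))
    stop("ids listed both as mapped and unmapped: ", paste(clash, collapse = ", "))
  structure(list(entries = entries, unmapped = unique(as.character(unmapped))),
            class = "id_map")
}

#' Read an identifier map from a two-column TSV
#'
#' Column 1 is the source id, column 2 the target; rows with an empty target
#' populate the `unmapped` set.
#'
#' @param path Path to the TSV file (with header).
#' @return An `id_map`.
#' @export
read_id_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("id map needs two columns: ", path)
  src <- as.character(tab[[1]])
  tgt <- as.character(tab[[2]])
  tgt[is.na(tgt)] <- ""
  ok <- nzchar(tgt)
  id_map(entries = stats::setNames(tgt[ok], src[ok]), unmapped = src[!ok])
}

apply_id_map_vec <- function(ids, map) {
  hit <- match(ids, names(map$entries))
  out <- ids
  out[!is.na(hit)] <- unname(map$entries[hit[!is.na(hit)]])
  out[ids %in% map$unmapped] <- NA_character_
  out
}

#' Read a STITCH-style chemical-protein links table
#'
#' Expects a TSV (plain or gzip) whose header names a chemical column, a
#' protein column and at least one score column. STITCH distributes integer
#' confidence scores on a 0--1000 scale; any score column containing values
#' above 1 is normalized by division by 1000 to the `[0, 1]` scale. Rows with
#' the wrong field count or non-numeric scores are skipped and logged by line
#' number. An optional identifier map merges equivalent ids (e.g. isoform or
#' salt variants); edges merged by the map collapse keeping the maximum score
#' per channel, and rows whose ids are flagged unmapped are dropped and
#' counted.
#'
#' @param path Path to the links TSV.
#' @param id_map Optional `id_map` applied to both id columns.
#' @return A `cpi_network` with one score channel per score column. The
#'   attribute `"ingest_log"` records skipped line numbers and dropped
#'   unmapped rows.
#' @export
read_stitch_links <- function(path, id_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) < 2) stop("no data rows in ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  lh <- tolower(header)
  chem_col <- which(grepl("chemical|compound", lh))[1]
  prot_col <- which(grepl("protein", lh))[1]
  if (is.na(chem_col)) chem_col <- 1L
  if (is.na(prot_col)) prot_col <- 2L
  score_cols <- setdiff(seq_along(header), c(chem_col, prot_col))
  if (!length(score_cols)) stop("no score column in ", path)

  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  nf <- lengths(fields)
  ok <- nf == length(header)
  skipped <- which(!ok) + 1L
  rows <- fields[ok]
  if (length(rows)) {
    mat <- matrix(unlist(rows), nrow = length(rows), byrow = TRUE)
    scores <- suppressWarnings(
      matrix(as.numeric(mat[, score_cols, drop = FALSE]), nrow = nrow(mat)))
    bad <- rowSums(is.na(scores)) > 0
    skipped <- sort(c(skipped, which(ok)[bad] + 1L))
    mat <- mat[!bad, , drop = FALSE]
    scores <- scores[!bad, , drop = FALSE]
  } else {
    mat <- matrix(character(), 0, length(header))
    scores <- matrix(numeric(), 0, length(score_cols))
  }
  if (length(skipped))
    message("read_stitch_links: skipped ", length(skipped),
            " malformed row(s) at line(s) ",
            paste(utils::head(skipped, 10), collapse = ", "))
  if (nrow(mat) == 0) stop("zero parsable rows in ", path)

  chem <- mat[, chem_col]
  prot <- mat[, prot_col]
  # 0-1000 integer scale -> [0,1]
  for (j in seq_len(ncol(scores)))
    if (any(scores[, j] > 1, na.rm = TRUE)) scores[, j] <- scores[, j] / 1000

  n_unmapped <- 0L
  if (!is.null(id_map)) {
    stopifnot(inherits(id_map, "id_map"))
    chem2 <- apply_id_map_vec(chem, id_map)
    prot2 <- apply_id_map_vec(prot, id_map)
    drop <- is.na(chem2) | is.na(prot2)
    n_unmapped <- sum(drop)
    chem <- chem2[!drop]; prot <- prot2[!drop]
    scores <- scores[!drop, , drop = FALSE]
    if (n_unmapped)
      message("read_stitch_links: dropped ", n_unmapped, " unmapped row(s)")
    if (!length(chem)) stop("all rows unmapped in ", path)
  }

  edges <- data.frame(compound = chem, protein = prot, stringsAsFactors = FALSE)
  ch_names <- make.names(header[score_cols], unique = TRUE)
  for (j in seq_along(score_cols)) edges[[ch_names[j]]] <- pmin(pmax(scores[, j], 0), 1)
  net <- cpi_network(unique(chem), unique(prot), edges,
                     provenance = paste0("stitch:", basename(path)))
  attr(net, "ingest_log") <- list(skipped_lines = skipped,
                                  n_skipped = length(skipped),
                                  n_unmapped_dropped = n_unmapped)
  net
}

#' Read KEGG KGML pathway files into an enzyme-compound network
#'
#' For every `<reaction>` of every pathway file, an edge is created between
#' each enzyme/gene entry mapped to the reaction (via its `reaction`
#' attribute) and each substrate or product compound entry. Direction is
#' discarded: both substrates and products link to the reaction's enzymes.
#' Only KEGG 'C'-number compound entries enter the network; glycan (`gl:`)
#' and drug (`dr:`) entries as well as `group` and map-link entries are
#' ignored. Edges are deduplicated across reactions and pathway files, so the
#' result is independent of file ordering. All edges carry a `kegg` score
#' channel fixed at 1.
#'
#' @param paths Character vector of KGML file paths.
#' @return A `cpi_network` (compound partition: KEGG C numbers; protein
#'   partition: enzyme/gene identifiers as given in the KGML `name`
#'   attributes). The attribute `"ingest_log"` counts reactions skipped for
#'   lack of an enzyme mapping.
#' @export
read_kgml_network <- function(paths) {
  stopifnot(length(paths) >= 1)
  all_edges <- list()
  n_skipped <- 0L
  for (path in paths) {
    doc <- tryCatch(xml2::read_xml(path),
                    error = function(e) stop("cannot parse KGML file ", path,
                                             ": ", conditionMessage(e)))
    entries <- xml2::xml_find_all(doc, ".//entry")
    e_id <- xml2::xml_attr(entries, "id")
    e_type <- xml2::xml_attr(entries, "type")
    e_name <- xml2::xml_attr(entries, "name")
    e_reac <- xml2::xml_attr(entries, "reaction")

    # entry id -> C numbers (compound entries only; drop glycans/drugs)
    cpd_ids <- lapply(seq_along(entries), function(i) {
      if (!identical(e_type[i], "compound")) return(character())
      toks <- strsplit(e_name[i], "\\s+")[[1]]
      sub("^cpd:", "", toks[grepl("^cpd:C\\d+$", toks)])
    })
    names(cpd_ids) <- e_id

    # reaction name token -> enzyme identifiers
    enz_idx <- which(e_type %in% c("enzyme", "gene") & !is.na(e_reac) & nzchar(e_reac))
    rxn2enz <- new.env(hash = TRUE, parent = emptyenv())
    for (i in enz_idx) {
      enz_names <- strsplit(e_name[i], "\\s+")[[1]]
      for (rn in strsplit(e_reac[i], "\\s+")[[1]]) {
        cur <- if (exists(rn, envir = rxn2enz, inherits = FALSE))
          get(rn, envir = rxn2enz) else character()
        assign(rn, unique(c(cur, enz_names)), envir = rxn2enz)
      }
    }

    reactions <- xml2::xml_find_all(doc, ".//reaction")
    for (rx in reactions) {
      rn_toks <- strsplit(xml2::xml_attr(rx, "name"), "\\s+")[[1]]
      enzymes <- unique(unlist(lapply(rn_toks, function(rn)
        if (exists(rn, envir = rxn2enz, inherits = FALSE))
          get(rn, envir = rxn2enz) else character())))
      if (!length(enzymes)) { n_skipped <- n_skipped + 1L; next }
      part_ids <- c(xml2::xml_attr(xml2::xml_find_all(rx, "./substrate"), "id"),
                    xml2::xml_attr(xml2::xml_find_all(rx, "./product"), "id"))
      cids <- unique(unlist(lapply(part_ids,
                                   function(i) cpd_ids[[i]] %||% character())))
      if (!length(cids)) next
      all_edges[[length(all_edges) + 1L]] <-
        expand.grid(compound = cids, protein = enzymes,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (!length(all_edges)) stop("no enzyme-compound edges found in KGML input")
  edges <- dedup_pairs(do.call(rbind, all_edges))
  edges <- edges[order(edges$compound, edges$protein), , drop = FALSE]
  edges$kegg <- 1
  net <- cpi_network(unique(edges$compound), unique(edges$protein), edges,
                     provenance = "kegg:kgml")
  attr(net, "ingest_log") <- list(n_reactions_skipped = n_skipped)
  net
}

#' Read a two-column compound-protein pair list
#'
#' Used for validation sets of positive or negative pairs. Rows with missing
#' fields are skipped with a message; duplicates are removed.
#'
#' @param path Path to a TSV with header and at least two id columns
#'   (compound, protein in that order).
#' @return Data frame with columns `compound`, `protein`.
#' @export
read_pair_list <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) == 0) return(pairs_df())
  if (ncol(tab) < 2) stop("pair list needs two columns: ", path)
  cmp <- as.character(tab[[1]]); prt <- as.character(tab[[2]])
  bad <- is.na(cmp) | is.na(prt) | !nzchar(cmp) | !nzchar(prt)
  if (any(bad))
    message("read_pair_list: skipped ", sum(bad), " malformed row(s)")
  dedup_pairs(pairs_df(cmp[!bad], prt[!bad]))
}

#' Write a CPI network as a TSV edge list with a JSON sidecar
#'
#' The TSV carries columns `compound`, `protein` and one column per score
#' channel; the sidecar `<path>.json` records the density summary, channels
#' and provenance.
#'
#' @param net A `cpi_network`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "cpi_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  side <- c(density_summary(net),
            list(channels = net$channels, provenance = net$provenance))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a CPI network written by [write_network()]
#'
#' @param path TSV path as written by [write_network()].
#' @return A `cpi_network`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("compound", "protein") %in% names(tab)))
    stop("expected 'compound' and 'protein' columns in ", path)
  tab$compound <- as.character(tab$compound)
  tab$protein <- as.character(tab$protein)
  prov <- ""
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path)
    prov <- side$provenance %||% ""
  }
  cpi_network(unique(tab$compound), unique(tab$protein), tab, provenance = prov)
}
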