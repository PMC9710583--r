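# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical internal key for a (compound, protein) pair
edge_key <- function(compound, protein) paste(compound, protein, sep = "\r")

# round half away from zero (the documented hold-out rounding rule)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# pipe-separated multi-valued TSV fields -> list of character vectors
split_multi <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  lapply(strsplit(x, "|", fixed = TRUE), function(v) v[nzchar(v)])
}

join_multi <- function(lst) {
  vapply(lst, function(v) paste(v, collapse = "|"), character(1))
}

# sorted-vector intersection preserving order (used in the enumeration hot path)
intersect_sorted <- function(a, b) a[a %in% b]

pairs_df <- function(compound = character(), protein = character()) {
  data.frame(compound = as.character(compound), protein = as.character(protein),
             stringsAsFactors = FALSE)
}

# deduplicate a pair table, keeping first occurrence
dedup_pairs <- function(pairs) {
  pairs[!duplicated(edge_key(pairs$compound, pairs$protein)), , drop = FALSE]
}
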