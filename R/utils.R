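# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical unordered edge key
#'
#' Databases report both orientations of an undirected interaction; edges are
#' stored once under the lexicographically sorted identifier pair.
#' @param a,b character vectors of endpoint identifiers
#' @return list with components `a`, `b` (sorted pairs) and `key`
#' @keywords internal
#' @noRd
canonical_pair <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  lo <- ifelse(a <= b, a, b)
  hi <- ifelse(a <= b, b, a)
  list(a = lo, b = hi, key = paste(lo, hi, sep = "\r"))
}

# Locale-independent (byte-order) character sort, so emitted tables are
# reproducible across platforms.
sort_c <- function(x) sort(x, method = "radix")

# ';'-joined set fields: split, union, and rejoin in sorted order so that
# provenance merging is order-independent and files are byte-reproducible.
split_set <- function(x) {
  if (length(x) == 0) return(character(0))
  out <- unlist(strsplit(x[!is.na(x)], ";", fixed = TRUE), use.names = FALSE)
  out <- out[nzchar(out)]
  sort_c(unique(out))
}

join_set <- function(x) paste(split_set(x), collapse = ";")

# Union-merge the ';'-joined set column `x` grouped by `key`, preserving the
# order of first appearance of each key.
merge_set_by <- function(x, key) {
  vapply(split(x, factor(key, levels = unique(key))), join_set, character(1))
}

# Empty canonical edge table (shared schema for species and merged networks).
empty_edges <- function() {
  data.frame(
    id_a = character(0), id_b = character(0), origin = character(0),
    source_dbs = character(0), detection_methods = character(0),
    pubmed_ids = character(0), stringsAsFactors = FALSE
  )
}

# Collapse an edge table to one row per canonical pair with union-merged
# provenance and origin sets.
collapse_edges <- function(edges) {
  if (nrow(edges) == 0) return(empty_edges())
  cp <- canonical_pair(edges$id_a, edges$id_b)
  keyf <- factor(cp$key, levels = unique(cp$key))
  first <- !duplicated(cp$key)
  out <- data.frame(
    id_a = cp$a[first], id_b = cp$b[first],
    origin = merge_set_by(edges$origin, cp$key),
    source_dbs = merge_set_by(edges$source_dbs, cp$key),
    detection_methods = merge_set_by(edges$detection_methods, cp$key),
    pubmed_ids = merge_set_by(edges$pubmed_ids, cp$key),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$id_a, out$id_b, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Deterministic per-stage / per-replicate seed derivation: fold a salt string
# into the base seed so independent stages draw from unrelated streams while
# remaining a pure function of (seed, salt).  Result stays below 2^31.
derive_seed <- function(seed, salt) {
  h <- sum(utf8ToInt(as.character(salt)) * seq_along(utf8ToInt(as.character(salt))))
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483647)
}

stop_stage <- function(stage, msg, call. = FALSE) {
  stop(sprintf("[%s] %s", stage, msg), call. = call.)
}
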