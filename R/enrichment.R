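#' Gene-set collections and the GMT format
#'
#' A gene-set collection is a named list of unique member-id vectors
#' with an optional per-term description, matching the GMT file layout
#' (term, description, tab-separated member ids).
#'
#' @param sets Named list of character vectors (term id -> members).
#' @param description Optional named character vector of term
#'   descriptions.
#' @return An object of class `"gene_set_collection"`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop_invalid("sets must be a uniquely named list")
  if (any(lengths(sets) == 0L))
    stop_invalid("every gene set must be non-empty")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(description))
    description <- setNames(rep("", length(sets)), names(sets))
  structure(sets, description = description[names(sets)],
            class = "gene_set_collection")
}

#' @rdname gene_set_collection
#' @param path GMT file path.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad))
    stop_invalid("malformed GMT: lines with fewer than 3 fields")
  ids <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- ids
  gene_set_collection(sets, setNames(desc, ids))
}

#' @rdname gene_set_collection
#' @param collection A `gene_set_collection`.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "description")
  lines <- vapply(names(collection), function(id)
    paste(c(id, desc[[id]], collection[[id]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each term, tests whether the query list (e.g. differentially
#' expressed peptides) overlaps the term's members more than expected
#' under hypergeometric sampling from the universe:
#' `p = P(overlap >= k)` with the term intersected with the universe
#' beforehand.  The default universe in this package's pipeline is the
#' detectable measured panel, not the genome.  P-values are BH-adjusted
#' across terms.
#'
#' @param query Character vector of query ids (must lie in `universe`).
#' @param collection A [gene_set_collection()].
#' @param universe Character vector of background ids.
#' @return Data frame of class `"enrichment_result"`, sorted by
#'   adjusted p: `term`, `description`, `k` (overlap), `K` (set size in
#'   universe), `n` (query size), `N` (universe size), `p`, `adj_p`,
#'   `overlap` (list column of overlapping ids).
#' @export
ora <- function(query, collection, universe) {
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (!all(query %in% universe))
    stop_invalid("query must be a subset of the universe")
  if (length(query) == 0L) {
    warning("empty query; returning no enrichment results", call. = FALSE)
    return(structure(
      data.frame(term = character(0), description = character(0),
                 k = integer(0), K = integer(0), n = integer(0),
                 N = integer(0), p = numeric(0), adj_p = numeric(0)),
      class = c("enrichment_result", "data.frame")))
  }
  N <- length(universe); n <- length(query)
  desc <- attr(collection, "description")
  rows <- lapply(names(collection), function(term) {
    members <- intersect(collection[[term]], universe)
    K <- length(members)
    ov <- intersect(query, members)
    k <- length(ov)
    p <- if (K == 0L) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    list(term = term, description = unname(desc[[term]]),
         k = k, K = K, n = n, N = N, p = p, overlap = ov)
  })
  out <- data.frame(
    term = vapply(rows, `[[`, character(1), "term"),
    description = vapply(rows, `[[`, character(1), "description"),
    k = vapply(rows, `[[`, integer(1), "k"),
    K = vapply(rows, `[[`, integer(1), "K"),
    n = vapply(rows, `[[`, integer(1), "n"),
    N = vapply(rows, `[[`, integer(1), "N"),
    p = vapply(rows, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE
  )
  out$adj_p <- bh_adjust(out$p)
  out$overlap <- I(lapply(rows, `[[`, "overlap"))
  out <- out[order(out$adj_p, out$p, out$term), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Jaccard term network of enriched terms
#'
#' Builds the edge list of the enrichment term network: nodes are
#' significant terms (adjusted p below `alpha`), node weight is
#' `-log10(adj_p)`, and each pair of terms is connected with the
#' Jaccard coefficient `|A ∩ B| / |A ∪ B|` of their overlap-member
#' sets; edges below `min_jaccard` are dropped.
#'
#' @param results An `enrichment_result` from [ora()].
#' @param min_jaccard Minimum Jaccard coefficient to keep an edge.
#' @param alpha Significance cut-off on adjusted p (default 0.05).
#' @return A list with `nodes` (term, weight) and `edges` (term_a,
#'   term_b, jaccard).
#' @export
term_network <- function(results, min_jaccard = 0, alpha = 0.05) {
  sig <- results[results$adj_p < alpha, , drop = FALSE]
  nodes <- data.frame(term = sig$term,
                      weight = -log10(pmax(sig$adj_p, 1e-300)),
                      stringsAsFactors = FALSE)
  edges <- data.frame(term_a = character(0), term_b = character(0),
                      jaccard = numeric(0), stringsAsFactors = FALSE)
  if (nrow(sig) >= 2L) {
    combs <- utils::combn(seq_len(nrow(sig)), 2L)
    jac <- apply(combs, 2L, function(ix) {
      a <- sig$overlap[[ix[1]]]; b <- sig$overlap[[ix[2]]]
      u <- length(union(a, b))
      if (u == 0L) 0 else length(intersect(a, b)) / u
    })
    edges <- data.frame(term_a = sig$term[combs[1, ]],
                        term_b = sig$term[combs[2, ]],
                        jaccard = jac, stringsAsFactors = FALSE)
    edges <- edges[edges$jaccard >= min_jaccard, , drop = FALSE]
    rownames(edges) <- NULL
  }
  list(nodes = nodes, edges = edges)
}

#' Write enrichment results and term-network edges as TSV
#'
#' @param results An `enrichment_result`.
#' @param path Output TSV for the per-term table.
#' @export
write_enrichment <- function(results, path) {
  out <- results[, c("term", "description", "k", "K", "n", "N", "p", "adj_p")]
  out$overlap <- vapply(results$overlap, paste, character(1), collapse = ",")
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_enrichment
#' @param network A [term_network()] result.
#' @export
write_term_network <- function(network, path) {
  write.table(network$edges, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
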