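#' Load a protein-protein edge table
#'
#' Reads one of three tab-separated dialects into a normalised undirected
#' edge table:
#' \describe{
#'   \item{biogrid}{BioGRID export with columns "Official Symbol Interactor A",
#'     "Official Symbol Interactor B" and "Experimental System".}
#'   \item{string}{STRING link export with columns protein1, protein2 and
#'     combined_score; scores on the 0-1000 database scale are divided by
#'     1000 so confidence is always in [0, 1].}
#'   \item{literature}{two-column hand-curated list (protein_a, protein_b).}
#' }
#' Accessions are matched case-insensitively (stored upper-case); self-loops
#' are dropped and (A,B)/(B,A) duplicates collapse to a single edge.
#'
#' @param path path to the tab-separated file (with header).
#' @param source one of \code{"biogrid"}, \code{"string"},
#'   \code{"literature"}.
#' @return A data.frame of class \code{"edge_table"}: \code{protein_a},
#'   \code{protein_b} (a <= b lexicographically), \code{source},
#'   \code{evidence_method} (NA for string/literature), \code{confidence}
#'   (NA for biogrid/literature).
#' @export
load_edge_table <- function(path, source = c("biogrid", "string", "literature")) {
  source <- match.arg(source)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (source == "biogrid") {
    need <- c("Official Symbol Interactor A", "Official Symbol Interactor B",
              "Experimental System")
    if (!all(need %in% names(df)))
      stop("load_edge_table: not a BioGRID export (missing ",
           paste(setdiff(need, names(df)), collapse = ", "), ")")
    ed <- data.frame(protein_a = df[[need[1]]], protein_b = df[[need[2]]],
                     source = "biogrid", evidence_method = df[[need[3]]],
                     confidence = NA_real_, stringsAsFactors = FALSE)
  } else if (source == "string") {
    need <- c("protein1", "protein2", "combined_score")
    if (!all(need %in% names(df)))
      stop("load_edge_table: not a STRING link export (missing ",
           paste(setdiff(need, names(df)), collapse = ", "), ")")
    conf <- as.numeric(df$combined_score)
    if (any(conf > 1, na.rm = TRUE)) conf <- conf / 1000
    ed <- data.frame(protein_a = df$protein1, protein_b = df$protein2,
                     source = "string", evidence_method = NA_character_,
                     confidence = conf, stringsAsFactors = FALSE)
  } else {
    if (ncol(df) < 2)
      stop("load_edge_table: literature list needs two columns")
    ed <- data.frame(protein_a = df[[1]], protein_b = df[[2]],
                     source = "literature", evidence_method = NA_character_,
                     confidence = NA_real_, stringsAsFactors = FALSE)
  }
  normalise_edges(ed)
}

normalise_edges <- function(ed) {
  ed$protein_a <- toupper(trimws(ed$protein_a))
  ed$protein_b <- toupper(trimws(ed$protein_b))
  ed <- ed[ed$protein_a != ed$protein_b, , drop = FALSE]  # drop self-loops
  swap <- ed$protein_a > ed$protein_b
  tmp <- ed$protein_a[swap]
  ed$protein_a[swap] <- ed$protein_b[swap]
  ed$protein_b[swap] <- tmp
  ed <- ed[!duplicated(ed[, c("protein_a", "protein_b", "source",
                              "evidence_method")]), , drop = FALSE]
  rownames(ed) <- NULL
  class(ed) <- c("edge_table", "data.frame")
  ed
}

#' Default evidence filter rules
#'
#' BioGRID: only physical interactions — Affinity Capture-RNA, Protein-RNA
#' and Proximity Label-MS evidence is disregarded. STRING: confidence
#' strictly greater than 0.4. Literature edges always pass.
#'
#' @param exclude_methods BioGRID evidence methods to drop.
#' @param min_confidence strict lower bound on STRING confidence.
#' @return A list of rules for \code{\link{filter_edges}}.
#' @export
default_edge_rules <- function(exclude_methods = c("Affinity Capture-RNA",
                                                   "Protein-RNA",
                                                   "Proximity Label-MS"),
                               min_confidence = 0.4) {
  list(exclude_methods = exclude_methods, min_confidence = min_confidence)
}

#' Apply evidence filters to an edge table
#'
#' @param edges an \code{edge_table}.
#' @param rules list from \code{\link{default_edge_rules}}.
#' @return The filtered \code{edge_table} (never adds edges; idempotent).
#' @export
filter_edges <- function(edges, rules = default_edge_rules()) {
  keep <- rep(TRUE, nrow(edges))
  bg <- edges$source == "biogrid"
  keep[bg] <- !(edges$evidence_method[bg] %in% rules$exclude_methods)
  st <- edges$source == "string"
  keep[st] <- !is.na(edges$confidence[st]) &
    edges$confidence[st] > rules$min_confidence
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("edge_table", "data.frame")
  out
}

#' Assemble the interactome network over a fixed node set
#'
#' Builds an undirected igraph whose vertices are exactly \code{node_set}
#' (e.g. the co-recovered proteins) and whose edges are the supplied edges
#' with both endpoints in the node set. The same interaction reported by
#' several sources becomes one edge with the union of sources as provenance;
#' the \code{line_type} attribute follows the network-figure legend: solid
#' for database evidence, dotted for literature-only.
#'
#' @param node_set character vector of protein accessions (nonempty).
#' @param ... any number of \code{edge_table}s.
#' @param categories optional named character vector (protein -> interactome
#'   category) stored as a vertex attribute.
#' @return An \code{igraph} object with vertex attributes \code{name},
#'   \code{category} and edge attributes \code{provenance},
#'   \code{line_type}.
#' @export
build_network <- function(node_set, ..., categories = NULL) {
  if (length(node_set) == 0) stop("build_network: empty node set")
  node_set <- sort(unique(toupper(node_set)))
  tabs <- list(...)
  ed <- if (length(tabs)) do.call(rbind, lapply(tabs, as.data.frame))
        else data.frame(protein_a = character(), protein_b = character(),
                        source = character())
  ed <- ed[ed$protein_a %in% node_set & ed$protein_b %in% node_set, ,
           drop = FALSE]
  if (nrow(ed)) {
    key <- paste(ed$protein_a, ed$protein_b, sep = "|")
    prov <- vapply(split(ed$source, key),
                   function(s) paste(sort(unique(s)), collapse = ","), "")
    pairs <- do.call(rbind, strsplit(names(prov), "|", fixed = TRUE))
    g <- igraph::graph_from_data_frame(
      data.frame(from = pairs[, 1], to = pairs[, 2],
                 provenance = unname(prov), stringsAsFactors = FALSE),
      directed = FALSE, vertices = node_set)
    db <- grepl("biogrid|string", igraph::E(g)$provenance)
    igraph::E(g)$line_type <- ifelse(db, "solid", "dotted")
  } else {
    g <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(node_set)
  }
  if (!is.null(categories)) {
    igraph::V(g)$category <-
      unname(categories[match(igraph::V(g)$name, toupper(names(categories)))])
  }
  g
}

#' Write a network as GraphML and an edge-list TSV
#'
#' @param g igraph from \code{\link{build_network}}.
#' @param graphml_path,edges_path output paths (either may be NULL to skip).
#' @return Invisibly, the paths written.
#' @export
write_network <- function(g, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(edges_path)) {
    el <- igraph::as_data_frame(g, what = "edges")
    utils::write.table(el, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(graphml_path, edges_path))
}

#' Read a gene-set collection in GMT format
#'
#' @param path path to a GMT file.
#' @return Named list of character vectors (members upper-cased, unique).
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(sets, function(s) unique(toupper(s)))
}

#' Hypergeometric over-representation test
#'
#' For each gene set, tests whether the query (e.g. co-recovered proteins)
#' overlaps the set more than expected by chance from the universe:
#' p = P(X >= k) under Hypergeometric(N, K, n) with N the universe size,
#' K the in-universe set size, n the query size and k the observed overlap.
#' P-values are Benjamini-Hochberg adjusted across sets. The recommended
#' universe is all proteins surviving the replicate-presence filter
#' (detection-conditioned background).
#'
#' @param query character vector of accessions, a subset of \code{universe}.
#' @param gene_sets named list of character vectors (e.g. from
#'   \code{\link{read_gmt}}); members are intersected with the universe.
#' @param universe character vector of accessions defining the background.
#' @return A data.frame of class \code{"ora_result"}: \code{set_id},
#'   \code{overlap}, \code{set_size}, \code{query_size},
#'   \code{universe_size}, \code{p}, \code{q}, ordered by p.
#' @export
overrepresentation_test <- function(query, gene_sets, universe) {
  query <- unique(toupper(query))
  universe <- unique(toupper(universe))
  if (!all(query %in% universe))
    stop("overrepresentation_test: query must be a subset of the universe")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(gene_sets), function(id) {
    set <- intersect(unique(toupper(gene_sets[[id]])), universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, overlap = k, set_size = K, query_size = n,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("ora_result", "data.frame")
  res
}
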