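# Global association network: merge per-subset edge lists, detect modules
# with Girvan-Newman edge betweenness (dendrogram cut at maximum
# modularity), score partitions with Newman-Girvan Q, and test modularity
# against rewired null networks. Clustering and betweenness run on the
# unweighted graph; correlation weights are kept as edge annotations.

.check_asv_ids <- function(ids) {
  bad <- !is.character(ids) | is.na(ids) | !nzchar(ids) | grepl("\\s", ids)
  assert_that(!any(bad), "malformed ASV ids in edge list: %s",
              paste(utils::head(ids[bad], 3), collapse = ", "))
}

#' Merge per-subset edge lists into one global undirected network
#'
#' Takes the significant positive edges of each (ocean, fraction, layer)
#' subset and unions them. A pair occurring in several subsets collapses to
#' a single edge whose weight is the maximum r across subsets and whose
#' \code{subsets} attribute records the provenance.
#'
#' @param edge_lists list of data.frames as returned by
#'   \code{\link{significant_edges}} (columns asv_i, asv_j, r, subset).
#' @return an undirected simple \code{igraph} with edge attributes
#'   \code{weight} (max r) and \code{subsets}.
#' @export
merge_subset_networks <- function(edge_lists) {
  assert_that(is.list(edge_lists) && length(edge_lists) >= 1,
              "need at least one edge list")
  df <- do.call(rbind, lapply(edge_lists, function(e)
    e[, c("asv_i", "asv_j", "r", "subset")]))
  .check_asv_ids(c(df$asv_i, df$asv_j))
  a <- pmin(df$asv_i, df$asv_j)
  b <- pmax(df$asv_i, df$asv_j)
  key <- paste(a, b, sep = "\r")
  agg_r <- tapply(df$r, key, max)
  agg_sub <- tapply(as.character(df$subset), key, function(s)
    paste(sort(unique(s)), collapse = ";"))
  keys <- sort(names(agg_r))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  edges <- data.frame(from = vapply(parts, `[`, "", 1),
                      to = vapply(parts, `[`, "", 2),
                      weight = as.numeric(agg_r[keys]),
                      subsets = as.character(agg_sub[keys]),
                      stringsAsFactors = FALSE)
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

#' Newman-Girvan modularity of a partition
#'
#' \deqn{Q = \sum_c (L_c/m - (d_c/2m)^2)} on the unweighted graph, where
#' L_c is the number of edges inside module c, d_c the total degree of its
#' nodes and m the edge count.
#'
#' @param network an \code{igraph}.
#' @param membership named vector node -> module id covering all nodes (or
#'   an unnamed vector in vertex order).
#' @return Q in [-0.5, 1].
#' @export
modularity_q <- function(network, membership) {
  vn <- igraph::V(network)$name
  if (!is.null(names(membership))) {
    assert_that(all(vn %in% names(membership)),
                "membership missing for nodes: %s",
                paste(utils::head(setdiff(vn, names(membership)), 3), collapse = ", "))
    membership <- membership[vn]
  } else {
    assert_that(length(membership) == length(vn),
                "membership must cover all nodes")
  }
  m <- igraph::ecount(network)
  assert_that(m >= 1, "modularity undefined for an edgeless graph")
  ends <- igraph::ends(network, igraph::E(network), names = FALSE)
  memb <- as.character(membership)
  same <- memb[ends[, 1]] == memb[ends[, 2]]
  deg <- igraph::degree(network)
  q <- 0
  for (c in unique(memb)) {
    l_c <- sum(same & memb[ends[, 1]] == c)
    d_c <- sum(deg[memb == c])
    q <- q + l_c / m - (d_c / (2 * m))^2
  }
  q
}

#' Girvan-Newman edge-betweenness module detection
#'
#' Iteratively removes the edge of maximum betweenness and cuts the
#' resulting dendrogram at the partition of maximum modularity (igraph's
#' \code{cluster_edge_betweenness}, run unweighted). Singleton components
#' become their own modules.
#'
#' @param network an \code{igraph}.
#' @return object of class \code{module_assignment}: list(membership (named
#'   integer), modularity_Q, n_modules).
#' @export
edge_betweenness_clusters <- function(network) {
  assert_that(igraph::vcount(network) >= 1, "network is empty")
  if (igraph::ecount(network) == 0) {
    memb <- setNames(seq_len(igraph::vcount(network)), igraph::V(network)$name)
    return(structure(list(membership = memb, modularity_Q = NA_real_,
                          n_modules = length(memb)),
                     class = "module_assignment"))
  }
  # igraph warns that membership is cut at the maximum-modularity level,
  # which is exactly the convention we want
  cl <- suppressWarnings(igraph::cluster_edge_betweenness(network,
                                                          weights = NULL,
                                                          directed = FALSE))
  memb <- setNames(as.integer(igraph::membership(cl)), igraph::V(network)$name)
  structure(list(membership = memb,
                 modularity_Q = modularity_q(network, memb),
                 n_modules = length(unique(memb))),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("Module assignment: %d nodes in %d modules, Q = %.4f\n",
              length(x$membership), x$n_modules, x$modularity_Q))
  invisible(x)
}

# One endpoint-resampling rewire: each endpoint of each edge is replaced by
# a uniformly random node with probability p; loops and multi-edges are then
# dropped. Edge count before simplification is preserved, degrees are not.
.rewire_endpoint <- function(network, p) {
  n <- igraph::vcount(network)
  ends <- igraph::ends(network, igraph::E(network), names = FALSE)
  flip <- matrix(runif(length(ends)) < p, ncol = 2)
  ends[flip] <- sample.int(n, sum(flip), replace = TRUE)
  g <- igraph::graph_from_edgelist(ends, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::V(g)$name <- igraph::V(network)$name
  igraph::simplify(g)
}

#' Rewiring null test for network modularity
#'
#' Generates \code{n} shuffled instances of the network, re-clusters each
#' with edge betweenness, and reports the proportion of null modularities at
#' least as extreme (>=) as the observed one. Mode \code{"endpoint"}
#' resamples each edge endpoint with probability \code{p_rewire} (preserving
#' edge count, not degrees); mode \code{"degseq"} uses degree-preserving
#' double-edge swaps. Multi-edges and self-loops arising from rewiring are
#' dropped before clustering.
#'
#' @param network an \code{igraph} with >= 2 edges.
#' @param n number of shuffled instances (default 999; must be >= 1).
#' @param p_rewire endpoint resampling probability (default 0.5).
#' @param seed integer seed.
#' @param mode "endpoint" (default) or "degseq".
#' @return list(null_p, q_obs, q_null (length n), n).
#' @export
rewire_null_test <- function(network, n = 999, p_rewire = 0.5, seed = 1,
                             mode = c("endpoint", "degseq")) {
  mode <- match.arg(mode)
  assert_that(n >= 1, "n must be >= 1")
  assert_that(igraph::ecount(network) >= 2, "network needs >= 2 edges")
  obs <- edge_betweenness_clusters(network)
  q_null <- numeric(n)
  with_seed(derive_seed(seed, "rewire"), {
    for (b in seq_len(n)) {
      g <- if (mode == "endpoint") {
        .rewire_endpoint(network, p_rewire)
      } else {
        igraph::simplify(igraph::rewire(
          network, igraph::keeping_degseq(niter = igraph::ecount(network) * 5)))
      }
      q_null[b] <- if (igraph::ecount(g) == 0) NA_real_ else
        edge_betweenness_clusters(g)$modularity_Q
    }
  })
  ok <- !is.na(q_null)
  list(null_p = sum(q_null[ok] >= obs$modularity_Q) / sum(ok),
       q_obs = obs$modularity_Q, q_null = q_null, n = n)
}

#' Write a network as an edge-list TSV and a membership TSV
#'
#' @param network an \code{igraph} from \code{\link{merge_subset_networks}}.
#' @param assignment a \code{module_assignment} (optional).
#' @param edge_path,membership_path output paths.
#' @return invisibly the written paths.
#' @export
write_network_tsv <- function(network, assignment = NULL, edge_path,
                              membership_path = NULL) {
  e <- igraph::as_data_frame(network, what = "edges")
  write.table(e, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(assignment) && !is.null(membership_path)) {
    write.table(data.frame(asv_id = names(assignment$membership),
                           module_id = unname(assignment$membership)),
                membership_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(edge_path, membership_path))
}
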