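#' Jaccard similarity of two gene sets
#'
#' @param a,b non-empty character vectors (treated as sets).
#' @return |a intersect b| / |a union b|, in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("Jaccard similarity is undefined for an empty set")
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Pathway similarity network over significant pathways
#'
#' Computes pairwise Jaccard similarities on the full annotated gene
#' sets (redundancy is an annotation property, so sets are not
#' restricted to network-covered genes) and keeps pairs with similarity
#' `>= cutoff`. Significant pathways with no qualifying partner remain
#' as singleton nodes.
#'
#' @param significant named list of [pathway_set()] objects (the
#'   significant pathways).
#' @param cutoff Jaccard threshold, default 0.3.
#' @return object of class `similarity_network`: list with `nodes`
#'   (pathway ids), `edges` (data.frame a, b, jaccard), `cutoff`.
#' @export
build_similarity_network <- function(significant, cutoff = 0.3) {
  ids <- unname(vapply(significant, `[[`, "", "id"))
  ids_order <- order(ids)
  significant <- significant[ids_order]
  ids <- ids[ids_order]
  n <- length(ids)
  ea <- character(0); eb <- character(0); ej <- numeric(0)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        sim <- jaccard(significant[[i]]$genes, significant[[j]]$genes)
        if (sim >= cutoff) {
          ea <- c(ea, ids[i]); eb <- c(eb, ids[j]); ej <- c(ej, sim)
        }
      }
    }
  }
  structure(list(nodes = ids,
                 edges = data.frame(a = ea, b = eb, jaccard = ej,
                                    stringsAsFactors = FALSE),
                 cutoff = cutoff),
            class = "similarity_network")
}

#' Markov clustering of the pathway similarity network
#'
#' Standard MCL on the Jaccard-weighted adjacency: self-loops equal to
#' each node's maximum incident weight (1 for isolated nodes) are added,
#' columns are normalized to a stochastic matrix, and expansion (matrix
#' power) alternates with inflation (elementwise power + renormalize)
#' and pruning of entries below `pruning` until the matrix is idempotent
#' within `tol`. Clusters are the connected components of the limit
#' matrix's nonzero structure; singletons form their own clusters.
#' Output is deterministic: members and cluster order are sorted by
#' pathway id.
#'
#' @param net a `similarity_network`.
#' @param inflation inflation exponent (default 2).
#' @param expansion expansion power (default 2).
#' @param pruning entries below this are zeroed each cycle (1e-5).
#' @param tol idempotence tolerance on the max absolute change (1e-8).
#' @param max_iter iteration cap (default 200).
#' @return object of class `cluster_assignment`: list with `clusters`
#'   (named list of member id vectors) and `n_clusters`.
#' @export
mcl_cluster <- function(net, inflation = 2, expansion = 2,
                        pruning = 1e-5, tol = 1e-8, max_iter = 200L) {
  stopifnot(inherits(net, "similarity_network"), inflation > 1)
  ids <- net$nodes
  n <- length(ids)
  if (n == 0L) {
    return(structure(list(clusters = list(), n_clusters = 0L),
                     class = "cluster_assignment"))
  }
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(net$edges) > 0L) {
    ia <- match(net$edges$a, ids)
    ib <- match(net$edges$b, ids)
    M[cbind(ia, ib)] <- net$edges$jaccard
    M[cbind(ib, ia)] <- net$edges$jaccard
  }
  loop <- apply(M, 2, max)
  diag(M) <- ifelse(loop > 0, loop, 1)
  normalize <- function(m) sweep(m, 2, colSums(m), "/")
  M <- normalize(M)
  for (it in seq_len(max_iter)) {
    Mexp <- M
    for (e in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- normalize(Mexp^inflation)
    Minf[Minf < pruning] <- 0
    Minf <- normalize(Minf)
    delta <- max(abs(Minf - M))
    M <- Minf
    if (delta < tol) break
    if (it == max_iter) {
      stop("Markov clustering did not converge within ", max_iter,
           " iterations (residual ", signif(delta, 3), ")")
    }
  }
  g <- igraph::graph_from_adjacency_matrix(M > 0 | t(M) > 0,
                                           mode = "undirected")
  comp <- igraph::components(g)$membership
  clusters <- split(ids, comp[ids])
  clusters <- clusters[order(vapply(clusters, min, ""))]
  names(clusters) <- sprintf("C%03d", seq_along(clusters))
  clusters <- lapply(clusters, function(m) sort(unname(m)))
  structure(list(clusters = clusters, n_clusters = length(clusters)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Cluster assignment:", x$n_clusters, "cluster(s) over",
      length(unlist(x$clusters)), "pathway(s)\n")
  invisible(x)
}

#' Display selection for the enrichment map
#'
#' Each cluster is represented by its most significant member (lowest
#' FDR; ties broken by higher PS, then pathway id). Clusters are ranked
#' by their representative's FDR and at most `max_clusters` are shown;
#' within a cluster at most `max_members` members with the lowest FDR
#' are retained.
#'
#' @param assignment a `cluster_assignment`.
#' @param results enrichment table from [pathway_enrichment()].
#' @param max_clusters display cap on clusters (default 20).
#' @param max_members display cap on members per cluster (default 10).
#' @return data.frame: pathway_id, cluster_id, representative (logical),
#'   cluster_rank, fdr, ps; ordered by cluster rank then member FDR.
#' @export
select_display <- function(assignment, results, max_clusters = 20L,
                           max_members = 10L) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (assignment$n_clusters == 0L) {
    return(data.frame(pathway_id = character(0), cluster_id = character(0),
                      representative = logical(0), cluster_rank = integer(0),
                      fdr = numeric(0), ps = numeric(0),
                      stringsAsFactors = FALSE))
  }
  idx <- stats::setNames(seq_len(nrow(results)), results$pathway_id)
  per_cluster <- lapply(names(assignment$clusters), function(cid) {
    members <- assignment$clusters[[cid]]
    ri <- idx[members]
    if (anyNA(ri)) stop("cluster member missing from results: ",
                        paste(members[is.na(ri)], collapse = ", "))
    ord <- order(results$fdr[ri], -results$ps[ri], members)
    members <- members[ord]
    ri <- ri[ord]
    data.frame(pathway_id = members, cluster_id = cid,
               representative = seq_along(members) == 1L,
               fdr = results$fdr[ri], ps = results$ps[ri],
               stringsAsFactors = FALSE)
  })
  rep_fdr <- vapply(per_cluster, function(d) d$fdr[1L], 0)
  rep_ps <- vapply(per_cluster, function(d) d$ps[1L], 0)
  rep_id <- vapply(per_cluster, function(d) d$pathway_id[1L], "")
  rank_ord <- order(rep_fdr, -rep_ps, rep_id)
  per_cluster <- per_cluster[utils::head(rank_ord, max_clusters)]
  out <- do.call(rbind, lapply(seq_along(per_cluster), function(r) {
    d <- utils::head(per_cluster[[r]], max_members)
    d$cluster_rank <- r
    d
  }))
  rownames(out) <- NULL
  out[, c("pathway_id", "cluster_id", "representative", "cluster_rank",
          "fdr", "ps")]
}
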