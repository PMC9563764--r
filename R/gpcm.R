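#' Normalize gene identifiers
#'
#' Strips surrounding whitespace and upper-cases symbol identifiers.
#' Purely numeric identifiers (Entrez-style) are kept as digit strings.
#' No mapping between symbol and Entrez namespaces is attempted; a run is
#' expected to use a single namespace throughout.
#'
#' @param x character vector of raw identifiers.
#' @return character vector of normalized identifiers.
#' @export
normalize_gene_id <- function(x) {
  x <- trimws(as.character(x))
  numeric_id <- grepl("^[0-9]+$", x)
  x[!numeric_id] <- toupper(x[!numeric_id])
  x
}

#' Load an interaction edge table
#'
#' Reads a TSV of gene-gene interactions with at least two columns
#' (gene_a, gene_b) and an optional third provenance column (origin,
#' e.g. a database name). Identifiers are normalized, self-loops are
#' dropped (with a message reporting the count), and duplicate
#' (unordered pair, origin) rows are collapsed.
#'
#' @param path path to a tab-separated file. A header line starting with
#'   `gene_a` (case-insensitive) is skipped.
#' @param source one of `"pathway"`, `"ppi"`, `"tf"`: the interaction
#'   class this table contributes to the crosstalk map.
#' @return data.frame with columns `a`, `b`, `source`, `origin`. The
#'   unordered pair is stored canonically with `a <= b`.
#' @export
load_edges <- function(path, source = c("pathway", "ppi", "tf")) {
  source <- match.arg(source)
  if (!file.exists(path)) {
    stop("edge table not readable: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("edge table is empty: ", path)
    return(data.frame(a = character(0), b = character(0),
                      source = character(0), origin = character(0),
                      stringsAsFactors = FALSE))
  }
  first <- tolower(trimws(strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]][1L]))
  start <- if (identical(first, "gene_a")) 2L else 1L
  if (start > length(lines)) {
    warning("edge table has a header but no rows: ", path)
    return(data.frame(a = character(0), b = character(0),
                      source = character(0), origin = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[start:length(lines)], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- which(nf < 2L)[1L] + start - 1L
    stop("edge table row with fewer than 2 fields at line ", bad,
         " of ", path)
  }
  a <- normalize_gene_id(vapply(fields, `[[`, "", 1L))
  b <- normalize_gene_id(vapply(fields, `[[`, "", 2L))
  origin <- vapply(fields, function(f) {
    if (length(f) >= 3L) trimws(f[[3L]]) else ""
  }, "")
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    stop("empty gene identifier in ", path)
  }
  self <- a == b
  if (any(self)) {
    message(sum(self), " self-loop(s) dropped from ", basename(path))
  }
  a2 <- pmin(a, b)
  b2 <- pmax(a, b)
  df <- data.frame(a = a2[!self], b = b2[!self], source = source,
                   origin = origin[!self], stringsAsFactors = FALSE)
  unique(df)
}

#' Keep interactions reported by multiple sources
#'
#' Retains unordered gene pairs whose provenance spans at least
#' `min_sources` distinct origin labels. Repeated listings inside a
#' single origin do not count. This is the reliability filter applied to
#' protein-protein interactions before they enter the crosstalk map.
#'
#' @param edges edge data.frame as returned by [load_edges()].
#' @param min_sources minimum number of distinct origins (default 2).
#' @return filtered edge data.frame.
#' @export
filter_ppi_by_source_count <- function(edges, min_sources = 2) {
  stopifnot(min_sources >= 1)
  if (nrow(edges) == 0L) return(edges)
  key <- paste(edges$a, edges$b, sep = "\r")
  n_origin <- vapply(split(edges$origin, key),
                     function(o) length(unique(o)), 0L)
  keep <- key %in% names(n_origin)[n_origin >= min_sources]
  edges[keep, , drop = FALSE]
}

#' Keep interactions touching at least one pathway gene
#'
#' An edge is retained if either endpoint belongs to the union of all
#' pathway gene sets. Applied to PPI and TF-gene regulation tables so the
#' crosstalk map stays anchored to annotated pathways.
#'
#' @param edges edge data.frame.
#' @param pathway_genes character vector: union of all pathway members.
#' @return filtered edge data.frame.
#' @export
filter_edges_by_pathway_membership <- function(edges, pathway_genes) {
  pathway_genes <- normalize_gene_id(pathway_genes)
  keep <- edges$a %in% pathway_genes | edges$b %in% pathway_genes
  edges[keep, , drop = FALSE]
}

#' Assemble the global pathway crosstalk map
#'
#' Merges pathway-derived interactions, PPIs and TF-gene regulations into
#' one simple undirected graph. Parallel edges contributed by several
#' sources are collapsed into a single edge that retains all provenance
#' tags; direction is discarded. Nodes are the genes incident to at least
#' one edge, ordered lexicographically so the transition operator is
#' reproducible bit-for-bit. The column-normalized adjacency operator
#' \eqn{W} (with \eqn{W_{ij} = 1/\mathrm{deg}(j)} for every edge
#' \eqn{\{i,j\}}) drives the random-walk propagation.
#'
#' @param pathway_edges,ppi_edges,tf_edges edge data.frames (any may be
#'   `NULL` or empty); source-specific filters are assumed to have been
#'   applied already.
#' @return an object of class `gpcm`: list with `nodes` (sorted ids),
#'   `edges` (one row per unordered pair with comma-joined `source` and
#'   `origin` tags), `degree` (named integer), and `W` (sparse
#'   `dgCMatrix`, every column summing to exactly 1).
#' @export
build_gpcm <- function(pathway_edges = NULL, ppi_edges = NULL,
                       tf_edges = NULL) {
  parts <- Filter(function(e) !is.null(e) && nrow(e) > 0L,
                  list(pathway_edges, ppi_edges, tf_edges))
  if (length(parts) == 0L) stop("GPCM has no edges")
  all_edges <- do.call(rbind, parts)
  key <- paste(all_edges$a, all_edges$b, sep = "\r")
  first <- !duplicated(key)
  merged <- all_edges[first, c("a", "b"), drop = FALSE]
  src <- vapply(split(all_edges$source, key),
                function(s) paste(sort(unique(s)), collapse = ","), "")
  org <- vapply(split(all_edges$origin, key), function(o) {
    o <- unique(o[nzchar(o)])
    paste(sort(o), collapse = ",")
  }, "")
  merged$source <- src[key[first]]
  merged$origin <- org[key[first]]
  merged <- merged[order(merged$a, merged$b), , drop = FALSE]
  rownames(merged) <- NULL

  nodes <- sort(unique(c(merged$a, merged$b)))
  n <- length(nodes)
  ia <- match(merged$a, nodes)
  ib <- match(merged$b, nodes)
  adj <- Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia),
                              x = 1, dims = c(n, n),
                              dimnames = list(nodes, nodes))
  degree <- Matrix::colSums(adj)
  W <- adj %*% Matrix::Diagonal(n, 1 / degree)
  dimnames(W) <- list(nodes, nodes)
  structure(list(nodes = nodes, edges = merged,
                 degree = stats::setNames(as.integer(degree), nodes),
                 W = methods::as(W, "CsparseMatrix")),
            class = "gpcm")
}

#' @export
print.gpcm <- function(x, ...) {
  cat("Global pathway crosstalk map\n")
  cat("  nodes:", length(x$nodes), "\n")
  cat("  edges:", nrow(x$edges), "\n")
  cat("  degree: min", min(x$degree), "/ median", stats::median(x$degree),
      "/ max", max(x$degree), "\n")
  invisible(x)
}

#' Construct a pathway gene set
#'
#' @param id pathway identifier.
#' @param name display name (defaults to the id).
#' @param source_db annotation source label.
#' @param genes character vector of member genes (normalized, deduplicated).
#' @return object of class `pathway_set`.
#' @export
pathway_set <- function(id, name = id, source_db = "", genes) {
  genes <- unique(normalize_gene_id(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) stop("pathway ", id, " has no genes")
  structure(list(id = as.character(id), name = as.character(name),
                 source_db = as.character(source_db), genes = genes),
            class = "pathway_set")
}

#' Read pathway gene sets from a GMT file
#'
#' Standard GMT: one set per line, `id TAB description TAB gene TAB ...`.
#'
#' @param path path to the GMT file.
#' @param source_db label recorded on every set (default: file name).
#' @return named list of [pathway_set()] objects.
#' @export
read_gmt <- function(path, source_db = basename(path)) {
  if (!file.exists(path)) stop("GMT file not readable: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop("GMT line ", i, " has fewer than 3 fields in ", path)
    }
    pathway_set(id = f[[1L]], name = f[[2L]], source_db = source_db,
                genes = f[-(1:2)])
  })
  names(sets) <- vapply(sets, `[[`, "", "id")
  if (anyDuplicated(names(sets))) stop("duplicate pathway ids in ", path)
  sets
}

#' Write pathway gene sets to a GMT file
#'
#' @param pathways list of [pathway_set()] objects.
#' @param path output path.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(pathways, function(p) {
    paste(c(p$id, p$name, p$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a crosstalk map as a node/edge TSV pair
#'
#' The transition operator is always rebuilt from the edge list on read,
#' never stored.
#'
#' @param gpcm a `gpcm` object.
#' @param nodes_path,edges_path output paths.
#' @export
write_gpcm <- function(gpcm, nodes_path, edges_path) {
  utils::write.table(data.frame(gene = gpcm$nodes,
                                degree = gpcm$degree[gpcm$nodes]),
                     nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  out <- gpcm$edges
  names(out)[1:2] <- c("gene_a", "gene_b")
  utils::write.table(out, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edges_path)
}

#' Rebuild a crosstalk map from its serialized edge table
#'
#' @param edges_path path written by [write_gpcm()].
#' @return a `gpcm` object (identical to the one serialized).
#' @export
read_gpcm <- function(edges_path) {
  df <- utils::read.delim(edges_path, stringsAsFactors = FALSE)
  edges <- data.frame(a = normalize_gene_id(df$gene_a),
                      b = normalize_gene_id(df$gene_b),
                      source = df$source, origin = df$origin,
                      stringsAsFactors = FALSE)
  # split multi-tag rows back into per-source rows so build_gpcm re-merges
  src <- strsplit(edges$source, ",", fixed = TRUE)
  rep_idx <- rep(seq_len(nrow(edges)), lengths(src))
  expanded <- edges[rep_idx, , drop = FALSE]
  expanded$source <- unlist(src)
  build_gpcm(pathway_edges = expanded)
}
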