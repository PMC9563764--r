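#' Specification for a synthetic benchmark world
#'
#' Describes a scale-free gene network, an overlapping pathway
#' collection sampled from graph neighborhoods, and a DE profile with an
#' optional planted risk pathway. Defaults emulate the qualitative
#' features of the real crosstalk map at desk scale: power-law degrees,
#' most genes in more than one pathway, and background expression noise
#' with lognormal fold changes and uniform P-values.
#'
#' @param n_genes network size (default 2000).
#' @param attachment edges added per node in preferential attachment
#'   (default 3; the graph is connected by construction).
#' @param n_pathways number of gene sets (default 200).
#' @param size_range inclusive pathway size range (default c(10, 50)).
#' @param planted_pathway id of the pathway carrying signal (optional).
#' @param effect_size signal strength `e >= 0`. Planted members draw
#'   |log2 FC| ~ Normal(2e, 0.25^2) with random sign and
#'   P ~ Uniform(0, 0.01^e); `e = 1` is the strong-signal regime and
#'   `e = 0` makes planted genes exactly background.
#' @param sigma natural-log SD of background fold changes
#'   (FC ~ exp(Normal(0, sigma)); default log(2), i.e. unit SD on the
#'   log2 scale).
#' @param seed RNG seed controlling every stochastic choice.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 2000L, attachment = 3L,
                         n_pathways = 200L, size_range = c(10L, 50L),
                         planted_pathway = NULL, effect_size = 0,
                         sigma = log(2), seed = 1L) {
  stopifnot(n_genes >= 2, attachment >= 1, n_pathways >= 1,
            length(size_range) == 2L, size_range[1] >= 1,
            size_range[2] >= size_range[1], effect_size >= 0, sigma > 0)
  structure(list(n_genes = as.integer(n_genes),
                 attachment = as.integer(attachment),
                 n_pathways = as.integer(n_pathways),
                 size_range = as.integer(size_range),
                 planted_pathway = planted_pathway,
                 effect_size = effect_size, sigma = sigma,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic scale-free crosstalk map
#'
#' Connected preferential-attachment graph with heavy-tailed degrees,
#' mimicking the topology of real molecular interaction maps. Node
#' names are `G0001 ...`; edges carry synthetic provenance tags drawn in
#' roughly the proportions the three interaction classes contribute to
#' the real map. Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [fixture_spec()].
#' @return a `gpcm`.
#' @export
make_network <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed, {
    g <- igraph::sample_pa(spec$n_genes, power = 1, m = spec$attachment,
                           directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    width <- max(4L, nchar(as.character(spec$n_genes)))
    nm <- sprintf(paste0("G%0", width, "d"), seq_len(spec$n_genes))
    src <- sample(c("pathway", "ppi", "tf"), nrow(el), replace = TRUE,
                  prob = c(0.84, 0.15, 0.01))
    a <- nm[el[, 1]]; b <- nm[el[, 2]]
    edges <- data.frame(a = pmin(a, b), b = pmax(a, b), source = src,
                        origin = "synthetic", stringsAsFactors = FALSE)
    edges <- unique(edges)
    build_gpcm(pathway_edges = edges[edges$source == "pathway", ],
               ppi_edges = edges[edges$source == "ppi", ],
               tf_edges = edges[edges$source == "tf", ])
  })
}

#' Sample overlapping pathways as graph neighborhoods
#'
#' Each pathway grows from a random seed node by repeatedly absorbing
#' random frontier neighbors until its target size. Neighborhood
#' sampling (rather than uniform gene draws) creates the gene-sharing
#' and crosstalk structure between pathways that the propagation method
#' exploits. Deterministic for a fixed `spec$seed`.
#'
#' @param gpcm network from [make_network()].
#' @param spec a [fixture_spec()].
#' @return named list of [pathway_set()] objects (ids `PW001 ...`).
#' @export
make_pathways <- function(gpcm, spec) {
  stopifnot(inherits(gpcm, "gpcm"), inherits(spec, "fixture_spec"))
  g <- igraph::graph_from_data_frame(gpcm$edges[, c("a", "b")],
                                     directed = FALSE,
                                     vertices = gpcm$nodes)
  adj <- igraph::as_adj_list(g)
  adj <- lapply(adj, function(v) names(v))
  .with_seed(spec$seed + 1L, {
    sets <- lapply(seq_len(spec$n_pathways), function(k) {
      size <- sample(seq(spec$size_range[1], spec$size_range[2]), 1L)
      size <- min(size, length(gpcm$nodes))
      members <- sample(gpcm$nodes, 1L)
      frontier <- setdiff(adj[[members]], members)
      while (length(members) < size) {
        if (length(frontier) == 0L) {
          pool <- setdiff(gpcm$nodes, members)
          nxt <- sample(pool, 1L)
        } else {
          nxt <- frontier[sample.int(length(frontier), 1L)]
        }
        members <- c(members, nxt)
        frontier <- setdiff(union(frontier, adj[[nxt]]), members)
      }
      pathway_set(id = sprintf("PW%03d", k),
                  name = sprintf("Synthetic pathway %d", k),
                  source_db = "synthetic", genes = members)
    })
    names(sets) <- vapply(sets, `[[`, "", "id")
    sets
  })
}

#' Generate a synthetic DE profile, optionally with planted signal
#'
#' Every network gene receives a background fold change
#' FC ~ exp(Normal(0, sigma)) and P ~ Uniform(0, 1). When
#' `spec$planted_pathway` is set and `effect_size > 0`, that pathway's
#' member genes are overwritten with elevated |log2 FC| and small
#' P-values (see [fixture_spec()]). Deterministic for a fixed
#' `spec$seed`.
#'
#' @param gpcm network from [make_network()].
#' @param pathways list from [make_pathways()].
#' @param spec a [fixture_spec()].
#' @return a `de_profile` covering all network genes.
#' @export
make_profile <- function(gpcm, pathways, spec) {
  stopifnot(inherits(gpcm, "gpcm"), inherits(spec, "fixture_spec"))
  genes <- gpcm$nodes
  n <- length(genes)
  .with_seed(spec$seed + 2L, {
    fc <- exp(stats::rnorm(n, 0, spec$sigma))
    p <- stats::runif(n)
    tab <- data.frame(gene = genes, fc = fc, p = p,
                      stringsAsFactors = FALSE)
    e <- spec$effect_size
    if (!is.null(spec$planted_pathway) && e > 0) {
      if (!spec$planted_pathway %in% names(pathways)) {
        stop("planted pathway id unknown: ", spec$planted_pathway)
      }
      members <- intersect(pathways[[spec$planted_pathway]]$genes, genes)
      m <- length(members)
      mag <- pmax(stats::rnorm(m, 2 * e, 0.25), 0)
      sgn <- sample(c(-1, 1), m, replace = TRUE)
      idx <- match(members, tab$gene)
      tab$fc[idx] <- 2^(sgn * mag)
      tab$p[idx] <- stats::runif(m, 0, 0.01^e)
    }
    structure(list(table = tab, alpha = 1L, beta = 1L),
              class = "de_profile")
  })
}

#' Write a fixture to the pipeline's input formats
#'
#' Emits the same formats the pipeline reads -- per-class edge TSVs, a
#' GMT file, and a profile TSV (log2 fold-change scale) -- so fixtures
#' double as format documentation.
#'
#' @param gpcm,pathways,profile fixture components.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths.
#' @export
write_fixture <- function(gpcm, pathways, profile, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(edges = file.path(dir, "edges.tsv"),
             gmt = file.path(dir, "pathways.gmt"),
             profile = file.path(dir, "profile.tsv"))
  ed <- gpcm$edges
  # one row per provenance tag so the combined-file reader can re-split
  src <- strsplit(ed$source, ",", fixed = TRUE)
  ed <- ed[rep(seq_len(nrow(ed)), lengths(src)), ]
  ed$source <- unlist(src)
  # PPI rows are listed under two synthetic origins so they survive the
  # pipeline's >= 2-distinct-sources reliability filter
  ppi <- ed$source == "ppi"
  if (any(ppi)) {
    dup <- ed[ppi, ]
    ed$origin[ppi] <- "synthA"
    dup$origin <- "synthB"
    ed <- rbind(ed, dup)
    ed <- ed[order(ed$a, ed$b, ed$source, ed$origin), ]
  }
  utils::write.table(
    data.frame(gene_a = ed$a, gene_b = ed$b, source = ed$source,
               origin = ed$origin),
    paths[["edges"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(pathways, paths[["gmt"]])
  utils::write.table(
    data.frame(gene = profile$table$gene,
               log2fc = log2(profile$table$fc),
               pvalue = profile$table$p),
    paths[["profile"]], sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}
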