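# small in-code builders shared across test files

edge_df <- function(a, b, source = "pathway", origin = "") {
  data.frame(a = pmin(a, b), b = pmax(a, b), source = source,
             origin = origin, stringsAsFactors = FALSE)
}

# simple named graphs
toy_gpcm <- function(pairs) {
  a <- vapply(pairs, `[[`, "", 1L)
  b <- vapply(pairs, `[[`, "", 2L)
  build_gpcm(pathway_edges = edge_df(a, b))
}

path_graph <- function(nodes) {
  n <- length(nodes)
  toy_gpcm(Map(c, nodes[-n], nodes[-1]))
}

cycle_graph <- function(n) {
  nodes <- sprintf("N%02d", seq_len(n))
  toy_gpcm(c(Map(c, nodes[-n], nodes[-1]), list(c(nodes[n], nodes[1]))))
}

# connected Erdos-Renyi-ish graph: random tree plus extra edges
random_connected_gpcm <- function(n, extra = n, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("N%03d", seq_len(n))
  parent <- c(NA, vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L))
  a <- nodes[parent[-1]]
  b <- nodes[-1]
  for (k in seq_len(extra)) {
    ij <- sample.int(n, 2L)
    a <- c(a, nodes[ij[1]])
    b <- c(b, nodes[ij[2]])
  }
  keep <- a != b
  build_gpcm(pathway_edges = edge_df(a[keep], b[keep]))
}

de_vector_from <- function(values) {
  structure(list(values = values, L = length(values), alpha = 1L,
                 beta = 1L), class = "de_vector")
}

write_tsv_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# shared small fixture world for pipeline-level tests
small_world <- function(seed = 11, effect = 0, planted = "PW001") {
  sp <- fixture_spec(n_genes = 250L, attachment = 3L, n_pathways = 25L,
                     size_range = c(8L, 20L), planted_pathway = planted,
                     effect_size = effect, seed = seed)
  net <- make_network(sp)
  pw <- make_pathways(net, sp)
  prof <- make_profile(net, pw, sp)
  list(spec = sp, net = net, pathways = pw, profile = prof)
}
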