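test_that("jaccard similarity follows the set definition", {
  expect_equal(jaccard(c("A", "B"), c("A", "B")), 1)
  expect_equal(jaccard(c("A", "B"), c("C", "D")), 0)
  expect_equal(jaccard(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_error(jaccard(character(0), "A"), "empty")
})

sets_for <- function(genes_list) {
  out <- lapply(names(genes_list), function(id)
    pathway_set(id, genes = genes_list[[id]]))
  names(out) <- names(genes_list)
  out
}

test_that("similarity network applies the >= cutoff rule", {
  pw <- sets_for(list(P1 = c("A", "B", "C"), P2 = c("A", "B", "C"),
                      P3 = c("X", "Y")))
  net <- build_similarity_network(pw, cutoff = 0.3)
  expect_equal(nrow(net$edges), 1L)   # duplicated pair only
  expect_setequal(net$nodes, c("P1", "P2", "P3"))  # singleton retained

  # cutoff = 1 keeps only identical sets
  net1 <- build_similarity_network(pw, cutoff = 1)
  expect_equal(net1$edges$jaccard, 1)
  # cutoff = 0 connects every pair (>= semantics, including disjoint)
  net0 <- build_similarity_network(pw, cutoff = 0)
  expect_equal(nrow(net0$edges), 3L)
})

test_that("MCL respects components and isolates singletons", {
  pw <- sets_for(list(P1 = c("A", "B", "C"), P2 = c("A", "B", "D"),
                      P3 = c("X", "Y", "Z"), P4 = c("X", "Y", "W"),
                      P5 = c("Q", "R")))
  net <- build_similarity_network(pw, cutoff = 0.3)
  cl <- mcl_cluster(net)
  members <- lapply(cl$clusters, sort)
  expect_equal(cl$n_clusters, 3L)
  expect_true(list(c("P1", "P2")) %in% members)
  expect_true(list(c("P3", "P4")) %in% members)
  expect_true(list("P5") %in% members)
  # partition: every pathway exactly once
  expect_setequal(unlist(members), names(pw))
  expect_equal(anyDuplicated(unlist(members)), 0L)

  # all-singleton network
  iso <- build_similarity_network(sets_for(list(S1 = "A", S2 = "B")),
                                  cutoff = 0.3)
  cli <- mcl_cluster(iso)
  expect_equal(cli$n_clusters, 2L)
})

test_that("weak bridge between two triangles splits at inflation 2", {
  # hand-built barbell similarity network: triangles of weight 1 joined
  # by a single 0.31 edge
  net <- structure(list(
    nodes = sprintf("P%d", 1:6),
    edges = data.frame(
      a = c("P1", "P1", "P2", "P4", "P4", "P5", "P3"),
      b = c("P2", "P3", "P3", "P5", "P6", "P6", "P4"),
      jaccard = c(1, 1, 1, 1, 1, 1, 0.31)),
    cutoff = 0.3), class = "similarity_network")
  cl <- mcl_cluster(net, inflation = 2)
  got <- lapply(cl$clusters, sort)
  expect_equal(cl$n_clusters, 2L)
  expect_true(list(c("P1", "P2", "P3")) %in% got)
  expect_true(list(c("P4", "P5", "P6")) %in% got)

  # oracle: reference MCL loop written out longhand, independent of the
  # package implementation
  ids <- net$nodes
  M <- matrix(0, 6, 6, dimnames = list(ids, ids))
  for (k in seq_len(nrow(net$edges))) {
    M[net$edges$a[k], net$edges$b[k]] <- net$edges$jaccard[k]
    M[net$edges$b[k], net$edges$a[k]] <- net$edges$jaccard[k]
  }
  diag(M) <- apply(M, 2, max)
  M <- sweep(M, 2, colSums(M), "/")
  for (i in 1:100) {
    M <- M %*% M
    M <- M^2
    M <- sweep(M, 2, colSums(M), "/")
    M[M < 1e-5] <- 0
    M <- sweep(M, 2, colSums(M), "/")
  }
  # attractor rows and their supported columns, merged when overlapping
  groups <- lapply(which(rowSums(M) > 0), function(i) ids[M[i, ] > 0])
  merged <- list()
  for (g in groups) {
    hit <- vapply(merged, function(m) length(intersect(m, g)) > 0, TRUE)
    merged <- c(merged[!hit],
                list(sort(union(g, unlist(merged[hit])))))
  }
  expect_setequal(lapply(merged, paste, collapse = ","),
                  list("P1,P2,P3", "P4,P5,P6"))
})

test_that("raising the cutoff never merges separated components", {
  pw <- sets_for(list(P1 = LETTERS[1:10], P2 = LETTERS[3:12],
                      P3 = paste0("x", 1:10), P4 = paste0("x", 2:11)))
  lo <- mcl_cluster(build_similarity_network(pw, cutoff = 0.2))
  hi <- mcl_cluster(build_similarity_network(pw, cutoff = 0.6))
  # each high-cutoff cluster sits inside one low-cutoff cluster
  lo_of <- function(id) names(Filter(function(m) id %in% m,
                                     lo$clusters))[1]
  for (m in hi$clusters) {
    expect_equal(length(unique(vapply(m, lo_of, ""))), 1L)
  }
})

test_that("display selection ranks and caps clusters and members", {
  n_path <- 60
  ids <- sprintf("P%02d", seq_len(n_path))
  results <- data.frame(pathway_id = ids,
                        fdr = seq(0.0001, 0.05, length.out = n_path),
                        ps = rev(seq_len(n_path)))
  # 25 clusters: one big (14 members), the rest small
  clusters <- c(list(ids[1:14]),
                split(ids[15:60], rep(1:23, length.out = 46)))
  names(clusters) <- sprintf("C%03d", seq_along(clusters))
  assignment <- structure(list(clusters = clusters,
                               n_clusters = length(clusters)),
                          class = "cluster_assignment")
  disp <- select_display(assignment, results)
  expect_lte(length(unique(disp$cluster_id)), 20L)
  expect_lte(max(table(disp$cluster_id)), 10L)
  # representative of the big cluster is its lowest-FDR member
  big <- disp[disp$cluster_id == "C001", ]
  expect_equal(big$pathway_id[big$representative], "P01")
  expect_equal(nrow(big), 10L)
  # clusters ranked by representative FDR
  rep_rows <- disp[disp$representative, ]
  expect_false(is.unsorted(rep_rows$fdr))

  # small case: everything shown
  small <- structure(list(clusters = list(C001 = ids[1:2],
                                          C002 = ids[3:4]),
                          n_clusters = 2L), class = "cluster_assignment")
  expect_equal(nrow(select_display(small, results)), 4L)
})
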