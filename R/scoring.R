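#' Gene risk scores
#'
#' Integrates propagated crosstalk effects with differential-expression
#' scores: \eqn{RS_j = \sum_i C_{ji} DE_i}, the matrix-vector product
#' `C %*% DE`. A gene's risk is the crosstalk-weighted sum of every
#' profile gene's DE evidence, so genes with modest expression change
#' can still score highly through network neighbors.
#'
#' @param cm a `crosstalk_matrix` whose seed order equals the DE-vector
#'   gene order (hard error otherwise).
#' @param de a `de_vector`.
#' @return named numeric vector over all network genes (class
#'   `risk_scores`).
#' @export
compute_risk_scores <- function(cm, de) {
  stopifnot(inherits(cm, "crosstalk_matrix"), inherits(de, "de_vector"))
  if (!identical(cm$seeds, names(de$values))) {
    stop("crosstalk-matrix seed order does not match DE vector gene order")
  }
  rs <- as.vector(cm$C %*% de$values)
  structure(stats::setNames(rs, rownames(cm$C)), class = "risk_scores")
}

# membership operator: sparse K x N matrix whose rows average member-gene
# risk scores; pathways with fewer than min_size mapped genes are dropped
.membership_matrix <- function(pathways, gpcm, min_size = 3L) {
  meta <- data.frame(
    pathway_id = vapply(pathways, `[[`, "", "id"),
    name = vapply(pathways, `[[`, "", "name"),
    source_db = vapply(pathways, `[[`, "", "source_db"),
    size = vapply(pathways, function(p) length(p$genes), 0L),
    stringsAsFactors = FALSE)
  members <- lapply(pathways, function(p) match(p$genes, gpcm$nodes))
  members <- lapply(members, function(m) m[!is.na(m)])
  meta$n <- lengths(members)
  meta$coverage <- ifelse(meta$size > 0, meta$n / meta$size, 0)
  keep <- meta$n >= min_size
  if (any(!keep)) {
    message(sum(!keep), " pathway(s) skipped: fewer than ", min_size,
            " genes mapped to the crosstalk map")
  }
  meta <- meta[keep, , drop = FALSE]
  members <- members[keep]
  rownames(meta) <- NULL
  i <- rep(seq_along(members), lengths(members))
  M <- Matrix::sparseMatrix(
    i = i, j = unlist(members),
    x = 1 / meta$n[i],
    dims = c(nrow(meta), length(gpcm$nodes)),
    dimnames = list(meta$pathway_id, gpcm$nodes))
  list(M = M, meta = meta)
}

#' Pathway enrichment scores
#'
#' The enrichment score of pathway k is the mean risk score of its
#' member genes: \eqn{PS_k = \frac{1}{n}\sum_{j=1}^n RS_j}. Member genes
#' absent from the crosstalk map are excluded from both the mean and
#' `n`; the covered fraction is reported per pathway. Pathways with
#' fewer than `min_size` mapped genes are skipped (tiny sets make the
#' permutation null degenerate); `min_size = 1` disables the floor.
#'
#' @param rs `risk_scores` from [compute_risk_scores()].
#' @param pathways list of [pathway_set()] objects.
#' @param gpcm the `gpcm` the risk scores were computed on.
#' @param min_size minimum number of mapped member genes (default 3).
#' @return data.frame: pathway_id, name, source_db, size (annotated),
#'   n (mapped), coverage, ps.
#' @export
compute_pathway_scores <- function(rs, pathways, gpcm, min_size = 3L) {
  stopifnot(inherits(rs, "risk_scores"), inherits(gpcm, "gpcm"))
  mm <- .membership_matrix(pathways, gpcm, min_size)
  out <- mm$meta
  out$ps <- as.vector(mm$M %*% as.numeric(rs))
  out
}
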