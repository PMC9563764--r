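#' Propagation parameters for the random walk with restart
#'
#' @param r restart coefficient in (0, 1). Default 0.7, the value at
#'   which benchmark rank performance peaks.
#' @param tol per-seed convergence threshold on the L1 change between
#'   successive iterates. Default 1e-10.
#' @param max_iter safety cap on iterations; the geometric contraction
#'   bound makes ~70 iterations sufficient at the defaults.
#' @param epsilon truncation digits for the stored crosstalk matrix:
#'   entries below `10^-epsilon` are zeroed and survivors are truncated
#'   to `epsilon` decimal digits. `0` disables truncation. Default 3.
#' @return object of class `rwr_params`.
#' @export
rwr_params <- function(r = 0.7, tol = 1e-10, max_iter = 10000L,
                       epsilon = 3L) {
  stopifnot(r > 0, r < 1, tol > 0, max_iter >= 1,
            epsilon >= 0, epsilon == as.integer(epsilon))
  structure(list(r = r, tol = tol, max_iter = as.integer(max_iter),
                 epsilon = as.integer(epsilon)),
            class = "rwr_params")
}

.seed_indicator <- function(gpcm, seeds) {
  idx <- match(seeds, gpcm$nodes)
  if (anyNA(idx)) {
    stop("seed gene(s) not in the crosstalk map: ",
         paste(utils::head(seeds[is.na(idx)], 5), collapse = ", "))
  }
  Matrix::sparseMatrix(i = idx, j = seq_along(idx), x = 1,
                       dims = c(length(gpcm$nodes), length(idx)),
                       dimnames = list(gpcm$nodes, seeds))
}

.rwr_iterate <- function(W, N0, r, tol, max_iter) {
  C <- as.matrix(N0)
  restart <- (1 - r) * C
  for (t in seq_len(max_iter)) {
    C_new <- r * as.matrix(W %*% C) + restart
    resid <- max(colSums(abs(C_new - C)))
    C <- C_new
    if (resid < tol) return(C)
  }
  stop("random walk did not converge within ", max_iter,
       " iterations (residual ", signif(resid, 3), ")")
}

#' Random walk with restart from a single seed gene
#'
#' Iterates \eqn{C^t = r W C^{t-1} + (1-r) N_i} from \eqn{C^1 = N_i}
#' (the indicator of the seed) until the L1 change between iterates
#' falls below `tol`. Because `W` is column-stochastic the iterate keeps
#' unit mass, and for `r < 1` the map contracts geometrically, so the
#' limit equals the closed-form solution of [solve_rwr_exact()].
#'
#' @param gpcm a `gpcm`.
#' @param seed a gene present in the map.
#' @param params an [rwr_params()] object.
#' @return named numeric vector over all network genes (untruncated).
#' @export
rwr_single_seed <- function(gpcm, seed, params = rwr_params()) {
  stopifnot(inherits(gpcm, "gpcm"), length(seed) == 1L)
  N0 <- .seed_indicator(gpcm, seed)
  C <- .rwr_iterate(gpcm$W, N0, params$r, params$tol, params$max_iter)
  stats::setNames(as.vector(C), gpcm$nodes)
}

#' Multi-seed random walk with restart
#'
#' Runs one restart walk per seed gene (typically the profile genes
#' mapped to the network) and assembles the crosstalk-effect matrix `C`
#' with one column per seed, rows over all network genes. Entry
#' `C[j, i]` is the influence of seed gene `i` on network gene `j`.
#' Columns are independent, so seed order only permutes columns.
#' Truncation per `params$epsilon` is applied after convergence.
#'
#' @param gpcm a `gpcm`.
#' @param seeds character vector of seed genes (deterministic column
#'   order, usually the DE-vector gene order).
#' @param params an [rwr_params()] object.
#' @return object of class `crosstalk_matrix`: list with `C` (sparse
#'   N x L), `seeds`, `params`.
#' @export
multi_rwr <- function(gpcm, seeds, params = rwr_params()) {
  stopifnot(inherits(gpcm, "gpcm"))
  if (length(seeds) == 0L) stop("empty seed list")
  N0 <- .seed_indicator(gpcm, seeds)
  C <- .rwr_iterate(gpcm$W, N0, params$r, params$tol, params$max_iter)
  cm <- structure(list(C = methods::as(methods::as(C, "CsparseMatrix"),
                                       "generalMatrix"),
                       seeds = seeds, params = params,
                       truncated = FALSE),
                  class = "crosstalk_matrix")
  dimnames(cm$C) <- list(gpcm$nodes, seeds)
  apply_truncation(cm, params$epsilon)
}

#' Closed-form restart-walk solution (test oracle)
#'
#' Solves \eqn{(I - rW) x = (1-r) N_i} directly. For `r < 1` and
#' column-stochastic `W` the system is nonsingular, and the solution is
#' the fixed point the iterative walk converges to.
#'
#' @param gpcm a `gpcm` (small enough for a direct sparse solve).
#' @param seed a gene present in the map.
#' @param r restart coefficient in (0, 1).
#' @return named numeric vector over all network genes.
#' @export
solve_rwr_exact <- function(gpcm, seed, r = 0.7) {
  stopifnot(inherits(gpcm, "gpcm"), r > 0, r < 1)
  n <- length(gpcm$nodes)
  e <- .seed_indicator(gpcm, seed)
  A <- Matrix::Diagonal(n) - r * gpcm$W
  x <- Matrix::solve(A, (1 - r) * e)
  stats::setNames(as.vector(x), gpcm$nodes)
}

#' Truncate a crosstalk matrix to epsilon decimal digits
#'
#' Entries strictly below `10^-epsilon` are set to zero; surviving
#' entries keep `epsilon` decimal digits (truncated toward zero, so
#' entries only shrink and column sums never increase). This storage
#' optimization sparsifies `C` with a bounded loss of mass per column
#' (< N x 10^-epsilon).
#'
#' @param cm a `crosstalk_matrix`.
#' @param epsilon non-negative integer; `0` is the identity.
#' @return the truncated `crosstalk_matrix`.
#' @export
apply_truncation <- function(cm, epsilon = 3L) {
  stopifnot(inherits(cm, "crosstalk_matrix"), epsilon >= 0)
  epsilon <- as.integer(epsilon)
  if (epsilon == 0L) return(cm)
  C <- cm$C
  scale <- 10^epsilon
  C@x <- trunc(C@x * scale) / scale
  cm$C <- Matrix::drop0(C)
  cm$truncated <- TRUE
  cm
}

#' @export
print.crosstalk_matrix <- function(x, ...) {
  cat("Crosstalk-effect matrix:", nrow(x$C), "genes x", ncol(x$C),
      "seeds;", length(x$C@x), "nonzeros",
      if (x$truncated) sprintf("(epsilon=%d)", x$params$epsilon) else
        "(untruncated)", "\n")
  invisible(x)
}

#' Cache a crosstalk matrix as a coordinate-list TSV
#'
#' @param cm a `crosstalk_matrix`.
#' @param path output path (columns row_gene, col_gene, value).
#' @export
write_crosstalk <- function(cm, path) {
  trip <- Matrix::summary(cm$C)
  df <- data.frame(row_gene = rownames(cm$C)[trip$i],
                   col_gene = colnames(cm$C)[trip$j],
                   value = trip$x, stringsAsFactors = FALSE)
  utils::write.table(df[order(df$col_gene, df$row_gene), ], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
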