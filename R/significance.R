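#' Permute a DE vector over its gene labels
#'
#' Reassigns the multiset of DE values uniformly at random to the same
#' gene labels. The value multiset is preserved exactly; only the
#' gene-to-value assignment changes. Used to build the permutation null
#' for pathway scores.
#'
#' @param de a `de_vector`.
#' @param rng_seed integer seed (the permutation is a pure function of
#'   it).
#' @return a `de_vector` with permuted values.
#' @export
permute_profile <- function(de, rng_seed) {
  stopifnot(inherits(de, "de_vector"))
  perm <- .with_seed(rng_seed, sample.int(de$L))
  de$values <- stats::setNames(de$values[perm], names(de$values))
  de
}

# run expr under a local RNG state, restoring the caller's stream
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Permutation null distribution of pathway scores
#'
#' For each of `h` permutations the DE values are shuffled over the seed
#' genes and all pathway scores recomputed. The crosstalk matrix does
#' not depend on DE, so it is computed once and reused: each permutation
#' is a single matrix product. Per-permutation RNG streams are derived
#' as `rng_seed + k`, so increasing `h` extends the null without
#' reshuffling earlier permutations.
#'
#' @param cm a `crosstalk_matrix` (seed order = DE order).
#' @param de a `de_vector`.
#' @param pathways list of [pathway_set()] objects.
#' @param gpcm the `gpcm`.
#' @param h number of permutations (default 1000).
#' @param rng_seed master seed (keep `rng_seed + h` below 2^31).
#' @param min_size pathway size floor, as in [compute_pathway_scores()].
#' @return object of class `permutation_null`: list with `ps_random`
#'   (matrix, pathways x h), `h`, `seed`, `meta` (pathway table).
#' @export
permutation_null <- function(cm, de, pathways, gpcm, h = 1000L,
                             rng_seed = 1L, min_size = 3L) {
  stopifnot(inherits(cm, "crosstalk_matrix"), inherits(de, "de_vector"),
            h >= 1)
  if (!identical(cm$seeds, names(de$values))) {
    stop("crosstalk-matrix seed order does not match DE vector gene order")
  }
  h <- as.integer(h)
  L <- de$L
  perm_mat <- vapply(seq_len(h), function(k) {
    .with_seed(rng_seed + k, sample.int(L))
  }, integer(L))
  DEmat <- matrix(de$values[perm_mat], nrow = L, ncol = h)
  mm <- .membership_matrix(pathways, gpcm, min_size)
  RSmat <- as.matrix(cm$C %*% DEmat)
  ps_random <- as.matrix(mm$M %*% RSmat)
  rownames(ps_random) <- mm$meta$pathway_id
  structure(list(ps_random = ps_random, h = h, seed = rng_seed,
                 meta = mm$meta),
            class = "permutation_null")
}

#' Empirical permutation P-value
#'
#' Proportion of null scores at least as large as the observed score:
#' `p = N(PS_random >= PS) / h`. Ties count as extreme (a conservative
#' reading of "larger than"); an exceedance count of zero flags the
#' pathway for generalized-Pareto refinement.
#'
#' @param ps observed pathway score.
#' @param null_values numeric vector of permuted scores.
#' @param h permutation count (defaults to `length(null_values)`).
#' @return empirical P-value in \[0, 1\].
#' @export
empirical_pvalue <- function(ps, null_values, h = length(null_values)) {
  stopifnot(length(null_values) == h)
  sum(null_values >= ps) / h
}

# ---- generalized Pareto machinery -----------------------------------

# survival function of GPD(sigma, xi) on x >= 0
.gpd_surv <- function(x, sigma, xi) {
  x <- pmax(x, 0)
  if (abs(xi) < 1e-9) {
    exp(-x / sigma)
  } else {
    z <- 1 + xi * x / sigma
    ifelse(z <= 0, if (xi < 0) 0 else 1, z^(-1 / xi))
  }
}

# maximum-likelihood GPD fit on exceedances x > 0; moment start,
# Nelder-Mead on (log sigma, xi); NULL on failure
.fit_gpd <- function(x) {
  m <- mean(x)
  v <- stats::var(x)
  if (!is.finite(v) || v <= 0) return(NULL)
  xi0 <- 0.5 * (1 - m^2 / v)
  sigma0 <- 0.5 * m * (m^2 / v + 1)
  if (sigma0 <= 0) sigma0 <- m
  nll <- function(par) {
    sigma <- exp(par[1]); xi <- par[2]
    if (abs(xi) < 1e-9) {
      length(x) * log(sigma) + sum(x) / sigma
    } else {
      z <- 1 + xi * x / sigma
      if (any(z <= 0)) return(1e10)
      length(x) * log(sigma) + (1 + 1 / xi) * sum(log(z))
    }
  }
  fit <- tryCatch(
    stats::optim(c(log(sigma0), min(max(xi0, -0.45), 5)), nll,
                 method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0) return(NULL)
  list(sigma = exp(fit$par[1]), xi = fit$par[2], nll = fit$value)
}

# Anderson-Darling statistic for a fitted GPD
.gpd_ad_stat <- function(x, sigma, xi) {
  z <- sort(1 - .gpd_surv(x, sigma, xi))
  z <- pmin(pmax(z, 1e-12), 1 - 1e-12)
  n <- length(z)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(z) + log(1 - rev(z))))
}

# parametric bootstrap around a fitted GPD: Anderson-Darling
# goodness-of-fit P-value plus bias-corrected parameters (the shape MLE
# has O(1/n) negative bias, which compounds exponentially when the fit
# is extrapolated far into the tail). Deterministic given seed.
.gpd_boot <- function(x, fit, n_boot = 99L, seed = 1L) {
  a_obs <- .gpd_ad_stat(x, fit$sigma, fit$xi)
  n <- length(x)
  boot <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      u <- stats::runif(n)
      xb <- if (abs(fit$xi) < 1e-9) {
        -fit$sigma * log(u)
      } else {
        fit$sigma * (u^(-fit$xi) - 1) / fit$xi
      }
      fb <- .fit_gpd(xb)
      if (is.null(fb)) return(c(NA_real_, NA_real_, NA_real_))
      c(.gpd_ad_stat(xb, fb$sigma, fb$xi), log(fb$sigma), fb$xi)
    }, c(0, 0, 0))
  })
  ok <- is.finite(boot[1, ])
  gof_p <- (1 + sum(boot[1, ok] >= a_obs)) / (1 + sum(ok))
  list(gof_p = gof_p,
       sigma_bc = exp(2 * log(fit$sigma) - mean(boot[2, ok])),
       xi_bc = 2 * fit$xi - mean(boot[3, ok]))
}

#' Generalized-Pareto refinement of a permutation tail P-value
#'
#' With `h` permutations the empirical P-value has resolution `1/h` and
#' is often exactly 0 for strong pathways. The upper tail of the null is
#' modeled instead: the `n_exceed` largest null scores above a threshold
#' `t` (midpoint between the `n_exceed`-th and `(n_exceed+1)`-th largest)
#' are fitted by a generalized Pareto distribution via maximum
#' likelihood, and the refined P-value is
#' `(n_exceed / h) * S_GPD(ps - t)`. Because the shape MLE carries an
#' O(1/n) negative bias that compounds exponentially under deep tail
#' extrapolation, the fitted parameters are bootstrap bias-corrected
#' before the survival probability is evaluated. The fit is accepted
#' only if a parametric-bootstrap Anderson-Darling test does not reject
#' at `gof_alpha`; on rejection `n_exceed` is halved and the fit retried
#' down to `min_exceed`, after which the estimate falls back to the
#' conservative `(count + 1) / (h + 1)`. Scores at or below the
#' threshold are not refined: the empirical P-value is returned.
#'
#' @param ps observed pathway score.
#' @param null_values permutation null scores.
#' @param n_exceed initial number of tail exceedances to fit (250).
#' @param min_exceed smallest tail size before falling back (50).
#' @param gof_alpha goodness-of-fit rejection level (0.05).
#' @param gof_boot bootstrap replicates for the goodness-of-fit test.
#' @param seed seed for the (deterministic) bootstrap.
#' @return refined P-value.
#' @export
gpd_refine <- function(ps, null_values, n_exceed = 250L, min_exceed = 50L,
                       gof_alpha = 0.05, gof_boot = 99L, seed = 1L) {
  h <- length(null_values)
  s <- sort(null_values, decreasing = TRUE)
  count <- sum(null_values >= ps)
  # never fit more than the top quarter of the null: the tail model is
  # only meaningful on the tail (with the default h = 1000 this leaves
  # n_exceed = 250 untouched)
  ne <- min(as.integer(n_exceed), h - 1L, h %/% 4L)
  while (ne >= min_exceed) {
    t <- (s[ne] + s[ne + 1L]) / 2
    if (ps <= t) return(count / h)
    exceed <- s[seq_len(ne)] - t
    if (stats::var(exceed) < .Machine$double.eps) break
    fit <- .fit_gpd(exceed)
    if (!is.null(fit)) {
      boot <- .gpd_boot(exceed, fit, gof_boot, seed)
      if (boot$gof_p >= gof_alpha) {
        return((ne / h) * .gpd_surv(ps - t, boot$sigma_bc, boot$xi_bc))
      }
    }
    ne <- ne %/% 2L
  }
  warning("generalized-Pareto fit unavailable; ",
          "falling back to (count+1)/(h+1)")
  (count + 1) / (h + 1)
}

#' Benjamini-Hochberg adjusted P-values
#'
#' Step-up FDR adjustment: `p_(i) * m / i` with a running minimum from
#' the largest P-value down, capped at 1. Output order matches input
#' order.
#'
#' @param pvalues numeric vector of finite P-values.
#' @return numeric vector of adjusted values (FDR).
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(is.finite(pvalues)))
  m <- length(pvalues)
  if (m == 0L) return(numeric(0))
  ord <- order(pvalues, decreasing = TRUE)
  adj <- pmin(1, cummin(pvalues[ord] * m / (m:1)))
  adj[order(ord)]
}

#' Pathway significance from a permutation null
#'
#' Computes empirical P-values for every pathway, refines P-values whose
#' exceedance count falls below `gpd_floor` with the generalized-Pareto
#' tail model (when `gpd = TRUE`; otherwise the conservative
#' `(count+1)/(h+1)` replaces exact zeros), applies Benjamini-Hochberg
#' FDR control across pathways, and flags significance at
#' `fdr < fdr_threshold`.
#'
#' @param ps_table pathway score table from [compute_pathway_scores()];
#'   must cover the same pathways as the null.
#' @param null a `permutation_null`.
#' @param fdr_threshold significance cutoff on FDR (default 0.01).
#' @param gpd logical: refine tail P-values (default TRUE).
#' @param gpd_floor refine when the exceedance count is below this
#'   (default 10).
#' @param ... further arguments passed to [gpd_refine()].
#' @return data.frame sorted by FDR then PS descending: pathway_id,
#'   name, source_db, size, n, coverage, ps, p_empirical, p_final, fdr,
#'   significant.
#' @export
pathway_enrichment <- function(ps_table, null, fdr_threshold = 0.01,
                               gpd = TRUE, gpd_floor = 10L, ...) {
  stopifnot(inherits(null, "permutation_null"))
  idx <- match(ps_table$pathway_id, rownames(null$ps_random))
  if (anyNA(idx)) {
    stop("pathway score table and permutation null cover different sets")
  }
  h <- null$h
  res <- ps_table
  counts <- vapply(seq_len(nrow(res)), function(k) {
    sum(null$ps_random[idx[k], ] >= res$ps[k])
  }, 0)
  res$p_empirical <- counts / h
  res$p_final <- res$p_empirical
  low <- which(counts < gpd_floor)
  for (k in low) {
    res$p_final[k] <- if (gpd) {
      gpd_refine(res$ps[k], null$ps_random[idx[k], ], ...)
    } else {
      (counts[k] + 1) / (h + 1)
    }
  }
  res$fdr <- bh_fdr(res$p_final)
  res$significant <- res$fdr < fdr_threshold
  res[order(res$fdr, -res$ps, res$pathway_id), , drop = FALSE]
}
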