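#' Rank difference between two analysis settings
#'
#' Mean normalized shift in the target pathway's rank across benchmark
#' datasets: \eqn{DR = \frac{1}{M}\sum_m |R_{b,m} - R_{a,m}| / K}, where
#' `K` is the candidate pathway count. Values lie in \[0, 1\] when ranks
#' do not exceed `K`; `DR = 0` means the optimization left every rank
#' unchanged.
#'
#' @param records data.frame with columns `rank_before`, `rank_after`
#'   and `K` (constant across rows).
#' @return the DR value.
#' @export
rank_difference <- function(records) {
  stopifnot(nrow(records) >= 1,
            all(c("rank_before", "rank_after", "K") %in% names(records)))
  K <- unique(records$K)
  if (length(K) != 1L) stop("K must be constant across records")
  if (K == 0) stop("K must be positive")
  mean(abs(records$rank_before - records$rank_after) / K)
}

#' Relative running-time difference
#'
#' \eqn{DT = \frac{1}{M}\sum_m (T_{b,m} - T_{a,m}) / T_{b,m}}: the mean
#' fractional speed-up (negative when the "after" setting is slower;
#' bounded above by 1).
#'
#' @param records data.frame with positive columns `time_before`,
#'   `time_after`.
#' @return the DT value.
#' @export
time_difference <- function(records) {
  stopifnot(nrow(records) >= 1,
            all(c("time_before", "time_after") %in% names(records)))
  if (any(records$time_before <= 0)) {
    stop("time_before must be strictly positive")
  }
  mean((records$time_before - records$time_after) / records$time_before)
}

#' Rank ratio of a target pathway
#'
#' `RR = rank / denominator`: the target pathway's rank normalized by
#' the candidate pathway count, lower is better. The denominator
#' defaults to the number of candidate pathways `K`; the literal
#' benchmark formula divides by the dataset count `M` instead, which can
#' exceed 1 for ranks above `M` -- pass `denominator = M` to reproduce
#' it (a message notes the choice either way).
#'
#' @param rank integer rank(s), >= 1.
#' @param denominator positive count (candidate pathways `K`, or dataset
#'   count `M` for the literal formula).
#' @return RR value(s).
#' @export
rank_ratio <- function(rank, denominator) {
  stopifnot(all(rank >= 1), length(denominator) == 1L)
  if (denominator == 0) stop("denominator must be positive")
  message("rank ratio computed with denominator ", denominator)
  rank / denominator
}

#' Stability of significant-pathway calls across dataset pairs
#'
#' For each condition (e.g. cancer type) profiled by two independent
#' datasets, the Jaccard similarity of the two significant-pathway sets
#' is computed; `S` is the mean over the `D` pairs. A pair with both
#' sets empty contributes `J = 0` with a warning.
#'
#' @param sig_sets list of `D` pairs; each element is a list of two
#'   character vectors of significant pathway ids.
#' @return the S value in \[0, 1\].
#' @export
stability <- function(sig_sets) {
  stopifnot(length(sig_sets) >= 1)
  js <- vapply(sig_sets, function(pair) {
    stopifnot(length(pair) == 2L)
    a <- unique(pair[[1]]); b <- unique(pair[[2]])
    if (length(a) == 0L && length(b) == 0L) {
      warning("both significant sets empty in a pair; J = 0")
      return(0)
    }
    if (length(a) == 0L || length(b) == 0L) return(0)
    jaccard(a, b)
  }, 0)
  mean(js)
}

#' Compute benchmark metrics from a records table
#'
#' Convenience wrapper for a TSV of benchmark records (columns
#' dataset_id, rank_before, rank_after, time_before, time_after, K).
#'
#' @param records data.frame of benchmark records.
#' @param rr_denominator denominator for the per-dataset rank ratios
#'   (defaults to the candidate count `K`).
#' @return list with `DR`, `DT`, and a per-dataset `RR` vector.
#' @export
benchmark_metrics <- function(records, rr_denominator = NULL) {
  if (is.null(rr_denominator)) rr_denominator <- unique(records$K)[1]
  list(DR = rank_difference(records),
       DT = time_difference(records),
       RR = rank_ratio(records$rank_after, rr_denominator))
}
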