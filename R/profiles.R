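#' Load a differential-expression profile
#'
#' Reads a per-gene table with a header. Recognized columns
#' (case-insensitive): gene identifier in `gene` / `symbol` / `entrez`;
#' fold change in `fc` / `log2fc` / `foldchange`; P-value in `pvalue` /
#' `p` / `p.value`. At least one of the fold-change and P-value columns
#' must be present. The fold-change scale is never guessed: pass
#' `fc_scale = "log2"` when the column holds log2 fold changes (they are
#' converted to ratio scale as \eqn{FC = 2^{log2FC}}).
#'
#' Availability flags are profile-level: `alpha = 1` when a P-value
#' column exists, `beta = 1` when a fold-change column exists. A gene
#' missing a value inside an available column gets that value's neutral
#' element (P = 1, FC = 1), contributing zero evidence from the missing
#' part. Duplicate gene rows are resolved deterministically: largest
#' |log2 FC| wins, ties by smallest P, then first occurrence.
#'
#' @param path TSV with header.
#' @param fc_scale `"ratio"` or `"log2"`.
#' @return object of class `de_profile`: list with `table` (data.frame
#'   gene / fc / p), `alpha`, `beta`.
#' @export
load_profile <- function(path, fc_scale = c("ratio", "log2")) {
  fc_scale <- match.arg(fc_scale)
  if (!file.exists(path)) stop("profile not readable: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  cn <- tolower(names(df))
  gene_col <- which(cn %in% c("gene", "symbol", "entrez"))[1]
  fc_col <- which(cn %in% c("fc", "log2fc", "foldchange"))[1]
  p_col <- which(cn %in% c("pvalue", "p", "p.value"))[1]
  if (is.na(gene_col)) stop("no gene identifier column in ", path)
  if (is.na(fc_col) && is.na(p_col)) {
    stop("no usable score column (fc/log2fc or pvalue) in ", path)
  }
  gene <- normalize_gene_id(df[[gene_col]])
  beta <- as.integer(!is.na(fc_col))
  alpha <- as.integer(!is.na(p_col))

  fc <- rep(1, nrow(df))
  if (beta == 1L) {
    raw <- as.numeric(df[[fc_col]])
    if (fc_scale == "log2") {
      fc <- ifelse(is.na(raw), 1, 2^raw)
    } else {
      bad <- !is.na(raw) & raw <= 0
      if (any(bad)) {
        stop("non-positive ratio fold change for gene ",
             gene[which(bad)[1]],
             " (use --fc-scale log2 for log-scale input)")
      }
      fc <- ifelse(is.na(raw), 1, raw)
    }
  }
  p <- rep(1, nrow(df))
  if (alpha == 1L) {
    rawp <- as.numeric(df[[p_col]])
    bad <- !is.na(rawp) & (rawp < 0 | rawp > 1)
    if (any(bad)) {
      stop("P-value outside [0,1] for gene ", gene[which(bad)[1]])
    }
    p <- ifelse(is.na(rawp), 1, rawp)
  }

  tab <- data.frame(gene = gene, fc = fc, p = p, stringsAsFactors = FALSE)
  if (anyDuplicated(tab$gene)) {
    n_dup <- sum(duplicated(tab$gene))
    warning(n_dup, " duplicate gene row(s) resolved ",
            "(largest |log2 FC|, then smallest P, then first occurrence)")
    ord <- order(-abs(log2(tab$fc)), tab$p, seq_len(nrow(tab)))
    tab <- tab[ord, , drop = FALSE]
    tab <- tab[!duplicated(tab$gene), , drop = FALSE]
    tab <- tab[order(match(tab$gene, gene)), , drop = FALSE]
  }
  rownames(tab) <- NULL
  structure(list(table = tab, alpha = alpha, beta = beta),
            class = "de_profile")
}

#' @export
print.de_profile <- function(x, ...) {
  cat("Differential-expression profile:", nrow(x$table), "genes",
      sprintf("(alpha=%d, beta=%d)\n", x$alpha, x$beta))
  invisible(x)
}

#' Gene differential-expression score
#'
#' Combines fold change and P-value into a score in \[0, 1\]:
#' \deqn{DE = (1-P)^\alpha \left[1 - FC^{-1/2}\right]^\beta, \quad FC \ge 1}
#' \deqn{DE = (1-P)^\alpha \left[1 - FC^{+1/2}\right]^\beta, \quad 0 < FC < 1}
#' The square-root mapping puts the fold change on \[0, 1) and makes FC
#' values of n and 1/n contribute identically, so up- and down-regulation
#' of equal magnitude carry equal weight. `alpha` / `beta` switch each
#' factor off when the corresponding input type is unavailable.
#'
#' @param fc ratio-scale fold change, strictly positive (ignored when
#'   `beta = 0`).
#' @param p P-value in \[0, 1\] (ignored when `alpha = 0`).
#' @param alpha,beta 0/1 availability flags; both zero is an error.
#' @return numeric vector of DE scores in \[0, 1\].
#' @export
compute_de_score <- function(fc = 1, p = 1, alpha = 1, beta = 1) {
  if (alpha == 0 && beta == 0) {
    stop("at least one of P-value and fold change must be available")
  }
  n <- max(length(fc), length(p))
  fc <- rep_len(fc, n)
  p <- rep_len(p, n)
  de <- rep(1, n)
  if (alpha == 1) {
    if (any(is.na(p) | p < 0 | p > 1)) stop("P-values must lie in [0,1]")
    de <- de * (1 - p)
  }
  if (beta == 1) {
    if (any(is.na(fc) | fc <= 0)) {
      stop("ratio fold changes must be strictly positive")
    }
    fc_term <- ifelse(fc >= 1, 1 - fc^(-0.5), 1 - fc^(0.5))
    de <- de * fc_term
  }
  de
}

#' Map a profile onto the crosstalk map as a DE vector
#'
#' Scores are computed only for profile genes present in the network;
#' the count of unmapped genes is reported. `L`, the size of the
#' intersection, is the number of propagation seeds downstream.
#'
#' @param profile a `de_profile`.
#' @param gpcm a `gpcm`.
#' @return object of class `de_vector`: list with `values` (named
#'   numeric, profile order restricted to mapped genes), `L`, and the
#'   availability flags.
#' @export
build_de_vector <- function(profile, gpcm) {
  stopifnot(inherits(profile, "de_profile"), inherits(gpcm, "gpcm"))
  tab <- profile$table
  in_net <- tab$gene %in% gpcm$nodes
  if (!any(in_net)) stop("no profile gene maps to the network")
  n_out <- sum(!in_net)
  if (n_out > 0L) {
    message(n_out, " profile gene(s) absent from the crosstalk map ",
            "were excluded")
  }
  tab <- tab[in_net, , drop = FALSE]
  values <- compute_de_score(tab$fc, tab$p, profile$alpha, profile$beta)
  names(values) <- tab$gene
  structure(list(values = values, L = length(values),
                 alpha = profile$alpha, beta = profile$beta),
            class = "de_vector")
}

#' @export
print.de_vector <- function(x, ...) {
  cat("DE vector over", x$L, "network genes; mean score",
      signif(mean(x$values), 4), "\n")
  invisible(x)
}
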