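#' Assemble the bipartite block matrix for the connectedness ranking
#'
#' From the significance-masked adjacency `A` (blood rows x CSF columns)
#' builds the symmetric 2n x 2n block matrix
#' `M = [[0, |A|], [|A|', 0]]`, whose zero diagonal blocks encode that
#' only cross-fluid edges count.  The absolute value is used because the
#' ranking measures a metabolite's ability to influence others,
#' regardless of the correlation sign.  The geometric-series scale factor
#' is fixed at `alpha = 1 / (0.01 + ||M||_F)`, which guarantees
#' `alpha * ||M||_F < 1` and hence convergence of the path-counting
#' series.
#'
#' @param A numeric n x n adjacency matrix (rows = blood metabolites,
#'   columns = CSF metabolites); typically `net$A` from
#'   [significance_filter()].
#' @param blood_names,csf_names metabolite names; default to the
#'   dimnames of `A`.
#' @return An object of class `block_matrix`: list with `M`, `n`,
#'   `alpha_scale`, `frobenius_norm`, `degenerate` (TRUE when `A` is all
#'   zero), and the name vectors.
#' @examples
#' B <- build_block_matrix(matrix(c(0.5, 0, -0.3, 0.8), 2))
#' B$frobenius_norm   # sqrt(2 * (0.25 + 0.09 + 0.64)) = 1.4
#' @export
build_block_matrix <- function(A, blood_names = NULL, csf_names = NULL) {
  A <- as.matrix(A)
  if (!all(is.finite(A))) stop("`A` contains non-finite entries")
  n <- nrow(A)
  m <- ncol(A)
  if (is.null(blood_names))
    blood_names <- rownames(A) %||% sprintf("blood%02d", seq_len(n))
  if (is.null(csf_names))
    csf_names <- colnames(A) %||% sprintf("csf%02d", seq_len(m))
  absA <- abs(A)
  M <- rbind(cbind(matrix(0, n, n), absA),
             cbind(t(absA), matrix(0, m, m)))
  fro <- sqrt(sum(M^2))
  alpha <- 1 / (0.01 + fro)
  degenerate <- fro == 0
  if (degenerate)
    warning("adjacency is all zero: no significant cross-fluid ",
            "correlations; all connectedness scores will be 0")
  stopifnot(alpha * fro < 1)
  structure(list(M = M, n = n, n_blood = n, n_csf = m,
                 alpha_scale = alpha, frobenius_norm = fro,
                 degenerate = degenerate,
                 blood_names = blood_names, csf_names = csf_names),
            class = "block_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Path-counting connectedness scores
#'
#' Computes `T' = M (I - alpha M)^{-1}` -- the closed form of the
#' geometric series `M * sum_k (alpha M)^k`, which accumulates walks of
#' every length between metabolites with weight `alpha^(k-1)` on
#' k-step walks -- and scores each metabolite by its column sum of `T'`.
#' The first n columns score the blood metabolites, the last n the CSF
#' metabolites.  The linear system is solved by LU factorization rather
#' than explicit inversion, and the spectral radius condition
#' `rho(alpha M) < 1` is asserted before solving.  Only the ordering of
#' scores is meaningful, not their absolute scale.
#'
#' @param B a [build_block_matrix()] result.
#' @return An object of class `connectedness`: list with `scores_blood`
#'   and `scores_csf` (named, nonnegative), per-fluid ranked tables
#'   (`table_blood`, `table_csf`; ties broken by metabolite name), and
#'   the scale `alpha_scale`.
#' @export
connectedness_scores <- function(B) {
  stopifnot(inherits(B, "block_matrix"))
  M <- B$M
  a <- B$alpha_scale
  if (B$degenerate || all(M == 0)) {
    colsum <- setNames(numeric(nrow(M)),
                       c(B$blood_names, B$csf_names))
  } else {
    ev <- eigen(a * M, symmetric = TRUE, only.values = TRUE)$values
    sr <- max(abs(ev))
    stopifnot(sr < 1)          # guaranteed by alpha < 1/||M||_F
    I <- diag(nrow(M))
    ## T' = M (I - aM)^{-1}; solve (I - aM)' X = M' and transpose
    Tp <- t(solve(t(I - a * M), t(M)))
    colsum <- setNames(colSums(Tp), c(B$blood_names, B$csf_names))
    ## an isolated metabolite (zero column of M) has score exactly 0:
    ## every power of M keeps its column zero, so enforce the exact value
    ## rather than leaving LU round-off
    colsum[colSums(M) == 0] <- 0
  }
  nb <- B$n_blood
  sb <- colsum[seq_len(nb)]
  sc <- colsum[nb + seq_len(B$n_csf)]
  mktab <- function(s) {
    ord <- order(-s, names(s))
    data.frame(metabolite = names(s)[ord], score = unname(s[ord]),
               rank = seq_along(s), stringsAsFactors = FALSE)
  }
  structure(list(scores_blood = sb, scores_csf = sc,
                 table_blood = mktab(sb), table_csf = mktab(sc),
                 alpha_scale = a),
            class = "connectedness")
}

#' @export
print.connectedness <- function(x, n = 6, ...) {
  cat("<connectedness> ", length(x$scores_blood), " blood / ",
      length(x$scores_csf), " CSF metabolites (alpha = ",
      signif(x$alpha_scale, 5), ")\n", sep = "")
  cat("top blood:\n")
  print(head(x$table_blood, n), row.names = FALSE)
  cat("top CSF:\n")
  print(head(x$table_csf, n), row.names = FALSE)
  invisible(x)
}

#' @export
plot.connectedness <- function(x, fluid = c("blood", "csf"), n = 15, ...) {
  fluid <- match.arg(fluid)
  tab <- head(if (fluid == "blood") x$table_blood else x$table_csf, n)
  op <- par(mar = c(4, 8, 2, 1)); on.exit(par(op))
  barplot(rev(tab$score), names.arg = rev(tab$metabolite), horiz = TRUE,
          las = 1, xlab = "connectedness score",
          main = paste("connectedness,", fluid), ...)
  invisible(x)
}

#' Truncated-series connectedness (independent check)
#'
#' Column sums of the K-term partial sum
#' `sum_{k=1..K} alpha^{k-1} M^k = M * sum_{k=0..K-1} (alpha M)^k`,
#' computed by explicit matrix powers.  Converges to
#' [connectedness_scores()] as K grows; used as a cross-check of the
#' resolvent closed form.
#'
#' @param B a [build_block_matrix()] result.
#' @param K number of series terms, >= 1.
#' @return Named score vector over all 2n metabolites (blood first).
#' @export
truncated_series_scores <- function(B, K = 500) {
  stopifnot(inherits(B, "block_matrix"), K >= 1)
  M <- B$M
  a <- B$alpha_scale
  term <- M                       # alpha^(k-1) M^k at k = 1
  acc <- M
  if (K > 1) for (k in 2:K) {
    term <- a * (term %*% M)
    acc <- acc + term
  }
  setNames(colSums(acc), c(B$blood_names, B$csf_names))
}

#' Compare connectedness scores between two groups
#'
#' Joins two score vectors by metabolite name and reports per-metabolite
#' scores, the difference `group2 - group1`, and each group's rank (ties
#' broken lexicographically by name).
#'
#' @param scores1,scores2 named score vectors over the same metabolites
#'   (e.g. `scores_blood` for wild type and transgenic).
#' @param labels length-2 character, column labels for the two groups.
#' @return Data frame with columns `metabolite`, `score_<label1>`,
#'   `score_<label2>`, `difference`, `rank_<label1>`, `rank_<label2>`,
#'   ordered by descending absolute difference.
#' @export
rank_and_diff <- function(scores1, scores2, labels = c("WT", "APP")) {
  if (is.null(names(scores1)) || is.null(names(scores2)))
    stop("score vectors must be named by metabolite")
  if (!setequal(names(scores1), names(scores2)))
    stop("metabolite name lists differ: ",
         paste(union(setdiff(names(scores1), names(scores2)),
                     setdiff(names(scores2), names(scores1))),
               collapse = ", "))
  nm <- sort(names(scores1))
  s1 <- scores1[nm]
  s2 <- scores2[nm]
  rk <- function(s) {
    ord <- order(-s, names(s))
    r <- integer(length(s))
    r[ord] <- seq_along(s)
    r
  }
  out <- data.frame(metabolite = nm, s1 = unname(s1), s2 = unname(s2),
                    difference = unname(s2 - s1),
                    r1 = rk(s1), r2 = rk(s2), stringsAsFactors = FALSE)
  names(out)[c(2, 3, 5, 6)] <- c(paste0("score_", labels),
                                 paste0("rank_", labels))
  out[order(-abs(out$difference), out$metabolite), ]
}
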