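#' Cross-fluid Spearman correlation network
#'
#' Computes the Spearman rank correlation between every shared metabolite
#' in blood and every shared metabolite in CSF over matched samples.
#' Entry `rho[i, j]` is the correlation between metabolite `i` in blood
#' and metabolite `j` in CSF; the reverse-direction network is simply the
#' transpose.  Within-fluid correlations are deliberately not part of the
#' object: the network describes co-variation across the blood--brain
#' barrier only.
#'
#' Two-sided p-values test rho != 0.  For n <= 9 matched samples the
#' permutation null distribution of rho is enumerated exactly over all
#' n! orderings (conditioning on the observed rank multisets, so ties are
#' handled with average ranks); for larger n the usual t approximation
#' `t = r sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom is used.
#'
#' @param blood,csf `conc_table` objects with matching `sample_id`s in
#'   the same order (at least 3 samples).
#' @param shared character vector of metabolite names present in both
#'   tables; defaults to the intersection.
#' @param alpha significance level stored for later filtering.
#' @return An object of class `corr_network`: list with `blood_names`,
#'   `csf_names`, `rho`, `pvals`, `A` (NULL until
#'   [significance_filter()]), `n_samples`, `alpha`.
#' @export
spearman_network <- function(blood, csf, shared = NULL, alpha = 0.05) {
  stopifnot(inherits(blood, "data.frame"), inherits(csf, "data.frame"))
  if (nrow(blood) != nrow(csf) ||
      !all(blood$sample_id == csf$sample_id))
    stop("blood and csf tables must contain the same samples in the same ",
         "order (matched pools)")
  n <- nrow(blood)
  if (n < 3) stop("need at least 3 matched samples, got ", n)
  mb <- if (inherits(blood, "conc_table")) metabolites(blood) else
    setdiff(names(blood), c("sample_id", "sex", "genotype", "age_point",
                            "fluid"))
  mc <- if (inherits(csf, "conc_table")) metabolites(csf) else
    setdiff(names(csf), c("sample_id", "sex", "genotype", "age_point",
                          "fluid"))
  if (is.null(shared)) shared <- intersect(mb, mc)
  if (!length(shared)) stop("no shared metabolites between the two tables")
  missing_b <- setdiff(shared, mb)
  missing_c <- setdiff(shared, mc)
  if (length(missing_b) || length(missing_c))
    stop("shared metabolites absent from a table: ",
         paste(unique(c(missing_b, missing_c)), collapse = ", "))

  X <- as.matrix(as.data.frame(blood)[, shared, drop = FALSE])
  Y <- as.matrix(as.data.frame(csf)[, shared, drop = FALSE])
  p <- length(shared)
  rho <- matrix(0, p, p, dimnames = list(shared, shared))
  pv <- matrix(1, p, p, dimnames = list(shared, shared))
  rx <- apply(X, 2, rank)
  ry <- apply(Y, 2, rank)
  degen_x <- apply(X, 2, function(v) length(unique(v)) < 2)
  degen_y <- apply(Y, 2, function(v) length(unique(v)) < 2)
  if (any(degen_x) || any(degen_y))
    warning("zero-variance metabolite(s): ",
            paste(unique(c(shared[degen_x], shared[degen_y])),
                  collapse = ", "), "; rho set to 0, p to 1")
  for (i in seq_len(p)) {
    if (degen_x[i]) next
    for (j in seq_len(p)) {
      if (degen_y[j]) next
      r <- stats::cor(rx[, i], ry[, j])
      rho[i, j] <- r
      pv[i, j] <- spearman_pvalue(rx[, i], ry[, j], r)
    }
  }
  structure(list(blood_names = shared, csf_names = shared, rho = rho,
                 pvals = pv, A = NULL, n_samples = n, alpha = alpha),
            class = "corr_network")
}

## ---- exact / approximate Spearman p-values --------------------------------

# caches: permutation index matrices per n, and rho null distributions per
# rank-multiset pair (the permutation distribution depends only on those)
.perm_cache <- new.env(parent = emptyenv())
.rho_dist_cache <- new.env(parent = emptyenv())

## all permutations of 1..n, built by iterative insertion (n <= 9)
perm_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  P <- matrix(1L, 1L, 1L)
  if (n > 1L) for (k in 2L:n) {
    m <- nrow(P)
    out <- matrix(0L, m * k, k)
    for (pos in seq_len(k)) {
      rows <- (pos - 1L) * m + seq_len(m)
      if (pos > 1L) out[rows, seq_len(pos - 1L)] <- P[, seq_len(pos - 1L)]
      out[rows, pos] <- k
      if (pos < k) out[rows, (pos + 1L):k] <- P[, pos:(k - 1L)]
    }
    P <- out
  }
  .perm_cache[[key]] <- P
  P
}

## exact two-sided permutation p-value for ranks ra vs rb (with ties OK)
spearman_exact_p <- function(ra, rb, rho_obs) {
  n <- length(ra)
  key <- paste(n, paste(sort(ra), collapse = ","),
               paste(sort(rb), collapse = ","), sep = "|")
  dist <- .rho_dist_cache[[key]]
  if (is.null(dist)) {
    P <- perm_matrix(n)
    Xp <- matrix(ra[P], nrow(P))
    S <- as.numeric(Xp %*% rb)
    dist <- (S - n * mean(ra) * mean(rb)) / ((n - 1) * sd(ra) * sd(rb))
    .rho_dist_cache[[key]] <- dist
  }
  mean(abs(dist) >= abs(rho_obs) - 1e-12)
}

## dispatcher: exact enumeration for n <= 9, t approximation above
spearman_pvalue <- function(ra, rb, rho_obs) {
  n <- length(ra)
  if (n <= 9) return(spearman_exact_p(ra, rb, rho_obs))
  if (abs(rho_obs) >= 1) return(0)
  tt <- rho_obs * sqrt((n - 2) / (1 - rho_obs^2))
  2 * pt(-abs(tt), df = n - 2)
}

#' @export
print.corr_network <- function(x, ...) {
  cat("<corr_network> ", length(x$blood_names), " blood x ",
      length(x$csf_names), " CSF metabolites, n = ", x$n_samples,
      " matched samples\n", sep = "")
  if (!is.null(x$A))
    cat("  ", sum(x$A != 0), " significant edges at alpha = ", x$alpha,
        "\n", sep = "")
  else cat("  significance mask not yet applied\n")
  invisible(x)
}

#' @export
summary.corr_network <- function(object, ...) {
  print(object)
  cat("  |rho| quartiles:",
      paste(signif(stats::quantile(abs(object$rho)), 3), collapse = " "),
      "\n")
  invisible(object)
}

#' @export
plot.corr_network <- function(x, main = "cross-fluid Spearman rho", ...) {
  m <- if (!is.null(x$A)) x$A else x$rho
  image(seq_along(x$csf_names), seq_along(x$blood_names), t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
        col = hcl.colors(51, "Blue-Red"), zlim = c(-1, 1),
        xlab = "CSF metabolite", ylab = "blood metabolite", main = main,
        axes = FALSE, ...)
  axis(1, at = seq_along(x$csf_names), labels = x$csf_names, las = 2,
       cex.axis = 0.6)
  axis(2, at = seq_along(x$blood_names), labels = rev(x$blood_names),
       las = 1, cex.axis = 0.6)
  invisible(x)
}

#' Apply the significance mask to a correlation network
#'
#' Populates the adjacency matrix `A`: `A[i, j] = rho[i, j]` where
#' `pvals[i, j] <= alpha`, and 0 otherwise.  Optionally applies a
#' Benjamini--Hochberg correction across all pairs first (off by
#' default; the raw per-pair level matches the study design this package
#' emulates).
#'
#' @param net a `corr_network` from [spearman_network()].
#' @param alpha significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return The network with `A` populated and `alpha` updated.
#' @export
significance_filter <- function(net, alpha = 0.05, adjust = c("none", "BH")) {
  stopifnot(inherits(net, "corr_network"))
  adjust <- match.arg(adjust)
  pv <- net$pvals
  if (adjust == "BH")
    pv <- matrix(stats::p.adjust(pv, method = "BH"), nrow(pv),
                 dimnames = dimnames(pv))
  net$A <- ifelse(pv <= alpha, net$rho, 0)
  net$alpha <- alpha
  net
}

#' Harmonize significant pairs across two genotype networks
#'
#' Builds the union of blood--CSF metabolite pairs significant in either
#' network and returns, for each network, the same ordered pair list with
#' that group's own correlation (significant or not).  This mirrors the
#' comparison rule: a pair significant in the wild-type network is also
#' listed, with its raw correlation, for the transgenic network, and vice
#' versa, so the two groups always report the same pairs.
#'
#' @param net1,net2 `corr_network` objects with identical metabolite name
#'   lists and populated `A`.
#' @return A list of two data frames (`pairs1`, `pairs2`), each with
#'   columns `blood`, `csf`, `rho`, `significant`, ordered by blood then
#'   CSF name.
#' @export
harmonize_pairs <- function(net1, net2) {
  stopifnot(inherits(net1, "corr_network"), inherits(net2, "corr_network"))
  if (!identical(net1$blood_names, net2$blood_names) ||
      !identical(net1$csf_names, net2$csf_names))
    stop("the two networks do not share metabolite name lists")
  if (is.null(net1$A) || is.null(net2$A))
    stop("apply significance_filter() to both networks first")
  sig <- (net1$A != 0) | (net2$A != 0)
  idx <- which(sig, arr.ind = TRUE)
  if (!nrow(idx)) {
    empty <- data.frame(blood = character(), csf = character(),
                        rho = numeric(), significant = logical())
    return(list(pairs1 = empty, pairs2 = empty))
  }
  ord <- order(net1$blood_names[idx[, 1]], net1$csf_names[idx[, 2]])
  idx <- idx[ord, , drop = FALSE]
  mk <- function(net) data.frame(
    blood = net$blood_names[idx[, 1]],
    csf = net$csf_names[idx[, 2]],
    rho = net$rho[idx],
    significant = net$A[idx] != 0,
    stringsAsFactors = FALSE)
  list(pairs1 = mk(net1), pairs2 = mk(net2))
}

#' Fisher-z test for genotype differences in correlation
#'
#' For each harmonized metabolite pair, transforms the two groups'
#' correlations with Fisher's z (`atanh`) and tests their difference with
#' the normal statistic
#' `z = (z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided.  Correlations
#' at exactly +/-1 are clamped to +/-(1 - 1e-10) with a warning, since
#' `atanh` diverges there.
#'
#' @param pairs1,pairs2 data frames from [harmonize_pairs()] (same pairs,
#'   same order), e.g. wild-type and transgenic.
#' @param n1,n2 per-group sample sizes (>= 4 so the z variance 1/(n-3)
#'   exists).
#' @param alpha significance level for the `significant` flag.
#' @return Data frame with columns `blood`, `csf`, `r1`, `r2`, `z_stat`,
#'   `p_value`, `significant`; `z_stat` is positive when `pairs1`'s
#'   correlation is larger on the z scale.
#' @examples
#' p1 <- data.frame(blood = "acetate", csf = "taurine", rho = 0.89)
#' p2 <- data.frame(blood = "acetate", csf = "taurine", rho = -0.43)
#' differential_correlations(p1, p2, n1 = 10, n2 = 10)
#' @export
differential_correlations <- function(pairs1, pairs2, n1, n2,
                                      alpha = 0.05) {
  if (nrow(pairs1) != nrow(pairs2) ||
      (nrow(pairs1) && (!all(pairs1$blood == pairs2$blood) ||
                        !all(pairs1$csf == pairs2$csf))))
    stop("`pairs1` and `pairs2` must list the same pairs in the same order")
  if (n1 < 4 || n2 < 4)
    stop("Fisher-z variance is 1/(n-3); need n >= 4 per group ",
         "(got n1 = ", n1, ", n2 = ", n2, ")")
  clamp <- function(r) {
    if (any(abs(r) >= 1)) {
      warning("correlation(s) at +/-1 clamped to +/-(1 - 1e-10) for the ",
              "z transform")
      r <- pmin(pmax(r, -(1 - 1e-10)), 1 - 1e-10)
    }
    r
  }
  r1 <- clamp(pairs1$rho)
  r2 <- clamp(pairs2$rho)
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  z <- (atanh(r1) - atanh(r2)) / se
  p <- 2 * pnorm(-abs(z))
  data.frame(blood = pairs1$blood, csf = pairs1$csf,
             r1 = pairs1$rho, r2 = pairs2$rho,
             z_stat = z, p_value = p, significant = p <= alpha,
             stringsAsFactors = FALSE)
}

#' Per-group cross-fluid networks for a sex-stratified cohort
#'
#' Splits matched blood/CSF tables by sex x genotype (pooling the two age
#' points by default, or additionally by age point) and computes a
#' significance-filtered network for each group.
#'
#' @param blood,csf matched `conc_table`s for the whole cohort.
#' @param alpha significance level.
#' @param by_age also stratify by age point.
#' @param adjust multiple-testing adjustment passed to
#'   [significance_filter()].
#' @return Named list of `corr_network` objects
#'   (`"female.WT"`, `"female.APP"`, ...).
#' @export
group_networks <- function(blood, csf, alpha = 0.05, by_age = FALSE,
                           adjust = "none") {
  stopifnot(all(blood$sample_id == csf$sample_id))
  key <- if (by_age)
    interaction(blood$sex, blood$genotype, blood$age_point, drop = TRUE)
  else interaction(blood$sex, blood$genotype, drop = TRUE)
  out <- lapply(levels(key), function(lv) {
    rows <- which(key == lv)
    significance_filter(
      spearman_network(conc_table(as.data.frame(blood)[rows, ]),
                       conc_table(as.data.frame(csf)[rows, ]),
                       alpha = alpha),
      alpha = alpha, adjust = adjust)
  })
  names(out) <- levels(key)
  out
}

#' Write the matrices of a network as CSV files
#'
#' @param net a `corr_network`.
#' @param dir output directory.
#' @param prefix file-name prefix (e.g. the group label).
#' @return Invisibly, the written file paths.
#' @export
write_network <- function(net, dir, prefix = "network") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_", c("rho", "pvals", "A"),
                                 ".csv"))
  write.csv(net$rho, paths[1])
  write.csv(net$pvals, paths[2])
  if (!is.null(net$A)) write.csv(net$A, paths[3]) else paths <- paths[1:2]
  invisible(paths)
}
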