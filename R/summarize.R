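#' Early-vs-late log concentration ratios
#'
#' For each metabolite within each sex x genotype group (and fluid),
#' computes `log10(mean(late) / mean(early))` of the group-mean
#' concentrations: positive values mean the metabolite rises with age.
#' Non-positive group means yield `NA` with a warning.
#'
#' @param table a `conc_table` containing both age points for every
#'   group.
#' @return Data frame with columns `metabolite`, `fluid`, `sex`,
#'   `genotype`, `mean_early`, `mean_late`, `log10_late_over_early`.
#' @export
log_ratio_table <- function(table) {
  stopifnot(inherits(table, "conc_table"))
  mets <- metabolites(table)
  groups <- unique(as.data.frame(table)[, c("sex", "genotype", "fluid")])
  out <- list()
  for (g in seq_len(nrow(groups))) {
    sel <- table$sex == groups$sex[g] &
      table$genotype == groups$genotype[g] &
      table$fluid == groups$fluid[g]
    early <- sel & table$age_point == "early"
    late <- sel & table$age_point == "late"
    if (!any(early) || !any(late))
      stop("group ", groups$sex[g], "/", groups$genotype[g],
           " lacks one of the age points")
    me <- colMeans(as.data.frame(table)[early, mets, drop = FALSE])
    ml <- colMeans(as.data.frame(table)[late, mets, drop = FALSE])
    bad <- me <= 0 | ml <= 0
    if (any(bad))
      warning("non-positive group mean for ",
              paste(mets[bad], collapse = ", "),
              " in ", groups$sex[g], "/", groups$genotype[g],
              "; log ratio set to NA")
    lr <- ifelse(bad, NA_real_, log10(ml / me))
    out[[g]] <- data.frame(metabolite = mets, fluid = groups$fluid[g],
                           sex = groups$sex[g], genotype = groups$genotype[g],
                           mean_early = unname(me), mean_late = unname(ml),
                           log10_late_over_early = unname(lr),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Rank metabolites by one-way ANOVA across a grouping factor
#'
#' Fits a one-way ANOVA per metabolite (concentration ~ group) and
#' returns F statistics and p-values, sorted by decreasing F.  With two
#' groups, F equals the squared pooled-variance two-sample t statistic.
#'
#' @param table a `conc_table`.
#' @param grouping metadata column to group by (default `"genotype"`).
#' @return Data frame with columns `metabolite`, `F`, `p`, `df1`, `df2`,
#'   sorted by decreasing `F`.
#' @export
anova_rank <- function(table, grouping = "genotype") {
  stopifnot(inherits(table, "conc_table"))
  g <- factor(as.data.frame(table)[[grouping]])
  if (nlevels(g) < 2) stop("grouping `", grouping, "` has < 2 levels")
  counts <- table(g)
  if (any(counts < 2))
    stop("level(s) with fewer than 2 samples: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  mets <- metabolites(table)
  res <- t(vapply(mets, function(m) {
    y <- as.data.frame(table)[[m]]
    a <- anova(lm(y ~ g))
    c(F = a[["F value"]][1], p = a[["Pr(>F)"]][1],
      df1 = a[["Df"]][1], df2 = a[["Df"]][2])
  }, numeric(4)))
  out <- data.frame(metabolite = mets, F = res[, "F"], p = res[, "p"],
                    df1 = res[, "df1"], df2 = res[, "df2"],
                    stringsAsFactors = FALSE, row.names = NULL)
  ## F = 0 means identical group means; the test is then non-informative
  out$p[out$F == 0] <- 1
  out[order(-out$F, out$metabolite), ]
}

#' Consensus feature selection: ANOVA x ridge-logistic
#'
#' Ranks metabolites two ways -- by one-way ANOVA F and by the absolute
#' coefficient of an L2-regularized (ridge) logistic regression on
#' standardized concentrations -- and returns the intersection of the two
#' top-k lists.  Requiring agreement between a univariate test and a
#' multivariate regularized model guards against features selected by
#' either method's idiosyncrasies alone.
#'
#' @param table a `conc_table`.
#' @param grouping binary metadata column (default `"genotype"`).
#' @param lambda ridge penalty on standardized features (default 1).
#' @param k size of each top list; the consensus is their intersection.
#' @return A list with `consensus` (character vector), `anova` (the
#'   [anova_rank()] table) and `ridge` (data frame metabolite /
#'   abs_coefficient, sorted).
#' @export
ridge_consensus <- function(table, grouping = "genotype", lambda = 1,
                            k = 10) {
  stopifnot(inherits(table, "conc_table"))
  g <- factor(as.data.frame(table)[[grouping]])
  if (nlevels(g) != 2)
    stop("`", grouping, "` must have exactly 2 levels for the logistic ",
         "model (got ", nlevels(g), ")")
  mets <- metabolites(table)
  X <- as.matrix(as.data.frame(table)[, mets, drop = FALSE])
  X <- scale(X)
  X[is.na(X)] <- 0                     # zero-variance columns carry no signal
  y <- as.integer(g) - 1L
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  beta <- abs(as.numeric(fit$beta))
  ridge_tab <- data.frame(metabolite = mets, abs_coefficient = beta,
                          stringsAsFactors = FALSE)
  ridge_tab <- ridge_tab[order(-ridge_tab$abs_coefficient,
                               ridge_tab$metabolite), ]
  an <- anova_rank(table, grouping)
  k <- min(k, length(mets))
  consensus <- if (k > 0)
    sort(intersect(head(an$metabolite, k), head(ridge_tab$metabolite, k)))
  else character(0)
  list(consensus = consensus, anova = an, ridge = ridge_tab)
}
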