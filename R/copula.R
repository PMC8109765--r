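#' Describe the study design for the concentration simulator
#'
#' Mirrors the design of a paired-biofluid mouse metabolomics study: two
#' sexes x two genotypes (wild type vs. amyloid-accumulating transgenic)
#' x two age points, with a small number of pooled replicates per cell and
#' matched blood / CSF measurements per replicate.  Defaults emulate 51
#' metabolites quantified in both fluids and 3 pooled replicates per
#' group.
#'
#' @param n_metabolites_blood,n_metabolites_csf metabolite counts per
#'   fluid.
#' @param n_shared number of metabolites present in both fluids; the
#'   first `n_shared` metabolites of each fluid share names (`met01`,
#'   ...).  Must not exceed either fluid's count.
#' @param replicates_per_group pooled replicates per sex x genotype x age
#'   cell, at least 3.
#' @param seed integer seed used for all random draws.
#' @return A list of class `study_design` with a `groups` data frame
#'   (sex, genotype, age_point).
#' @export
study_design <- function(n_metabolites_blood = 51, n_metabolites_csf = 51,
                         n_shared = 51, replicates_per_group = 3,
                         seed = 1L) {
  if (n_shared > min(n_metabolites_blood, n_metabolites_csf))
    stop("n_shared (", n_shared, ") exceeds a fluid's metabolite count")
  if (replicates_per_group < 3)
    stop("replicates_per_group must be >= 3")
  groups <- expand.grid(sex = c("male", "female"),
                        genotype = c("WT", "APP"),
                        age_point = c("early", "late"),
                        stringsAsFactors = FALSE)
  structure(list(n_metabolites_blood = as.integer(n_metabolites_blood),
                 n_metabolites_csf = as.integer(n_metabolites_csf),
                 n_shared = as.integer(n_shared),
                 replicates_per_group = as.integer(replicates_per_group),
                 groups = groups, seed = as.integer(seed)),
            class = "study_design")
}

#' Gaussian-copula specification for cross-fluid rank correlation
#'
#' Prescribes the target Spearman correlation between each shared
#' metabolite in blood and each shared metabolite in CSF, together with
#' log-normal marginals per metabolite.  The latent Pearson correlation is
#' obtained through the exact Gaussian-copula relation
#' `rho_P = 2 sin(pi * rho_S / 6)`, which makes the target rank
#' correlations attainable exactly in the large-sample limit.  The
#' assembled joint latent correlation matrix (identity within each fluid,
#' converted targets across fluids) must be positive semi-definite.
#'
#' @param target_spearman `n_shared x n_shared` matrix of Spearman
#'   correlations in `[-1, 1]`; rows index blood metabolites, columns CSF
#'   metabolites.
#' @param meanlog_blood,sdlog_blood,meanlog_csf,sdlog_csf log-normal
#'   location/scale, recycled to each fluid's metabolite count.
#' @param noise_sd additional i.i.d. Gaussian noise on the log scale
#'   (measurement error); 0 disables it.
#' @return A list of class `copula_spec`.
#' @export
copula_spec <- function(target_spearman, meanlog_blood = 0,
                        sdlog_blood = 0.5, meanlog_csf = 0,
                        sdlog_csf = 0.5, noise_sd = 0) {
  target_spearman <- as.matrix(target_spearman)
  if (any(abs(target_spearman) > 1))
    stop("target Spearman correlations must lie in [-1, 1]")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(target_spearman = target_spearman,
                 meanlog_blood = meanlog_blood, sdlog_blood = sdlog_blood,
                 meanlog_csf = meanlog_csf, sdlog_csf = sdlog_csf,
                 noise_sd = noise_sd),
            class = "copula_spec")
}

## assemble the joint latent correlation matrix and check PSD
copula_latent_corr <- function(design, copula) {
  nb <- design$n_metabolites_blood
  nc <- design$n_metabolites_csf
  ns <- design$n_shared
  ts <- copula$target_spearman
  if (!all(dim(ts) == c(ns, ns)))
    stop("target_spearman must be ", ns, " x ", ns,
         " (got ", nrow(ts), " x ", ncol(ts), ")")
  latent <- diag(nb + nc)
  cross <- 2 * sin(pi * ts / 6)          # Spearman -> latent Pearson
  latent[seq_len(ns), nb + seq_len(ns)] <- cross
  latent[nb + seq_len(ns), seq_len(ns)] <- t(cross)
  ev <- eigen(latent, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("joint latent correlation matrix is not positive semi-definite ",
         "(smallest eigenvalue ", signif(min(ev), 6), ")")
  latent
}

#' Simulate matched blood and CSF concentration tables
#'
#' Draws latent multivariate-normal scores with the copula's joint
#' correlation, transforms them through log-normal marginals, and applies
#' genotype and age effects as additive offsets on the log scale (which
#' preserves both the marginal family and within-group rank
#' correlations).  Blood and CSF rows are matched sample-for-sample, so
#' cross-fluid Spearman correlations of the shared metabolites converge
#' to `target_spearman` as the number of replicates grows.
#'
#' Default group effects: a log-scale shift of `genotype_shift` is added
#' to APP samples and `age_shift` to late-age samples, for the leading
#' `affected_fraction` of each fluid's metabolites.  These emulate the
#' moderate (~20%) concentration differences typical of transgenic-model
#' metabolomics; set both to 0 for a homogeneous cohort.
#'
#' @param design a [study_design()].
#' @param copula a [copula_spec()].
#' @param genotype_shift,age_shift log-scale mean offsets.
#' @param affected_fraction fraction (from the front of the metabolite
#'   list) receiving the group effects.
#' @return A list with `blood` and `csf` concentration tables (class
#'   `conc_table`: columns sample_id, sex, genotype, age_point, fluid,
#'   then metabolites) and `truth` (latent correlation, targets, effect
#'   configuration, seed).
#' @examples
#' des <- study_design(n_metabolites_blood = 4, n_metabolites_csf = 4,
#'                     n_shared = 4, replicates_per_group = 5, seed = 7)
#' cop <- copula_spec(diag(0.8, 4))
#' tabs <- simulate_concentration_table(des, cop)
#' head(tabs$blood)
#' @export
simulate_concentration_table <- function(design, copula,
                                         genotype_shift = 0.2,
                                         age_shift = 0.2,
                                         affected_fraction = 0.3) {
  stopifnot(inherits(design, "study_design"), inherits(copula, "copula_spec"))
  latent <- copula_latent_corr(design, copula)
  nb <- design$n_metabolites_blood
  nc <- design$n_metabolites_csf
  ns <- design$n_shared
  reps <- design$replicates_per_group
  groups <- design$groups
  nsamp <- nrow(groups) * reps

  shared <- sprintf("met%02d", seq_len(ns))
  blood_names <- c(shared, if (nb > ns) sprintf("bld%02d", seq_len(nb - ns)))
  csf_names <- c(shared, if (nc > ns) sprintf("csf%02d", seq_len(nc - ns)))

  ed <- eigen(latent, symmetric = TRUE)
  L <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), nrow(latent))
  z <- with_seed(design$seed, {
    zz <- matrix(rnorm(nsamp * nrow(latent)), nsamp) %*% t(L)
    if (copula$noise_sd > 0)
      zz <- zz + matrix(rnorm(nsamp * nrow(latent), sd = copula$noise_sd),
                        nsamp)
    zz
  })

  meta <- groups[rep(seq_len(nrow(groups)), each = reps), , drop = FALSE]
  meta$sample_id <- sprintf("pool_%s_%s_%s_r%d", meta$sex, meta$genotype,
                            meta$age_point, rep(seq_len(reps),
                                                times = nrow(groups)))
  rownames(meta) <- NULL

  mlb <- rep_len(copula$meanlog_blood, nb)
  slb <- rep_len(copula$sdlog_blood, nb)
  mlc <- rep_len(copula$meanlog_csf, nc)
  slc <- rep_len(copula$sdlog_csf, nc)

  logb <- sweep(sweep(z[, seq_len(nb), drop = FALSE], 2, slb, `*`),
                2, mlb, `+`)
  logc <- sweep(sweep(z[, nb + seq_len(nc), drop = FALSE], 2, slc, `*`),
                2, mlc, `+`)

  n_aff_b <- ceiling(affected_fraction * nb)
  n_aff_c <- ceiling(affected_fraction * nc)
  app <- meta$genotype == "APP"
  late <- meta$age_point == "late"
  if (n_aff_b > 0) {
    logb[app, seq_len(n_aff_b)] <- logb[app, seq_len(n_aff_b)] + genotype_shift
    logb[late, seq_len(n_aff_b)] <- logb[late, seq_len(n_aff_b)] + age_shift
  }
  if (n_aff_c > 0) {
    logc[app, seq_len(n_aff_c)] <- logc[app, seq_len(n_aff_c)] + genotype_shift
    logc[late, seq_len(n_aff_c)] <- logc[late, seq_len(n_aff_c)] + age_shift
  }

  mk <- function(values, names, fluid) {
    colnames(values) <- names
    df <- cbind(data.frame(sample_id = meta$sample_id, sex = meta$sex,
                           genotype = meta$genotype,
                           age_point = meta$age_point, fluid = fluid,
                           stringsAsFactors = FALSE),
                as.data.frame(exp(values)))
    conc_table(df)
  }

  list(blood = mk(logb, blood_names, "blood"),
       csf = mk(logc, csf_names, "csf"),
       truth = list(latent_corr = latent,
                    target_spearman = copula$target_spearman,
                    shared = shared,
                    genotype_shift = genotype_shift, age_shift = age_shift,
                    affected_blood = blood_names[seq_len(n_aff_b)],
                    affected_csf = csf_names[seq_len(n_aff_c)],
                    seed = design$seed))
}

#' Concentration table container
#'
#' A data frame of relative metabolite concentrations, one row per sample,
#' with the metadata columns `sample_id`, `sex`, `genotype`, `age_point`,
#' `fluid` first and one numeric column per metabolite after them.
#'
#' @param df a data frame with the columns above.
#' @return `df` with class `conc_table` and a `metabolites` attribute.
#' @export
conc_table <- function(df) {
  need <- c("sample_id", "sex", "genotype", "age_point", "fluid")
  if (!all(need %in% names(df)))
    stop("concentration table must have columns ",
         paste(need, collapse = ", "))
  mets <- setdiff(names(df), need)
  if (!length(mets)) stop("concentration table has no metabolite columns")
  df <- df[, c(need, mets)]
  attr(df, "metabolites") <- mets
  class(df) <- c("conc_table", "data.frame")
  df
}

#' @export
print.conc_table <- function(x, ...) {
  mets <- attr(x, "metabolites")
  cat("<conc_table> ", nrow(x), " samples x ", length(mets),
      " metabolites (fluid: ", paste(unique(x$fluid), collapse = "/"),
      ")\n", sep = "")
  print.data.frame(head(as.data.frame(x)[, seq_len(min(8, ncol(x)))], 4))
  invisible(x)
}

#' Metabolite columns of a concentration table
#' @param x a `conc_table`.
#' @return Character vector of metabolite column names.
#' @export
metabolites <- function(x) attr(x, "metabolites")

#' Write / read a concentration table as CSV
#' @param x a `conc_table`.
#' @param path CSV file path.
#' @return `read_conc_table()` returns a `conc_table`.
#' @export
write_conc_table <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_conc_table
#' @export
read_conc_table <- function(path) {
  conc_table(read.csv(path, stringsAsFactors = FALSE))
}
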