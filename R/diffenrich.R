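#' Empirical-Bayes variance prior from observed residual variances
#'
#' Estimates the hyperparameters (d0, s0^2) of the scaled inverse-chi-squared
#' variance prior by the standard moment method on log variances: the mean and
#' spread of log s_g^2 (bias-corrected with digamma/trigamma terms for the
#' sampling chi-squared noise at d_g df) are matched to the theoretical
#' scaled-F marginal. When the excess spread of log variances is <= 0 the
#' prior degrees of freedom are infinite; infinity is represented by the
#' documented cap 1e6.
#'
#' @param s2 numeric vector of observed residual variances (log2^2 units).
#' @param df numeric vector (recycled) of residual degrees of freedom.
#' @param min_proteins minimum number of usable variances (default 30).
#' @return A list of class \code{"variance_prior"}: \code{d0} (possibly the
#'   1e6 cap), \code{s0_sq}, and \code{n_used}.
#' @export
fit_fdist_moments <- function(s2, df, min_proteins = 30L) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & is.finite(df) & df >= 1
  s2 <- s2[ok]; df <- df[ok]
  if (length(s2) < min_proteins)
    stop("fit_fdist_moments: only ", length(s2),
         " usable variances (need >= ", min_proteins, ")")
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- mean((e - emean)^2 * n / (n - 1) - trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    d0 <- min(d0, D0_CAP)
  } else {
    d0 <- D0_CAP
    s0_sq <- exp(mean(log(s2)))
  }
  structure(list(d0 = d0, s0_sq = s0_sq, n_used = n),
            class = "variance_prior")
}

# cap used to represent an infinite prior df in outputs
D0_CAP <- 1e6

# Newton inversion of the trigamma function (solve trigamma(y) = x, x > 0)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Fit the variance prior from a log2 matrix
#'
#' Computes per-protein pooled within-group residual variances over every
#' (bait, condition) group with >= 2 present replicates, then fits the
#' empirical-Bayes prior via \code{\link{fit_fdist_moments}}.
#'
#' @param logmat log2 matrix with design attribute.
#' @param design optional \code{sample_design} override.
#' @return A \code{variance_prior}.
#' @export
fit_variance_prior <- function(logmat, design = NULL) {
  design <- log_matrix_design(logmat, design)
  rv <- residual_variances(logmat, design)
  fit_fdist_moments(rv$s2, rv$df)
}

residual_variances <- function(logmat, design) {
  groups <- unique(design$group)
  ss <- matrix(0, nrow(logmat), 1)
  dfv <- numeric(nrow(logmat))
  sstot <- numeric(nrow(logmat))
  for (g in groups) {
    cols <- design$sample_id[design$group == g]
    x <- logmat[, cols, drop = FALSE]
    ng <- rowSums(!is.na(x))
    mu <- rowMeans(x, na.rm = TRUE)
    dev <- sweep(x, 1, mu)
    ssg <- rowSums(dev^2, na.rm = TRUE)
    use <- ng >= 2
    sstot[use] <- sstot[use] + ssg[use]
    dfv[use] <- dfv[use] + (ng[use] - 1)
  }
  s2 <- ifelse(dfv >= 1, sstot / pmax(dfv, 1), NA_real_)
  list(s2 = s2, df = dfv)
}

#' Moderated t-test of one group against another
#'
#' Two-group comparison on log2 intensities with empirical-Bayes variance
#' shrinkage: for each protein with >= 2 present values in both groups,
#' logFC is the difference of group means, the pooled residual variance
#' s_g^2 (d_g = n1 + n2 - 2) is shrunk to
#' s_post^2 = (d0 * s0^2 + d_g * s_g^2) / (d0 + d_g), and
#' t = logFC / sqrt(s_post^2 * (1/n1 + 1/n2)) is referred to a t distribution
#' on d0 + d_g df (two-sided). Proteins with a degenerate group are marked
#' \code{testable = FALSE}, never silently dropped. \code{d0 = 0} reduces to
#' the ordinary pooled two-sample t-test.
#'
#' @param logmat log2 matrix.
#' @param contrast character of length 2: \code{c(group1, group2)}; logFC is
#'   group1 minus group2 (e.g. \code{c("Cav1_NT", "NES_NT")}).
#' @param prior a \code{variance_prior}, or a list with \code{d0},
#'   \code{s0_sq} (\code{d0 = 0} disables shrinkage).
#' @param design optional \code{sample_design} override.
#' @return A data.frame of class \code{"diff_result"}: \code{protein_id},
#'   \code{logFC}, \code{s_g_sq}, \code{d_g}, \code{s_post_sq}, \code{t_mod},
#'   \code{p}, \code{df_total}, \code{testable}; contrast and prior stored as
#'   attributes.
#' @export
moderated_t_test <- function(logmat, contrast, prior, design = NULL) {
  design <- log_matrix_design(logmat, design)
  stopifnot(length(contrast) == 2)
  unknown <- setdiff(contrast, design$group)
  if (length(unknown))
    stop("moderated_t_test: unknown group(s): ", paste(unknown, collapse = ", "))
  d0 <- min(prior$d0, D0_CAP)
  s0_sq <- prior$s0_sq

  c1 <- design$sample_id[design$group == contrast[1]]
  c2 <- design$sample_id[design$group == contrast[2]]
  x1 <- logmat[, c1, drop = FALSE]; x2 <- logmat[, c2, drop = FALSE]
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- apply(x1, 1, stats::var, na.rm = TRUE)
  v2 <- apply(x2, 1, stats::var, na.rm = TRUE)

  testable <- n1 >= 2 & n2 >= 2
  logFC <- ifelse(testable, m1 - m2, NA_real_)
  d_g <- ifelse(testable, n1 + n2 - 2, NA_real_)
  s_g_sq <- ifelse(testable, ((n1 - 1) * v1 + (n2 - 1) * v2) / pmax(d_g, 1),
                   NA_real_)
  if (d0 > 0) {
    s_post_sq <- (d0 * s0_sq + d_g * s_g_sq) / (d0 + d_g)
  } else {
    s_post_sq <- s_g_sq
  }
  se <- sqrt(s_post_sq * (1 / n1 + 1 / n2))
  t_mod <- logFC / se
  df_total <- pmin(d0 + d_g, D0_CAP)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)

  res <- data.frame(protein_id = rownames(logmat), logFC = logFC,
                    s_g_sq = s_g_sq, d_g = d_g, s_post_sq = s_post_sq,
                    t_mod = t_mod, p = p, df_total = df_total,
                    testable = testable,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "contrast") <- contrast
  attr(res, "prior") <- list(d0 = d0, s0_sq = s0_sq)
  class(res) <- c("diff_result", "data.frame")
  res
}

#' Call enrichment per condition against the spatial reference
#'
#' A protein is called enriched in a condition iff it is testable, its raw
#' p-value is strictly below \code{p_thresh} and its logFC is strictly above
#' \code{lfc_thresh} — the volcano-plot rule "p-value < 0.05 and logFC > 0"
#' (defaults).
#'
#' @param results named list of \code{diff_result} for the condition-vs-NES
#'   contrasts; names are the conditions (e.g. NT, HYPO, REC).
#' @param p_thresh p-value threshold, strict (default 0.05).
#' @param lfc_thresh log2 fold-change threshold, strict (default 0).
#' @param use_q if TRUE, threshold Benjamini-Hochberg adjusted values instead
#'   of raw p (stricter optional mode; default FALSE as in the headline
#'   analysis).
#' @return A logical matrix of class \code{"enrichment_calls"}, proteins x
#'   conditions.
#' @export
call_enrichment <- function(results, p_thresh = 0.05, lfc_thresh = 0,
                            use_q = FALSE) {
  stopifnot(is.list(results), length(results) >= 1, !is.null(names(results)))
  ids <- results[[1]]$protein_id
  for (r in results)
    if (!identical(r$protein_id, ids))
      stop("call_enrichment: results do not share one protein universe")
  calls <- sapply(results, function(r) {
    p <- if (use_q) bh_adjust(r$p[r$testable]) else r$p[r$testable]
    out <- rep(FALSE, length(ids))
    out[r$testable] <- p < p_thresh & r$logFC[r$testable] > lfc_thresh
    out
  })
  rownames(calls) <- ids
  class(calls) <- c("enrichment_calls", class(calls))
  calls
}

INTERACTOME_CATEGORIES <- c("NT_only", "HYPO_only", "REC_only", "NT_HYPO",
                            "NT_REC", "HYPO_REC", "NT_HYPO_REC", "none")

#' Classify the interactome by condition-membership pattern
#'
#' Partitions proteins into the 2^3 membership categories of the NT/HYPO/REC
#' enrichment calls. The co-recovered set — proteins enriched with the bait
#' at rest and after recovery, i.e. the tension-sensitive interactome of the
#' network figure — is NT_REC plus NT_HYPO_REC.
#'
#' @param calls an \code{enrichment_calls} matrix with columns NT, HYPO, REC.
#' @return A list of class \code{"interactome_classes"}: \code{category}
#'   (named character per protein), \code{counts} (per category),
#'   \code{n_significant} (unique proteins in any category),
#'   \code{co_recovered} (character vector of protein ids).
#' @export
classify_interactome <- function(calls) {
  stopifnot(all(c("NT", "HYPO", "REC") %in% colnames(calls)))
  nt <- calls[, "NT"]; hy <- calls[, "HYPO"]; re <- calls[, "REC"]
  category <- rep("none", nrow(calls))
  category[nt & !hy & !re] <- "NT_only"
  category[!nt & hy & !re] <- "HYPO_only"
  category[!nt & !hy & re] <- "REC_only"
  category[nt & hy & !re] <- "NT_HYPO"
  category[nt & !hy & re] <- "NT_REC"
  category[!nt & hy & re] <- "HYPO_REC"
  category[nt & hy & re] <- "NT_HYPO_REC"
  names(category) <- rownames(calls)
  counts <- table(factor(category, levels = INTERACTOME_CATEGORIES))
  structure(list(category = category,
                 counts = counts,
                 n_significant = sum(category != "none"),
                 co_recovered = names(category)[category %in%
                                                  c("NT_REC", "NT_HYPO_REC")]),
            class = "interactome_classes")
}

#' Row z-score profiles across conditions
#'
#' For each protein, z = (x - row mean) / row sd over non-missing entries
#' (sample sd, denominator n - 1), either per Cav1 sample or per Cav1
#' condition mean. Rows with fewer than 2 distinct non-missing values are
#' flagged undefined; missing entries are flagged NA (the heatmap's "not
#' identified").
#'
#' @param logmat log2 matrix.
#' @param protein_subset optional character vector of protein ids to profile.
#' @param mode \code{"per_sample"} (every Cav1 sample column) or
#'   \code{"per_condition_mean"} (mean over replicates per condition first).
#' @param design optional \code{sample_design} override.
#' @return A list of class \code{"z_profile"}: \code{z} matrix,
#'   \code{na_flags} logical matrix, \code{undefined} logical per row.
#' @export
zscore_profiles <- function(logmat, protein_subset = NULL,
                            mode = c("per_sample", "per_condition_mean"),
                            design = NULL) {
  mode <- match.arg(mode)
  design <- log_matrix_design(logmat, design)
  if (!is.null(protein_subset)) {
    missing_ids <- setdiff(protein_subset, rownames(logmat))
    if (length(missing_ids))
      stop("zscore_profiles: unknown protein id(s): ",
           paste(utils::head(missing_ids, 3), collapse = ", "))
    logmat <- logmat[protein_subset, , drop = FALSE]
  }
  cav <- design[design$bait == "Cav1", , drop = FALSE]
  if (mode == "per_sample") {
    x <- logmat[, cav$sample_id, drop = FALSE]
  } else {
    conds <- c("NT", "HYPO", "REC")
    x <- sapply(conds, function(cc) {
      cols <- cav$sample_id[cav$condition == cc]
      rowMeans(logmat[, cols, drop = FALSE], na.rm = TRUE)
    })
    x[is.nan(x)] <- NA_real_
    rownames(x) <- rownames(logmat)
  }
  mu <- rowMeans(x, na.rm = TRUE)
  sdv <- apply(x, 1, stats::sd, na.rm = TRUE)
  n_distinct <- apply(x, 1, function(r) length(unique(r[!is.na(r)])))
  undefined <- n_distinct < 2 | is.na(sdv) | sdv == 0
  z <- sweep(sweep(x, 1, mu), 1, sdv, "/")
  z[undefined, ] <- NA_real_
  structure(list(z = z, na_flags = is.na(x), undefined = undefined),
            class = "z_profile")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-adjusted p-values; optional stricter significance mode (the
#' headline analysis thresholds raw p-values).
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed).
#' @return Adjusted values (monotone, <= 1).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("bh_adjust: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
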