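#' Configuration for the synthetic LFQ proximity-proteomics generator
#'
#' Defines the planted interactor classes and noise model used to emulate a
#' 4-group (Cav1 under NT/HYPO/REC plus the NES spatial reference) triplicate
#' LFQ experiment. Intensities are generated on the log2 scale as
#' baseline + class effect(condition) + Normal(0, replicate_sd), exponentiated
#' for the raw table, and left-censored to missing below a fixed log2
#' detection limit (missing-not-at-random). An optional \code{mcar_rate}
#' additionally drops observed values completely at random.
#'
#' Planted classes and their default log2 enrichments over the NES reference:
#' \describe{
#'   \item{core_caveolar}{NT = 3, HYPO = 0, REC = 3 — the tension-sensitive
#'     caveolar core that dissociates under hypo-osmotic shock and re-associates
#'     on recovery.}
#'   \item{nt_rec_specific}{NT = 2, HYPO = 0, REC = 2 — weaker co-recovered
#'     interactors with the same membership pattern.}
#'   \item{hypo_specific}{NT = 0, HYPO = 2.5, REC = 0 — recruited only under
#'     high membrane tension.}
#'   \item{hypo_rec_specific}{NT = 0, HYPO = 2.5, REC = 2.5.}
#'   \item{background}{all zero — non-specific bystanders.}
#' }
#'
#' @param n_proteins number of simulated protein groups.
#' @param n_replicates replicates per group (>= 2).
#' @param class_fractions named numeric vector over the five classes, summing
#'   to 1.
#' @param effect_sizes named list: per class, named numeric vector of log2
#'   enrichment over NES for conditions NT, HYPO, REC.
#' @param baseline_mean,baseline_sd mean and sd of per-protein baseline log2
#'   intensity.
#' @param replicate_sd within-group replicate noise, log2 units (> 0).
#' @param detection_limit log2 intensity below which a value is censored to
#'   missing; \code{-Inf} disables censoring.
#' @param mcar_rate probability of additional completely-at-random dropout
#'   (default 0).
#' @param seed integer RNG seed.
#' @return A list of class \code{"synth_proteome_config"}.
#' @export
synth_proteome_config <- function(n_proteins = 2000L,
                                  n_replicates = 3L,
                                  class_fractions = c(core_caveolar = 0.05,
                                                      nt_rec_specific = 0.05,
                                                      hypo_specific = 0.05,
                                                      hypo_rec_specific = 0.03,
                                                      background = 0.82),
                                  effect_sizes = list(
                                    core_caveolar = c(NT = 3, HYPO = 0, REC = 3),
                                    nt_rec_specific = c(NT = 2, HYPO = 0, REC = 2),
                                    hypo_specific = c(NT = 0, HYPO = 2.5, REC = 0),
                                    hypo_rec_specific = c(NT = 0, HYPO = 2.5, REC = 2.5),
                                    background = c(NT = 0, HYPO = 0, REC = 0)),
                                  baseline_mean = 25,
                                  baseline_sd = 2,
                                  replicate_sd = 0.5,
                                  detection_limit = 22,
                                  mcar_rate = 0,
                                  seed = 1L) {
  if (abs(sum(class_fractions) - 1) > 1e-8)
    stop("synth_proteome_config: class_fractions must sum to 1")
  if (n_replicates < 2L)
    stop("synth_proteome_config: n_replicates must be >= 2")
  if (replicate_sd <= 0)
    stop("synth_proteome_config: replicate_sd must be > 0")
  if (!all(names(class_fractions) %in% names(effect_sizes)))
    stop("synth_proteome_config: every class needs an effect_sizes entry")
  if (mcar_rate < 0 || mcar_rate >= 1)
    stop("synth_proteome_config: mcar_rate must be in [0, 1)")
  structure(list(n_proteins = as.integer(n_proteins),
                 n_replicates = as.integer(n_replicates),
                 class_fractions = class_fractions,
                 effect_sizes = effect_sizes,
                 baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd,
                 replicate_sd = replicate_sd,
                 detection_limit = detection_limit,
                 mcar_rate = mcar_rate,
                 seed = as.integer(seed)),
            class = "synth_proteome_config")
}

#' Simulate an LFQ proximity-labelling experiment with planted ground truth
#'
#' Draws per-protein baselines, assigns each protein to an interactor class,
#' adds the class's condition-specific log2 enrichment to the Cav1 groups,
#' adds replicate noise, censors values below the detection limit to missing,
#' and returns both the raw-scale intensity table and the planted truth.
#'
#' @param config a \code{\link{synth_proteome_config}}.
#' @return A list with elements \code{table} (an \code{intensity_table}: raw
#'   intensities with all QC flags FALSE and the 4 x n_replicates design) and
#'   \code{truth} (data.frame: \code{protein_id}, \code{class}, and true log2
#'   effects \code{effect_NT}, \code{effect_HYPO}, \code{effect_REC}).
#' @export
simulate_lfq_experiment <- function(config = synth_proteome_config()) {
  stopifnot(inherits(config, "synth_proteome_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  design <- default_design(config$n_replicates)

  classes <- names(config$class_fractions)
  n_per <- drop(stats::rmultinom(1, n, config$class_fractions))
  class_lab <- rep(classes, n_per)

  protein_id <- sprintf("PROT%05d", seq_len(n))
  eff <- t(vapply(class_lab, function(cl) config$effect_sizes[[cl]][c("NT", "HYPO", "REC")],
                  numeric(3)))
  colnames(eff) <- c("NT", "HYPO", "REC")

  baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
  logmat <- matrix(NA_real_, n, nrow(design),
                   dimnames = list(protein_id, design$sample_id))
  for (j in seq_len(nrow(design))) {
    mu <- baseline
    if (design$bait[j] == "Cav1")
      mu <- mu + eff[, design$condition[j]]
    logmat[, j] <- mu + stats::rnorm(n, 0, config$replicate_sd)
  }
  logmat[logmat < config$detection_limit] <- NA_real_
  if (config$mcar_rate > 0) {
    drop <- matrix(stats::runif(length(logmat)) < config$mcar_rate,
                   nrow(logmat))
    logmat[drop] <- NA_real_
  }

  raw <- 2^logmat
  flags <- data.frame(contaminant = rep(FALSE, n), reverse = FALSE,
                      only_by_site = FALSE)
  truth <- data.frame(protein_id = protein_id, class = class_lab,
                      effect_NT = eff[, "NT"], effect_HYPO = eff[, "HYPO"],
                      effect_REC = eff[, "REC"],
                      stringsAsFactors = FALSE, row.names = NULL)
  list(table = new_intensity_table(raw, flags, design), truth = truth)
}

#' Write an intensity table in the MaxQuant proteinGroups dialect
#'
#' Tab-separated text with columns "Majority protein IDs", one
#' "LFQ intensity <sample>" column per sample, and the three QC flag columns
#' ("Potential contaminant", "Reverse", "Only identified by site") using the
#' MaxQuant "+" / empty convention. Missing intensities are written as 0,
#' the MaxQuant convention for "not identified".
#'
#' @param table an \code{intensity_table}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_protein_table <- function(table, path) {
  stopifnot(inherits(table, "intensity_table"))
  raw <- table$intensity
  raw[is.na(raw)] <- 0
  df <- data.frame(check.names = FALSE,
                   "Majority protein IDs" = rownames(table$intensity))
  for (s in colnames(raw)) df[[paste("LFQ intensity", s)]] <- raw[, s]
  df[["Potential contaminant"]] <- ifelse(table$flags$contaminant, "+", "")
  df[["Reverse"]] <- ifelse(table$flags$reverse, "+", "")
  df[["Only identified by site"]] <- ifelse(table$flags$only_by_site, "+", "")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
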