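#' Run configuration for the proteomics pipeline
#'
#' Validates and assembles the configuration of an end-to-end proteomics run.
#' Input is either a proteinGroups-style file plus design, an
#' \code{intensity_table}, or a \code{synth_proteome_config} for a synthetic
#' run.
#'
#' @param table an \code{intensity_table}, or NULL.
#' @param table_path path to a proteinGroups-style TSV (with \code{design}).
#' @param design a \code{\link{sample_design}} (required with
#'   \code{table_path}).
#' @param synth a \code{\link{synth_proteome_config}} for synthetic input.
#' @param k replicate-presence threshold (NULL = full group size).
#' @param p_thresh,lfc_thresh significance thresholds (strict; defaults 0.05
#'   and 0).
#' @param use_q threshold BH-adjusted values instead of raw p.
#' @param impute enable down-shifted imputation (default FALSE).
#' @param impute_width,impute_shift imputation parameters.
#' @param seed integer seed recorded in outputs and used for imputation.
#' @param out_dir optional output directory for tables and the summary JSON.
#' @return A validated list of class \code{"run_config"}.
#' @export
run_config <- function(table = NULL, table_path = NULL, design = NULL,
                       synth = NULL, k = NULL, p_thresh = 0.05,
                       lfc_thresh = 0, use_q = FALSE, impute = FALSE,
                       impute_width = 0.3, impute_shift = 1.8, seed = 1L,
                       out_dir = NULL) {
  n_inputs <- (!is.null(table)) + (!is.null(table_path)) + (!is.null(synth))
  if (n_inputs != 1)
    stop("run_config: provide exactly one of table, table_path, synth")
  if (!is.null(table_path)) {
    if (!file.exists(table_path))
      stop("run_config: table_path does not exist: ", table_path)
    if (is.null(design)) stop("run_config: table_path requires a design")
  }
  if (!is.null(table)) design <- table$design
  if (!is.null(synth)) {
    stopifnot(inherits(synth, "synth_proteome_config"))
    design <- default_design(synth$n_replicates)
  }
  if (!is.null(k)) {
    min_group <- min(table(design$group))
    if (k > min_group)
      stop("run_config: k = ", k, " exceeds the smallest group size (",
           min_group, ")")
  }
  if (p_thresh <= 0 || p_thresh > 1) stop("run_config: p_thresh out of range")
  structure(list(table = table, table_path = table_path, design = design,
                 synth = synth, k = k, p_thresh = p_thresh,
                 lfc_thresh = lfc_thresh, use_q = use_q, impute = impute,
                 impute_width = impute_width, impute_shift = impute_shift,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full differential-enrichment pipeline
#'
#' Executes read -> flag removal -> log2 -> replicate-presence filter ->
#' (optional imputation) -> variance-prior fit -> three condition-vs-NES
#' moderated t-tests and three pairwise Cav1 contrasts -> enrichment calls ->
#' interactome classification -> z-score profiles, logging per-stage row
#' counts. When \code{out_dir} is set, per-contrast result TSVs, the
#' classification table, the z-score matrix (with "NA" literals) and a
#' machine-readable JSON summary are written.
#'
#' @param config a \code{\link{run_config}}.
#' @return A list of class \code{"pipeline_result"}: \code{logmat},
#'   \code{prior}, \code{results} (named list of \code{diff_result}; vs-NES
#'   contrasts named NT/HYPO/REC, pairwise named e.g. NT_vs_HYPO),
#'   \code{calls}, \code{classes}, \code{zprofile}, \code{truth} (synthetic
#'   runs only), \code{summary} (counts and thresholds), \code{log}
#'   (character vector of stage messages).
#' @export
run_proteomics_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character()
  note <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    msg
  }
  truth <- NULL
  if (!is.null(config$synth)) {
    sim <- simulate_lfq_experiment(config$synth)
    table <- sim$table; truth <- sim$truth
    note("input: synthetic experiment, ", nrow(table$intensity), " proteins")
  } else if (!is.null(config$table_path)) {
    table <- read_protein_table(config$table_path, config$design)
    note("input: ", config$table_path, ", ", nrow(table$intensity), " proteins")
  } else {
    table <- config$table
    note("input: in-memory table, ", nrow(table$intensity), " proteins")
  }

  n0 <- nrow(table$intensity)
  table <- remove_flagged_rows(table)
  note("remove_flagged_rows: ", n0, " -> ", nrow(table$intensity))
  logmat <- log2_transform(table)
  logmat <- replicate_presence_filter(logmat, k = config$k)
  note(utils::tail(attr(logmat, "provenance"), 1))
  if (config$impute) {
    logmat <- impute_downshifted(logmat, config$impute_width,
                                 config$impute_shift, config$seed)
    note(utils::tail(attr(logmat, "provenance"), 1))
  }

  prior <- fit_variance_prior(logmat)
  note(sprintf("variance prior: d0 = %.4g, s0_sq = %.4g (n = %d)",
               prior$d0, prior$s0_sq, prior$n_used))

  conditions <- c("NT", "HYPO", "REC")
  results <- list()
  for (cc in conditions)
    results[[cc]] <- moderated_t_test(logmat,
                                      c(paste0("Cav1_", cc), "NES_NT"), prior)
  pairwise <- list(c("NT", "REC"), c("NT", "HYPO"), c("REC", "HYPO"))
  for (pr in pairwise) {
    nm <- paste0(pr[1], "_vs_", pr[2])
    results[[nm]] <- moderated_t_test(logmat, paste0("Cav1_", pr), prior)
  }
  calls <- call_enrichment(results[conditions], config$p_thresh,
                           config$lfc_thresh, config$use_q)
  classes <- classify_interactome(calls)
  note("significant (any condition): ", classes$n_significant,
       "; co-recovered (NT&REC): ", length(classes$co_recovered))

  sig <- names(classes$category)[classes$category != "none"]
  zprof <- if (length(sig) >= 1)
    zscore_profiles(logmat, sig, mode = "per_condition_mean") else NULL

  summary <- list(n_input = n0,
                  n_after_flags = nrow(table$intensity),
                  n_after_presence = nrow(logmat),
                  prior = list(d0 = prior$d0, s0_sq = prior$s0_sq),
                  thresholds = list(p = config$p_thresh,
                                    logFC = config$lfc_thresh,
                                    use_q = config$use_q,
                                    k = if (is.null(config$k))
                                      min(table(config$design$group))
                                    else config$k),
                  imputation = config$impute,
                  seed = config$seed,
                  category_counts = as.list(unclass(classes$counts)),
                  n_significant = classes$n_significant,
                  n_co_recovered = length(classes$co_recovered))

  res <- structure(list(logmat = logmat, prior = prior, results = results,
                        calls = calls, classes = classes, zprofile = zprof,
                        truth = truth, summary = summary, log = log),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(res$results)) {
    out <- res$results[[nm]][, c("protein_id", "logFC", "t_mod", "p",
                                 "df_total", "testable")]
    utils::write.table(out, file.path(out_dir, paste0("contrast_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cls <- data.frame(protein_id = names(res$classes$category),
                    category = unname(res$classes$category))
  utils::write.table(cls, file.path(out_dir, "interactome_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$zprofile)) {
    z <- res$zprofile$z
    utils::write.table(cbind(protein_id = rownames(z), as.data.frame(z)),
                       file.path(out_dir, "zscore_matrix.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  }
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(res$log, file.path(out_dir, "pipeline.log"))
  invisible(out_dir)
}

#' Sensitivity and false-category rate against planted truth
#'
#' For a synthetic run: sensitivity is the fraction of planted tension-
#' sensitive interactors (classes core_caveolar and nt_rec_specific, i.e.
#' the planted NT&REC pattern) classified NT_REC or NT_HYPO_REC; the
#' false-category rate is the fraction of planted background proteins,
#' among those surviving the presence filter, assigned any non-none
#' category.
#'
#' @param result a \code{pipeline_result} from a synthetic run.
#' @return List: \code{sensitivity}, \code{background_false_rate},
#'   \code{n_planted}, \code{n_background}.
#' @export
recovery_metrics <- function(result) {
  if (is.null(result$truth)) stop("recovery_metrics: no planted truth")
  truth <- result$truth
  cat_ <- result$classes$category
  planted <- truth$protein_id[truth$class %in%
                                c("core_caveolar", "nt_rec_specific")]
  planted_seen <- intersect(planted, names(cat_))
  hit <- cat_[planted_seen] %in% c("NT_REC", "NT_HYPO_REC")
  bg <- intersect(truth$protein_id[truth$class == "background"], names(cat_))
  list(sensitivity = if (length(planted)) sum(hit) / length(planted) else NA,
       background_false_rate = if (length(bg)) mean(cat_[bg] != "none") else NA,
       n_planted = length(planted), n_background = length(bg))
}

#' End-to-end demo on synthetic data
#'
#' Generates every synthetic fixture (LFQ experiment, interaction edge
#' tables, gene sets, polarised-cell and PLA images, migration tracks), runs
#' every analysis module, and writes a browsable bundle of tables, plots and
#' a manifest under \code{out_dir}. Two runs with the same seed produce
#' identical tables.
#'
#' @param seed integer seed driving every generator.
#' @param out_dir output directory.
#' @return Invisibly, a list with the main results (pipeline result, ORA
#'   table, imaging and motility summaries) and the manifest of files
#'   written.
#' @export
run_demo <- function(seed = 1L, out_dir = tempfile("caviprox_demo_")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- run_config(synth = synth_proteome_config(seed = seed), seed = seed,
                    out_dir = file.path(out_dir, "proteomics"))
  pipe <- run_proteomics_pipeline(cfg)

  # --- network + over-representation on synthetic annotations -------------
  set.seed(seed + 1L)
  universe <- rownames(pipe$logmat)
  co <- pipe$classes$co_recovered
  net_dir <- file.path(out_dir, "network")
  dir.create(net_dir, showWarnings = FALSE)
  files <- write_synthetic_edge_files(co, universe, net_dir)
  gmt_path <- file.path(net_dir, "synthetic_sets.gmt")
  write_synthetic_gmt(pipe$truth, universe, gmt_path)
  edges <- rbind(
    filter_edges(load_edge_table(files["biogrid"], "biogrid")),
    filter_edges(load_edge_table(files["string"], "string")),
    filter_edges(load_edge_table(files["literature"], "literature")))
  class(edges) <- c("edge_table", "data.frame")
  g <- build_network(co, edges, categories = pipe$classes$category)
  write_network(g, file.path(net_dir, "network.graphml"),
                file.path(net_dir, "network_edges.tsv"))
  ora <- overrepresentation_test(co, read_gmt(gmt_path), universe)
  utils::write.table(ora, file.path(net_dir, "ora_results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- imaging -------------------------------------------------------------
  img_dir <- file.path(out_dir, "imaging")
  dir.create(img_dir, showWarnings = FALSE)
  pol <- simulate_polarized_cell_image(rear_fold = 8, noise = "poisson",
                                       seed = seed)
  axis <- estimate_polarity_axis(pol$mask, pol$image)
  idx <- rear_localization_index(pol$image, pol$mask, axis = axis,
                                 background = pol$truth$background)
  qp <- quadrant_profile(pol$image, pol$mask, axis,
                         background = pol$truth$background)
  pla <- simulate_pla_image(n_dots = 12, min_separation = 20, seed = seed)
  dots <- count_pla_dots(pla$image, pla$mask)
  pla_axis <- estimate_polarity_axis(pla$mask, pla$image,
                                     rear_hint = c(1, 1))
  rf <- rear_fraction_of_dots(dots$centroids, pla_axis, pla$mask)
  r_coloc <- pearson_colocalization(pol$image, pol$image + 10, pol$mask)
  imaging <- data.frame(rear_index = idx,
                        rear_quadrant_mean = qp$quadrant_means["rear"],
                        front_quadrant_mean = qp$quadrant_means["front"],
                        pla_dots = dots$n_total,
                        pla_rear_fraction = rf$fraction,
                        pearson_r = r_coloc)
  utils::write.table(imaging, file.path(img_dir, "imaging_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_image_tiff(pol$image, file.path(img_dir, "polarized_cell.tiff"),
                   scale = max(pol$image))
  write_image_tiff(pla$image, file.path(img_dir, "pla.tiff"),
                   scale = max(pla$image))
  write_image_tiff(pla$mask, file.path(img_dir, "pla_mask.tiff"), scale = 1)

  # --- motility ------------------------------------------------------------
  mot_dir <- file.path(out_dir, "motility")
  dir.create(mot_dir, showWarnings = FALSE)
  tracks <- simulate_tracks(60, seed = seed + 2L)
  tracks <- normalize_tracks_to_origin(tracks)
  write_tracks(tracks, file.path(mot_dir, "tracks.csv"))
  stats_tab <- track_statistics(tracks)
  utils::write.table(stats_tab, file.path(mot_dir, "track_stats.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  curve <- msd(tracks, max_lag = 60)
  utils::write.table(curve, file.path(mot_dir, "msd.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  fit <- fit_furth(curve)

  # --- plots ---------------------------------------------------------------
  plot_dir <- file.path(out_dir, "plots")
  dir.create(plot_dir, showWarnings = FALSE)
  grDevices::pdf(file.path(plot_dir, "volcano_NT.pdf"), width = 5, height = 5)
  r <- pipe$results$NT
  plot(r$logFC, -log10(r$p), pch = 20, cex = 0.4,
       col = ifelse(r$testable & r$p < 0.05 & r$logFC > 0, "red", "grey40"),
       xlab = "log2 fold change (Cav1 NT / NES)", ylab = "-log10 p",
       main = "NT vs spatial reference")
  grDevices::dev.off()
  grDevices::pdf(file.path(plot_dir, "msd.pdf"), width = 5, height = 5)
  plot(curve$lag_min, curve$msd_um2, pch = 20,
       xlab = "lag (min)", ylab = expression(MSD ~ (mu * m^2)),
       main = sprintf("PRW fit: S = %.2f um/min, P = %.1f min", fit$S, fit$P))
  lines(curve$lag_min, furth_msd(curve$lag_min, fit$S, fit$P), col = "red")
  grDevices::dev.off()
  if (!is.null(pipe$zprofile)) {
    grDevices::pdf(file.path(plot_dir, "zscore_heatmap.pdf"), 5, 7)
    z <- pipe$zprofile$z[!pipe$zprofile$undefined, , drop = FALSE]
    graphics::image(t(z[order(z[, "NT"]), ]), axes = FALSE,
                    main = "z-scored condition means",
                    col = grDevices::hcl.colors(64, "RdBu", rev = TRUE))
    graphics::axis(1, at = c(0, 0.5, 1), labels = colnames(z))
    grDevices::dev.off()
  }

  manifest <- list.files(out_dir, recursive = TRUE)
  writeLines(manifest, file.path(out_dir, "MANIFEST.txt"))
  invisible(list(pipeline = pipe, ora = ora, imaging = imaging,
                 track_stats = stats_tab, msd = curve, furth = fit,
                 manifest = manifest, out_dir = out_dir))
}

# Synthetic interaction-edge fixtures over the recovered proteins: a mix of
# edges that survive the evidence filters and edges that must be removed.
write_synthetic_edge_files <- function(nodes, universe, dir) {
  nodes <- unique(toupper(nodes))
  if (length(nodes) < 2) nodes <- unique(toupper(utils::head(universe, 10)))
  pairs <- t(utils::combn(nodes, 2))
  take <- function(n) pairs[sample.int(nrow(pairs), min(n, nrow(pairs))), ,
                            drop = FALSE]
  bg <- take(40)
  bg_df <- data.frame(check.names = FALSE,
                      "Official Symbol Interactor A" = bg[, 1],
                      "Official Symbol Interactor B" = bg[, 2],
                      "Experimental System" = sample(
                        c("Two-hybrid", "Affinity Capture-MS",
                          "Proximity Label-MS", "Affinity Capture-RNA"),
                        nrow(bg), replace = TRUE))
  st <- take(40)
  st_df <- data.frame(protein1 = st[, 1], protein2 = st[, 2],
                      combined_score = sample(150:950, nrow(st)))
  lit <- take(8)
  lit_df <- data.frame(protein_a = lit[, 1], protein_b = lit[, 2])
  paths <- c(biogrid = file.path(dir, "synthetic_biogrid.tsv"),
             string = file.path(dir, "synthetic_string.tsv"),
             literature = file.path(dir, "synthetic_literature.tsv"))
  utils::write.table(bg_df, paths["biogrid"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(st_df, paths["string"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(lit_df, paths["literature"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

# Synthetic gene sets: one set per planted class plus random decoys.
write_synthetic_gmt <- function(truth, universe, path) {
  sets <- split(truth$protein_id, truth$class)
  sets <- lapply(sets, function(s) intersect(s, universe))
  sets <- sets[vapply(sets, length, 1L) >= 3]
  for (i in 1:3)
    sets[[paste0("decoy_", i)]] <- sample(universe, min(50, length(universe)))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, paste0(nm, " synthetic set"), sets[[nm]]), collapse = "\t"),
    "")
  writeLines(lines, path)
  invisible(path)
}
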