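#' Construct an intensity table
#'
#' Container for protein-level raw LFQ intensities together with the MaxQuant
#' QC flags and the sample design. Raw zeros mean "not identified" in the
#' MaxQuant convention and are stored as \code{NA}.
#'
#' @param intensity numeric matrix, proteins x samples, rownames = protein
#'   accessions, colnames = design sample ids; \code{NA} = missing.
#' @param flags data.frame with logical columns \code{contaminant},
#'   \code{reverse}, \code{only_by_site}, one row per protein.
#' @param design a \code{\link{sample_design}}.
#' @return A list of class \code{"intensity_table"}.
#' @export
new_intensity_table <- function(intensity, flags, design) {
  stopifnot(is.matrix(intensity), inherits(design, "sample_design"))
  if (is.null(rownames(intensity)))
    stop("intensity_table: intensity needs protein-id rownames")
  if (anyDuplicated(rownames(intensity)))
    stop("intensity_table: duplicate protein ids")
  if (!identical(sort(colnames(intensity)), sort(design$sample_id)))
    stop("intensity_table: intensity columns must match design sample ids")
  intensity <- intensity[, design$sample_id, drop = FALSE]
  if (any(intensity < 0, na.rm = TRUE))
    stop("intensity_table: negative intensities")
  stopifnot(nrow(flags) == nrow(intensity),
            all(c("contaminant", "reverse", "only_by_site") %in% names(flags)))
  structure(list(intensity = intensity, flags = flags, design = design),
            class = "intensity_table")
}

#' Read a MaxQuant-style proteinGroups table
#'
#' Parses the tab-separated proteinGroups dialect: protein accessions from
#' "Majority protein IDs", one "LFQ intensity <sample>" column per design
#' sample, and the "+"-coded QC flag columns. Raw zeros are mapped to missing
#' at read time: a MaxQuant 0 means "not identified", and the downstream
#' replicate-presence rule is a presence rule, not an intensity rule.
#'
#' @param path path to the tab-separated file.
#' @param design a \code{\link{sample_design}}; every \code{sample_id} must
#'   have a matching "LFQ intensity" column.
#' @return An \code{\link{new_intensity_table}}.
#' @export
read_protein_table <- function(path, design) {
  if (!file.exists(path)) stop("read_protein_table: no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  idcol <- "Majority protein IDs"
  if (!idcol %in% names(df))
    stop("read_protein_table: missing column '", idcol, "'")
  ids <- as.character(df[[idcol]])
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("read_protein_table: duplicate protein id '", dup, "'")
  }
  want <- paste("LFQ intensity", design$sample_id)
  missing_cols <- setdiff(want, names(df))
  if (length(missing_cols))
    stop("read_protein_table: missing sample column(s): ",
         paste(missing_cols, collapse = ", "))
  raw <- as.matrix(df[, want, drop = FALSE])
  if (!is.numeric(raw)) {
    bad <- which(is.na(suppressWarnings(apply(df[, want, drop = FALSE], 2, as.numeric)))
                 & !is.na(df[, want, drop = FALSE]), arr.ind = TRUE)
    if (nrow(bad))
      stop("read_protein_table: unparseable numeric at row ", bad[1, 1],
           ", column '", want[bad[1, 2]], "'")
    storage.mode(raw) <- "double"
  }
  dimnames(raw) <- list(ids, design$sample_id)
  raw[raw == 0] <- NA_real_
  parse_flag <- function(col) {
    if (!col %in% names(df)) return(rep(FALSE, nrow(df)))
    x <- trimws(as.character(df[[col]]))
    !is.na(x) & x == "+"   # MaxQuant writes "+" or leaves the cell empty
  }
  flags <- data.frame(contaminant = parse_flag("Potential contaminant"),
                      reverse = parse_flag("Reverse"),
                      only_by_site = parse_flag("Only identified by site"))
  new_intensity_table(raw, flags, design)
}

#' Remove contaminant, reverse and site-only protein groups
#'
#' Drops every row with any of the three MaxQuant QC flags set (common
#' contaminants, reverse-database hits, proteins identified only by
#' site-specific modifications), preserving the order of the rest.
#'
#' @param table an \code{intensity_table}.
#' @return The filtered \code{intensity_table}.
#' @export
remove_flagged_rows <- function(table) {
  stopifnot(inherits(table, "intensity_table"))
  keep <- !(table$flags$contaminant | table$flags$reverse |
              table$flags$only_by_site)
  new_intensity_table(table$intensity[keep, , drop = FALSE],
                      table$flags[keep, , drop = FALSE], table$design)
}

#' Log2-transform an intensity table
#'
#' Element-wise log2 of the raw intensities; missing stays missing. Errors on
#' nonpositive present values (raw zeros must already be encoded as missing).
#'
#' @param table an \code{intensity_table}.
#' @return A numeric matrix (proteins x samples) of log2 intensities with
#'   attributes \code{design} and append-only \code{provenance}.
#' @export
log2_transform <- function(table) {
  stopifnot(inherits(table, "intensity_table"))
  x <- table$intensity
  if (any(x <= 0, na.rm = TRUE))
    stop("log2_transform: nonpositive intensity present; raw zeros must be missing")
  lm <- log2(x)
  attr(lm, "design") <- table$design
  attr(lm, "provenance") <- "log2_transform"
  lm
}

log_matrix_design <- function(logmat, design = NULL) {
  if (is.null(design)) design <- attr(logmat, "design")
  if (is.null(design)) stop("log matrix carries no design; pass one explicitly")
  design
}

add_provenance <- function(logmat, step) {
  attr(logmat, "provenance") <- c(attr(logmat, "provenance"), step)
  logmat
}

#' Replicate-presence filter
#'
#' Retains a protein iff it was identified (non-missing) in at least \code{k}
#' replicates of at least one (bait, condition) group — the "identified in
#' three out of three replicates of at least one sample" rule, with "sample"
#' read as a condition group. The default \code{k} is the full group size.
#'
#' @param logmat log2 matrix from \code{\link{log2_transform}}.
#' @param k required number of present replicates (default: minimum group
#'   size, i.e. all replicates of a group).
#' @param design optional \code{sample_design} override.
#' @return The filtered log2 matrix, provenance appended.
#' @export
replicate_presence_filter <- function(logmat, k = NULL, design = NULL) {
  design <- log_matrix_design(logmat, design)
  group_sizes <- table(design$group)
  if (is.null(k)) k <- min(group_sizes)
  if (k > min(group_sizes))
    stop("replicate_presence_filter: k = ", k,
         " exceeds the smallest group size (", min(group_sizes), ")")
  present <- !is.na(logmat)
  keep <- rep(FALSE, nrow(logmat))
  for (g in unique(design$group)) {
    cols <- design$sample_id[design$group == g]
    keep <- keep | rowSums(present[, cols, drop = FALSE]) >= k
  }
  out <- logmat[keep, , drop = FALSE]
  attr(out, "design") <- design
  attr(out, "provenance") <- attr(logmat, "provenance")
  add_provenance(out, sprintf("replicate_presence_filter(k=%d): %d -> %d proteins",
                              k, nrow(logmat), sum(keep)))
}

#' Down-shifted normal imputation of missing log2 intensities
#'
#' Optional Perseus-style stage, disabled by default in the pipeline: missing
#' values in sample column s are drawn from
#' Normal(mean_s - shift * sd_s, (width * sd_s)^2), emulating draws from the
#' low-abundance tail below the detection limit. Parameters and seed are
#' recorded in provenance.
#'
#' @param logmat log2 matrix.
#' @param width sd of the imputation distribution as a fraction of the
#'   observed column sd (default 0.3).
#' @param shift downward shift in observed-column sds (default 1.8).
#' @param seed integer RNG seed.
#' @return The imputed log2 matrix.
#' @export
impute_downshifted <- function(logmat, width = 0.3, shift = 1.8, seed = 1L) {
  design <- attr(logmat, "design")
  n_missing <- colSums(is.na(logmat))
  n_present <- colSums(!is.na(logmat))
  if (any(n_present < 2 & n_missing > 0))
    stop("impute_downshifted: a column with missing values has < 2 observed values")
  set.seed(seed)
  out <- logmat
  for (j in seq_len(ncol(out))) {
    miss <- is.na(out[, j])
    if (!any(miss)) next
    m <- mean(out[!miss, j]); s <- stats::sd(out[!miss, j])
    out[miss, j] <- stats::rnorm(sum(miss), m - shift * s, width * s)
  }
  attr(out, "design") <- design
  attr(out, "provenance") <- attr(logmat, "provenance")
  add_provenance(out, sprintf(
    "impute_downshifted(width=%g, shift=%g, seed=%d): %d values imputed",
    width, shift, seed, sum(n_missing)))
}
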