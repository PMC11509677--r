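#' Construct a sample design table
#'
#' Maps LFQ sample columns to the experimental design of the proximity
#' proteomics experiment: bait (\code{"Cav1"} APEX2 fusion or the cytoplasmic
#' \code{"NES"} spatial reference), osmotic condition (\code{"NT"} iso-osmotic
#' control, \code{"HYPO"} 5-min hypo-osmotic shock, \code{"REC"} 30-min
#' recovery) and replicate index. The NES reference is profiled only under
#' iso-osmotic conditions.
#'
#' @param sample_id character vector of unique sample identifiers, matching
#'   the "LFQ intensity <sample_id>" columns of the protein table.
#' @param bait character vector, one of \code{"Cav1"} or \code{"NES"} per sample.
#' @param condition character vector, one of \code{"NT"}, \code{"HYPO"},
#'   \code{"REC"} per sample.
#' @param replicate integer replicate index within each (bait, condition) group.
#' @return A \code{data.frame} of class \code{"sample_design"} with columns
#'   \code{sample_id}, \code{bait}, \code{condition}, \code{replicate} and a
#'   derived \code{group} label \code{"<bait>_<condition>"}.
#' @export
sample_design <- function(sample_id, bait, condition, replicate) {
  stopifnot(length(sample_id) == length(bait),
            length(bait) == length(condition),
            length(condition) == length(replicate))
  if (anyDuplicated(sample_id))
    stop("sample_design: sample_id values must be unique")
  if (!all(bait %in% c("Cav1", "NES")))
    stop("sample_design: bait must be 'Cav1' or 'NES'")
  if (!all(condition %in% c("NT", "HYPO", "REC")))
    stop("sample_design: condition must be 'NT', 'HYPO' or 'REC'")
  if (any(bait == "NES" & condition != "NT"))
    stop("sample_design: the NES spatial reference is profiled under NT only")
  d <- data.frame(sample_id = as.character(sample_id),
                  bait = bait, condition = condition,
                  replicate = as.integer(replicate),
                  stringsAsFactors = FALSE)
  d$group <- paste(d$bait, d$condition, sep = "_")
  if (any(table(d$group) < 1L)) stop("sample_design: empty group")
  class(d) <- c("sample_design", "data.frame")
  d
}

#' Default 4-group x 3-replicate design
#'
#' The design of the osmotic-perturbation experiment: Cav1 bait under NT,
#' HYPO and REC, plus the NES spatial reference under NT, each in triplicate.
#'
#' @param n_replicates replicates per group (default 3).
#' @return A \code{sample_design}.
#' @export
default_design <- function(n_replicates = 3L) {
  groups <- rbind(c("Cav1", "NT"), c("Cav1", "HYPO"),
                  c("Cav1", "REC"), c("NES", "NT"))
  bait <- rep(groups[, 1], each = n_replicates)
  condition <- rep(groups[, 2], each = n_replicates)
  replicate <- rep(seq_len(n_replicates), times = nrow(groups))
  sample_design(paste(bait, condition, replicate, sep = "_"),
                bait, condition, replicate)
}

#' Sample ids belonging to one (bait, condition) group
#' @param design a \code{sample_design}.
#' @param group group label \code{"<bait>_<condition>"}.
#' @return character vector of sample ids.
#' @export
group_samples <- function(design, group) {
  if (!group %in% design$group)
    stop("unknown group: ", group)
  design$sample_id[design$group == group]
}
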