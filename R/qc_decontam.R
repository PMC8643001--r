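# Sample QC, control-based contaminant flagging, control-prevalence
# diagnostics, and rarefaction.

#' Depth-based sample quality control
#'
#' Keeps exactly the samples whose read total is at least `min_depth`
#' (the boundary passes) and tallies survivors by sample type and PMA
#' status.  The default gate of 5000 reads is the conventional threshold
#' for low-biomass cleanroom amplicon surveys.
#'
#' @param x a [feature_table]
#' @param metadata a metadata data frame covering every sample in `x`
#' @param min_depth minimum read total to pass (default 5000)
#' @return list with `table` (the filtered [feature_table]) and `report`,
#'   a `qc_report` holding per-sample totals, pass flags and the survivor
#'   tally by (sample_type, pma_treated)
#' @export
qc_filter <- function(x, metadata, min_depth = 5000) {
  stopifnot(min_depth >= 1)
  if (ncol(x$counts) == 0L) stop("feature table has no samples")
  metadata <- align_metadata(metadata, sample_ids(x))
  totals <- sample_totals(x)
  pass <- totals >= min_depth
  kept <- ft_subset(x, samples = names(totals)[pass])
  tally <- as.data.frame(table(
    sample_type = metadata$sample_type[pass],
    pma_treated = metadata$pma_treated[pass]))
  tally <- tally[tally$Freq > 0L, , drop = FALSE]
  report <- structure(list(totals = totals, pass = pass,
                           min_depth = min_depth, tally = tally),
                      class = "qc_report")
  list(table = kept, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d / %d samples pass at min_depth = %d\n",
              sum(x$pass), length(x$pass), x$min_depth))
  if (nrow(x$tally)) {
    cat("  passing samples by group:\n")
    print(x$tally, row.names = FALSE)
  }
  invisible(x)
}

align_metadata <- function(metadata, ids) {
  i <- match(ids, metadata$sample_id)
  if (anyNA(i))
    stop("sample(s) absent from metadata: ",
         paste(utils::head(ids[is.na(i)], 5L), collapse = ", "))
  metadata[i, , drop = FALSE]
}

#' Flag putative reagent/processing contaminants from control samples
#'
#' A feature is flagged as a contaminant when both clauses hold:
#' \enumerate{
#'   \item it has a nonzero count in \emph{every} control sample
#'     (prevalence 1.0 across `prevalence_control_types`), and
#'   \item its abundance aggregated over the no-template controls
#'     (`abundance_control_types`) exceeds its abundance aggregated over
#'     the study (floor) samples.
#' }
#' By default the prevalence clause uses all control types (field, negative,
#' extraction) while the abundance clause uses only the no-template
#' controls (negative + extraction), since field controls are exposed to
#' room air and carry genuine signal.  Flagged features are removed from
#' the returned table.
#'
#' @param x a [feature_table]
#' @param metadata metadata covering the samples of `x`
#' @param prevalence_control_types sample types forming the 100%-prevalence
#'   control set
#' @param abundance_control_types sample types forming the no-template set
#'   for the abundance clause
#' @param aggregator how to aggregate raw counts for the abundance clause:
#'   arithmetic mean (default), median, or max
#' @return list with `table` (filtered [feature_table]) and `report`, a
#'   `contaminant_report` with per-feature diagnostics
#' @export
flag_contaminants <- function(x, metadata,
                              prevalence_control_types = control_sample_types(),
                              abundance_control_types = c("negative_control",
                                                          "extraction_control"),
                              aggregator = c("mean", "median", "max")) {
  aggregator <- match.arg(aggregator)
  metadata <- align_metadata(metadata, sample_ids(x))
  prev_ctrl <- metadata$sample_type %in% prevalence_control_types
  abun_ctrl <- metadata$sample_type %in% abundance_control_types
  study <- metadata$sample_type == "floor"
  if (!any(prev_ctrl) || !any(abun_ctrl))
    stop("no control samples present; skip decontamination explicitly ",
         "rather than running it without controls")
  if (!any(study)) stop("no study (floor) samples present")
  agg <- switch(aggregator, mean = rowMeans,
                median = function(m) apply(m, 1L, stats::median),
                max = function(m) apply(m, 1L, max))
  cnt <- x$counts
  prev <- rowMeans(cnt[, prev_ctrl, drop = FALSE] > 0L)
  ctrl_abund <- agg(cnt[, abun_ctrl, drop = FALSE])
  study_abund <- agg(cnt[, study, drop = FALSE])
  flagged <- prev == 1 & ctrl_abund > study_abund
  diagnostics <- data.frame(
    feature_id = feature_ids(x),
    control_prevalence = prev,
    control_abundance = ctrl_abund,
    study_abundance = study_abund,
    flagged = flagged,
    row.names = NULL)
  report <- structure(list(
    flagged = feature_ids(x)[flagged],
    diagnostics = diagnostics,
    prevalence_controls = sample_ids(x)[prev_ctrl],
    abundance_controls = sample_ids(x)[abun_ctrl],
    aggregator = aggregator), class = "contaminant_report")
  list(table = ft_subset(x, features = report$flagged, drop_features = TRUE),
       report = report)
}

#' @export
print.contaminant_report <- function(x, ...) {
  cat(sprintf("<contaminant_report> %d feature(s) flagged (%s aggregator)\n",
              length(x$flagged), x$aggregator))
  if (length(x$flagged))
    cat("  flagged:", paste(utils::head(x$flagged, 10L), collapse = ", "),
        if (length(x$flagged) > 10L) "..." else "", "\n")
  invisible(x)
}

#' Control-prevalence diagnostics
#'
#' Reports (a) how many features are present (raw count > 0) in any
#' control sample, and (b) how many of those occur in fewer than
#' `prevalence_cut` of the study (floor) samples — the classic signature
#' of low-level reagent noise.
#'
#' @inheritParams flag_contaminants
#' @param prevalence_cut fraction of study samples below which a control
#'   feature counts as rare (default 0.10)
#' @param control_types sample types considered controls
#' @return list with `n_control_features` and `n_rare_in_study`
#' @export
control_prevalence_stats <- function(x, metadata, prevalence_cut = 0.10,
                                     control_types = control_sample_types()) {
  stopifnot(prevalence_cut > 0, prevalence_cut <= 1)
  metadata <- align_metadata(metadata, sample_ids(x))
  ctrl <- metadata$sample_type %in% control_types
  study <- metadata$sample_type == "floor"
  in_ctrl <- rowSums(x$counts[, ctrl, drop = FALSE] > 0L) > 0L
  study_prev <- rowMeans(x$counts[, study, drop = FALSE] > 0L)
  list(n_control_features = sum(in_ctrl),
       n_rare_in_study = sum(in_ctrl & study_prev < prevalence_cut))
}

#' Rarefy a feature table to even depth
#'
#' Samples with fewer than `depth` reads are dropped; every surviving
#' sample is subsampled \emph{without replacement} to exactly `depth`
#' reads (a single multivariate-hypergeometric draw, not an average over
#' draws).  Deterministic under `seed`.
#'
#' @param x a [feature_table]
#' @param depth target depth (default 5000)
#' @param seed integer seed for the subsampling draw
#' @return a rarefied [feature_table]
#' @export
rarefy <- function(x, depth = 5000, seed = 1L) {
  stopifnot(depth >= 1)
  totals <- sample_totals(x)
  keep <- names(totals)[totals >= depth]
  x <- ft_subset(x, samples = keep)
  set.seed(seed)
  out <- apply(x$counts, 2L, rarefy_column, depth = depth)
  dimnames(out) <- dimnames(x$counts)
  feature_table(out, x$taxonomy)
}

# Multivariate hypergeometric draw by sequential rhyper: condition on the
# number already drawn; exact and O(#features) per sample.
rarefy_column <- function(counts, depth) {
  total <- sum(counts)
  out <- integer(length(counts))
  remaining <- total
  need <- depth
  for (i in seq_along(counts)) {
    if (need == 0L) break
    ci <- counts[i]
    if (ci == 0L) next
    draw <- stats::rhyper(1L, ci, remaining - ci, need)
    out[i] <- draw
    need <- need - draw
    remaining <- remaining - ci
  }
  out
}
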