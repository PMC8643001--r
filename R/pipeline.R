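# End-to-end orchestration: simulate/load -> QC -> decontaminate ->
# rarefy -> predict sporulation -> category/log-ratio/gradient/richness
# statistics -> bioburden arithmetic, with per-stage seeds derived from a
# single master seed and a machine-readable consolidated report.

#' Derive a stage seed from the master seed
#'
#' Deterministic, stage-name-keyed, and kept inside the 32-bit integer
#' range so it is portable across platforms.
#'
#' @param master_seed integer master seed
#' @param stage stage name
#' @return integer seed
#' @export
stage_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(master_seed) * 10007 + h * 101) %% 2147483647)
}

#' Configuration for an end-to-end pipeline run
#'
#' @param simulate a [study_config()] to generate the inputs, or `NULL`
#'   when `inputs` provides paths
#' @param inputs optional named list of paths: `table` (dense TSV),
#'   `metadata`, `tree` (Newick), `trait_labels` (TSV: feature_id, state)
#' @param stages character vector of optional stages to run; any of
#'   `decontam`, `rarefy`, `hsp`, `categories`, `logratio_gradient`,
#'   `richness`, `bioburden`
#' @param min_depth QC depth gate (default 5000)
#' @param rarefaction_depth even depth for rarefaction (default
#'   `min_depth`)
#' @param read_threshold genus/feature total-read inclusion threshold for
#'   category accounting (default 100)
#' @param prevalence_cut study-prevalence cut for control diagnostics
#'   (default 0.10)
#' @param tau classification threshold for sporulation prediction
#' @param ssb_ratio SSB viable-per-spore constant (default 50,000)
#' @param plate_records optional plate-count data frame for
#'   [bioburden_table()]
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it via [stage_seed()]
#' @param outdir optional output directory for the JSON report and
#'   per-stage TSV artifacts
#' @return a `run_config` list
#' @export
run_config <- function(simulate = study_config(),
                       inputs = NULL,
                       stages = c("decontam", "rarefy", "hsp", "categories",
                                  "logratio_gradient", "richness",
                                  "bioburden"),
                       min_depth = 5000,
                       rarefaction_depth = min_depth,
                       read_threshold = 100,
                       prevalence_cut = 0.10,
                       tau = 0.5,
                       ssb_ratio = 50000,
                       plate_records = NULL,
                       seed = 1L,
                       outdir = NULL) {
  known <- c("decontam", "rarefy", "hsp", "categories",
             "logratio_gradient", "richness", "bioburden")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(simulate) && is.null(inputs))
    stop("either a simulate config or input paths are required")
  structure(list(simulate = simulate, inputs = inputs, stages = stages,
                 min_depth = min_depth,
                 rarefaction_depth = rarefaction_depth,
                 read_threshold = read_threshold,
                 prevalence_cut = prevalence_cut, tau = tau,
                 ssb_ratio = ssb_ratio, plate_records = plate_records,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    sim$seed <- stage_seed(config$seed, "simulate")
    bundle <- simulate_cleanroom_study(do.call(study_config, unclass(sim)))
    return(list(table = bundle$table, metadata = bundle$metadata,
                tree = bundle$tree, trait_labels = bundle$truth$known_labels,
                bundle = bundle))
  }
  inp <- config$inputs
  table <- read_feature_table(inp$table)
  metadata <- read_metadata(inp$metadata)
  tree <- if (!is.null(inp$tree)) read_newick(inp$tree) else NULL
  trait_labels <- NULL
  if (!is.null(inp$trait_labels)) {
    df <- utils::read.delim(inp$trait_labels, colClasses = "character")
    trait_labels <- stats::setNames(df[[2L]], df[[1L]])
  }
  list(table = table, metadata = metadata, tree = tree,
       trait_labels = trait_labels, bundle = NULL)
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order; each optional stage can be toggled off,
#' in which case the report marks it `"skipped"`.  A stage failure stops
#' the run naming the stage.  With a fixed master seed the report is fully
#' reproducible.
#'
#' @param config a [run_config()]
#' @return a `run_report` list; if `config$outdir` is set, also writes
#'   `report.json` and per-stage TSV artifacts there
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  on_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  enabled <- function(s) s %in% config$stages
  report <- list(parameters = list(
    min_depth = config$min_depth,
    rarefaction_depth = config$rarefaction_depth,
    read_threshold = config$read_threshold,
    prevalence_cut = config$prevalence_cut,
    tau = config$tau, ssb_ratio = config$ssb_ratio,
    seed = config$seed, stages = config$stages))

  dat <- on_stage("load", load_pipeline_inputs(config))
  table <- dat$table; metadata <- dat$metadata

  qc <- on_stage("qc", qc_filter(table, metadata, config$min_depth))
  tally <- qc$report$tally
  report$qc <- list(
    n_samples_in = ncol(table$counts),
    n_samples_pass = sum(qc$report$pass),
    pass_by_group = if (nrow(tally)) stats::setNames(
      tally$Freq, paste0(tally$sample_type,
                         ifelse(tally$pma_treated == "TRUE", "+PMA", "-PMA")))
      else NULL)
  table <- qc$table

  if (enabled("decontam")) {
    dec <- on_stage("decontam", flag_contaminants(table, metadata))
    prev <- on_stage("decontam",
                     control_prevalence_stats(table, metadata,
                                              config$prevalence_cut))
    report$decontam <- list(
      n_contaminants = length(dec$report$flagged),
      flagged = dec$report$flagged,
      n_control_features = prev$n_control_features,
      n_rare_in_study = prev$n_rare_in_study)
    table <- dec$table
  } else {
    report$decontam <- "skipped"
  }

  if (enabled("rarefy")) {
    table <- on_stage("rarefy",
                      rarefy(table, config$rarefaction_depth,
                             seed = stage_seed(config$seed, "rarefy")))
    report$rarefy <- list(depth = config$rarefaction_depth,
                          n_samples = ncol(table$counts))
  } else {
    report$rarefy <- "skipped"
  }

  spore_labels <- dat$trait_labels
  if (enabled("hsp")) {
    if (is.null(dat$tree) || is.null(dat$trait_labels)) {
      report$hsp <- "skipped"
    } else {
      hsp <- on_stage("hsp", {
        traits <- dat$trait_labels
        pred <- hsp_empirical(dat$tree, traits, tau = config$tau)
        cv <- loocv_average_precision(dat$tree, traits)
        list(pred = pred, cv = cv)
      })
      # merge training labels with predictions for downstream accounting
      predicted <- stats::setNames(hsp$pred$label, hsp$pred$tip)
      spore_labels <- c(dat$trait_labels, predicted)
      report$hsp <- list(
        n_predicted = nrow(hsp$pred),
        n_predicted_spore = sum(hsp$pred$label == "spore_former"),
        loocv_average_precision = hsp$cv$average_precision)
    }
  } else {
    report$hsp <- "skipped"
  }

  categories <- NULL
  if (enabled("categories")) {
    if (is.null(spore_labels)) {
      report$categories <- "skipped"
    } else {
      categories <- on_stage("categories",
                             classify_taxa(table, spore_labels,
                                           read_threshold =
                                             config$read_threshold))
      fr <- on_stage("categories", category_fractions(table, categories))
      report$categories <- list(
        n_included = sum(categories$category != "excluded"),
        n_excluded = sum(categories$category == "excluded"),
        fractions = stats::setNames(fr$fraction, fr$category))
    }
  } else {
    report$categories <- "skipped"
  }

  if (enabled("logratio_gradient")) {
    if (is.null(spore_labels)) {
      report$gradient <- "skipped"
    } else {
      grad <- on_stage("logratio_gradient", {
        lab <- spore_labels[intersect(names(spore_labels),
                                      feature_ids(table))]
        num <- names(lab)[lab == "spore_former"]
        den <- names(lab)[lab == "non_spore_former"]
        lr <- group_log_ratio(table, num, den)
        gradient_correlation(lr$values, metadata)
      })
      report$gradient <- list(r = grad$r, p = grad$p,
                              n_locations = grad$n_locations)
    }
  } else {
    report$gradient <- "skipped"
  }

  if (enabled("richness")) {
    rich <- on_stage("richness", richness_tests(table, metadata))
    report$richness <- list(kruskal_statistic = rich$kruskal$statistic,
                            kruskal_p = rich$kruskal$p,
                            n_groups = length(unique(rich$richness$group)))
  } else {
    report$richness <- "skipped"
  }

  if (enabled("bioburden") && !is.null(config$plate_records)) {
    bb <- on_stage("bioburden",
                   bioburden_table(config$plate_records, config$ssb_ratio))
    report$bioburden <- bb
  } else {
    report$bioburden <- "skipped"
  }

  out <- structure(list(report = report, table = table,
                        metadata = metadata,
                        categories = categories, config = config),
                   class = "run_report")
  if (!is.null(config$outdir)) write_run_report(out, config$outdir)
  out
}

write_run_report <- function(x, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(x$report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_feature_table(x$table, file.path(outdir, "final_table.tsv"))
  write_metadata(x$metadata, file.path(outdir, "metadata.tsv"))
  if (!is.null(x$categories))
    utils::write.table(x$categories, file.path(outdir, "categories.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  # the configuration that produced the run, re-serialized verbatim
  cfg <- x$config
  cfg$plate_records <- NULL
  jsonlite::write_json(
    lapply(unclass(cfg), function(v) if (is.null(v)) NA else unclass(v)),
    file.path(outdir, "config.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, force = TRUE)
  invisible(outdir)
}

#' @export
print.run_report <- function(x, ...) {
  r <- x$report
  cat("<run_report>\n")
  cat(sprintf("  QC: %d / %d samples pass (min_depth %s)\n",
              r$qc$n_samples_pass, r$qc$n_samples_in,
              format(r$parameters$min_depth)))
  if (is.list(r$decontam))
    cat(sprintf("  decontam: %d contaminant(s); %d control features, %d rare in study\n",
                r$decontam$n_contaminants, r$decontam$n_control_features,
                r$decontam$n_rare_in_study))
  if (is.list(r$hsp))
    cat(sprintf("  HSP: %d tips predicted, LOOCV AP %.3f\n",
                r$hsp$n_predicted, r$hsp$loocv_average_precision))
  if (is.list(r$categories))
    cat(sprintf("  categories: %s\n",
                paste(sprintf("%s %.2f%%", names(r$categories$fractions),
                              100 * r$categories$fractions),
                      collapse = ", ")))
  if (is.list(r$gradient))
    cat(sprintf("  gradient: r = %.3f, p = %.4g over %d locations\n",
                r$gradient$r, r$gradient$p, r$gradient$n_locations))
  if (is.list(r$richness))
    cat(sprintf("  richness: Kruskal-Wallis chi^2 = %.2f, p = %.4g\n",
                r$richness$kruskal_statistic, r$richness$kruskal_p))
  invisible(x)
}
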