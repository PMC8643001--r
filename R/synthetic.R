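# Synthetic cleanroom studies with known ground truth.
#
# The generator reproduces the statistical structure the downstream
# analyses assume: a multi-session floor survey on a radial location grid,
# PMA-treated/naive sample pairs, three control classes, a phylogenetically
# conserved binary spore trait, a spore/non-spore abundance gradient in
# radius, reagent contaminants spiked into every control, and variable
# (negative-binomial) sequencing depth with a configurable low-depth tail.

#' Simulate a rooted binary tree
#'
#' Random topology with exponential(1) branch lengths; a stand-in for a
#' reference 16S backbone phylogeny.  Deterministic under `seed`.
#'
#' @param n_tips number of tips (>= 2)
#' @param seed integer seed
#' @param tip_labels optional character vector of tip labels
#' @return an [ape::phylo] tree
#' @export
simulate_tree <- function(n_tips, seed = 1L, tip_labels = NULL) {
  if (n_tips < 2L) stop("n_tips must be at least 2")
  set.seed(seed)
  tree <- ape::rtree(n_tips, rooted = TRUE, br = stats::rexp)
  if (!is.null(tip_labels)) {
    stopifnot(length(tip_labels) == n_tips)
    tree$tip.label <- tip_labels
  }
  tree
}

#' Simulate a binary trait on a tree
#'
#' Two-state continuous-time Markov chain run root-to-tip.  The chain is
#' parameterized by its stationary probability of the positive state
#' (`root_state_prob`, from which the root state is drawn) and an overall
#' transition rate per unit branch length, so the infinite-rate limit gives
#' independent Bernoulli(`root_state_prob`) tips while small rates give a
#' phylogenetically autocorrelated trait.  Transition probability along a
#' branch of length \eqn{\ell}: \eqn{P(j\,|\,i) = \pi_j + (\delta_{ij} -
#' \pi_j) e^{-r\ell}}.
#'
#' @param tree an [ape::phylo] tree
#' @param rate transition rate >= 0 per unit branch length
#' @param root_state_prob stationary probability of state TRUE
#' @param seed integer seed
#' @return named logical vector over tips (TRUE = positive state)
#' @export
simulate_binary_trait <- function(tree, rate, root_state_prob = 0.5,
                                  seed = 1L) {
  stopifnot(rate >= 0, root_state_prob >= 0, root_state_prob <= 1)
  set.seed(seed)
  n <- ape::Ntip(tree)
  nnode <- n + tree$Nnode
  state <- logical(nnode)
  root <- n + 1L
  state[root] <- stats::runif(1L) < root_state_prob
  pre <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  el <- if (is.null(pre$edge.length)) rep(0, nrow(pre$edge)) else pre$edge.length
  for (e in seq_len(nrow(pre$edge))) {
    p <- pre$edge[e, 1L]; ch <- pre$edge[e, 2L]
    decay <- exp(-rate * el[e])
    p_true <- root_state_prob + (as.numeric(state[p]) - root_state_prob) * decay
    state[ch] <- stats::runif(1L) < p_true
  }
  out <- state[seq_len(n)]
  names(out) <- tree$tip.label
  out
}

#' Convert a logical spore indicator to trait-state strings
#' @param x named logical vector (TRUE = spore-former)
#' @return named character vector of `spore_former` / `non_spore_former`
#' @export
as_trait_states <- function(x) {
  out <- ifelse(x, "spore_former", "non_spore_former")
  names(out) <- names(x)
  out
}

spore_genus_pool <- function() {
  c(nsa_genus_default(),
    "Clostridium", "Geobacillus", "Actinomyces", "Actinoplanes",
    "Microbispora", "Dolichospermum", "Mycobacterium", "Paenisporosarcina")
}

non_spore_genus_pool <- function() {
  c("Sphingobium", "Pseudomonas", "Caulobacter", "Acinetobacter",
    "Azospira", "Deinococcus", "Acidovorax", "Arthrobacter",
    "Sphingomonas", "Paracoccus", "Cupriavidus", "Micrococcus",
    "Staphylococcus", "Massilia", "Brevibacterium", "Methylobacterium",
    "Ralstonia", "Bradyrhizobium", "Novosphingobium", "Microvirga")
}

#' Configuration for a synthetic cleanroom study
#'
#' Defaults mirror the design of an 11-session, 13-location floor survey
#' with 98 sampling events, each processed PMA-naive and PMA-treated, plus
#' field, negative and extraction controls.  Radii are in the same
#' arbitrary length units the statistics treat as opaque (schematic
#' "pixels"), spaced uniformly on [50, 1000].
#'
#' @param n_locations number of floor locations
#' @param radii radial distance from the entrance per location
#' @param n_sessions number of sampling sessions
#' @param n_floor_events number of (session, location) sampling events;
#'   each yields a PMA-naive/PMA-treated sample pair
#' @param n_field_controls,n_negative_controls,n_extraction_controls
#'   control sample counts (field and negative controls come in PMA pairs;
#'   extraction controls are PMA-naive)
#' @param n_features number of sOTUs
#' @param spore_fraction stationary probability of the spore trait
#' @param trait_rate trait transition rate per unit branch length
#' @param beta log-linear radius effect applied to spore-former expected
#'   abundance (negative = spore-formers decay away from the entrance)
#' @param live_fraction_mean mean of the per-taxon Beta-distributed live
#'   fraction (PMA removes the dead complement)
#' @param live_fraction_conc concentration of that Beta distribution
#' @param n_contaminants number of reagent contaminant taxa spiked into
#'   every control
#' @param control_contaminant_weight fraction of expected control reads on
#'   contaminant taxa
#' @param floor_contaminant_rel relative intensity of contaminant taxa in
#'   floor samples (small: trace reagent carryover)
#' @param depth_mean,depth_dispersion negative-binomial mean and size for
#'   per-sample read totals
#' @param low_depth_fraction fraction of samples forced below the QC depth
#' @param qc_depth the QC depth the low-depth tail is defined against
#' @param label_fraction fraction of taxa whose true spore trait is exposed
#'   as a training label (the rest are prediction targets)
#' @param seed mandatory integer seed; identical configs give identical
#'   bundles
#' @return a `study_config` list
#' @export
study_config <- function(n_locations = 13L,
                         radii = seq(50, 1000, length.out = n_locations),
                         n_sessions = 11L,
                         n_floor_events = 98L,
                         n_field_controls = 12L,
                         n_negative_controls = 12L,
                         n_extraction_controls = 8L,
                         n_features = 300L,
                         spore_fraction = 0.3,
                         trait_rate = 0.05,
                         beta = -0.002,
                         live_fraction_mean = 1 / 3,
                         live_fraction_conc = 4,
                         n_contaminants = 7L,
                         control_contaminant_weight = 0.8,
                         floor_contaminant_rel = 0.01,
                         depth_mean = 50000,
                         depth_dispersion = 5,
                         low_depth_fraction = 0.2,
                         qc_depth = 5000,
                         label_fraction = 0.6,
                         seed = 1L) {
  cfg <- list(n_locations = as.integer(n_locations), radii = radii,
              n_sessions = as.integer(n_sessions),
              n_floor_events = as.integer(n_floor_events),
              n_field_controls = as.integer(n_field_controls),
              n_negative_controls = as.integer(n_negative_controls),
              n_extraction_controls = as.integer(n_extraction_controls),
              n_features = as.integer(n_features),
              spore_fraction = spore_fraction, trait_rate = trait_rate,
              beta = beta, live_fraction_mean = live_fraction_mean,
              live_fraction_conc = live_fraction_conc,
              n_contaminants = as.integer(n_contaminants),
              control_contaminant_weight = control_contaminant_weight,
              floor_contaminant_rel = floor_contaminant_rel,
              depth_mean = depth_mean, depth_dispersion = depth_dispersion,
              low_depth_fraction = low_depth_fraction, qc_depth = qc_depth,
              label_fraction = label_fraction, seed = as.integer(seed))
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

validate_study_config <- function(cfg) {
  stopifnot(length(cfg$radii) == cfg$n_locations, all(cfg$radii > 0),
            cfg$n_features >= 2L,
            cfg$spore_fraction >= 0, cfg$spore_fraction <= 1,
            cfg$trait_rate >= 0,
            cfg$live_fraction_mean > 0, cfg$live_fraction_mean <= 1,
            cfg$live_fraction_conc > 0,
            cfg$control_contaminant_weight >= 0,
            cfg$control_contaminant_weight < 1,
            cfg$low_depth_fraction >= 0, cfg$low_depth_fraction < 1,
            cfg$label_fraction >= 0, cfg$label_fraction <= 1,
            cfg$depth_mean > 0, cfg$depth_dispersion > 0,
            length(cfg$seed) == 1L, !is.na(cfg$seed))
  if (cfg$n_contaminants >= cfg$n_features)
    stop("contaminant set must be smaller than the feature set")
  if (cfg$n_floor_events > cfg$n_locations * cfg$n_sessions)
    stop("more floor events than (session, location) combinations")
  invisible(cfg)
}

#' Simulate a complete cleanroom study with ground truth
#'
#' Expected floor-sample composition per taxon is a log-normal baseline
#' multiplied by `exp(beta * radius)` for spore-formers; the dead
#' complement of each taxon's live fraction contributes only to PMA-naive
#' samples.  Controls are dominated by the contaminant taxa (which are
#' guaranteed a nonzero count in every control while keeping the drawn
#' column totals exact) over a faint background of the community.  Counts
#' are multinomial at each sample's drawn depth.
#'
#' @param config a [study_config()]
#' @return a `study_bundle`: list with `table` (a [feature_table] with
#'   taxonomy), `metadata`, `tree`, `truth` (trait, live_fraction,
#'   contaminants, known_labels, depths) and `config`
#' @export
simulate_cleanroom_study <- function(config = study_config()) {
  cfg <- validate_study_config(config)
  fid <- sprintf("f%04d", seq_len(cfg$n_features))
  tree <- simulate_tree(cfg$n_features, seed = cfg$seed, tip_labels = fid)
  trait <- simulate_binary_trait(tree, cfg$trait_rate, cfg$spore_fraction,
                                 seed = cfg$seed + 1L)
  set.seed(cfg$seed + 2L)

  # taxonomy consistent with the trait: spore-formers draw genera from the
  # spore pool (NSA genera included), others from the non-spore pool
  genus <- character(cfg$n_features)
  genus[trait] <- sample(spore_genus_pool(), sum(trait), replace = TRUE)
  genus[!trait] <- sample(non_spore_genus_pool(), sum(!trait), replace = TRUE)
  taxonomy <- paste0("k__Bacteria;p__p", seq_len(cfg$n_features),
                     ";g__", genus)
  names(taxonomy) <- fid

  contaminants <- sample(fid, cfg$n_contaminants)
  is_contam <- fid %in% contaminants
  baseline <- stats::rlnorm(cfg$n_features, 0, 1)
  a <- cfg$live_fraction_mean * cfg$live_fraction_conc
  b <- (1 - cfg$live_fraction_mean) * cfg$live_fraction_conc
  live_frac <- stats::rbeta(cfg$n_features, a, b)

  # design: sampling events, each a PMA pair
  grid <- expand.grid(session = seq_len(cfg$n_sessions),
                      location = seq_len(cfg$n_locations))
  ev <- grid[sample(nrow(grid), cfg$n_floor_events), , drop = FALSE]
  meta <- list(); comps <- list()

  floor_comp <- function(loc, treated) {
    r <- cfg$radii[loc]
    inten <- baseline * ifelse(trait, exp(cfg$beta * r), 1)
    inten[is_contam] <- baseline[is_contam] * cfg$floor_contaminant_rel
    if (treated) inten <- inten * live_frac
    inten / sum(inten)
  }
  control_comp <- function(treated) {
    bg <- baseline
    if (treated) bg <- bg * live_frac
    bg[is_contam] <- 0
    bg <- bg / sum(bg) * (1 - cfg$control_contaminant_weight)
    cw <- baseline[is_contam] / sum(baseline[is_contam]) *
      cfg$control_contaminant_weight
    bg[is_contam] <- cw
    bg
  }

  add_sample <- function(id, type, treated, loc, sess, comp) {
    meta[[length(meta) + 1L]] <<- data.frame(
      sample_id = id, sample_type = type, pma_treated = treated,
      location_id = if (is.na(loc)) NA_integer_ else loc,
      radius = if (is.na(loc)) NA_real_ else cfg$radii[loc],
      session_index = sess,
      session_date = as.character(as.Date("2016-03-01") + 14L * (sess - 1L)))
    comps[[length(comps) + 1L]] <<- comp
  }

  for (i in seq_len(nrow(ev))) {
    s <- ev$session[i]; l <- ev$location[i]
    base_id <- sprintf("S%02d.L%02d", s, l)
    add_sample(paste0(base_id, ".N"), "floor", FALSE, l, s,
               floor_comp(l, FALSE))
    add_sample(paste0(base_id, ".T"), "floor", TRUE, l, s,
               floor_comp(l, TRUE))
  }
  ctrl_plan <- rbind(
    data.frame(type = "field_control",
               treated = rep(c(FALSE, TRUE), length.out = cfg$n_field_controls)),
    data.frame(type = "negative_control",
               treated = rep(c(FALSE, TRUE), length.out = cfg$n_negative_controls)),
    data.frame(type = "extraction_control",
               treated = rep(FALSE, cfg$n_extraction_controls)))
  if (nrow(ctrl_plan)) {
    for (i in seq_len(nrow(ctrl_plan))) {
      sess <- ((i - 1L) %% cfg$n_sessions) + 1L
      id <- sprintf("C%02d.%s%s", i,
                    toupper(substr(ctrl_plan$type[i], 1L, 1L)),
                    if (ctrl_plan$treated[i]) "T" else "N")
      add_sample(id, ctrl_plan$type[i], ctrl_plan$treated[i], NA, sess,
                 control_comp(ctrl_plan$treated[i]))
    }
  }
  metadata <- validate_metadata(do.call(rbind, meta))
  n_samp <- nrow(metadata)

  # depths: NB body truncated at the QC depth, plus a forced low-depth tail
  depth <- stats::rnbinom(n_samp, mu = cfg$depth_mean,
                          size = cfg$depth_dispersion)
  depth <- pmax(depth, cfg$qc_depth)
  low <- stats::runif(n_samp) < cfg$low_depth_fraction
  depth[low] <- sample(seq(500L, cfg$qc_depth - 1L), sum(low), replace = TRUE)

  counts <- matrix(0L, cfg$n_features, n_samp,
                   dimnames = list(fid, metadata$sample_id))
  is_control <- metadata$sample_type != "floor"
  for (j in seq_len(n_samp)) {
    p <- comps[[j]]
    if (is_control[j] && depth[j] > cfg$n_contaminants) {
      # reserve one read per contaminant so every control is positive for
      # every contaminant; the column total still equals the drawn depth
      draw <- stats::rmultinom(1L, depth[j] - cfg$n_contaminants, p)[, 1L]
      draw[is_contam] <- draw[is_contam] + 1L
    } else {
      draw <- stats::rmultinom(1L, depth[j], p)[, 1L]
    }
    counts[, j] <- draw
  }

  known <- sample(fid, round(cfg$label_fraction * cfg$n_features))
  known_labels <- as_trait_states(trait[known])

  structure(list(
    table = feature_table(counts, taxonomy),
    metadata = metadata,
    tree = tree,
    truth = list(trait = trait, live_fraction = stats::setNames(live_frac, fid),
                 contaminants = contaminants, known_labels = known_labels,
                 depths = stats::setNames(depth, metadata$sample_id)),
    config = cfg), class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf(paste0(
    "<study_bundle> %d features x %d samples (%d floor, %d control)\n",
    "  spore-formers: %d | contaminants: %d | seed: %d\n"),
    nrow(x$table$counts), ncol(x$table$counts),
    sum(x$metadata$sample_type == "floor"),
    sum(x$metadata$sample_type != "floor"),
    sum(x$truth$trait), length(x$truth$contaminants), x$config$seed))
  invisible(x)
}

#' Write a study bundle to a directory as plain-text files
#'
#' Emits `table.tsv` (dense), `metadata.tsv`, `tree.nwk` and
#' `truth.tsv` (per-feature trait, live fraction, contaminant flag).
#'
#' @param bundle a `study_bundle`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_study_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(bundle$table, file.path(dir, "table.tsv"))
  write_metadata(bundle$metadata, file.path(dir, "metadata.tsv"))
  write_newick(bundle$tree, file.path(dir, "tree.nwk"))
  fid <- feature_ids(bundle$table)
  truth <- data.frame(feature_id = fid,
                      spore_former = bundle$truth$trait[fid],
                      live_fraction = bundle$truth$live_fraction[fid],
                      contaminant = fid %in% bundle$truth$contaminants,
                      taxonomy = bundle$table$taxonomy[fid])
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
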