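# Shared fixtures and independent oracles, all built in code.

toy_table <- function(counts, fids = NULL, sids = NULL, taxonomy = NULL) {
  if (is.null(fids)) fids <- paste0("f", seq_len(nrow(counts)))
  if (is.null(sids)) sids <- paste0("s", seq_len(ncol(counts)))
  dimnames(counts) <- list(fids, sids)
  feature_table(counts, taxonomy)
}

toy_metadata <- function(sample_id, sample_type,
                         pma_treated = rep(FALSE, length(sample_id)),
                         location_id = NA, radius = NA,
                         session_index = 1L) {
  n <- length(sample_id)
  loc <- rep(location_id, length.out = n)
  rad <- rep(radius, length.out = n)
  if (all(is.na(rad))) rad[sample_type == "floor"] <- 100
  if (all(is.na(loc))) loc[sample_type == "floor"] <- 1L
  validate_metadata(data.frame(
    sample_id = sample_id, sample_type = sample_type,
    pma_treated = rep(pma_treated, length.out = n),
    location_id = loc, radius = rad,
    session_index = rep(session_index, length.out = n),
    session_date = "2016-03-02"))
}

# random small count table with a floor/control design
random_design_table <- function(n_feat, n_floor, n_ctrl, max_count = 20L) {
  counts <- matrix(sample(0:max_count, n_feat * (n_floor + n_ctrl),
                          replace = TRUE, prob = c(0.4, rep(0.6 / max_count,
                                                            max_count))),
                   n_feat, n_floor + n_ctrl)
  sids <- c(paste0("fl", seq_len(n_floor)), paste0("ct", seq_len(n_ctrl)))
  tab <- toy_table(counts, sids = sids)
  md <- toy_metadata(sids, c(rep("floor", n_floor),
                             rep("negative_control", n_ctrl)))
  list(table = tab, metadata = md)
}

# naive double-loop restatement of the two-clause contaminant rule
oracle_flag_contaminants <- function(table, metadata) {
  cnt <- table$counts
  md <- metadata[match(colnames(cnt), metadata$sample_id), ]
  ctrl <- which(md$sample_type %in% c("field_control", "negative_control",
                                      "extraction_control"))
  ntc <- which(md$sample_type %in% c("negative_control",
                                     "extraction_control"))
  floor <- which(md$sample_type == "floor")
  flagged <- character(0)
  for (f in rownames(cnt)) {
    in_all <- TRUE
    for (j in ctrl) if (cnt[f, j] == 0) in_all <- FALSE
    if (in_all && mean(cnt[f, ntc]) > mean(cnt[f, floor]))
      flagged <- c(flagged, f)
  }
  flagged
}

# nearest-informative-ancestor probability by explicit subtree enumeration,
# masking the focal tip
oracle_hsp_prob <- function(tree, states, tip_index) {
  p <- function(node) tree$edge[, 1L][match(node, tree$edge[, 2L])]
  a <- p(tip_index)
  while (!is.na(a)) {
    tips <- setdiff(phangorn::Descendants(tree, a, "tips")[[1L]], tip_index)
    st <- states[tips]
    st <- st[st != "unknown"]
    if (length(st)) return(mean(st == "spore_former"))
    a <- p(a)
  }
  NA_real_
}

random_trait_states <- function(n, p_unknown = 0.3) {
  sample(c("spore_former", "non_spore_former", "unknown"), n, replace = TRUE,
         prob = c((1 - p_unknown) / 2, (1 - p_unknown) / 2, p_unknown))
}
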