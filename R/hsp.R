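# Hidden state prediction of sporulation ability on a reference phylogeny.
#
# The estimator is the empirical-probability variant: the probability that
# an unlabeled tip is a spore-former equals the fraction of spore-formers
# among the labeled tips descending from its nearest informative ancestor
# (the first node on the path from the tip's parent to the root that has at
# least one labeled descendant, the focal tip itself always excluded).
# The estimator uses topology only; branch lengths never enter.

trait_states <- c("spore_former", "non_spore_former", "unknown")

normalize_seq <- function(s) gsub("[-. ]", "", toupper(s))

#' Build a tip trait table by exact 16S sequence matching
#'
#' A trait record labels a reference tip iff its (gap-stripped, uppercased)
#' sequence is byte-identical to the tip's sequence — the 100%-identity
#' rule.  A record matching several tips labels all of them; a tip matched
#' by records with conflicting states takes the majority state, with exact
#' ties resolved to `unknown`.
#'
#' @param ref_sequences named character vector of reference tip sequences
#'   (names are tip labels)
#' @param trait_records data frame with columns `record_id`, `sequence`,
#'   `spore_former` (logical)
#' @return named character vector over `names(ref_sequences)` with values
#'   in `spore_former` / `non_spore_former` / `unknown`
#' @export
build_reference_traits <- function(ref_sequences, trait_records) {
  stopifnot(all(c("record_id", "sequence", "spore_former") %in%
                  names(trait_records)))
  if (nrow(trait_records) == 0L) stop("empty trait record set")
  ref_norm <- normalize_seq(ref_sequences)
  rec_norm <- normalize_seq(trait_records$sequence)
  votes_pos <- integer(length(ref_sequences))
  votes_neg <- integer(length(ref_sequences))
  idx <- split(seq_along(ref_norm), ref_norm)
  for (r in seq_len(nrow(trait_records))) {
    hit <- idx[[rec_norm[r]]]
    if (is.null(hit)) next
    if (isTRUE(trait_records$spore_former[r])) {
      votes_pos[hit] <- votes_pos[hit] + 1L
    } else {
      votes_neg[hit] <- votes_neg[hit] + 1L
    }
  }
  state <- rep("unknown", length(ref_sequences))
  state[votes_pos > votes_neg] <- "spore_former"
  state[votes_neg > votes_pos] <- "non_spore_former"
  names(state) <- names(ref_sequences)
  state
}

# -- tree bookkeeping ---------------------------------------------------

# parent[i] = parent node of node i (0 for the root)
parent_vector <- function(tree) {
  p <- integer(ape::Ntip(tree) + tree$Nnode)
  p[tree$edge[, 2L]] <- tree$edge[, 1L]
  p
}

# per-node counts of labeled descendants: n_known and n_spore, where a tip
# counts as its own descendant
node_trait_counts <- function(tree, traits) {
  n <- ape::Ntip(tree)
  stopifnot(!is.null(names(traits)))
  bad <- setdiff(names(traits), tree$tip.label)
  if (length(bad))
    stop("trait label(s) not in tree: ", paste(utils::head(bad, 5L),
                                               collapse = ", "))
  state <- rep("unknown", n)
  names(state) <- tree$tip.label
  state[names(traits)] <- as.character(traits)
  if (!all(state %in% trait_states))
    stop("trait states must be one of: ", paste(trait_states, collapse = ", "))
  n_known <- integer(n + tree$Nnode)
  n_spore <- integer(n + tree$Nnode)
  n_known[seq_len(n)] <- as.integer(state != "unknown")
  n_spore[seq_len(n)] <- as.integer(state == "spore_former")
  post <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1L]; c <- post$edge[e, 2L]
    n_known[p] <- n_known[p] + n_known[c]
    n_spore[p] <- n_spore[p] + n_spore[c]
  }
  list(n_known = n_known, n_spore = n_spore, tip_state = state)
}

#' Empirical per-node state frequencies
#'
#' For every node `v`, the fraction of known spore-former tips among the
#' known tips descending from `v` (a tip descends from itself).  Nodes with
#' no known descendant have no defined frequency and are excluded.
#'
#' @param tree an [ape::phylo] tree
#' @param traits named character vector (tip label -> state in
#'   `spore_former` / `non_spore_former` / `unknown`); tips absent from the
#'   vector are treated as unknown
#' @return data frame with columns `node`, `n_known`, `n_spore`, `freq`,
#'   one row per node with at least one known descendant
#' @export
node_state_frequencies <- function(tree, traits) {
  ct <- node_trait_counts(tree, traits)
  if (all(ct$n_known == 0L)) stop("no known tips")
  def <- which(ct$n_known > 0L)
  data.frame(node = def,
             n_known = ct$n_known[def],
             n_spore = ct$n_spore[def],
             freq = ct$n_spore[def] / ct$n_known[def],
             row.names = NULL)
}

#' Hidden state prediction via nearest-informative-ancestor frequencies
#'
#' Each unknown tip receives the empirical spore-former frequency of the
#' first node on the path from its parent to the root that has at least
#' one known descendant tip.  The focal tip never contributes to any count
#' (it is unknown), so the same routine is leakage-free under
#' leave-one-out evaluation.  Predicted label is `spore_former` when the
#' probability is at least `tau` (ties go to the positive class:
#' conservative for planetary protection).
#'
#' @inheritParams node_state_frequencies
#' @param tau classification threshold in (0,1), default 0.5
#' @return an `hsp_result`: data frame with columns `tip`, `prob`,
#'   `source_node`, `label`, plus attribute `tau`
#' @export
hsp_empirical <- function(tree, traits, tau = 0.5) {
  stopifnot(tau > 0, tau < 1)
  ct <- node_trait_counts(tree, traits)
  if (all(ct$n_known == 0L)) stop("no known tips; cannot predict")
  par <- parent_vector(tree)
  unknown <- which(ct$tip_state == "unknown")
  tips <- tree$tip.label[unknown]
  prob <- numeric(length(unknown))
  src <- integer(length(unknown))
  for (i in seq_along(unknown)) {
    a <- par[unknown[i]]
    while (a != 0L && ct$n_known[a] == 0L) a <- par[a]
    # a is guaranteed informative: the root sees every known tip
    prob[i] <- ct$n_spore[a] / ct$n_known[a]
    src[i] <- a
  }
  res <- data.frame(tip = tips, prob = prob, source_node = src,
                    label = ifelse(prob >= tau, "spore_former",
                                   "non_spore_former"),
                    row.names = NULL)
  structure(res, class = c("hsp_result", "data.frame"), tau = tau)
}

#' @export
print.hsp_result <- function(x, ...) {
  cat(sprintf("<hsp_result> %d tip(s) predicted at tau = %g; %d spore-former\n",
              nrow(x), attr(x, "tau"), sum(x$label == "spore_former")))
  NextMethod()
}

#' Leave-one-out cross-validated average precision
#'
#' Each labeled tip is masked in turn and re-predicted by
#' [hsp_empirical()]; the (true state, predicted probability) pairs are
#' swept into a precision-recall curve with step interpolation,
#' \eqn{AP = \sum_k (R_k - R_{k-1}) P_k}, positive class = spore-former.
#' Tied scores are processed as a single group.
#'
#' @inheritParams node_state_frequencies
#' @return a `loocv_report`: list with `predictions` (tip, true_state,
#'   prob), `curve` (recall, precision per score group) and
#'   `average_precision`
#' @export
loocv_average_precision <- function(tree, traits) {
  ct <- node_trait_counts(tree, traits)
  known <- which(ct$tip_state != "unknown")
  if (length(known) < 2L) stop("need at least 2 known tips")
  if (length(unique(ct$tip_state[known])) < 2L)
    stop("both states must be represented; average precision is undefined ",
         "for a single-state trait table")
  par <- parent_vector(tree)
  prob <- numeric(length(known))
  for (i in seq_along(known)) {
    t <- known[i]
    is_spore <- ct$tip_state[t] == "spore_former"
    a <- par[t]
    # subtract the held-out tip from every ancestor on its root path as we
    # walk; stop at the first node still informative without it
    while (a != 0L && ct$n_known[a] - 1L == 0L) a <- par[a]
    if (a == 0L)
      stop("held-out tip is the only known tip")  # excluded by pre-check
    prob[i] <- (ct$n_spore[a] - as.integer(is_spore)) / (ct$n_known[a] - 1L)
  }
  truth <- ct$tip_state[known] == "spore_former"
  ap <- average_precision(truth, prob)
  structure(list(
    predictions = data.frame(tip = tree$tip.label[known],
                             true_state = ct$tip_state[known],
                             prob = prob, row.names = NULL),
    curve = ap$curve,
    average_precision = ap$ap), class = "loocv_report")
}

#' @export
print.loocv_report <- function(x, ...) {
  cat(sprintf("<loocv_report> %d held-out tips, average precision %.4f\n",
              nrow(x$predictions), x$average_precision))
  invisible(x)
}

#' @export
plot.loocv_report <- function(x, ...) {
  plot(x$curve$recall, x$curve$precision, type = "s", xlim = c(0, 1),
       ylim = c(0, 1), xlab = "Recall", ylab = "Precision",
       main = sprintf("LOOCV precision-recall (AP = %.3f)",
                      x$average_precision), ...)
  invisible(x)
}

#' Average precision with step interpolation
#'
#' \eqn{AP = \sum_k (R_k - R_{k-1}) P_k} over the descending sweep of
#' unique score values; all observations sharing a score enter as one
#' group.
#'
#' @param truth logical vector (TRUE = positive class)
#' @param scores numeric scores, higher = more positive
#' @return list with `ap` and `curve` (data frame threshold, recall,
#'   precision)
#' @export
average_precision <- function(truth, scores) {
  stopifnot(length(truth) == length(scores), any(truth))
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(truth)
  tp <- fp <- 0L
  rec <- prec <- numeric(length(thr))
  for (k in seq_along(thr)) {
    in_group <- scores == thr[k]
    tp <- tp + sum(truth[in_group])
    fp <- fp + sum(!truth[in_group])
    rec[k] <- tp / P
    prec[k] <- tp / (tp + fp)
  }
  ap <- sum(diff(c(0, rec)) * prec)
  list(ap = ap,
       curve = data.frame(threshold = thr, recall = rec, precision = prec))
}

# -- query placement ----------------------------------------------------

# p-distance between two sequences.  Equal-length inputs are taken as
# aligned: compare columns where neither has a gap.  Unequal lengths are
# globally aligned first (Biostrings), then compared the same way.
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("unequal-length sequences need a global alignment; ",
           "install Biostrings or supply pre-aligned sequences")
    al <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                        gapOpening = 1, gapExtension = 1)
    a <- as.character(Biostrings::alignedPattern(al))
    b <- as.character(Biostrings::alignedSubject(al))
  }
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  ok <- !(av %in% c("-", ".")) & !(bv %in% c("-", "."))
  if (!any(ok)) stop("no comparable positions between sequences")
  mean(av[ok] != bv[ok])
}

# graft a new tip as sibling of an existing tip: a new internal node is
# inserted at the existing tip's end (its pendant edge keeps its length,
# the old tip hangs from the new node with length 0), so all distances
# between pre-existing tips are untouched.
insert_sibling_tip <- function(tree, at_tip, new_label, pendant) {
  n <- ape::Ntip(tree); m <- tree$Nnode
  t <- match(at_tip, tree$tip.label)
  if (is.na(t)) stop("tip '", at_tip, "' not in tree")
  edge <- tree$edge
  len <- tree$edge.length
  # renumber: tips keep 1..n, new tip = n+1, internal nodes shift by +1
  edge[edge > n] <- edge[edge > n] + 1L
  new_tip <- n + 1L
  new_node <- n + m + 2L
  at_edge <- which(edge[, 2L] == t)
  edge[at_edge, 2L] <- new_node
  edge <- rbind(edge, c(new_node, t), c(new_node, new_tip))
  len <- c(len, 0, pendant)
  out <- structure(list(edge = edge, edge.length = len,
                        tip.label = c(tree$tip.label, new_label),
                        Nnode = m + 1L), class = "phylo")
  ape::reorder.phylo(out, "cladewise")
}

#' Place query sequences onto a reference phylogeny
#'
#' A deliberately simple placement: each query is attached as a new tip,
#' sibling to its best-hit reference tip under normalized p-distance
#' (ties broken by the lexicographically smallest tip label), with pendant
#' branch length equal to that p-distance.  Distances among the original
#' tips are preserved exactly.  Sequences of equal length are treated as
#' pre-aligned to a common coordinate system; unequal lengths are globally
#' aligned pairwise first.
#'
#' @param tree reference [ape::phylo] tree
#' @param ref_sequences named character vector of reference sequences
#'   (names must be tip labels of `tree`)
#' @param query_sequences named character vector of query sequences; names
#'   become the new tip labels
#' @return list with `tree` (the extended phylogeny) and `placements`
#'   (data frame: query, best_hit, p_distance)
#' @export
place_queries <- function(tree, ref_sequences, query_sequences) {
  if (!length(query_sequences)) stop("empty query set")
  bad <- setdiff(names(ref_sequences), tree$tip.label)
  if (length(bad))
    stop("reference sequence(s) not on tree: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  if (anyDuplicated(c(tree$tip.label, names(query_sequences))))
    stop("query labels collide with existing tip labels")
  refs <- ref_sequences[order(names(ref_sequences))]  # lexicographic ties
  placements <- data.frame(query = names(query_sequences),
                           best_hit = NA_character_,
                           p_distance = NA_real_, row.names = NULL)
  for (q in seq_along(query_sequences)) {
    d <- vapply(refs, p_distance, numeric(1L), b = query_sequences[[q]])
    best <- which.min(d)  # first minimum = lexicographically smallest label
    placements$best_hit[q] <- names(refs)[best]
    placements$p_distance[q] <- d[best]
    tree <- insert_sibling_tip(tree, names(refs)[best],
                               names(query_sequences)[q], d[best])
  }
  list(tree = tree, placements = placements)
}
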