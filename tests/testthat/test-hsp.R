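test_that("trait records label reference tips only on exact sequence match", {
  refs <- c(A = "ACGT", B = "ACGA", C = "TTTT")
  rec <- data.frame(record_id = c("r1", "r2"),
                    sequence = c("acg-t", "ACGC"),
                    spore_former = c(TRUE, TRUE))
  tt <- build_reference_traits(refs, rec)
  expect_equal(unname(tt["A"]), "spore_former")  # gap/case insensitive
  expect_equal(unname(tt["B"]), "unknown")       # one base off matches nothing
  expect_equal(unname(tt["C"]), "unknown")
})

test_that("conflicting trait records resolve by majority, ties to unknown", {
  refs <- c(A = "ACGT", B = "GGGG")
  rec <- data.frame(record_id = paste0("r", 1:5),
                    sequence = c("ACGT", "ACGT", "ACGT", "GGGG", "GGGG"),
                    spore_former = c(TRUE, TRUE, FALSE, TRUE, FALSE))
  tt <- build_reference_traits(refs, rec)
  expect_equal(unname(tt["A"]), "spore_former")  # 2 vs 1
  expect_equal(unname(tt["B"]), "unknown")       # exact tie
  expect_error(build_reference_traits(refs, rec[0, ]), "empty")
})

test_that("node frequencies are the fraction of known spore tips below", {
  tr <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  traits <- c(A = "spore_former", B = "spore_former", C = "spore_former",
              D = "non_spore_former")
  f <- node_state_frequencies(tr, traits)
  root <- ape::Ntip(tr) + 1L
  expect_equal(f$freq[f$node == root], 0.75)

  # a node with no known descendants is absent from the map
  traits2 <- c(A = "spore_former", B = "unknown", C = "unknown",
               D = "unknown")
  f2 <- node_state_frequencies(tr, traits2)
  cd_parent <- ape::getMRCA(tr, c("C", "D"))
  expect_false(cd_parent %in% f2$node)
})

test_that("node frequencies agree with brute-force subtree enumeration", {
  set.seed(77)
  for (i in 1:20) {
    tr <- simulate_tree(20, seed = i)
    st <- random_trait_states(20)
    names(st) <- tr$tip.label
    if (!any(st != "unknown")) next
    f <- node_state_frequencies(tr, st)
    for (k in seq_len(nrow(f))) {
      tips <- phangorn::Descendants(tr, f$node[k], "tips")[[1L]]
      known <- st[tips][st[tips] != "unknown"]
      expect_equal(f$freq[k], mean(known == "spore_former"))
    }
  }
})

test_that("unknown tips take the nearest informative ancestor frequency", {
  tr <- read_newick(text = "((A:1,B:1):1,(C:1,U:1):1);")
  res <- hsp_empirical(tr, c(A = "spore_former", B = "spore_former",
                             C = "non_spore_former", U = "unknown"))
  expect_equal(res$prob[res$tip == "U"], 0)  # parent sees only C

  res2 <- hsp_empirical(tr, c(A = "spore_former", B = "spore_former",
                              C = "unknown", U = "unknown"))
  expect_equal(res2$prob[res2$tip == "U"], 1)  # climbs to the root (A, B)
  expect_equal(res2$source_node[res2$tip == "U"], ape::Ntip(tr) + 1L)

  all_spore <- hsp_empirical(tr, c(A = "spore_former", B = "spore_former",
                                   C = "spore_former", U = "unknown"))
  expect_true(all(all_spore$prob == 1))
  expect_error(hsp_empirical(tr, c(A = "unknown", B = "unknown",
                                   C = "unknown", U = "unknown")),
               "no known tips")
})

test_that("predictions are invariant to branch-length rescaling", {
  tr <- simulate_tree(40, seed = 19)
  st <- random_trait_states(40)
  names(st) <- tr$tip.label
  if (!any(st != "unknown")) st[1] <- "spore_former"
  scaled <- tr
  scaled$edge.length <- scaled$edge.length * 7
  expect_identical(hsp_empirical(tr, st), hsp_empirical(scaled, st))
})

test_that("LOOCV requires both states and excludes the held-out tip", {
  tr <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_error(loocv_average_precision(
    tr, c(A = "spore_former", B = "spore_former")), "both states")

  traits <- c(A = "spore_former", B = "spore_former",
              C = "non_spore_former", D = "non_spore_former")
  cv <- loocv_average_precision(tr, traits)
  # each held-out tip is predicted from its sibling alone: perfect scores
  expect_equal(cv$average_precision, 1.0)
  expect_equal(sort(cv$predictions$prob[cv$predictions$true_state ==
                                          "spore_former"]), c(1, 1))
})

test_that("a trait perfectly clustered in one clade sweeps to AP 1", {
  tr <- simulate_tree(30, seed = 41)
  root <- ape::Ntip(tr) + 1L
  kids <- tr$edge[tr$edge[, 1L] == root, 2L]
  left <- phangorn::Descendants(tr, kids[1L], "tips")[[1L]]
  expect_true(length(left) >= 2 && length(left) <= 28)  # informative split
  states <- setNames(rep("non_spore_former", 30), tr$tip.label)
  states[tr$tip.label[left]] <- "spore_former"
  cv <- loocv_average_precision(tr, states)
  expect_equal(cv$average_precision, 1.0)
})

test_that("average precision follows the hand-swept step interpolation", {
  ex <- average_precision(c(TRUE, FALSE, TRUE), c(0.9, 0.8, 0.7))
  expect_equal(ex$ap, 5 / 6)
  tied <- average_precision(c(TRUE, FALSE, FALSE, TRUE), rep(0.4, 4))
  expect_equal(tied$ap, 0.5)  # one tie group: AP = prevalence
  expect_true(all(diff(ex$curve$recall) >= 0))
})

test_that("queries attach to their best hit with p-distance pendants", {
  tr <- read_newick(text = "((A:1,B:1):1,C:3);")
  refs <- c(A = "AAAA", B = "AAAT", C = "GGGG")
  out <- place_queries(tr, refs, c(Q = "AAAA"))
  expect_equal(out$placements$best_hit, "A")
  expect_equal(out$placements$p_distance, 0)
  d <- ape::cophenetic.phylo(out$tree)
  expect_equal(d["Q", "A"], 0)
  # distances among pre-existing tips untouched
  d0 <- ape::cophenetic.phylo(tr)
  expect_equal(d[rownames(d0), colnames(d0)], d0)

  # equidistant tie goes to the lexicographically smallest label
  tie <- place_queries(tr, c(B = "AAAT", A = "AAAA", C = "GGGG"),
                       c(Q = "AAAG"))
  expect_equal(tie$placements$best_hit, "A")
})

test_that("mutated queries overwhelmingly return to their source tip", {
  set.seed(101)
  hits <- 0L; total <- 0L
  bases <- c("A", "C", "G", "T")
  for (i in 1:100) {
    n <- 12L
    tr <- simulate_tree(n, seed = i)
    refs <- vapply(seq_len(n), function(j)
      paste(sample(bases, 200, TRUE), collapse = ""), character(1))
    names(refs) <- tr$tip.label
    src <- sample(n, 1L)
    q <- strsplit(refs[[src]], "")[[1L]]
    mut <- sample(200, 4L)  # 2% mutation
    q[mut] <- vapply(q[mut], function(b) sample(setdiff(bases, b), 1L), "")
    out <- place_queries(tr, refs, setNames(paste(q, collapse = ""), "Q"))
    hits <- hits + (out$placements$best_hit == tr$tip.label[src])
    total <- total + 1L
  }
  expect_gte(hits / total, 0.95)
})

test_that("unequal-length queries go through a global alignment", {
  tr <- read_newick(text = "((A:1,B:1):1,C:3);")
  refs <- c(A = "ACGTACGTAC", B = "ACGTACGTTT", C = "TTTTTTTTTT")
  out <- place_queries(tr, refs, c(Q = "ACGTACGT"))  # A minus two bases
  expect_equal(out$placements$best_hit, "A")
  expect_lt(out$placements$p_distance, 0.1)
})
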