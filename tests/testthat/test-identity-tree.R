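test_that("percent identity arithmetic matches the substitution counts", {
  base <- random_record("ref", 251, seed = 1)
  expect_equal(percent_identity(base, base), 100)
  one <- mutate_record(base, 1, seed = 2)
  expect_equal(round(percent_identity(base, one), 1), 99.6)
  base250 <- random_record("ref250", 250, seed = 3)
  two <- mutate_record(base250, 2, seed = 4)
  expect_equal(round(percent_identity(base250, two), 1), 99.2)
  expect_error(percent_identity(base, base250), "length")
})

test_that("gap columns are excluded from the identity denominator", {
  a <- aq_record("a", "AC-DEF-G", aligned = TRUE)
  b <- aq_record("b", "ACW-EFYG", aligned = TRUE)
  # comparable columns 1,2,5,6,8 all match; gapped columns are masked
  expect_equal(percent_identity(a, b), 100 * 5 / 5)
  allgap <- aq_record("g", "----", aligned = TRUE)
  other <- aq_record("h", "AC--", aligned = TRUE)
  expect_error(percent_identity(allgap, other), "no comparable")
})

test_that("p-distance is the identity complement and is metric", {
  recs <- list(random_record("a", 120, 10))
  recs[[2]] <- mutate_record(recs[[1]], 5, 11, id = "b")
  recs[[3]] <- mutate_record(recs[[1]], 40, 12, id = "c")
  d <- p_distance_matrix(recs)
  expect_equal(d, t(d))
  expect_equal(diag(d), setNames(rep(0, 3), c("a", "b", "c")))
  expect_equal(d["a", "b"], 1 - percent_identity(recs[[1]], recs[[2]]) / 100)

  # symmetry + triangle inequality over random 4-sequence alignments
  for (s in 1:30) {
    base <- random_record("r1", 60, 100 + s)
    rs <- list(base,
               mutate_record(base, sample(1:30, 1), 200 + s, "r2"),
               mutate_record(base, sample(1:30, 1), 300 + s, "r3"),
               random_record("r4", 60, 400 + s))
    dd <- p_distance_matrix(rs)
    expect_equal(dd, t(dd))
    for (i in 1:4) for (j in 1:4) for (k in 1:4)
      expect_lte(dd[i, k], dd[i, j] + dd[j, k] + 1e-12)
  }
})

test_that("one substitution over 251 columns gives d = 1/251", {
  base <- random_record("x", 251, 21)
  one <- mutate_record(base, 1, 22, id = "y")
  d <- p_distance_matrix(list(base, one, mutate_record(base, 3, 23, "z")))
  expect_equal(d["x", "y"], 1 / 251)
})

test_that("three-taxon NJ solves the three-point formulas", {
  d <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- nj_tree(d)
  # closed form: edge to A = (dAB + dAC - dBC) / 2, etc.
  want <- c(A = (0.3 + 0.5 - 0.6) / 2,
            B = (0.3 + 0.6 - 0.5) / 2,
            C = (0.5 + 0.6 - 0.3) / 2)
  got <- setNames(tree$edge.length[match(seq_len(3), tree$edge[, 2])],
                  tree$tip.label)
  expect_equal(got[names(want)], want, tolerance = 1e-12)
})

test_that("NJ recovers the topology of additive matrices (5-8 leaves)", {
  for (n in 5:8) {
    set.seed(n)
    true_tree <- ape::rtree(n)
    d <- ape::cophenetic.phylo(true_tree)   # path-sum distances: additive
    rec <- nj_tree(d[true_tree$tip.label, true_tree$tip.label])
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(true_tree),
                                           ape::unroot(rec))), 0)
  }
})

test_that("NJ guards and clamping behave", {
  d <- matrix(c(0, NA, 1, NA, 0, 1, 1, 1, 0), 3, 3)
  expect_error(nj_tree(d), "non-finite")
})

test_that("PIP-like and TIP-like fixtures split into two clades", {
  specs <- c(lapply(1:3, function(i)
    seq_gen_spec(paste0("PIP", i), "PIP2", n_substitutions = 4 * i,
                 seed = 30 + i)),
    lapply(1:3, function(i)
      seq_gen_spec(paste0("TIP", i), "TIP", n_substitutions = 4 * i,
                   seed = 60 + i)))
  set <- gen_aquaporin_set(specs)
  rep <- suppressMessages(run_sequence_study(set$records, set$maps))
  tree <- ape::read.tree(text = rep$tree)
  # root outside each set so monophyly tests the PIP|TIP bipartition
  expect_true(ape::is.monophyletic(
    ape::root(tree, outgroup = "TIP1", resolve.root = TRUE),
    paste0("PIP", 1:3)))
  expect_true(ape::is.monophyletic(
    ape::root(tree, outgroup = "PIP1", resolve.root = TRUE),
    paste0("TIP", 1:3)))
})

test_that("bootstrap support is high for a clean split", {
  specs <- c(lapply(1:2, function(i)
    seq_gen_spec(paste0("P", i), "PIP2", n_substitutions = 3, seed = i)),
    lapply(1:2, function(i)
      seq_gen_spec(paste0("T", i), "TIP", n_substitutions = 3,
                   seed = 10 + i)))
  set <- gen_aquaporin_set(specs)
  recs <- set$records
  # pad to equal length for the alignment-level bootstrap
  maxlen <- max(vapply(recs, function(r) nchar(r$sequence), integer(1)))
  recs <- lapply(recs, function(r)
    aq_record(r$id, paste0(r$sequence,
                           strrep("-", maxlen - nchar(r$sequence))),
              aligned = TRUE))
  tree <- nj_tree(p_distance_matrix(recs), records = recs,
                  bootstrap = 50, seed = 99)
  expect_true(all(tree$node.label[-1] >= 90))   # internal split support
})
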