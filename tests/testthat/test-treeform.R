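test_that("tree-form parsing: leaves, mixed brackets, sibling labels, ranges", {
  t1 <- parse_tree_string("(1,2)")
  expect_setequal(tree_leaves(t1), c("1", "2"))

  t2 <- parse_tree_string("(({[((1,2)3)(4,5)][(6,7)8]}9)10)")
  keys <- vapply(tree_clades(t2), paste, character(1), collapse = ",")
  for (cl in list(c("1","2"), c("1","2","3"), c("4","5"), c("6","7"),
                  c("6","7","8"), as.character(1:8), as.character(1:9)))
    expect_true(paste(sort(cl), collapse = ",") %in% keys,
                label = paste("clade", paste(cl, collapse = ",")))

  ## numeric ranges expand to sibling leaves
  t3 <- parse_tree_string("(({[1~5][(6,7)8]}9)10)")
  expect_setequal(tree_leaves(t3), as.character(1:10))
  expect_identical(classify_tree_form(t3)$type, "I")

  ## singleton groups collapse (unary nodes disappear)
  t4 <- parse_tree_string("((1,3)(4)(5))")
  expect_identical(length(t4$children), 3L)

  ## Newick with branch lengths
  t5 <- parse_tree_string("((A:0.1,B:0.2):0.05,C:0.3);")
  expect_setequal(tree_leaves(t5), c("A", "B", "C"))
})

test_that("unbalanced bracket strings are rejected with a position", {
  expect_error(parse_tree_string("(({([((1,2,3)4)5][(6,7)8]}9)10)"),
               "unbalanced")
  expect_error(parse_tree_string("((1,2)"), "unbalanced")
  expect_error(parse_tree_string("(1,2))"), "unbalanced")
})

test_that("parse -> serialize -> parse preserves clade sets", {
  for (s in anemonefish_tree_forms()$tree_form) {
    tr <- parse_tree_string(s)
    tr2 <- parse_tree_string(treeform_to_string(tr))
    k1 <- sort(vapply(tree_clades(tr), paste, character(1), collapse = ","))
    k2 <- sort(vapply(tree_clades(tr2), paste, character(1), collapse = ","))
    expect_identical(k1, k2)
  }
})

test_that("monophyly tests on published topologies", {
  nd1 <- parse_tree_string("(({[((1,2)3)(4,5)][(6,7)8]}9)10)")
  expect_true(is_monophyletic(nd1, as.character(1:8)))
  atp8 <- parse_tree_string("({[1,2,3,4,5][((6,7)8)9]}10)")
  expect_false(is_monophyletic(atp8, as.character(1:8)))
  expect_true(is_monophyletic(atp8, tree_leaves(atp8)))
  expect_error(is_monophyletic(nd1, c("1", "99")), "unknown leaf")
})

test_that("the 19 published tree forms reproduce the published type column", {
  tf <- anemonefish_tree_forms()
  got <- vapply(tf$tree_form,
                function(s) classify_tree_form(parse_tree_string(s))$type,
                character(1), USE.NAMES = FALSE)
  expect_identical(got, tf$type)
  counts <- table(got)
  expect_identical(as.integer(counts[c("I", "II", "III", "IV", "NM")]),
                   c(9L, 2L, 2L, 5L, 1L))
})

test_that("bracket kinds are decoration: substitution does not change the type", {
  tf <- anemonefish_tree_forms()
  for (i in c(1, 2, 6, 5)) {
    plain <- chartr("[]{}", "()()", tf$tree_form[i])
    expect_identical(classify_tree_form(parse_tree_string(plain))$type,
                     tf$type[i])
  }
})

test_that("types I/IV/NM are invariant under child rotation; II/III swap by written order", {
  rotate_children <- function(node) {
    if (!is.null(node$label)) return(node)
    kids <- lapply(node$children, rotate_children)
    node$children <- kids[c(length(kids), seq_len(length(kids) - 1L))]
    node
  }
  tf <- anemonefish_tree_forms()
  for (i in seq_len(nrow(tf))) {
    tr <- parse_tree_string(tf$tree_form[i])
    rot <- rotate_children(unclass(tr))
    class(rot) <- class(tr)
    got <- classify_tree_form(rot)$type
    if (tf$type[i] %in% c("II", "III")) {
      expect_true(got %in% c("II", "III"))
    } else {
      expect_identical(got, tf$type[i])
    }
  }
  ## the written-order rule itself: Premnas first -> II, medial -> III
  expect_identical(classify_tree_form(
    parse_tree_string("(({[8][1~5][6,7]}9)10)"))$type, "II")
  expect_identical(classify_tree_form(
    parse_tree_string("(({[1~5][8][6,7]}9)10)"))$type, "III")
  expect_identical(classify_tree_form(
    parse_tree_string("(({[1~5][6,7][8]}9)10)"))$type, "III")
})

test_that("sampled trees of every type round-trip through the classifier", {
  for (type in c("I", "II", "III", "IV", "NM")) {
    for (seed in 1:20) {
      tr <- sample_tree_of_type(type, seed = seed)
      expect_identical(classify_tree_form(tr)$type, type)
    }
  }
  expect_false(is_monophyletic(sample_tree_of_type("NM", seed = 3),
                               as.character(1:8)))
})

test_that("p-distances: identical pair is 0, one difference in four is 0.25", {
  expect_equal(p_distance_matrix(c(a = "ACGT", b = "ACGT"))["a", "b"], 0)
  expect_equal(p_distance_matrix(c(a = "ACGT", b = "ACGA"))["a", "b"], 0.25)
})

test_that("NJ recovers the generating topology for all 4- and 5-taxon shapes", {
  set.seed(17)
  for (n in c(4L, 5L)) {
    topos <- phangorn::allTrees(n, rooted = FALSE,
                                tip.label = paste0("t", seq_len(n)))
    for (k in seq_along(topos)) {
      phy <- topos[[k]]
      phy$edge.length <- runif(nrow(phy$edge), 0.05, 1)
      d <- additive_matrix(phy)
      nj_tree <- neighbor_joining(d)
      nj_phy <- attr(nj_tree, "phylo")
      expect_equal(as.numeric(ape::dist.topo(ape::unroot(nj_phy),
                                             ape::unroot(phy))), 0)
      ## independent oracle: exhaustive least-squares over all topologies
      best <- best_topology_by_ls(topos, d)
      expect_identical(best, k)
    }
  }
})

test_that("NJ on strongly supported type-I sequence data is typed I end to end", {
  gen <- sample_tree_of_type("I", seed = 99)
  seqs <- mutate_sequences(strrep("ACGTTGCAAT", 1200), gen, rate = 0.03,
                           seed = 99)
  d <- p_distance_matrix(seqs)
  tr <- neighbor_joining(d, outgroup = "10")
  rep_ <- treeform_report(c("concatenated" = treeform_to_string(tr)))
  expect_identical(rep_$type, "I")
})

test_that("non-symmetric or tiny distance matrices are rejected", {
  d <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(neighbor_joining(d), "three taxa|symmetric")
  d3 <- matrix(c(0, 1, 2, 3, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(d3), "symmetric")
})
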