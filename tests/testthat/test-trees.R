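# Tree/split data model: parsing, cluster extraction, compatibility,
# tree popping, RF distance, SPR moves, incompatibility degrees.

test_that("parse_newick reads supports, rejects degenerate input", {
  t <- parse_newick("((x:1,y:1)40:1,(z:1,w:1)100:1,u:1);")
  cl <- extract_clusters(t)
  expect_setequal(cl$support, c(40, 100))
  expect_true(attr(t, "has_supports"))
  expect_error(parse_newick("(a,b);"), "at least 3")
  expect_error(parse_newick("((a,b),(a,c),d);"), "duplicate")
  expect_error(parse_newick("((a,b),c);", taxa = c("a", "b", "z")),
               "mismatch")
  # posterior probabilities are rescaled to percent
  tp <- parse_newick("((x:1,y:1)0.9:1,(z:1,w:1)1.0:1,u:1);",
                     support_scale = "probability")
  expect_setequal(extract_clusters(tp)$support, c(90, 100))
  # auto detection treats all-below-1 labels as probabilities
  ta <- parse_newick("((x:1,y:1)0.5:1,(z:1,w:1)0.7:1,u:1);")
  expect_setequal(extract_clusters(ta)$support, c(50, 70))
  # comment dialect
  tc <- parse_newick("((x:1,y:1)[&support=40]:1,(z:1,w:1)[&support=100]:1,u:1);",
                     dialect = "comment")
  expect_setequal(extract_clusters(tc)$support, c(40, 100))
})

test_that("newick round-trip preserves the split set", {
  set.seed(11)
  for (m in c(5, 8, 12)) {
    t <- random_supported_tree(m)
    taxa <- attr(t, "taxa")
    t2 <- parse_newick(write_newick(t), taxa = taxa)
    expect_identical(split_set(t2, taxa), split_set(t, taxa))
    expect_equal(sort(extract_clusters(t2, taxa)$support),
                 sort(extract_clusters(t, taxa)$support))
  }
})

test_that("extract_clusters matches the worked example and edge counts", {
  taxa <- FIG_TAXA
  t3 <- parse_newick("((x:1,u:1)90:1,(z:1,w:1)100:1,y:1);", taxa = taxa)
  cl <- extract_clusters(t3)
  got <- setNames(cl$support, cl$key)
  expect_equal(unname(got[cluster_key(nc_cluster(c("x", "u"), taxa))]), 90)
  expect_equal(unname(got[cluster_key(nc_cluster(c("z", "w"), taxa))]), 100)
  expect_equal(nrow(cl), 2)
  # star tree has no nontrivial splits
  star <- parse_newick("(a,b,c,d,e);")
  expect_equal(nrow(extract_clusters(star)), 0)
  # unrooted binary trees carry m - 3 nontrivial splits
  set.seed(4)
  for (m in c(6, 10, 15)) {
    t <- random_supported_tree(m)
    expect_equal(nrow(extract_clusters(t)), m - 3)
  }
})

test_that("extract_clusters is invariant under re-rooting", {
  set.seed(21)
  t <- random_supported_tree(9)
  taxa <- attr(t, "taxa")
  for (og in sample(taxa, 3)) {
    rr <- ape::root(t, outgroup = og, resolve.root = TRUE)
    attr(rr, "taxa") <- taxa
    expect_identical(split_set(rr, taxa), split_set(t, taxa))
  }
})

test_that("are_compatible implements split compatibility", {
  taxa <- FIG_TAXA
  expect_true(are_compatible(nc_cluster(c("x", "y"), taxa),
                             nc_cluster(c("z", "w"), taxa)))
  expect_false(are_compatible(nc_cluster(c("x", "y"), taxa),
                              nc_cluster(c("x", "u"), taxa)))
  a <- nc_cluster(c("x", "y"), taxa)
  expect_true(are_compatible(a, a))
  # orientation must not matter
  expect_true(are_compatible(nc_cluster(c("x", "y"), taxa),
                             nc_cluster(c("x", "y", "u"), taxa)))
  # agreement with "tree_from_clusters succeeds"
  set.seed(7)
  for (rep in 1:40) {
    m <- sample(5:8, 1)
    taxa2 <- letters[1:m]
    s1 <- nc_cluster(sample(taxa2, sample(2:(m - 2), 1)), taxa2)
    s2 <- nc_cluster(sample(taxa2, sample(2:(m - 2), 1)), taxa2)
    built <- tryCatch({tree_from_clusters(list(s1, s2), taxa2); TRUE},
                      error = function(e) FALSE)
    expect_identical(are_compatible(s1, s2), built)
  }
})

test_that("tree_from_clusters round-trips split sets and builds stars", {
  star <- tree_from_clusters(character(), letters[1:5])
  expect_equal(nrow(extract_clusters(star, letters[1:5])), 0)
  set.seed(13)
  for (m in c(5, 9, 14)) {
    t <- random_supported_tree(m)
    taxa <- attr(t, "taxa")
    cl <- extract_clusters(t, taxa)
    t2 <- tree_from_clusters(cl$key, taxa, cl$support)
    expect_identical(split_set(t2, taxa), split_set(t, taxa))
  }
  expect_error(tree_from_clusters(
    list(nc_cluster(c("x", "y"), FIG_TAXA), nc_cluster(c("x", "u"), FIG_TAXA)),
    FIG_TAXA), "incompatible")
})

test_that("rf_distance matches the worked example and phangorn", {
  coll <- fig_trees()
  expect_equal(rf_distance(coll$trees[[1]], coll$trees[[2]]), 0)
  expect_equal(rf_distance(coll$trees[[1]], coll$trees[[1]]), 0)
  expect_equal(rf_distance(coll$trees[[1]], coll$trees[[3]]), 2)
  skip_if_not_installed("phangorn")
  set.seed(5)
  for (rep in 1:20) {
    m <- sample(5:12, 1)
    taxa <- sprintf("s%02d", seq_len(m))
    t1 <- random_supported_tree(m, taxa)
    t2 <- random_supported_tree(m, taxa)
    expect_equal(rf_distance(t1, t2, taxa),
                 as.numeric(phangorn::RF.dist(t1, t2)))
  }
})

test_that("spr_move performs valid moves and preserves unaffected supports", {
  taxa <- FIG_TAXA
  t3 <- parse_newick("((x:1,u:1)90:1,(z:1,w:1)100:1,y:1);", taxa = taxa)
  # the witness move for the worked example: the result displays {x,y}
  res <- spr_move(t3, "u", c("z", "w"))
  expect_true(cluster_key(nc_cluster(c("x", "y"), taxa)) %in%
                split_set(res, taxa))
  # the untouched {z,w} branch keeps its support
  cl <- extract_clusters(res, taxa)
  expect_equal(cl$support[cl$key == cluster_key(nc_cluster(c("z", "w"), taxa))],
               100)
  # identity move: regraft onto the original branch
  set.seed(9)
  t <- random_supported_tree(8)
  taxa8 <- attr(t, "taxa")
  S <- netcons:::node_sides(t, taxa8)
  ch <- t$edge[which(t$edge[, 2] <= 8)[1], 2]   # a leaf
  P <- S[ch, ]
  # its original neighbour branch: sibling side after pruning
  sides <- netcons:::all_sides(t, taxa8)
  sidesR <- netcons:::sides_after_prune(sides, P)
  back <- NULL
  for (A in sidesR) {
    r <- spr_move(t, P, A, taxa8)
    if (identical(split_set(r, taxa8), split_set(t, taxa8))) back <- r
  }
  expect_false(is.null(back))  # some regraft reproduces the original tree
  expect_error(spr_move(t3, c("x", "y"), "z"), "not a subtree")
  expect_error(spr_move(t3, c("z", "w"), "z"), "inside the pruned")
})

test_that("SPR neighbourhood size and distances match theory on 5 leaves", {
  t <- fig_trees()$trees[[1]]
  nb <- all_spr_neighbors(t)
  sig <- vapply(nb, function(x) paste(split_set(x, FIG_TAXA), collapse = "|"),
                "")
  # unrooted binary n = 5: 2(n-3)(2n-7) = 12 distinct SPR neighbours
  expect_equal(length(unique(sig)), 12)
  for (x in nb) expect_gte(rf_distance(t, x, FIG_TAXA), 2)
})

test_that("first_degree_incompatible reproduces the worked example", {
  taxa <- FIG_TAXA
  t3 <- parse_newick("((x:1,u:1)90:1,(z:1,w:1)100:1,y:1);", taxa = taxa)
  expect_true(first_degree_incompatible(nc_cluster(c("x", "y"), taxa), t3))
  # (xyw) needs two moves: second degree
  expect_false(first_degree_incompatible(nc_cluster(c("x", "y", "w"), taxa), t3))
  # a compatible cluster is not incompatible at all
  expect_false(first_degree_incompatible(nc_cluster(c("x", "u"), taxa), t3))
})

test_that("first_degree_incompatible agrees with exhaustive SPR search", {
  set.seed(31)
  for (rep in 1:40) {
    m <- sample(6:8, 1)
    taxa <- letters[1:m]
    t <- random_supported_tree(m, taxa)
    members <- sample(taxa, sample(2:(m - 2), 1))
    expect_identical(
      first_degree_incompatible(nc_cluster(members, taxa), t, taxa),
      oracle_first_degree(members, t, taxa),
      info = paste(rep, paste(members, collapse = ",")))
  }
})

test_that("rf_distance is a metric on random triples", {
  set.seed(17)
  for (rep in 1:25) {
    m <- sample(5:9, 1)
    taxa <- sprintf("s%02d", seq_len(m))
    a <- random_supported_tree(m, taxa)
    b <- random_supported_tree(m, taxa)
    c <- random_supported_tree(m, taxa)
    dab <- rf_distance(a, b, taxa); dba <- rf_distance(b, a, taxa)
    expect_identical(dab, dba)
    expect_identical(rf_distance(a, a, taxa), 0L)
    expect_lte(rf_distance(a, c, taxa), dab + rf_distance(b, c, taxa))
    if (dab == 0)
      expect_identical(split_set(a, taxa), split_set(b, taxa))
  }
})
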