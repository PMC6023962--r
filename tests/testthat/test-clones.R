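# Deterministic clone pipeline: V/J assignment, grouping, NJ trees,
# cutoff partition, ancestor choice.

test_that("assign_vj recovers the true genes and junction on clean reads", {
  g <- toy_germline()
  p <- toy_params()
  pool <- simulate_pool(300, p, g, frame = "any", seed = 401)
  a <- assign_vj(pool, g)
  expect_true(all(a$assigned))
  expect_equal(a$v_name, pool$v_name)
  expect_equal(a$j_name, pool$j_name)
  # junction calls may absorb insertion bases that happen to match the
  # germline continuation, so the inferred junction never exceeds the truth
  expect_true(all(a$vj_distance <= nchar(pool$ins_seq)))
  expect_gte(mean(a$vj_distance == nchar(pool$ins_seq)), 0.5)
})

test_that("assign_vj flags reads without both gene matches", {
  g <- toy_germline()
  expect_message(a <- assign_vj(g$v$seq[1], g), "unassigned")  # pure V read
  expect_false(a$assigned)
  expect_message(a2 <- assign_vj("ACGTACGTACGTACGTACGTACGTACGTACG", g),
                 "unassigned")
  expect_false(a2$assigned)
})

test_that("assignment accuracy on mutated reads exceeds 99%", {
  g <- toy_germline()
  p <- toy_params()
  fam <- simulate_clonal_families(250, p, g,
                                  family_size_probs = c(0, 0, 0, 1),
                                  mutation_count_probs = c(0.2, 0.4, 0.4),
                                  seed = 402)
  expect_equal(nrow(fam), 1000)
  a <- assign_vj(fam, g)
  acc <- mean(a$v_name == fam$v_name & a$j_name == fam$j_name, na.rm = TRUE)
  expect_gte(acc, 0.99)
})

test_that("grouping keys are respected and identical reads align identically", {
  g <- toy_germline()
  p <- toy_params()
  pool <- simulate_pool(60, p, g, frame = "any", seed = 403)
  pool2 <- pool[c(1, 1, 2), ]
  pool2$id <- c("r1", "r1b", "r2")
  a <- assign_vj(pool2, g)
  grp <- group_and_align(a, pool2, g, by = "junction")
  k1 <- which(vapply(grp, function(x) "r1" %in% x$members, logical(1)))
  expect_true("r1b" %in% grp[[k1]]$members)
  al <- grp[[k1]]$aligned[match(c("r1", "r1b"), grp[[k1]]$members)]
  expect_equal(al[1], al[2])
  # different junction lengths are never merged under junction keying
  for (grp_i in grp) {
    expect_equal(length(unique(grp_i$vj_distance)), 1)
    expect_equal(length(unique(nchar(grp_i$aligned))), 1)
  }
})

test_that("a simulated clone family lands in one equal-width group", {
  g <- toy_germline()
  p <- toy_params()
  fam <- simulate_clonal_families(1, p, g, family_size_probs = c(0, 0, 0, 0, 1),
                                  mutation_count_probs = c(0.3, 0.3, 0.2, 0.2),
                                  seed = 404)
  a <- assign_vj(fam, g)
  grp <- group_and_align(a, fam, g, by = "length")
  expect_equal(length(grp), 1)
  expect_equal(sort(grp[[1]]$members), sort(fam$id))
  expect_equal(length(unique(nchar(grp[[1]]$aligned))), 1)
})

test_that("neighbor joining reconstructs an additive 4-taxon tree", {
  # tree: (A,B) vs (C,D) with external edges 1, 2, 3, 4 and internal edge 5
  D <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  D["A", "B"] <- D["B", "A"] <- 1 + 2
  D["A", "C"] <- D["C", "A"] <- 1 + 5 + 3
  D["A", "D"] <- D["D", "A"] <- 1 + 5 + 4
  D["B", "C"] <- D["C", "B"] <- 2 + 5 + 3
  D["B", "D"] <- D["D", "B"] <- 2 + 5 + 4
  D["C", "D"] <- D["D", "C"] <- 3 + 4
  tr <- nj_tree(D)
  expect_s3_class(tr, "phylo")
  patristic <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(patristic, D, tolerance = 1e-10)

  # two taxa: a single edge of the given length
  D2 <- matrix(c(0, 7, 7, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  tr2 <- nj_tree(D2)
  expect_equal(sum(tr2$edge.length), 7)
  expect_equal(unname(ape::cophenetic.phylo(tr2)["x", "y"]), 7)
})

test_that("partition_clones cuts at the cutoff under both distance rules", {
  labs <- c("a1", "a2", "a3", "b1", "b2")
  D <- matrix(10, 5, 5, dimnames = list(labs, labs))
  diag(D) <- 0
  D[1:3, 1:3] <- 2; diag(D) <- 0
  D[4:5, 4:5] <- 1; diag(D) <- 0
  comp <- partition_clones(nj_tree(D), cutoff = 4)
  expect_equal(length(unique(comp)), 2)
  expect_equal(unname(comp["a1"] == comp["a3"]), TRUE)
  expect_equal(unname(comp["a1"] == comp["b1"]), FALSE)
  comp_h <- partition_clones(NULL, cutoff = 4, method = "hamming", dist = D)
  expect_equal(unname(comp_h), unname(comp))
  # cutoff 0 merges only identical sequences; huge cutoff merges everything
  expect_equal(length(unique(partition_clones(NULL, 0, "hamming", dist = D))), 5)
  D0 <- D; D0["a1", "a2"] <- D0["a2", "a1"] <- 0
  expect_equal(length(unique(partition_clones(NULL, 0, "hamming", dist = D0))), 4)
  expect_equal(length(unique(partition_clones(NULL, 100, "hamming", dist = D))), 1)
})

test_that("clone_ancestor minimizes germline distance with lexicographic ties", {
  expect_equal(clone_ancestor("only", 3), "only")
  expect_equal(clone_ancestor(c("r2", "r1", "r3"), c(1, 2, 1)), "r2")
  expect_equal(clone_ancestor(c("r2", "r1"), c(2, 2)), "r1")
})

test_that("end-to-end clone recovery finds simulated families", {
  g <- toy_germline()
  p <- toy_params(i_max = 12)
  p$p_ins[] <- 0
  p$p_ins[as.character(8:12)] <- c(0.15, 0.25, 0.25, 0.2, 0.15)
  fam <- simulate_clonal_families(60, p, g, min_junction_dist = 8, seed = 406)
  cl <- detect_clones(fam, g, cutoff = 4)
  expect_setequal(cl$read_id, fam$id)
  # clones partition each group
  expect_false(any(duplicated(cl$read_id)))
  expect_equal(sum(cl$is_ancestor), length(unique(cl$clone_id)))
  truth <- fam$family[match(cl$read_id, fam$id)]
  expect_gte(mclust::adjustedRandIndex(cl$clone_id, truth), 0.95)
  # byte-identical rerun
  expect_identical(cl, detect_clones(fam, g, cutoff = 4))
})
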