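# distance estimation, NJ subtrees, grafting, calibration, ultrametricity

test_that("JC69 distances follow the correction and its saturation contract", {
  s <- c(a = "ACGTACGTAC", b = "ACGTACGTAC")
  expect_equal(jc69_distances(s)[1, 2], 0)
  # p = 0.1 over 10 sites
  s2 <- c(a = "ACGTACGTAC", b = "ACGTACGTAT")
  expect_equal(jc69_distances(s2)[1, 2], -0.75 * log(1 - 0.4 / 3))
  # saturation: all 10 sites differ -> ceiling
  s3 <- c(a = "AAAAAAAAAA", b = "CCCCCCCCCC")
  expect_warning(D <- jc69_distances(s3, ceiling = 5), "saturated")
  expect_equal(D[1, 2], 5)
  expect_error(jc69_distances(c(a = "ACGT", b = "ACG")), "equal length")
  expect_error(jc69_distances(c(a = "NNNN", b = "ACGT")), "no comparable")
  # gapped columns are pairwise-deleted
  s4 <- c(a = "AC-TACGTAC", b = "ACGTACGTAT")
  expect_equal(jc69_distances(s4)[1, 2], -0.75 * log(1 - 4 * (1 / 9) / 3))
})

test_that("JC69 distances agree with ape's model on clean alignments", {
  tr <- with_seed_local(8, ape::rcoal(6))
  seqs <- evolve_sequences(tr, length = 800, rate = 0.3, seed = 9)
  D <- jc69_distances(seqs)
  bin <- ape::as.DNAbin(t(sapply(strsplit(tolower(seqs), ""), identity)))
  Dape <- as.matrix(ape::dist.dna(bin, model = "JC69", pairwise.deletion = TRUE))
  expect_equal(D[rownames(Dape), colnames(Dape)], Dape, tolerance = 1e-9)
})

test_that("NJ recovers additive distances exactly", {
  tr4 <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):2);")
  D <- ape::cophenetic.phylo(tr4)
  nj <- nj_tree(D)
  expect_equal(as.numeric(phangorn::RF.dist(ape::unroot(nj), ape::unroot(tr4))), 0)
  got <- ape::cophenetic.phylo(nj)
  expect_equal(got[rownames(D), colnames(D)], D, tolerance = 1e-9)
})

test_that("three-taxon NJ solves the three-point equations", {
  D <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nj <- nj_tree(D)
  got <- ape::cophenetic.phylo(nj)
  expect_equal(got[rownames(D), colnames(D)], D, tolerance = 1e-9)
  # 2 taxa: cherry splitting the distance
  D2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  ch <- nj_tree(D2)
  expect_equal(sort(ch$tip.label), c("A", "B"))
  expect_equal(ape::cophenetic.phylo(ch)["A", "B"], 4)
})

test_that("NJ is invariant to input taxon order", {
  tr <- with_seed_local(5, ape::rcoal(7))
  D <- ape::cophenetic.phylo(tr)
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  t1 <- nj_tree(D)
  t2 <- nj_tree(D[perm, perm])
  expect_equal(as.numeric(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2))), 0)
})

test_that("grafting replaces family tips by their OTU subtrees", {
  backbone <- ape::read.tree(text = "((Apidae:50,Formicidae:50):50,Carabidae:100);")
  sub <- ape::read.tree(text = "((x1:5,x2:5):5,x3:10);")
  res <- graft_subtrees(backbone, list(Apidae = sub))
  expect_setequal(res$tree$tip.label,
                  c("x1", "x2", "x3", "Formicidae", "Carabidae"))
  mrca <- ape::getMRCA(res$tree, c("x1", "x2", "x3"))
  expect_true(mrca > length(res$tree$tip.label))   # family is now internal

  # absent family -> unchanged tree plus skip report
  res2 <- graft_subtrees(backbone, list(Vespidae = sub))
  expect_equal(sort(res2$tree$tip.label), sort(backbone$tip.label))
  expect_equal(res2$skipped, "Vespidae")

  # single-OTU family attaches as a single renamed tip
  res3 <- graft_subtrees(backbone, list(Carabidae = "car_OTU1"))
  expect_true("car_OTU1" %in% res3$tree$tip.label)
  expect_false("Carabidae" %in% res3$tree$tip.label)

  # label collision is an error
  clash <- ape::read.tree(text = "(Formicidae:1,x9:1);")
  expect_error(graft_subtrees(backbone, list(Apidae = clash)), "already present")
})

test_that("grafting every family yields exactly the expected tip set", {
  sim <- simulate_dataset(seed = 4, n_families = 6, otus_per_family = 3)
  subtrees <- lapply(sim$alignments, function(a) nj_tree(jc69_distances(a)))
  res <- graft_subtrees(sim$backbone, subtrees, sim$taxonomy)
  expect_setequal(res$tree$tip.label, sim$taxonomy$otu_id)
})

test_that("sister-family insertion forms a cherry and refuses duplicates", {
  backbone <- ape::read.tree(text = "((F1:40,F3:40):60,F4:100);")
  t2 <- insert_family_as_sister(backbone, "F2", "F1")
  expect_true("F2" %in% t2$tip.label)
  mrca <- ape::getMRCA(t2, c("F1", "F2"))
  kids <- t2$edge[t2$edge[, 1] == mrca, 2]
  expect_setequal(t2$tip.label[kids], c("F1", "F2"))
  expect_error(insert_family_as_sister(t2, "F2", "F1"), "already present")
  expect_error(insert_family_as_sister(backbone, "F9", "Fx"), "not found")
})

test_that("bladj calibration spaces uncalibrated nodes evenly", {
  chain <- ape::read.tree(text = "(((T:1):1):1);")
  chain$node.label <- c("root", "U1", "U2")
  cal <- calibrate_ages(chain, c(root = 90))
  ages <- attr(cal, "node_ages")
  expect_equal(unname(ages), c(0, 90, 60, 30))
  # branch lengths are the age differences
  expect_equal(sort(cal$edge.length), c(30, 30, 30))
})

test_that("fully calibrated trees keep their ages exactly and idempotently", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  tr$node.label <- c("root", "n1", "n2")
  cal <- c(root = 100, n1 = 40, n2 = 70)
  t1 <- calibrate_ages(tr, cal)
  ages <- attr(t1, "node_ages")
  expect_equal(unname(ages[5:7]), c(100, 40, 70))
  t2 <- calibrate_ages(t1, cal)
  expect_equal(attr(t2, "node_ages"), ages)
  # conflicting calibration errors with the offending pair
  expect_error(calibrate_ages(tr, c(root = 30, n1 = 40)), "conflict")
})

test_that("random consistent calibrations give monotone root-to-tip ages", {
  for (seed in 1:5) {
    bb <- simulate_backbone(10, depth = 200, seed = seed)
    # calibrate a random subset of true node ages (always keep the root)
    keep <- with_seed_local(seed + 50, {
      k <- sample(2:(length(bb$ages) - 1), 1)
      unique(c(names(bb$ages)[1], sample(names(bb$ages), k)))
    })
    cal <- bb$ages[keep]
    out <- calibrate_ages(bb$tree, cal)
    ages <- attr(out, "node_ages")
    expect_true(all(out$edge.length > -1e-9))
    # every parent strictly older than its child
    expect_true(all(ages[out$edge[, 1]] > ages[out$edge[, 2]] - 1e-9))
    # fixed nodes unchanged
    lab_nodes <- match(names(cal), out$node.label) + length(out$tip.label)
    expect_equal(unname(ages[lab_nodes]), unname(cal))
  }
})

test_that("force_ultrametric equalizes tip heights within 1e-9", {
  # already ultrametric -> identity
  tr <- cherry_tree()
  out <- force_ultrametric(tr)
  expect_equal(out$edge.length, tr$edge.length)
  expect_equal(attr(out, "max_adjustment"), 0)
  # tip short by 0.3 -> terminal edge lengthened by 0.3
  t2 <- ape::read.tree(text = "((A:0.7,B:1):1,C:2);")
  out2 <- force_ultrametric(t2)
  d <- ape::node.depth.edgelength(out2)[1:3]
  expect_equal(max(d) - min(d), 0)
  expect_equal(out2$edge.length[out2$edge[, 2] == which(out2$tip.label == "A")], 1)
  # tolerance contract
  expect_error(force_ultrametric(t2, tol = 0.1), "exceeds tolerance")
  # random perturbed trees meet the post-condition
  for (seed in 1:5) {
    bb <- simulate_backbone(8, depth = 150, seed = seed)$tree
    bb$edge.length <- bb$edge.length * with_seed_local(seed, runif(length(bb$edge.length), 0.9, 1.1))
    out3 <- force_ultrametric(bb)
    d3 <- ape::node.depth.edgelength(out3)[1:8]
    expect_lt(max(d3) - min(d3), 1e-9)
  }
})

test_that("sequence evolution + JC + NJ recovers shallow subtrees", {
  # barcode-length alignments on shallow (0.15 subs/site) family trees whose
  # internal edges are resolvable (floored at 5% of the longest edge)
  hits <- vapply(1:100, function(r) {
    tr <- with_seed_local(7000 + r, ape::rtree(6))
    tr$edge.length <- pmax(tr$edge.length, 0.05 * max(tr$edge.length))
    tr$edge.length <- tr$edge.length * 0.15 / max(ape::node.depth.edgelength(tr)[1:6])
    seqs <- evolve_sequences(tr, length = 650, rate = 1, seed = 7100 + r)
    nj <- nj_tree(jc69_distances(seqs))
    as.numeric(phangorn::RF.dist(ape::unroot(nj), ape::unroot(tr))) == 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("graft + calibrate + force_ultrametric preserves tip labels", {
  sim <- simulate_dataset(seed = 9, n_families = 6, otus_per_family = 3)
  mt <- build_megatree(sim$backbone, sim$alignments, sim$taxonomy,
                       sim$calibrations)
  expect_setequal(mt$tree$tip.label, sim$taxonomy$otu_id)
  d <- ape::node.depth.edgelength(mt$tree)[seq_along(mt$tree$tip.label)]
  expect_lt(max(d) - min(d), 1e-9)
})
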