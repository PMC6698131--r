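square <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))

test_that("Kabsch superposition handles identity, rigid motion and scaling", {
  A <- coordinate_set("a", square)
  expect_equal(kabsch_superpose(A, A)$rmsd, 0, tolerance = 1e-12)
  expect_equal(kabsch_superpose(A, A)$rotation, diag(3), tolerance = 1e-9)

  set.seed(41)
  for (i in 1:10) {
    P <- matrix(rnorm(18), 6)
    R <- euler_rot(runif(1, 0, 2 * pi), runif(1, 0, pi), runif(1, 0, 2 * pi))
    Q <- P %*% t(R) + rep(rnorm(3, sd = 5), each = 6)
    fit <- kabsch_superpose(coordinate_set("p", P), coordinate_set("q", Q))
    expect_lt(fit$rmsd, 1e-9)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    expect_equal(crossprod(fit$rotation), diag(3), tolerance = 1e-9)
  }

  B <- coordinate_set("b", 2 * square)
  expect_equal(kabsch_superpose(A, B)$rmsd, sqrt(0.5), tolerance = 1e-9)

  expect_error(kabsch_superpose(A, A, pairs = cbind(1:2, 1:2)), "at least 3")
})

test_that("Kabsch rmsd matches the brute-force rotation oracle", {
  set.seed(42)
  for (i in 1:5) {
    P <- matrix(rnorm(15, sd = 2), 5)
    Q <- matrix(rnorm(15, sd = 2), 5)
    fit <- kabsch_superpose(coordinate_set("p", P), coordinate_set("q", Q))
    oracle <- grid_min_rmsd(P, Q)
    expect_equal(fit$rmsd, oracle, tolerance = 1e-3)
    # SVD optimum can never exceed the grid search result, nor the
    # un-rotated centroid-aligned RMSD
    expect_lte(fit$rmsd, oracle + 1e-9)
    Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
    expect_lte(fit$rmsd, sqrt(mean(rowSums((Qc - Pc)^2))) + 1e-12)
  }
})

test_that("pairwise RMSD matrices are symmetric, zero-diagonal, non-negative", {
  A <- coordinate_set("a", square)
  same <- list(A, coordinate_set("b", square), coordinate_set("c", square))
  m0 <- pairwise_rmsd_matrix(same)
  expect_equal(unname(m0), matrix(0, 3, 3))

  fx <- make_helix_bundle(n_clusters = 2, members_per_cluster = 3, seed = 43)
  m <- pairwise_rmsd_matrix(fx$structures)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 6))
  expect_true(all(m >= 0))

  # element-wise recomputation in reversed order gives the same matrix
  m_rev <- pairwise_rmsd_matrix(rev(fx$structures))
  expect_equal(m_rev[rownames(m), colnames(m)], m, tolerance = 1e-12)

  # missing correspondence is a coverage error naming the pair
  corr <- data.frame(idA = "m01", idxA = 1:60, idB = "m02", idxB = 1:60)
  expect_error(pairwise_rmsd_matrix(fx$structures[1:3], corr),
               "\\(m01, m03\\)")
})

test_that("correspondences derived from an alignment pair ungapped ranks", {
  aln <- nsltp_alignment(c(x = "AC.D", y = "A.CD"))
  corr <- correspondences_from_alignment(aln)
  # shared non-gap columns are 1 and 4 -> pairs (1,1) and (3,3)
  expect_equal(corr$idxA, c(1, 3))
  expect_equal(corr$idxB, c(1, 3))
})

test_that("distance trees round-trip additive matrices", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  dm <- cophenetic(tr)
  dm <- dm[order(rownames(dm)), order(colnames(dm))]
  nj <- build_distance_tree(dm)
  expect_equal(max(abs(cophenetic(nj)[rownames(dm), colnames(dm)] - dm)), 0,
               tolerance = 1e-9)

  set.seed(44)
  for (i in 1:5) {
    rt <- ape::rtree(sample(4:9, 1))
    dm <- cophenetic(rt)
    nj <- build_distance_tree(dm)
    expect_equal(max(abs(cophenetic(nj)[rownames(dm), colnames(dm)] - dm)), 0,
                 tolerance = 1e-9)
  }

  # three taxa: closed-form three-point branch lengths
  m3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nj3 <- build_distance_tree(m3)
  co3 <- cophenetic(nj3)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(unname(co3), unname(m3), tolerance = 1e-9)

  bad <- m3; bad[1, 2] <- 9
  expect_error(build_distance_tree(bad), "symmetric")
})

test_that("on ultrametric matrices the NJ topology matches UPGMA", {
  # ultrametric 4-leaf tree: ((A,B),(C,D)) with heights 1 and 3
  um <- matrix(c(0, 2, 6, 6,
                 2, 0, 6, 6,
                 6, 6, 0, 2,
                 6, 6, 2, 0), 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  nj <- build_distance_tree(um)
  # of the 3 possible unrooted 4-leaf topologies, NJ must pair A,B and C,D
  expect_true(ape::is.monophyletic(ape::root(nj, "D"), c("A", "B")))
})

test_that("cutoff clustering bounds intra-cluster distances, matching complete linkage", {
  m <- matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  p <- cut_clusters(m, 1.5)
  expect_equal(lapply(p, `[[`, "member_ids"), list(c("A", "B"), "C"))

  set.seed(45)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    rm <- random_dist_matrix(n)
    cutoff <- runif(1, min(rm[rm > 0]), max(rm))
    part <- cut_clusters(rm, cutoff)
    members <- lapply(part, `[[`, "member_ids")
    # disjoint cover
    expect_setequal(unlist(members), rownames(rm))
    expect_equal(sum(lengths(members)), n)
    # intra-cluster distances never exceed the cutoff
    for (g in members)
      if (length(g) > 1) expect_lte(max(rm[g, g]), cutoff)
    # equality with stats::hclust complete linkage cut at the same height
    oracle <- partition_from_assignment(
      cutree(hclust(as.dist(rm), method = "complete"), h = cutoff))
    expect_true(same_partition(members, oracle))
  }

  # cutoff >= max distance: everything in one cluster
  rm <- random_dist_matrix(6)
  all_in <- cut_clusters(rm, max(rm) + 1)
  expect_length(all_in, 1)
  # cutoff below the minimum positive distance: all singletons
  frag <- cut_clusters(rm, min(rm[rm > 0]) / 2)
  expect_length(frag, 6)
})

test_that("nested cutoffs refine each other and the sweep emits 23 partitions", {
  set.seed(46)
  rm <- random_dist_matrix(10)
  rm <- rm / max(rm) * 12
  sw <- sweep_clusters(rm)
  expect_length(sw, 23)
  expect_equal(names(sw)[1], "11.5")
  for (lev in 2:length(sw)) {
    finer <- lapply(sw[[lev]], `[[`, "member_ids")
    coarser <- lapply(sw[[lev - 1]], `[[`, "member_ids")
    for (g in finer)
      expect_true(any(vapply(coarser, function(cg) all(g %in% cg),
                             logical(1))))
  }
})

test_that("medoid selection matches brute force and breaks ties by id", {
  m <- matrix(c(0, 1, 1, 1, 0, 3, 1, 3, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(select_medoid(c("A", "B", "C"), m), "A")
  expect_equal(select_medoid("B", m), "B")
  expect_error(select_medoid(c("A", "Z"), m), "absent")

  set.seed(47)
  for (i in 1:10) {
    n <- sample(3:20, 1)
    rm <- random_dist_matrix(n)
    members <- sample(rownames(rm), sample(2:n, 1))
    sums <- vapply(members, function(id) sum(rm[id, members]), numeric(1))
    brute <- sort(members[sums == min(sums)])[1]
    expect_equal(select_medoid(members, rm), brute)
  }
})

test_that("annotation enrichment reproduces the printed defense-cluster counts", {
  ids <- sprintf("p%03d", 1:500)
  big <- list(list(member_ids = ids[1:402], cutoff = 3, medoid_id = "p001"))
  ann <- data.frame(id = ids[1:28], keywords = "defense")
  enr <- annotation_enrichment(big, ann)
  expect_equal(enr$annotated_count, 28)
  expect_equal(enr$annotated_fraction, 28 / 402)

  # 43-member cluster capturing 10 of 31 annotated ids
  cl43 <- list(list(member_ids = ids[1:43], cutoff = 1.5, medoid_id = "p001"))
  ann31 <- data.frame(id = c(ids[1:10], ids[100:120]),
                      keywords = c(rep("defense", 20), rep("resistance", 11)))
  enr43 <- annotation_enrichment(cl43, ann31)
  expect_equal(enr43$annotated_count, 10)
  expect_equal(enr43$captured_fraction, 10 / 31)

  none <- annotation_enrichment(cl43, data.frame(id = character(0),
                                                 keywords = character(0)))
  expect_equal(none$annotated_count, 0)
  expect_equal(none$captured_fraction, 0)
})

test_that("residue pair distances follow the superposition frame", {
  A <- coordinate_set("a", square)
  fit0 <- list(rotation = diag(3), translation = c(0, 0, 0))
  expect_equal(residue_pair_distance(A, A, fit0, 1, 1), 0)

  B <- coordinate_set("b", rbind(c(3, 4, 0), square[-1, ]))
  expect_equal(residue_pair_distance(A, B, fit0, 1, 1), 5)
  expect_error(residue_pair_distance(A, B, fit0, 99, 1), "99")

  # invariance under a shared extra rigid motion
  set.seed(48)
  P <- matrix(rnorm(15), 5); Q <- matrix(rnorm(15), 5)
  cp <- coordinate_set("p", P); cq <- coordinate_set("q", Q)
  fit <- kabsch_superpose(cp, cq)
  d0 <- residue_pair_distance(cp, cq, fit, 2, 4)
  R <- euler_rot(0.3, 1.1, 2.0); tr <- c(1, -2, 3)
  P2 <- P %*% t(R) + rep(tr, each = 5); Q2 <- Q %*% t(R) + rep(tr, each = 5)
  cp2 <- coordinate_set("p", P2); cq2 <- coordinate_set("q", Q2)
  fit2 <- kabsch_superpose(cp2, cq2)
  expect_equal(residue_pair_distance(cp2, cq2, fit2, 2, 4), d0,
               tolerance = 1e-9)
})

test_that("PDB CA reading round-trips written coordinate sets", {
  fx <- make_helix_bundle(n_clusters = 2, members_per_cluster = 1,
                          n_residues = 20, seed = 49)
  s <- fx$structures[[1]]
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ca_pdb(s, path)
  back <- read_ca_coordinates(path, id = s$id)
  expect_equal(back$ca_coordinates, s$ca_coordinates, tolerance = 1e-3)
  expect_equal(back$residue_numbers, s$residue_numbers)
})

test_that("RMSD matrices round-trip through TSV", {
  set.seed(50)
  rm <- random_dist_matrix(5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rmsd_tsv(rm, path)
  expect_equal(read_rmsd_tsv(path), rm, tolerance = 1e-9)
})
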