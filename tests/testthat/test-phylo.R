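test_that("correlation distance maps r = 1 to 0 and r = -1 to 200", {
  p <- mk_panel(c(A = 2, B = 2, C = 2))
  sc <- cbind(c(0L, 1L, 2L, 0L), c(0L, 1L, 2L, 0L), c(2L, 1L, 0L, 2L))
  m <- mk_mm(sc, p, snp = TRUE)
  dm <- correlation_distance(m)
  expect_equal(dm$d["A_s1", "B_s1"], 0)
  expect_equal(dm$r["A_s1", "C_s1"], -1)
  expect_equal(dm$d["A_s1", "C_s1"], 200)
  expect_equal(diag(dm$d), setNames(rep(0, 3), p$sample_id))
})

test_that("pairwise r matches the long-hand Pearson formula", {
  set.seed(55)
  p <- mk_panel(c(X = 2, Y = 2))
  sc <- matrix(sample(0:2, 200, replace = TRUE), 100, 2)
  sc[sample(100, 10), 1] <- NA
  sc[sample(100, 10), 2] <- NA
  m <- mk_mm(sc, p, snp = TRUE)
  dm <- correlation_distance(m)
  both <- !is.na(sc[, 1]) & !is.na(sc[, 2])
  x <- sc[both, 1]; y <- sc[both, 2]
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(dm$r["X_s1", "Y_s1"], r_hand)
  expect_equal(dm$d["X_s1", "Y_s1"], 100 * (1 - r_hand))
})

test_that("degenerate inputs are rejected with the offending pair named", {
  p <- mk_panel(c(A = 2, B = 2, C = 2))
  sc <- cbind(c(1L, 1L, 1L, 1L), c(0L, 1L, 2L, 0L), c(2L, 1L, 0L, 1L))
  m <- mk_mm(sc, p, snp = TRUE)
  expect_error(correlation_distance(m), "A_s1.*constant|constant.*A_s1")
  sc2 <- cbind(c(0L, 1L, NA, NA), c(2L, NA, 1L, 0L), c(2L, 1L, 0L, 1L))
  m2 <- mk_mm(sc2, p, snp = TRUE)
  expect_error(correlation_distance(m2), "share only")
  expect_error(correlation_distance(m, "A_s1"), "at least 2")
})

test_that("distances ignore marker order and permute with samples", {
  set.seed(77)
  p <- mk_panel(c(A = 2, B = 2, C = 2, D = 2))
  sc <- matrix(sample(0:2, 400, replace = TRUE), 100, 4)
  m <- mk_mm(sc, p, snp = TRUE)
  perm <- sample(100)
  m_perm <- mk_mm(sc[perm, ], p, snp = TRUE)
  d1 <- correlation_distance(m)$d
  d2 <- correlation_distance(m_perm)$d
  expect_equal(d1, d2)
  sub <- c("C_s1", "A_s1", "D_s1")
  d3 <- correlation_distance(m, sub)$d
  expect_equal(d3, d1[sub, sub])
})

test_that("UPGMA reproduces the hand-computed three-leaf tree", {
  m <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(m)
  expect_equal(tr$newick, "((A:1,B:1):3,C:4);")
  expect_equal(tr$heights, c(1, 4))
  expect_true(ape::is.ultrametric(tr$phylo))
  # equilateral matrix: tie broken lexicographically (A,B merge first)
  me <- matrix(5, 3, 3, dimnames = list(c("C", "A", "B"), c("C", "A", "B")))
  diag(me) <- 0
  tre <- upgma(me)
  expect_equal(tre$merges[[1]]$left, "A")
  expect_equal(tre$merges[[1]]$right, "B")
  expect_equal(tre$heights, c(2.5, 2.5))
})

test_that("UPGMA agrees with the average-linkage reference on random matrices", {
  set.seed(88)
  for (i in 1:10) {
    n <- 8
    pts <- matrix(rnorm(n * 3), n)
    m <- as.matrix(stats::dist(pts))
    dimnames(m) <- list(letters[1:n], letters[1:n])
    mine <- upgma(m)
    ref <- oracle_upgma(m)
    expect_true(same_topology(mine$phylo, ref$phylo))
    expect_equal(sort(mine$heights), ref$heights, tolerance = 1e-10)
    expect_equal(unname(tip_depths(mine$phylo)[letters[1:n]]),
                 rep(max(mine$heights), n), tolerance = 1e-10)
  }
})

test_that("UPGMA result is invariant to input label order", {
  set.seed(90)
  n <- 6
  m <- as.matrix(stats::dist(matrix(rnorm(n * 2), n)))
  dimnames(m) <- list(LETTERS[1:n], LETTERS[1:n])
  perm <- c(4, 1, 6, 2, 5, 3)
  t1 <- upgma(m)
  t2 <- upgma(m[perm, perm])
  expect_equal(t1$newick, t2$newick)
})

test_that("Newick output round-trips through a parser with identical heights", {
  m <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(m)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  expect_equal(readLines(f), "((A:1,B:1):3,C:4);")
  back <- ape::read.tree(f)
  expect_equal(sort(unname(tip_depths(back))), c(4, 4, 4))
  # single leaf
  t1 <- upgma(matrix(0, 1, 1, dimnames = list("A", "A")))
  write_newick(t1, f)
  expect_equal(readLines(f), "A:0;")
  # reserved characters in labels are single-quoted per Newick convention
  mq <- matrix(c(0, 3, 3, 0), 2,
               dimnames = list(c("Ae. tauschii", "x(1)"),
                               c("Ae. tauschii", "x(1)")))
  tq <- upgma(mq)
  write_newick(tq, f)
  expect_equal(readLines(f), "('Ae. tauschii':1.5,'x(1)':1.5);")
})

test_that("UPGMA on simulated diploid panels recovers the generating topology", {
  hits <- vapply(1:15, function(s) {
    res <- sim_matrices(simulate_diploids(triticeae_preset(seed = 3000 + s)))
    sm <- filter_call_rate(res$snp, 0.9)
    tr <- upgma(correlation_distance(sm))
    est <- tr$phylo
    est$tip.label <- sub("_1$", "", est$tip.label)
    true <- ape::read.tree(text = res$truth$extant_tree)
    same_topology(est, true)
  }, logical(1))
  expect_gte(sum(hits), 14)
})
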