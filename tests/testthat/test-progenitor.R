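test_that("retention is the retained fraction, undefined for empty analyzer sets", {
  expect_equal(retention(c("m1", "m2", "m3", "m4"), c("m1", "m2")), 0.5)
  expect_error(retention(character(0), "m1"), "empty analyzer")
  # superset target -> 1; disjoint target -> 0
  set.seed(1)
  for (i in 1:10) {
    a <- paste0("m", sample(1000, 50))
    expect_equal(retention(a, c(a, "extra")), 1)
    expect_equal(retention(a, paste0("x", 1:20)), 0)
  }
})

test_that("a noiseless union target retains each parent's specific set completely", {
  cfg <- small_config(seed = 5)
  sim <- simulate_diploids(cfg)
  sim <- simulate_polyploid(sim, "poly", c("P1", "P3"), loss = 0)
  res <- sim_matrices(sim)
  rt <- retention_table(res$markers, paste0("P", 1:4), "poly")
  expect_equal(unname(rt[c("P1", "P3"), "poly"]), c(1, 1))
})

test_that("retention table flags empty analyzer sets instead of dividing by zero", {
  p <- mk_panel(c(A = 2, B = 2, T = 4))
  # A and B identical -> neither has specific markers vs the other
  m <- mk_mm(rbind(c(1L, 1L, 1L), c(0L, 0L, 1L)), p)
  w <- capture_warnings(rt <- retention_table(m, c("A", "B"), "T"))
  expect_match(w, "empty marker set", all = TRUE)
  expect_length(w, 2L)
  expect_true(all(is.na(rt)))
  expect_true(all(attr(rt, "undefined")))
})

test_that("homoeology table splits shared/specific against reference subgenome totals", {
  p <- mk_panel(c(ref = 6, d1 = 2, d2 = 2), role = c("reference", "analyzer",
                                                     "analyzer"))
  chrom <- c("1A", "2A", "1B", "5B", "3D", "7D", "4A", "unassigned")
  sc <- rbind(
    c(1L, 1L, 1L),  # 1A: ref + both diploids
    c(1L, 1L, 0L),  # 2A: ref + d1
    c(1L, 0L, 0L),  # 1B: ref only
    c(1L, 0L, 1L),  # 5B: ref + d2
    c(1L, 1L, 1L),  # 3D
    c(1L, 0L, 0L),  # 7D
    c(0L, 1L, 0L),  # 4A: d1 only (not in reference)
    c(1L, 1L, 1L))  # unassigned: excluded from homoeology
  m <- mk_mm(sc, p, chromosome = chrom)
  ht <- homoeology_table(m, c("d1", "d2"), "ref")
  ref_tot <- attr(ht, "reference_totals")
  expect_equal(unname(ref_tot[c("A", "B", "D")]), c(2, 2, 2))
  d1 <- ht[ht$species == "d1", ]
  expect_equal(d1$total[d1$subgenome == "A"], 3L)   # 1A, 2A, 4A
  expect_equal(d1$shared[d1$subgenome == "A"], 1L)  # only 1A also in d2
  expect_equal(d1$pct[d1$subgenome == "A"], 150)    # 3 / ref total 2
  expect_equal(d1$total[d1$subgenome == "B"], 0L)
  expect_equal(d1$pct[d1$subgenome == "B"], 0)
  expect_true(all(ht$shared + ht$specific == ht$total))
  # zero reference markers on a subgenome is an error
  m2 <- mk_mm(sc[1:2, ], p, chromosome = c("1A", "2A"))
  expect_error(homoeology_table(m2, c("d1", "d2"), "ref"), "zero")
})

test_that("reported homoeology counts reproduce printed percentages", {
  ht <- as_homoeology_table(reported_homoeology_counts(), "T. aestivum")
  cell <- function(sp, g) ht[ht$species == sp & ht$subgenome == g, ]
  expect_equal(cell("T. urartu", "A")$total, 9786L)
  expect_equal(cell("T. urartu", "A")$pct, 45.3)
  expect_equal(cell("Ae. tauschii", "D")$total, 16556L)
  expect_equal(cell("Ae. tauschii", "D")$pct, 46.8)
  expect_equal(unname(attr(ht, "reference_totals")[c("A", "B", "D")]),
               c(21589L, 20642L, 35354L))
})

test_that("analyzer selection applies an inclusive threshold per subgenome", {
  ht <- as_homoeology_table(reported_homoeology_counts(), "T. aestivum")
  sel <- select_analyzers(ht, 10)
  expect_length(sel$union, 13)
  expect_false("T. aestivum" %in% sel$union)
  expect_true("Ae. speltoides" %in% sel$per_subgenome$B)
  expect_false("Ae. searsii" %in% sel$per_subgenome$A)  # 9.6 < 10
  expect_true("Ae. searsii" %in% sel$union)             # via B and D
  # raising the threshold never adds a species (monotone)
  for (thr in c(12, 15, 20, 50, 100)) {
    expect_true(all(select_analyzers(ht, thr)$union %in% sel$union))
  }
  expect_equal(select_analyzers(ht, 100)$union, character(0))
  expect_error(select_analyzers(ht, 0), "> 0")
})

test_that("analyzer selection equals a brute-force threshold scan on random tables", {
  set.seed(3)
  for (i in 1:5) {
    sp <- paste0("sp", 1:8)
    df <- expand.grid(species = c("ref", sp), subgenome = c("A", "B", "D"),
                      stringsAsFactors = FALSE)
    df$shared <- sample(0:5000, nrow(df))
    df$specific <- sample(0:5000, nrow(df))
    ht <- as_homoeology_table(df, "ref")
    thr <- runif(1, 5, 40)
    got <- select_analyzers(ht, thr)$union
    want <- unique(ht$species[ht$species != "ref" & ht$pct >= thr])
    expect_setequal(got, want)
  }
})

test_that("polyploid-specific screening recovers planted counts and degenerate cases", {
  cfg <- small_config(seed = 11)
  sim <- simulate_diploids(cfg)
  sim <- simulate_polyploid(sim, "T1", c("P1", "P3"), loss = 0.3)
  sim <- simulate_polyploid(sim, "T2", c("P2", "P4"), loss = 0.3)
  res <- sim_matrices(sim)
  rep <- polyploid_specific_markers(res$markers, c("T1", "T2"))
  # bookkeeping oracle: private = in one polyploid's set, not the other's
  ids <- res$truth$species_markers
  expect_equal(rep$specific[rep$species == "T1"],
               length(setdiff(ids$T1, ids$T2)))
  expect_equal(rep$specific[rep$species == "T2"],
               length(setdiff(ids$T2, ids$T1)))
  # identical marker sets -> zero specific markers each
  p <- mk_panel(c(X = 4, Y = 4))
  m <- mk_mm(rbind(c(1L, 1L), c(0L, 0L), c(1L, 1L)), p)
  rep2 <- polyploid_specific_markers(m, c("X", "Y"))
  expect_equal(rep2$specific, c(0L, 0L))
})

test_that("chromosome profiles expose planted segmental replacement", {
  cfg <- small_config(seed = 21, unassigned_rate = 0)
  sim <- simulate_diploids(cfg)
  sim <- simulate_polyploid(sim, "poly", c("P1", "P3"), loss = 0.1,
                            chrom_loss = c("3B" = 0.85))
  res <- sim_matrices(sim)
  spec <- select_species_specific(res$markers, "P1", c("P2", "P3", "P4"))
  prof <- chromosome_profile(res$markers, spec, "poly", "B", n_min = 20)
  expect_equal(prof$chromosome, 1:7)
  expect_true(all(prof$retention >= 0 & prof$retention <= 1))
  # chromosome 3 depressed well below the others
  expect_lt(prof$retention[3], min(prof$retention[-3]) - 0.3)
  # uniform loss: profile cells agree within binomial noise
  sim2 <- simulate_polyploid(simulate_diploids(small_config(seed = 22,
                                                            unassigned_rate = 0)),
                             "poly", c("P1", "P3"), loss = 0.2)
  res2 <- sim_matrices(sim2)
  spec2 <- select_species_specific(res2$markers, "P1", c("P2", "P3", "P4"))
  prof2 <- chromosome_profile(res2$markers, spec2, "poly", "B")
  p_hat <- sum(prof2$n_retained) / sum(prof2$n_markers)
  se <- sqrt(p_hat * (1 - p_hat) / prof2$n_markers)
  expect_true(all(abs(prof2$retention - p_hat) < 4 * se + 1e-9))
  # markers never assigned to the requested subgenome -> error
  m_un <- mk_mm(matrix(1L, 3, 2), mk_panel(c(A = 2, B = 4)),
                chromosome = rep("unassigned", 3))
  expect_error(chromosome_profile(m_un, paste0("m", 1:3), "B", "B"),
               "no analyzer markers")
  # low-support flag below n_min
  expect_true(any(chromosome_profile(res2$markers, spec2, "poly", "B",
                                     n_min = 10^6)$low_support))
})

test_that("progenitor calls resolve clear slots and report margin ties as unresolved", {
  p <- mk_panel(c(a1 = 2, a2 = 2, a3 = 2, a4 = 2, a5 = 2, tgt = 4))
  rt <- matrix(c(0.9, 0.85, 0.85, 0.2, 0.15), 5, 1,
               dimnames = list(paste0("a", 1:5), "tgt"))
  cl <- call_progenitors(rt, p, "tgt", margin = 0.1)
  expect_length(cl$slots, 2)
  expect_equal(cl$slots[[1]]$status, "resolved")
  expect_equal(cl$slots[[1]]$analyzers, "a1")
  expect_equal(cl$slots[[2]]$status, "unresolved")
  expect_setequal(cl$slots[[2]]$analyzers, c("a2", "a3"))
  # margin 0 degenerates to pure argmax fill, matching a sort oracle
  set.seed(13)
  for (i in 1:10) {
    r <- matrix(runif(5), 5, 1, dimnames = list(paste0("a", 1:5), "tgt"))
    cl0 <- call_progenitors(r, p, "tgt", margin = 0)
    top <- names(sort(r[, 1], decreasing = TRUE))[1:2]
    expect_equal(vapply(cl0$slots, `[[`, "", "analyzers"), top)
    expect_true(all(vapply(cl0$slots, `[[`, "", "status") == "resolved"))
  }
  expect_error(call_progenitors(rt[1, , drop = FALSE], p, "tgt"),
               "1 analyzer")
  expect_error(call_progenitors(rt, p, "a1"), "not polyploid")
})

test_that("margin-0 calls on noiseless unions recover the generating parents exactly", {
  for (s in 1:10) {
    cfg <- small_config(seed = 100 + s)
    sim <- simulate_diploids(cfg)
    sim <- simulate_polyploid(sim, "poly", c("P2", "P3"), loss = 0)
    res <- sim_matrices(sim)
    rt <- retention_table(res$markers, paste0("P", 1:4), "poly")
    cl <- call_progenitors(rt, res$panel, "poly", margin = 0)
    expect_setequal(unlist(lapply(cl$slots, `[[`, "analyzers")),
                    c("P2", "P3"))
  }
})

test_that("synthetic allotetraploids are recovered under loss and missing noise", {
  ok <- vapply(1:12, function(s) preset_recovery_ok(1200 + s), logical(1))
  expect_gte(sum(ok), 11)
})

test_that("cross-genome monomorphism counts identical complete score vectors", {
  p <- mk_panel(c(A = 4, B = 4, C = 4))
  sc <- rbind(c(0L, 0L, 0L), c(1L, 1L, 1L), c(2L, 2L, 2L), c(0L, 1L, 0L),
              c(0L, NA, 0L), c(1L, 2L, 1L))
  m <- mk_mm(sc, p, chromosome = c("1A", "2A", "3A", "4A", "5A", "6A"),
             snp = TRUE)
  grp <- list(all3 = p$sample_id, pair = p$sample_id[c(1, 2)])
  out <- cross_genome_monomorphism(m, grp)
  a3 <- out[out$group == "all3", ]
  expect_equal(a3$n_markers, 5L)        # the NA row is incomplete
  expect_equal(a3$pct, 100 * 3 / 5)
  pair <- out[out$group == "pair", ]
  expect_equal(pair$n_markers, 5L)
  expect_equal(pair$pct, 100 * 3 / 5)   # rows 4 and 6 differ between A and B
  # identical samples -> 100%
  m2 <- mk_mm(cbind(sc[, 1], sc[, 1], sc[, 1]), p,
              chromosome = rep("1B", 6), snp = TRUE)
  expect_equal(cross_genome_monomorphism(m2, list(g = p$sample_id))$pct, 100)
  # collapsing heterozygotes with presence merges 1 and 2
  out_h <- cross_genome_monomorphism(m, grp, collapse_het = TRUE)
  expect_equal(out_h[out_h$group == "all3", ]$pct, 100 * 4 / 5)
  expect_error(cross_genome_monomorphism(m, grp, partition = list()),
               "empty")
})

test_that("shared polyploid ancestry raises monomorphism above independent origins", {
  cfg <- small_config(seed = 31)
  sim <- simulate_diploids(cfg)
  # hexaploids sharing one tetraploid ancestor, diverging little since,
  # versus tetraploids formed independently from different accessions of
  # the same parents (higher planted divergence)
  sim <- simulate_polyploid(sim, "tet", c("P1", "P3"), loss = 0.1)
  sim <- simulate_polyploid(sim, "hexA", c("tet", "P2"), loss = 0.1,
                            snp_divergence = 0.01)
  sim <- simulate_polyploid(sim, "hexB", c("tet", "P2"), loss = 0.1,
                            snp_divergence = 0.01)
  sim <- simulate_polyploid(sim, "tetA", c("P1", "P3"), loss = 0.1,
                            snp_divergence = 0.06)
  sim <- simulate_polyploid(sim, "tetB", c("P1", "P3"), loss = 0.1,
                            snp_divergence = 0.06)
  res <- sim_matrices(sim)
  pan <- res$panel
  out <- cross_genome_monomorphism(
    res$snp,
    list(shared = pan$sample_id[pan$species %in% c("hexA", "hexB")],
         indep = pan$sample_id[pan$species %in% c("tetA", "tetB")]),
    partition = list(all = res$snp$markers$marker_id))
  expect_gt(out$pct[out$group == "shared"], out$pct[out$group == "indep"])
})
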