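# Fixtures are built in code: tiny panels/matrices with known structure,
# plus brute-force oracles kept deliberately independent of the package's
# vectorized implementations.

# panel with one sample per species: mk_panel(c(A = 2, B = 2, C = 4))
mk_panel <- function(ploidies, role = NULL) {
  sample_panel(paste0(names(ploidies), "_s1"), names(ploidies),
               unname(ploidies),
               role = role %||% ifelse(ploidies == 2, "analyzer", "target"))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# marker matrix from a plain matrix (rows markers, cols species of `panel`)
mk_mm <- function(scores, panel, chromosome = NULL, snp = FALSE) {
  if (is.null(rownames(scores)))
    rownames(scores) <- paste0("m", seq_len(nrow(scores)))
  colnames(scores) <- panel$sample_id
  if (snp) snp_matrix(scores, panel, chromosome)
  else marker_matrix(scores, panel, chromosome)
}

# random presence/absence matrix with missing calls
rand_mm <- function(n_markers, panel, p_present = 0.5, p_missing = 0.1,
                    chromosome = NULL) {
  sc <- matrix(rbinom(n_markers * nrow(panel), 1, p_present),
               n_markers, nrow(panel))
  sc[matrix(runif(length(sc)) < p_missing, nrow(sc))] <- NA_integer_
  mk_mm(sc, panel, chromosome)
}

# brute-force per-marker presence/absence/specificity, written as explicit
# loops over the truth table (oracle for marker_filters)
bf_species_state <- function(x, species, policy) {
  cols <- which(x$panel$species == species)
  t(apply(x$scores, 1, function(row) {
    v <- row[cols]
    present <- any(!is.na(v) & v == 1)
    absent <- if (policy == "strict") !any(is.na(v)) && all(v == 0)
              else !present
    c(present = present, absent = absent)
  }))
}

bf_specific <- function(x, focal, background, policy) {
  keep <- logical(nrow(x$scores))
  for (i in seq_len(nrow(x$scores))) {
    st_f <- bf_species_state(x, focal, policy)[i, ]
    ok <- st_f["present"]
    for (b in background) {
      st_b <- bf_species_state(x, b, policy)[i, ]
      ok <- ok && st_b["absent"]
    }
    keep[i] <- ok
  }
  x$markers$marker_id[keep]
}

# independent UPGMA reference: stats::hclust average linkage
oracle_upgma <- function(m) {
  hc <- stats::hclust(stats::as.dist(m), method = "average")
  list(phylo = ape::as.phylo(hc), heights = sort(hc$height) / 2)
}

# leaf-to-root depth per tip of an ultrametric phylo
tip_depths <- function(phy) {
  d <- ape::node.depth.edgelength(phy)
  stats::setNames(d[seq_along(phy$tip.label)], phy$tip.label)
}

# topology equality of two trees on the same label set (unrooted RF = 0)
same_topology <- function(a, b) {
  phangorn::RF.dist(ape::unroot(a), ape::unroot(b)) == 0
}

# a small config: 4 diploids on a balanced tree, fast to simulate
small_config <- function(seed = NULL, missing_rate = 0, ...) {
  sim_config(seed = seed,
             tree = "((P1:0.5,P2:0.5):0.5,(P3:0.5,P4:0.5):0.5);",
             pool_size = 2000, gain_rate = 600, n_snp = 800,
             missing_rate = missing_rate, ...)
}

# did every polyploid's extant true parents land in the top ploidy/2
# retention ranks of one simulated preset replicate?
preset_recovery_ok <- function(seed, lambda = 0.2, missing_rate = 0.03) {
  res <- simulate_panel(triticeae_preset(seed = seed, lambda = lambda,
                                         missing_rate = missing_rate))
  mm <- filter_call_rate(res$markers, 0.7)
  dip <- unique(res$panel$species[res$panel$ploidy == 2])
  tgt <- unique(res$panel$species[res$panel$ploidy > 2])
  rt <- retention_table(mm, dip, tgt)
  all(vapply(tgt, function(t) {
    truep <- setdiff(res$truth$polyploid_parents[[t]],
                     res$truth$hidden_species)
    slots <- res$panel$ploidy[match(t, res$panel$species)] / 2
    top <- names(sort(rt[, t], decreasing = TRUE))[seq_len(slots)]
    all(truep %in% top)
  }, logical(1)))
}
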