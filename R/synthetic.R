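# Synthetic DArT-style panels with known ancestry.
#
# Presence/absence markers evolve down a species tree by per-branch
# Bernoulli loss and private-marker gain; SNP scores evolve by per-branch
# 0<->1 flips. Allopolyploids are unions of their parents' marker sets
# with independent post-polyploidization loss, and heterozygous SNP calls
# where the parents disagree. The generator keeps full bookkeeping
# (SimTruth) so every downstream inference can be checked against ground
# truth.

#' Simulation configuration
#'
#' @param seed RNG seed; with a fixed seed the emitted matrices are
#'   bit-identical across runs.
#' @param tree Newick string (with branch lengths) for the diploid species
#'   tree; branch lengths are in arbitrary time units.
#' @param hidden_species diploid leaves simulated and usable as polyploid
#'   parents but pruned from the emitted panel (extinct donors).
#' @param pool_size ancestral presence/absence marker pool size at the root.
#' @param loss_rate marker loss rate per unit branch length; the per-branch
#'   loss probability is `1 - exp(-loss_rate * length)`.
#' @param gain_rate expected private-marker gains per unit branch length;
#'   the per-branch gain count is `round(gain_rate * length)`.
#' @param n_snp number of codominant SNP markers.
#' @param snp_sub_rate SNP substitution rate per unit branch length
#'   (0 <-> 1 flip probability `1 - exp(-rate * length)`).
#' @param snp_het_rate probability a diploid SNP call is rendered
#'   heterozygous (residual heterozygosity / scoring noise).
#' @param missing_rate per-cell missing-call probability at output.
#' @param chromosomes chromosome label set markers are assigned to.
#' @param chrom_weights optional assignment weights over `chromosomes`.
#' @param unassigned_rate fraction of markers left without a chromosome
#'   assignment (label `"unassigned"`).
#' @param polyploids list of [polyploid_event()] records.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = NULL, tree, hidden_species = character(),
                       pool_size = 12000, loss_rate = 0.25, gain_rate = 3000,
                       n_snp = 6000, snp_sub_rate = 0.3, snp_het_rate = 0.01,
                       missing_rate = 0.03, chromosomes = wheat_chromosomes(),
                       chrom_weights = NULL, unassigned_rate = 0.05,
                       polyploids = list()) {
  rates <- c(loss = 1 - exp(-loss_rate), missing = missing_rate,
             het = snp_het_rate, unassigned = unassigned_rate)
  if (any(rates < 0 | rates > 1)) stop_ctx("rates must lie in [0, 1]")
  cfg <- list(seed = seed, tree = tree, hidden_species = hidden_species,
              pool_size = as.integer(pool_size), loss_rate = loss_rate,
              gain_rate = gain_rate, n_snp = as.integer(n_snp),
              snp_sub_rate = snp_sub_rate, snp_het_rate = snp_het_rate,
              missing_rate = missing_rate, chromosomes = chromosomes,
              chrom_weights = chrom_weights, unassigned_rate = unassigned_rate,
              polyploids = polyploids)
  class(cfg) <- "sim_config"
  cfg
}

#' Declare a polyploidization event
#'
#' @param species name of the new allopolyploid.
#' @param parents distinct parental species, one per subgenome
#'   (`length(parents) == ploidy/2`).
#' @param loss post-polyploidization per-marker loss probability (lambda).
#' @param ploidy optional declared ploidy; must equal `2 * length(parents)`
#'   for diploid parents.
#' @param chrom_loss optional named vector of additional loss probability
#'   per chromosome label (models segmental replacement of a parental
#'   chromosome).
#' @param snp_divergence per-SNP probability of post-polyploidization
#'   divergence from the parental combination (genomic adjustment /
#'   different progenitor accessions).
#' @return a `polyploid_event` list.
#' @export
polyploid_event <- function(species, parents, loss = 0.2, ploidy = NULL,
                            chrom_loss = NULL, snp_divergence = 0.02) {
  parents <- as.character(parents)
  if (anyDuplicated(parents))
    stop_ctx("polyploid \"%s\": duplicated parent (%s); parents must be distinct species",
             species, parents[duplicated(parents)][1])
  if (!is.null(ploidy) && as.integer(ploidy) != 2L * length(parents))
    stop_ctx("polyploid \"%s\": %d parent(s) inconsistent with declared ploidy %d",
             species, length(parents), as.integer(ploidy))
  if (loss < 0 || loss > 1) stop_ctx("loss must lie in [0, 1]")
  if (snp_divergence < 0 || snp_divergence > 1)
    stop_ctx("snp_divergence must lie in [0, 1]")
  structure(list(species = species, parents = parents, loss = loss,
                 chrom_loss = chrom_loss, snp_divergence = snp_divergence),
            class = "polyploid_event")
}

draw_chromosomes <- function(n, cfg) {
  w <- cfg$chrom_weights %||% rep(1, length(cfg$chromosomes))
  w <- w / sum(w) * (1 - cfg$unassigned_rate)
  sample(c(cfg$chromosomes, "unassigned"), n, replace = TRUE,
         prob = c(w, cfg$unassigned_rate))
}

#' Simulate the diploid panel
#'
#' Evolves the ancestral marker pool and SNP genotypes down the configured
#' species tree and records each leaf's state. Polyploids are added with
#' [simulate_polyploid()]; matrices are materialized by [sim_matrices()].
#'
#' @param config a [sim_config()].
#' @return a `dart_sim` state object (leaf presence sets, genotypes,
#'   marker registry, bookkeeping).
#' @export
simulate_diploids <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  tr <- ape::read.tree(text = config$tree)
  if (is.null(tr) || ape::Ntip(tr) < 2L) {
    if (length(config$polyploids))
      stop_ctx("degenerate species tree (< 2 leaves) cannot host polyploid events")
    stop_ctx("species tree must have at least 2 leaves")
  }
  if (is.null(tr$edge.length)) stop_ctx("species tree needs branch lengths")
  tr <- ape::reorder.phylo(tr, "cladewise")  # parents precede children
  ntip <- ape::Ntip(tr)
  nnode <- ntip + tr$Nnode
  # marker registry grows as gains occur
  chrom <- draw_chromosomes(config$pool_size, config)
  origin <- rep("root", config$pool_size)
  sets <- vector("list", nnode)
  geno <- vector("list", nnode)
  root <- ntip + 1L
  sets[[root]] <- seq_len(config$pool_size)
  geno[[root]] <- integer(config$n_snp)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]; len <- tr$edge.length[e]
    p_loss <- 1 - exp(-config$loss_rate * len)
    keep <- sets[[p]][runif(length(sets[[p]])) >= p_loss]
    n_gain <- round(config$gain_rate * len)
    if (n_gain > 0) {
      idx <- length(chrom) + seq_len(n_gain)
      chrom <- c(chrom, draw_chromosomes(n_gain, config))
      branch <- if (ch <= ntip) tr$tip.label[ch] else paste0("node", ch)
      origin <- c(origin, rep(branch, n_gain))
      keep <- c(keep, idx)
    }
    sets[[ch]] <- keep
    g <- geno[[p]]
    p_sub <- 1 - exp(-config$snp_sub_rate * len)
    flip <- runif(config$n_snp) < p_sub
    g[flip] <- 1L - g[flip]
    geno[[ch]] <- g
  }
  leaf_sets <- setNames(sets[seq_len(ntip)], tr$tip.label)
  leaf_geno <- setNames(geno[seq_len(ntip)], tr$tip.label)
  structure(list(config = config, tree = tr,
                 marker_chrom = chrom, marker_origin = origin,
                 species_sets = leaf_sets, species_geno = leaf_geno,
                 species_ploidy = setNames(rep(2L, ntip), tr$tip.label),
                 species_parents = setNames(vector("list", ntip), tr$tip.label),
                 lost_after_merge = list()),
            class = "dart_sim")
}

#' Add an allopolyploid to a simulation
#'
#' The polyploid's presence set is the union of its parents' sets with
#' each marker independently dropped with probability `loss`; its SNP
#' score is the shared parental score where the parents agree and the
#' heterozygous code 2 where they differ.
#'
#' @param sim a `dart_sim` from [simulate_diploids()].
#' @param species,parents,loss,ploidy,chrom_loss see [polyploid_event()];
#'   alternatively pass an event via `event`.
#' @param event a [polyploid_event()] (overrides the individual arguments).
#' @return the updated `dart_sim`.
#' @export
simulate_polyploid <- function(sim, species, parents, loss = 0.2,
                               ploidy = NULL, chrom_loss = NULL,
                               snp_divergence = 0.02, event = NULL) {
  stopifnot(inherits(sim, "dart_sim"))
  ev <- event %||% polyploid_event(species, parents, loss, ploidy, chrom_loss,
                                   snp_divergence)
  unknown <- setdiff(ev$parents, names(sim$species_sets))
  if (length(unknown))
    stop_ctx("polyploid \"%s\": unknown parent species %s", ev$species,
             paste(unknown, collapse = ", "))
  if (ev$species %in% names(sim$species_sets))
    stop_ctx("species \"%s\" already exists in the simulation", ev$species)
  u <- sort(unique(unlist(sim$species_sets[ev$parents], use.names = FALSE)))
  p_drop <- rep(ev$loss, length(u))
  if (!is.null(ev$chrom_loss)) {
    hit <- match(sim$marker_chrom[u], names(ev$chrom_loss))
    extra <- ifelse(is.na(hit), 0, ev$chrom_loss[hit])
    p_drop <- 1 - (1 - p_drop) * (1 - extra)
  }
  kept <- u[runif(length(u)) >= p_drop]
  gmat <- do.call(cbind, sim$species_geno[ev$parents])
  agree <- rowSums(gmat == gmat[, 1L]) == ncol(gmat)
  g <- ifelse(agree, gmat[, 1L], 2L)
  if (ev$snp_divergence > 0) {  # post-merger adjustment / accession effects
    div <- runif(length(g)) < ev$snp_divergence
    g[div] <- ifelse(g[div] == 0L, 1L,
                     ifelse(g[div] == 1L, 0L, sample(0:1, sum(div),
                                                     replace = TRUE)))
  }
  sim$species_sets[[ev$species]] <- kept
  sim$species_geno[[ev$species]] <- as.integer(g)
  sim$species_ploidy[ev$species] <- sum(sim$species_ploidy[ev$parents])
  sim$species_parents[[ev$species]] <- ev$parents
  sim$lost_after_merge[[ev$species]] <- setdiff(u, kept)
  sim
}

#' Materialize simulated matrices, panel and truth
#'
#' Builds the emitted `marker_matrix`, `snp_matrix` and [sample_panel()]
#' (one sample per non-hidden species; diploids get role `"analyzer"`,
#' polyploids `"target"`), injects missing calls at the configured rate,
#' and returns the generator's bookkeeping as `truth`. Markers present in
#' no emitted sample are dropped, as they would never be discovered.
#'
#' @param sim a `dart_sim`.
#' @return list with `markers`, `snp`, `panel`, `truth`, `config`.
#' @export
sim_matrices <- function(sim) {
  stopifnot(inherits(sim, "dart_sim"))
  cfg <- sim$config
  extant <- setdiff(names(sim$species_sets), cfg$hidden_species)
  n_univ <- length(sim$marker_chrom)
  width <- max(6L, nchar(n_univ))
  ids <- sprintf("M%0*d", width, seq_len(n_univ))
  pav <- vapply(extant, function(sp) {
    v <- integer(n_univ); v[sim$species_sets[[sp]]] <- 1L; v
  }, integer(n_univ))
  seen <- rowSums(pav) > 0L
  pav <- pav[seen, , drop = FALSE]
  rownames(pav) <- ids[seen]
  if (cfg$missing_rate > 0)
    pav[runif(length(pav)) < cfg$missing_rate] <- NA_integer_
  snp <- vapply(extant, function(sp) sim$species_geno[[sp]], integer(cfg$n_snp))
  dip <- extant[sim$species_ploidy[extant] == 2L]
  het <- matrix(runif(length(snp)) < cfg$snp_het_rate, nrow(snp))
  het[, !extant %in% dip] <- FALSE
  snp[het] <- 2L
  rownames(snp) <- sprintf("S%0*d", width, seq_len(cfg$n_snp))
  if (cfg$missing_rate > 0)
    snp[runif(length(snp)) < cfg$missing_rate] <- NA_integer_
  sample_ids <- paste0(gsub("[^A-Za-z0-9_.-]+", "_", extant), "_1")
  colnames(pav) <- colnames(snp) <- sample_ids
  panel <- sample_panel(sample_ids, extant, sim$species_ploidy[extant],
                        genome_formula = vapply(extant, function(sp) {
                          pp <- sim$species_parents[[sp]]
                          if (is.null(pp)) sp else paste(pp, collapse = "+")
                        }, character(1)),
                        role = ifelse(sim$species_ploidy[extant] == 2L,
                                      "analyzer", "target"))
  species_ids <- lapply(sim$species_sets, function(s) ids[s])
  dip_extant <- dip
  counts <- vapply(dip_extant, function(sp) {
    v <- integer(n_univ); v[sim$species_sets[[sp]]] <- 1L; v
  }, integer(n_univ))
  in_one <- rowSums(counts) == 1L
  private <- lapply(dip_extant, function(sp) {
    ids[in_one & counts[, sp] == 1L]
  })
  names(private) <- dip_extant
  truth <- list(
    tree = ape::write.tree(sim$tree),
    extant_tree = if (length(cfg$hidden_species) &&
                      any(cfg$hidden_species %in% sim$tree$tip.label))
      ape::write.tree(ape::drop.tip(sim$tree,
                                    intersect(cfg$hidden_species,
                                              sim$tree$tip.label)))
      else ape::write.tree(sim$tree),
    hidden_species = cfg$hidden_species,
    species_markers = species_ids[extant],
    diploid_private = private,
    polyploid_parents = sim$species_parents[
      extant[sim$species_ploidy[extant] > 2L]],
    lost_after_merge = lapply(sim$lost_after_merge, function(s) ids[s]))
  list(markers = marker_matrix(pav, panel,
                               chromosome = sim$marker_chrom[seen]),
       snp = snp_matrix(snp, panel,
                        chromosome = draw_chromosomes(cfg$n_snp, cfg)),
       panel = panel, truth = truth, config = cfg)
}

#' Simulate a full diploid + polyploid panel
#'
#' Runs [simulate_diploids()], applies every configured
#' [polyploid_event()], and materializes matrices, panel and truth.
#'
#' @param config a [sim_config()].
#' @return as [sim_matrices()].
#' @export
simulate_panel <- function(config) {
  sim <- simulate_diploids(config)
  for (ev in config$polyploids) sim <- simulate_polyploid(sim, event = ev)
  sim_matrices(sim)
}

#' Triticeae-like preset configuration
#'
#' Eleven diploids in five section-like clades on an ultrametric tree of
#' depth 1, plus a hidden diploid (`anc_X`, a close relative of
#' `speltoides` and `mutica`) that donates subgenomes to five polyploids
#' and is pruned before output -- the extinct-donor scenario. Twelve
#' polyploids in total: seven with two extant parents (including one pair
#' with identical parent sets) and five carrying the hidden donor.
#' Defaults put species marker totals around 10^4 with species-specific
#' fractions of a few to a few tens of percent, the magnitudes typical of
#' genotyping-by-sequencing surveys of this group.
#'
#' @param seed RNG seed.
#' @param lambda post-polyploidization per-marker loss probability shared
#'   by all events.
#' @param missing_rate per-cell missing-call probability.
#' @param ... further overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
triticeae_preset <- function(seed = NULL, lambda = 0.2, missing_rate = 0.03,
                             ...) {
  tree <- paste0(
    "((mutica:0.5,(speltoides:0.45,anc_X:0.45):0.05):0.5,",
    "((((longissima:0.15,sharonensis:0.15):0.1,bicornis:0.25):0.1,",
    "searsii:0.35):0.45,((tauschii:0.55,caudata:0.55):0.15,",
    "((comosa:0.3,uniaristata:0.3):0.25,umbellulata:0.55):0.15):0.1):0.2);")
  ev <- function(sp, parents) polyploid_event(sp, parents, loss = lambda)
  sim_config(seed = seed, tree = tree, hidden_species = "anc_X",
             missing_rate = missing_rate,
             polyploids = list(
               ev("ventricosa",  c("tauschii", "uniaristata")),
               ev("cylindrica",  c("caudata", "tauschii")),
               ev("kotschyi",    c("longissima", "umbellulata")),
               ev("variabilis",  c("sharonensis", "umbellulata")),
               ev("biuncialis",  c("umbellulata", "comosa")),
               ev("ovata",       c("umbellulata", "comosa")),
               ev("triuncialis", c("umbellulata", "caudata")),
               ev("crassa",      c("tauschii", "comosa", "anc_X")),
               ev("vavilovii",   c("tauschii", "searsii", "anc_X")),
               ev("juvenalis",   c("tauschii", "umbellulata", "anc_X")),
               ev("triaristata", c("umbellulata", "uniaristata", "anc_X")),
               ev("columnaris",  c("umbellulata", "anc_X"))),
             ...)
}

#' Write a simulated panel to disk
#'
#' Emits the CSV dialects [read_silicodart()] / [read_snp()] /
#' [read_panel()] read, plus the generator truth as JSON.
#'
#' @param res result of [simulate_panel()] / [sim_matrices()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dart(res$markers, file.path(dir, "silicodart.csv"))
  write_dart(res$snp, file.path(dir, "snp.csv"))
  write.csv(as.data.frame(res$panel), file.path(dir, "panel.csv"),
            row.names = FALSE)
  jsonlite::write_json(res$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
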