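# Diploid-to-polyploid marker retention, homoeology-based analyzer
# selection, per-chromosome retention profiles and progenitor calling.
#
# The guiding quantity is diploid-polyploid monomorphism: the proportion of
# a diploid analyzer's (typically species-specific) markers that are also
# present in a polyploid's marker set. A diploid whose retention is
# considerably higher than the competition is taken as the putative donor
# of one subgenome of the polyploid.

#' Retention of an analyzer's markers in a target
#'
#' `|analyzer set  intersect  target presence set| / |analyzer set|`.
#'
#' @param analyzer_set marker ids of the diploid analyzer (a character
#'   vector or a `species_marker_set`); must be non-empty.
#' @param target_presence_set marker ids present in the target (character
#'   vector or `species_marker_set`).
#' @return the retained proportion in \[0, 1\].
#' @export
retention <- function(analyzer_set, target_presence_set) {
  a <- if (inherits(analyzer_set, "species_marker_set"))
    analyzer_set$marker_ids else as.character(analyzer_set)
  t <- if (inherits(target_presence_set, "species_marker_set"))
    target_presence_set$marker_ids else as.character(target_presence_set)
  if (!length(a))
    stop_ctx("retention is undefined for an empty analyzer set")
  sum(a %in% t) / length(a)
}

#' Retention table over analyzers and targets
#'
#' Builds the analyzer x target matrix of retained proportions, using
#' either species-specific analyzer sets (the low-noise choice) or each
#' analyzer's full presence set.
#'
#' @param x a `marker_matrix`.
#' @param analyzers diploid analyzer species.
#' @param targets polyploid target species.
#' @param marker_sets `"specific"` (default) to probe with species-specific
#'   markers, `"all"` for full presence sets.
#' @param background species against which specificity is defined; default
#'   the other analyzers.
#' @inheritParams species_presence
#' @return a `retention_table`: numeric matrix (rows analyzers, columns
#'   targets) with attributes `analyzer_sizes`, `marker_sets` and
#'   `undefined` (logical matrix flagging cells whose analyzer set was
#'   empty; such cells are `NA`, never silently 0/0).
#' @export
retention_table <- function(x, analyzers, targets,
                            marker_sets = c("specific", "all"),
                            background = NULL, missing_policy = "lenient") {
  marker_sets <- match.arg(marker_sets)
  missing_policy <- check_policy(missing_policy)
  sets <- lapply(analyzers, function(sp) {
    if (marker_sets == "all") species_presence(x, sp, missing_policy)$marker_ids
    else select_species_specific(x, sp, background %||% setdiff(analyzers, sp),
                                 missing_policy)$marker_ids
  })
  names(sets) <- analyzers
  tgt <- lapply(targets, function(sp) species_presence(x, sp, missing_policy)$marker_ids)
  names(tgt) <- targets
  rt <- matrix(NA_real_, length(analyzers), length(targets),
               dimnames = list(analyzers, targets))
  undef <- matrix(FALSE, length(analyzers), length(targets),
                  dimnames = dimnames(rt))
  for (a in analyzers) {
    if (!length(sets[[a]])) {
      undef[a, ] <- TRUE
      warning(sprintf("analyzer \"%s\" has an empty marker set; its retention row is undefined", a),
              call. = FALSE)
      next
    }
    for (t in targets) rt[a, t] <- retention(sets[[a]], tgt[[t]])
  }
  structure(rt, analyzer_sizes = lengths(sets), marker_sets = marker_sets,
            undefined = undef, class = c("retention_table", "matrix", "array"))
}

#' @export
print.retention_table <- function(x, ...) {
  cat(sprintf("<retention_table> %d analyzer(s) x %d target(s), %s analyzer sets\n",
              nrow(x), ncol(x), attr(x, "marker_sets")))
  print(round(unclass(x), 3))
  invisible(x)
}

# ---- homoeology ------------------------------------------------------------

build_homoeology <- function(df, reference_species, digits = 1) {
  stopifnot(all(c("species", "subgenome", "shared", "specific") %in% names(df)))
  df$shared <- as.integer(df$shared); df$specific <- as.integer(df$specific)
  df$total <- df$shared + df$specific
  if ("total_in" %in% names(df) && any(df$total != df$total_in))
    stop_ctx("shared + specific != total for %s / %s",
             df$species[df$total != df$total_in][1],
             df$subgenome[df$total != df$total_in][1])
  ref <- df[df$species == reference_species, , drop = FALSE]
  if (!nrow(ref)) stop_ctx("reference species \"%s\" absent from table", reference_species)
  ref_tot <- setNames(ref$total, ref$subgenome)
  if (any(ref_tot == 0L))
    stop_ctx("reference subgenome(s) with zero markers: %s",
             paste(names(ref_tot)[ref_tot == 0L], collapse = ", "))
  df$pct <- round_half_up(100 * df$total / ref_tot[df$subgenome], digits)
  stopifnot(all(df$shared + df$specific == df$total))  # hard invariant
  df$total_in <- NULL
  structure(df, reference_species = reference_species,
            reference_totals = ref_tot,
            class = c("homoeology_table", "data.frame"))
}

#' Homoeology of diploid marker sets to reference subgenomes
#'
#' For each screened diploid species and each subgenome of the reference
#' (chromosome groups A, B, D by default), counts the diploid's markers
#' assigned -- via their chromosome labels -- to that subgenome, splits them
#' into shared (also present in at least one other screened diploid) and
#' specific, and expresses the total as a percentage of the reference
#' species' own marker total on that subgenome. Markers labelled
#' `"unassigned"` are excluded here (but kept for retention/specificity).
#'
#' @param x a `marker_matrix` whose markers carry chromosome labels.
#' @param diploid_species the screened diploid species.
#' @param reference_species species providing the reference subgenomes
#'   (e.g. hexaploid bread wheat).
#' @param subgenomes subgenome letters, default `c("A","B","D")`.
#' @inheritParams species_presence
#' @return a `homoeology_table` data frame (`species`, `subgenome`,
#'   `shared`, `specific`, `total`, `pct`) with the reference species as
#'   its first rows and attribute `reference_totals`.
#' @export
homoeology_table <- function(x, diploid_species, reference_species,
                             subgenomes = c("A", "B", "D"),
                             missing_policy = "lenient") {
  missing_policy <- check_policy(missing_policy)
  sg <- subgenome_of(x$markers$chromosome)
  all_sp <- c(reference_species, diploid_species)
  st <- species_state(x, all_sp, missing_policy)
  pres <- st$present
  rows <- lapply(all_sp, function(sp) {
    others <- setdiff(diploid_species, sp)
    other_any <- rowSums(pres[, others, drop = FALSE]) > 0L
    do.call(rbind, lapply(subgenomes, function(g) {
      on_g <- !is.na(sg) & sg == g & pres[, sp]
      tot <- sum(on_g)
      sh <- sum(on_g & other_any)
      data.frame(species = sp, subgenome = g, shared = sh,
                 specific = tot - sh, stringsAsFactors = FALSE)
    }))
  })
  build_homoeology(do.call(rbind, rows), reference_species)
}

#' Assemble a homoeology table from reported counts
#'
#' The same arithmetic/rounding path as [homoeology_table()], applied to a
#' long data frame of counts (columns `species`, `subgenome`, `shared`,
#' `specific`, optionally `total` which is then cross-checked).
#'
#' @param counts long-format count data frame including the reference
#'   species' rows.
#' @param reference_species which species of `counts` defines the
#'   reference subgenome totals.
#' @return a `homoeology_table`.
#' @export
as_homoeology_table <- function(counts, reference_species) {
  df <- as.data.frame(counts, stringsAsFactors = FALSE)
  if ("total" %in% names(df)) { df$total_in <- as.integer(df$total); df$total <- NULL }
  build_homoeology(df, reference_species)
}

#' Select diploid analyzers by homoeology threshold
#'
#' A species is selected for a subgenome iff its homoeology percentage for
#' that subgenome is at least `threshold_percent` (inclusive, per the
#' "at least 10%" convention); the union across subgenomes is the analyzer
#' panel. The reference species itself is never selected.
#'
#' @param ht a `homoeology_table`.
#' @param threshold_percent positive percentage threshold (default 10).
#' @return an `analyzer_selection`: list with `per_subgenome` (named list
#'   of species vectors), `union` (species selected for >= 1 subgenome, in
#'   table order) and `threshold_percent`.
#' @export
select_analyzers <- function(ht, threshold_percent = 10) {
  stopifnot(inherits(ht, "homoeology_table"))
  if (!is.numeric(threshold_percent) || threshold_percent <= 0)
    stop_ctx("threshold_percent must be > 0")
  ref <- attr(ht, "reference_species")
  df <- ht[ht$species != ref, , drop = FALSE]
  sgs <- unique(df$subgenome)
  per <- lapply(sgs, function(g)
    unique(df$species[df$subgenome == g & df$pct >= threshold_percent]))
  names(per) <- sgs
  structure(list(per_subgenome = per,
                 union = unique(df$species)[unique(df$species) %in%
                                              unlist(per, use.names = FALSE)],
                 threshold_percent = threshold_percent),
            class = "analyzer_selection")
}

#' @export
print.analyzer_selection <- function(x, ...) {
  cat(sprintf("<analyzer_selection> %d species at >= %g%% homoeology\n",
              length(x$union), x$threshold_percent))
  for (g in names(x$per_subgenome))
    cat(sprintf("  %s: %s\n", g, paste(x$per_subgenome[[g]], collapse = ", ")))
  invisible(x)
}

#' Polyploid species-specific markers
#'
#' Screens a set of polyploid species against each other, selecting each
#' one's private markers in the same manner as for diploids -- the
#' polyploid list is its own background universe.
#'
#' @param x a `marker_matrix`.
#' @param polyploid_list the polyploid species screened against each other.
#' @inheritParams species_presence
#' @return a `specificity_report` (see [specificity_report()]).
#' @export
polyploid_specific_markers <- function(x, polyploid_list,
                                       missing_policy = "lenient") {
  specificity_report(x, species_list = polyploid_list,
                     missing_policy = missing_policy)
}

#' Per-chromosome retention profile
#'
#' Buckets an analyzer's marker set by chromosome number (1..7) within one
#' subgenome letter and computes the retained proportion in the target per
#' bucket -- the chromosome-level view that exposes segmental replacement
#' of a parental chromosome. Buckets with fewer than `n_min` markers are
#' flagged `low_support` (kept, not dropped).
#'
#' @param x a `marker_matrix` carrying chromosome labels.
#' @param analyzer_set analyzer marker ids (`species_marker_set` or
#'   character vector), typically species-specific.
#' @param target target species whose presence set is probed.
#' @param genome_letter subgenome letter selecting the chromosome group
#'   (e.g. `"B"` for 1B..7B).
#' @param n_min minimum markers per bucket before a cell is trusted.
#' @inheritParams species_presence
#' @return a `chromosome_profile` data frame: `chromosome` (1..7),
#'   `chrom_label`, `n_markers`, `n_retained`, `retention` (`NA` for empty
#'   buckets), `low_support`.
#' @export
chromosome_profile <- function(x, analyzer_set, target, genome_letter,
                               n_min = 20, missing_policy = "lenient") {
  missing_policy <- check_policy(missing_policy)
  ids <- if (inherits(analyzer_set, "species_marker_set"))
    analyzer_set$marker_ids else as.character(analyzer_set)
  chrom <- x$markers$chromosome[match(ids, x$markers$marker_id)]
  labels <- paste0(1:7, genome_letter)
  on_g <- chrom %in% labels
  if (!any(on_g))
    stop_ctx("no analyzer markers assigned to chromosomes %s-%s",
             labels[1], labels[7])
  tgt <- species_presence(x, target, missing_policy)$marker_ids
  num <- chromosome_number_of(chrom)
  prof <- do.call(rbind, lapply(1:7, function(k) {
    b <- ids[on_g & num == k]
    data.frame(chromosome = k, chrom_label = labels[k],
               n_markers = length(b), n_retained = sum(b %in% tgt),
               retention = if (length(b)) sum(b %in% tgt) / length(b) else NA_real_,
               low_support = length(b) < n_min, stringsAsFactors = FALSE)
  }))
  structure(prof, target = target, genome_letter = genome_letter,
            n_min = n_min, class = c("chromosome_profile", "data.frame"))
}

#' Call putative progenitors of a polyploid
#'
#' Ranks the analyzers by retention in the target and fills the target's
#' `ploidy/2` subgenome slots from the top. A slot is resolved only when
#' its candidate exceeds the best analyzer left outside all slots by at
#' least `margin` ("considerably higher" retention); otherwise the slot is
#' reported unresolved, listing the candidate together with the unplaced
#' analyzers within `margin` of it -- near-ties among closely related
#' analyzers thus surface as an "ancestral/unknown" slot rather than a
#' forced choice. With `margin = 0` the call degenerates to a pure argmax
#' fill of the slots.
#'
#' @param rt a `retention_table` (or named numeric matrix) containing a
#'   complete column for `target`.
#' @param panel the [sample_panel()] providing the target's ploidy.
#' @param target polyploid target species.
#' @param margin absolute retention margin required to resolve a slot.
#' @return a `progenitor_call`: list with `target`, `ploidy`, `margin`,
#'   `ranking` (named retention vector, descending) and `slots`, a list of
#'   `ploidy/2` records each holding `status` (`"resolved"`/`"unresolved"`),
#'   `analyzers` and their `retention` values.
#' @export
call_progenitors <- function(rt, panel, target, margin = 0.10) {
  if (!target %in% panel$species) stop_ctx("target \"%s\" not in panel", target)
  pl <- ploidy_of(panel, target)
  if (pl <= 2L) stop_ctx("target \"%s\" is not polyploid (ploidy %d)", target, pl)
  if (!target %in% colnames(rt)) stop_ctx("target \"%s\" not in retention table", target)
  slots_n <- pl %/% 2L
  r <- rt[, target]
  if (anyNA(r)) stop_ctx("retention column for \"%s\" is incomplete (undefined cells)", target)
  if (length(r) < slots_n)
    stop_ctx("only %d analyzer(s) for %d subgenome slots of \"%s\"",
             length(r), slots_n, target)
  ord <- order(-r, names(r))
  ranked <- r[ord]
  slots <- vector("list", slots_n)
  placed <- names(ranked)[seq_len(slots_n)]
  rest <- names(ranked)[-seq_len(slots_n)]
  for (k in rev(seq_len(slots_n))) {
    cand <- placed[k]
    best_rest <- if (length(rest)) max(ranked[rest]) else -Inf
    if (ranked[cand] - best_rest >= margin) {
      slots[[k]] <- list(status = "resolved", analyzers = cand,
                         retention = unname(ranked[cand]))
    } else {
      tied <- rest[ranked[cand] - ranked[rest] < margin]
      grp <- c(cand, tied)
      slots[[k]] <- list(status = "unresolved", analyzers = grp,
                         retention = unname(ranked[grp]))
      rest <- setdiff(rest, tied)
    }
  }
  stopifnot(length(slots) == slots_n)
  structure(list(target = target, ploidy = pl, margin = margin,
                 ranking = ranked, slots = slots),
            class = "progenitor_call")
}

#' @export
print.progenitor_call <- function(x, ...) {
  cat(sprintf("<progenitor_call> %s (%dx), margin %g\n", x$target, x$ploidy, x$margin))
  for (k in seq_along(x$slots)) {
    s <- x$slots[[k]]
    if (s$status == "resolved")
      cat(sprintf("  slot %d: %s (retention %.3f)\n", k, s$analyzers, s$retention))
    else
      cat(sprintf("  slot %d: unresolved / ancestral -- tied set {%s}\n", k,
                  paste(sprintf("%s %.3f", s$analyzers, s$retention), collapse = "; ")))
  }
  invisible(x)
}

# analyzers resolved into slots (helper for reports)
resolved_progenitors <- function(call) {
  unlist(lapply(call$slots, function(s)
    if (s$status == "resolved") s$analyzers else NULL))
}

#' Cross-genome SNP monomorphism
#'
#' For declared groups of samples and a partition of SNP markers into
#' subgenome classes, the percentage of markers called in every group
#' member (no missing) whose scores are identical across the group --
#' the similarity statistic used to compare homoeologous subgenomes
#' across polyploids.
#'
#' @param x a `snp_matrix`.
#' @param sample_groups named list of sample-id vectors.
#' @param partition named list of marker-id vectors; default partitions
#'   the assigned markers by subgenome letter of their chromosome label.
#' @param collapse_het if `TRUE`, heterozygous calls (2) are collapsed
#'   with the alternate homozygote (1) before comparison, i.e. identity is
#'   judged on allele presence rather than exact genotype.
#' @return data frame `group`, `partition`, `n_markers` (complete within
#'   group), `n_monomorphic`, `pct`.
#' @export
cross_genome_monomorphism <- function(x, sample_groups, partition = NULL,
                                      collapse_het = FALSE) {
  stopifnot(inherits(x, "snp_matrix"))
  if (is.null(partition)) {
    sg <- subgenome_of(x$markers$chromosome)
    partition <- split(x$markers$marker_id[!is.na(sg)], sg[!is.na(sg)])
  }
  if (!length(partition) || any(!lengths(partition)))
    stop_ctx("empty marker partition")
  sc <- x$scores
  if (collapse_het) sc[sc == 2L] <- 1L
  out <- do.call(rbind, lapply(names(sample_groups), function(g) {
    cols <- sample_groups[[g]]
    miss <- setdiff(cols, colnames(sc))
    if (length(miss)) stop_ctx("unknown sample(s) in group \"%s\": %s", g,
                               paste(miss, collapse = ", "))
    do.call(rbind, lapply(names(partition), function(p) {
      m <- sc[rownames(sc) %in% partition[[p]], cols, drop = FALSE]
      complete <- rowSums(is.na(m)) == 0L
      m <- m[complete, , drop = FALSE]
      mono <- if (nrow(m)) rowSums(m == m[, 1L]) == ncol(m) else logical(0)
      data.frame(group = g, partition = p, n_markers = nrow(m),
                 n_monomorphic = sum(mono),
                 pct = if (nrow(m)) 100 * sum(mono) / nrow(m) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
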