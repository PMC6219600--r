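# Species-level presence aggregation and species-specific marker selection.
#
# A dominant marker is judged "present" in a species if any of its samples
# scores 1; "absent" requires that no sample scores 1, with the treatment of
# missing calls set by missing_policy:
#   lenient - a missing call counts as absence (the binary matrix is taken
#             at face value after call-rate filtering);
#   strict  - any missing call removes the marker from the absence
#             judgement for that species (it can then be neither present
#             nor absent).

check_policy <- function(missing_policy) {
  match.arg(missing_policy, c("lenient", "strict"))
}

# logical matrix markers x species: present / absent under policy
species_state <- function(x, species_list, missing_policy) {
  sc <- x$scores
  pres <- vapply(species_list, function(sp) {
    cols <- sc[, samples_of(x$panel, sp), drop = FALSE]
    rowSums(cols == 1L, na.rm = TRUE) > 0L
  }, logical(nrow(sc)))
  abs_ <- if (missing_policy == "lenient") {
    !pres
  } else {
    vapply(species_list, function(sp) {
      cols <- sc[, samples_of(x$panel, sp), drop = FALSE]
      rowSums(is.na(cols)) == 0L & rowSums(cols == 1L) == 0L
    }, logical(nrow(sc)))
  }
  if (is.null(dim(pres))) {  # single-marker matrices
    pres <- matrix(pres, 1L, dimnames = list(NULL, species_list))
    abs_ <- matrix(abs_, 1L, dimnames = list(NULL, species_list))
  }
  list(present = pres, absent = abs_)
}

new_species_marker_set <- function(species, marker_ids, samples, missing_policy,
                                   background = NULL) {
  structure(list(species = species,
                 marker_ids = marker_ids,
                 provenance = list(samples = samples,
                                   missing_policy = missing_policy,
                                   presence_rule = "any-sample",
                                   background = background)),
            class = "species_marker_set")
}

#' @export
print.species_marker_set <- function(x, ...) {
  cat(sprintf("<species_marker_set> %s: %d marker(s)%s\n", x$species,
              length(x$marker_ids),
              if (is.null(x$provenance$background)) "" else
                sprintf(" specific against %d background species",
                        length(x$provenance$background))))
  invisible(x)
}

#' @export
length.species_marker_set <- function(x) length(x$marker_ids)

#' Markers present in a species
#'
#' Aggregates a species' samples into a single presence set: a marker is
#' present if any sample of the species scores 1 (missing calls never
#' create presence). The `missing_policy` affects only the companion
#' absence judgement used by [select_species_specific()].
#'
#' @param x a `marker_matrix`.
#' @param species species name (must occur in `x$panel`).
#' @param missing_policy `"lenient"` (default; missing counts as absent) or
#'   `"strict"` (missing excludes the marker from absence calls).
#' @return a `species_marker_set` with the present marker ids and a
#'   provenance record of the samples and policy used.
#' @export
species_presence <- function(x, species, missing_policy = "lenient") {
  missing_policy <- check_policy(missing_policy)
  st <- species_state(x, species, missing_policy)
  new_species_marker_set(species, x$markers$marker_id[st$present[, species]],
                         samples_of(x$panel, species), missing_policy)
}

#' Species-specific markers
#'
#' Selects the markers present in `focal_species` and absent (under
#' `missing_policy`) in every species of `background_species` -- the
#' filtering step at the heart of presence/absence genome analysis:
#' markers present in one species but absent in all the others.
#'
#' @param x a `marker_matrix`.
#' @param focal_species the species whose private markers are sought.
#' @param background_species species the markers must be absent from; must
#'   not contain `focal_species`.
#' @inheritParams species_presence
#' @return a `species_marker_set`, order-preserving in marker order.
#' @export
select_species_specific <- function(x, focal_species, background_species,
                                    missing_policy = "lenient") {
  missing_policy <- check_policy(missing_policy)
  if (!length(background_species)) stop_ctx("background_species is empty")
  if (focal_species %in% background_species)
    stop_ctx("focal species \"%s\" also appears in the background list", focal_species)
  st <- species_state(x, c(focal_species, background_species), missing_policy)
  keep <- st$present[, focal_species] &
    rowSums(st$absent[, background_species, drop = FALSE]) ==
      length(background_species)
  new_species_marker_set(focal_species, x$markers$marker_id[keep],
                         samples_of(x$panel, focal_species), missing_policy,
                         background = background_species)
}

#' Per-species marker totals and specificity report
#'
#' For each species of `species_list`: the total number of markers present,
#' the number specific to it (absent in all other listed species), and the
#' specific percentage rounded half-up to 2 decimals.
#'
#' @param x a `marker_matrix`.
#' @param species_list species screened against each other (>= 2); default
#'   all species in the panel.
#' @inheritParams species_presence
#' @return a `specificity_report` data frame with columns `species`,
#'   `total`, `specific`, `pct`; the specific marker ids are attached as
#'   attribute `"specific_ids"` (a named list).
#' @export
specificity_report <- function(x, species_list = NULL,
                               missing_policy = "lenient") {
  missing_policy <- check_policy(missing_policy)
  species_list <- species_list %||% panel_species(x$panel)
  if (length(species_list) < 2L) stop_ctx("need at least 2 species to screen")
  st <- species_state(x, species_list, missing_policy)
  n_bg <- length(species_list) - 1L
  sets <- lapply(species_list, function(sp) {
    bg <- setdiff(species_list, sp)
    keep <- st$present[, sp] &
      rowSums(st$absent[, bg, drop = FALSE]) == n_bg
    x$markers$marker_id[keep]
  })
  names(sets) <- species_list
  total <- colSums(st$present)
  specific <- lengths(sets)
  rep <- as_specificity_report(species_list, total, specific)
  attr(rep, "specific_ids") <- sets
  attr(rep, "missing_policy") <- missing_policy
  rep
}

#' Assemble a specificity report from counts
#'
#' The arithmetic/rounding path shared by [specificity_report()], usable
#' directly on externally reported marker counts.
#'
#' @param species species names.
#' @param total per-species total marker counts.
#' @param specific per-species specific marker counts.
#' @return a `specificity_report` data frame; `pct` is
#'   `100 * specific / total` rounded half-up to 2 decimals (`NA` when
#'   `total` is 0).
#' @export
as_specificity_report <- function(species, total, specific) {
  total <- as.integer(total); specific <- as.integer(specific)
  if (any(specific > total) || any(specific < 0L))
    stop_ctx("need 0 <= specific <= total for every species")
  pct <- ifelse(total > 0L, round_half_up(100 * specific / total, 2), NA_real_)
  df <- data.frame(species = as.character(species), total = total,
                   specific = specific, pct = pct, stringsAsFactors = FALSE)
  class(df) <- c("specificity_report", "data.frame")
  df
}

#' Write a specificity report and its marker lists
#'
#' @param rep a `specificity_report`.
#' @param path output CSV for the count table.
#' @param ids_dir optional directory; when given, one plain-text file of
#'   specific marker ids is written per species.
#' @return `path`, invisibly.
#' @export
write_specificity_report <- function(rep, path, ids_dir = NULL) {
  write.csv(as.data.frame(rep), path, row.names = FALSE)
  sets <- attr(rep, "specific_ids")
  if (!is.null(ids_dir) && !is.null(sets)) {
    dir.create(ids_dir, showWarnings = FALSE, recursive = TRUE)
    for (sp in names(sets)) {
      f <- file.path(ids_dir, paste0(gsub("[^A-Za-z0-9._-]+", "_", sp),
                                     "_specific_markers.txt"))
      writeLines(sets[[sp]], f)
    }
  }
  invisible(path)
}
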