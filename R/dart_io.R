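# Reading, validating and writing the two DArT-style CSV dialects
# (SilicoDArT presence/absence and one-row 0/1/2 SNP scores), plus the
# sample panel and call-rate filtering.

#' Construct a sample panel
#'
#' A sample panel maps each genotyped sample to its species, ploidy,
#' reported genome formula and analysis role. Ploidy/2 is taken as the
#' expected number of constituent subgenomes of the species.
#'
#' @param sample_id unique sample identifiers.
#' @param species species name per sample (a species may have several
#'   samples, e.g. two cultivars of bread wheat).
#' @param ploidy even integer >= 2 per sample.
#' @param genome_formula reported genome formula (free text), optional.
#' @param role one of `"analyzer"` (diploid probe), `"target"` (polyploid
#'   under analysis), `"reference"` (reference genome carrier) or
#'   `"other"`; optional, defaults to `"other"`.
#' @return a `sample_panel` data frame.
#' @export
sample_panel <- function(sample_id, species, ploidy,
                         genome_formula = NA_character_, role = "other") {
  sample_id <- as.character(sample_id)
  species <- as.character(species)
  ploidy <- as.integer(ploidy)
  if (anyDuplicated(sample_id))
    stop_ctx("duplicate sample_id(s): %s",
             paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  if (any(is.na(ploidy)) || any(ploidy < 2L) || any(ploidy %% 2L != 0L))
    stop_ctx("ploidy must be an even integer >= 2 for every sample")
  bad_pl <- tapply(ploidy, species, function(p) length(unique(p)) > 1L)
  if (any(bad_pl))
    stop_ctx("conflicting ploidy within species: %s",
             paste(names(bad_pl)[bad_pl], collapse = ", "))
  df <- data.frame(sample_id = sample_id, species = species, ploidy = ploidy,
                   genome_formula = rep_len(as.character(genome_formula),
                                            length(sample_id)),
                   role = rep_len(as.character(role), length(sample_id)),
                   stringsAsFactors = FALSE)
  class(df) <- c("sample_panel", "data.frame")
  df
}

#' Read a sample panel from CSV
#'
#' Expects columns `sample_id`, `species`, `ploidy` and optionally
#' `genome_formula` and `role`.
#'
#' @param path CSV file path.
#' @return a [sample_panel()].
#' @export
read_panel <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "species", "ploidy")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_ctx("panel file %s lacks column(s): %s", path,
             paste(missing_cols, collapse = ", "))
  sample_panel(df$sample_id, df$species, df$ploidy,
               genome_formula = df$genome_formula %||% NA_character_,
               role = df$role %||% "other")
}

panel_species <- function(panel, role = NULL) {
  if (!is.null(role)) panel <- panel[panel$role %in% role, , drop = FALSE]
  unique(panel$species)
}

samples_of <- function(panel, species) {
  ids <- panel$sample_id[panel$species == species]
  if (!length(ids)) stop_ctx("species \"%s\" not in panel", species)
  ids
}

ploidy_of <- function(panel, species) {
  unique(panel$ploidy[panel$species == species])
}

new_dart_matrix <- function(scores, panel, chromosome, subclass, allowed) {
  if (!inherits(panel, "sample_panel")) stop_ctx("panel must be a sample_panel")
  if (is.null(rownames(scores))) stop_ctx("score matrix must have marker_id rownames")
  if (anyDuplicated(rownames(scores)))
    stop_ctx("duplicate marker_id(s): %s",
             paste(unique(rownames(scores)[duplicated(rownames(scores))]),
                   collapse = ", "))
  if (!identical(sort(colnames(scores)), sort(panel$sample_id)))
    stop_ctx("sample columns do not match panel: extra {%s}, missing {%s}",
             paste(setdiff(colnames(scores), panel$sample_id), collapse = ", "),
             paste(setdiff(panel$sample_id, colnames(scores)), collapse = ", "))
  scores <- scores[, panel$sample_id, drop = FALSE]
  bad <- !(scores %in% c(allowed, NA))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(scores)), arr.ind = TRUE)[1, ]
    stop_ctx("invalid score %s at marker \"%s\", sample \"%s\" (allowed: %s or missing)",
             scores[idx[1], idx[2]], rownames(scores)[idx[1]],
             colnames(scores)[idx[2]], paste(allowed, collapse = "/"))
  }
  storage.mode(scores) <- "integer"
  chromosome <- if (is.null(chromosome)) rep("unassigned", nrow(scores))
                else normalize_chromosome(chromosome)
  markers <- data.frame(marker_id = rownames(scores),
                        chromosome = chromosome,
                        call_rate = rowMeans(!is.na(scores)),
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(scores = scores, markers = markers, panel = panel),
            class = c(subclass, "dart_matrix"))
}

#' Construct a SilicoDArT presence/absence marker matrix
#'
#' @param scores integer matrix, markers in rows (rownames = marker ids),
#'   samples in columns; values 1 (presence), 0 (absence) or `NA` (missing).
#' @param panel a [sample_panel()]; columns must match its `sample_id`s.
#' @param chromosome optional chromosome label per marker; normalized via
#'   [normalize_chromosome()].
#' @return a `marker_matrix` with per-marker metadata (`marker_id`,
#'   `chromosome`, `call_rate`); `call_rate` is always recomputed from the
#'   scores as the fraction of non-missing calls.
#' @export
marker_matrix <- function(scores, panel, chromosome = NULL) {
  new_dart_matrix(scores, panel, chromosome, "marker_matrix", c(0L, 1L))
}

#' Construct a codominant SNP marker matrix
#'
#' Scores follow the one-row DArT SNP dialect: 0 = reference-allele
#' homozygote, 1 = alternate-allele homozygote, 2 = heterozygote, `NA` =
#' missing call.
#'
#' @inheritParams marker_matrix
#' @return a `snp_matrix`.
#' @export
snp_matrix <- function(scores, panel, chromosome = NULL) {
  new_dart_matrix(scores, panel, chromosome, "snp_matrix", c(0L, 1L, 2L))
}

#' @export
print.dart_matrix <- function(x, ...) {
  cat(sprintf("<%s> %d markers x %d samples (%d species)\n",
              class(x)[1], nrow(x$scores), ncol(x$scores),
              length(unique(x$panel$species))))
  cat(sprintf("  call rate: min %.3f, median %.3f; %d marker(s) unassigned to a chromosome\n",
              min(x$markers$call_rate), stats::median(x$markers$call_rate),
              sum(x$markers$chromosome == "unassigned")))
  invisible(x)
}

#' @export
dim.dart_matrix <- function(x) dim(x$scores)

read_dart_csv <- function(path, panel, missing_codes, constructor, allowed) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 colClasses = "character")
  if (!nrow(df) || !"marker_id" %in% names(df))
    stop_ctx("%s: no rows or no marker_id column; not a DArT-style marker CSV", path)
  meta_cols <- intersect(c("marker_id", "chromosome", "call_rate"), names(df))
  sample_cols <- setdiff(names(df), meta_cols)
  dup <- duplicated(df$marker_id)
  if (any(dup)) {
    tab <- table(df$marker_id)
    if (all(tab == 2L))
      stop_ctx("%s: every marker_id appears twice; two-row SNP dialect is not supported, export the one-row 0/1/2 dialect", path)
    stop_ctx("%s: duplicate marker_id(s): %s", path,
             paste(utils::head(unique(df$marker_id[dup]), 5), collapse = ", "))
  }
  raw <- as.matrix(df[, sample_cols, drop = FALSE])
  raw[raw %in% missing_codes] <- NA
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- (!is.na(raw)) & (is.na(num) | !(num %in% allowed))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop_ctx("%s: invalid score \"%s\" at marker \"%s\", sample \"%s\" (row %d); allowed %s or missing code(s) %s",
             path, raw[idx[1], idx[2]], df$marker_id[idx[1]],
             sample_cols[idx[2]], idx[1], paste(allowed, collapse = "/"),
             paste(shQuote(missing_codes), collapse = ", "))
  }
  scores <- matrix(as.integer(num), nrow(num),
                   dimnames = list(df$marker_id, sample_cols))
  m <- constructor(scores, panel, chromosome = df$chromosome %||% NULL)
  if ("call_rate" %in% names(df)) {
    stored <- suppressWarnings(as.numeric(df$call_rate))
    off <- which(!is.na(stored) & abs(stored - m$markers$call_rate) > 1e-9)
    if (length(off))
      message(sprintf("%s: stored call_rate differs from recomputed for %d marker(s) (e.g. %s); recomputed values kept",
                      path, length(off), df$marker_id[off[1]]))
  }
  m
}

#' Read a SilicoDArT CSV
#'
#' The file must carry a header row; metadata columns `marker_id` and
#' optionally `chromosome` and `call_rate` precede one column per sample.
#' Any stored `call_rate` is compared with the value recomputed from the
#' scores; the recomputed value always wins (a message reports conflicts).
#'
#' @param path CSV file path.
#' @param panel a [sample_panel()] the sample columns must match.
#' @param missing_codes strings treated as missing calls; by convention
#'   both `"-"` and the empty cell occur in DArT exports.
#' @return a [marker_matrix()].
#' @export
read_silicodart <- function(path, panel, missing_codes = c("-", "")) {
  read_dart_csv(path, panel, missing_codes, marker_matrix, c(0, 1))
}

#' Read a one-row SNP CSV
#'
#' As [read_silicodart()] but scores are validated against \{0, 1, 2\}.
#' A file in which every marker id appears exactly twice is rejected as the
#' unsupported two-row dialect.
#'
#' @inheritParams read_silicodart
#' @return a [snp_matrix()].
#' @export
read_snp <- function(path, panel, missing_codes = c("-", "")) {
  read_dart_csv(path, panel, missing_codes, snp_matrix, c(0, 1, 2))
}

write_dart_csv <- function(x, path, missing_code) {
  sc <- x$scores
  out <- array(as.character(sc), dim = dim(sc))
  out[is.na(out)] <- missing_code
  colnames(out) <- colnames(sc)
  df <- cbind(x$markers[, c("marker_id", "chromosome", "call_rate")],
              as.data.frame(out, stringsAsFactors = FALSE))
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a marker or SNP matrix to CSV
#'
#' Writes the dialect [read_silicodart()] / [read_snp()] read, with missing
#' calls encoded as `"-"`; reading the file back reproduces the score
#' matrix exactly.
#'
#' @param x a `marker_matrix` or `snp_matrix`.
#' @param path output CSV path.
#' @param missing_code string written for missing calls.
#' @return `path`, invisibly.
#' @export
write_dart <- function(x, path, missing_code = "-") {
  stopifnot(inherits(x, "dart_matrix"))
  write_dart_csv(x, path, missing_code)
}

#' Filter markers on call rate
#'
#' Retains exactly the markers whose call rate is strictly greater than
#' `threshold` (the conventional DArT thresholds being > 0.7 for
#' presence/absence markers and > 0.9 for SNPs), preserving marker order.
#' Idempotent.
#'
#' @param x a `marker_matrix` or `snp_matrix`.
#' @param threshold call-rate threshold in \[0, 1\]; strict `>`.
#' @return a matrix of the same class with only the retained markers.
#' @export
filter_call_rate <- function(x, threshold) {
  stopifnot(inherits(x, "dart_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    stop_ctx("threshold must be a single value in [0, 1]")
  keep <- x$markers$call_rate > threshold
  if (!any(keep))
    message(sprintf("filter_call_rate: no markers exceed call rate %g; empty matrix returned", threshold))
  subset_markers(x, keep)
}

# subset rows of a dart_matrix, preserving class and metadata
subset_markers <- function(x, keep) {
  x$scores <- x$scores[keep, , drop = FALSE]
  x$markers <- x$markers[keep, , drop = FALSE]
  rownames(x$markers) <- NULL
  x
}
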