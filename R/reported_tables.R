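# Reported marker-count tables from a published DArTseq survey of 34
# Triticeae species (11 diploid and 12 polyploid Aegilops species, 8
# Triticum species and 3 distant wheat relatives), shipped as plain-text
# CSVs under inst/extdata. They provide real-scale inputs for the
# arithmetic paths (percentage and analyzer-selection rules) without any
# download.

extdata <- function(name) {
  f <- system.file("extdata", name, package = "dartpoly", mustWork = TRUE)
  read.csv(f, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Reported Triticeae sample panel
#'
#' The 35-sample panel of the survey (34 species; bread wheat represented
#' by two cultivars), with ploidy, reported genome formula and role.
#'
#' @return a [sample_panel()].
#' @export
triticeae_panel <- function() {
  df <- extdata("triticeae_panel.csv")
  sample_panel(df$sample_id, df$species, df$ploidy,
               genome_formula = df$genome_formula, role = df$role)
}

#' Reported diploid Aegilops marker counts
#'
#' Total and species-specific SilicoDArT marker counts of the 11 diploid
#' Aegilops species (call rate > 0.7), screened against each other.
#'
#' @return data frame `species`, `total`, `specific`.
#' @export
reported_diploid_counts <- function() extdata("triticeae_diploid_specificity.csv")

#' Reported homoeology counts against bread wheat
#'
#' SilicoDArT marker counts of 16 wheat-related diploid species (and the
#' bread-wheat reference itself) assigned to the A, B and D subgenomes of
#' bread wheat, split into shared (present in >= 1 other screened diploid)
#' and specific.
#'
#' @return long data frame `species`, `subgenome`, `shared`, `specific`;
#'   feed to [as_homoeology_table()] with reference `"T. aestivum"`.
#' @export
reported_homoeology_counts <- function() extdata("triticeae_wheat_homoeology.csv")

#' Reported polyploid Aegilops specific-marker counts
#'
#' Species-specific SilicoDArT marker counts of the 12 polyploid Aegilops
#' species, screened against each other.
#'
#' @return data frame `species`, `ploidy`, `genome_formula`, `specific`.
#' @export
reported_polyploid_counts <- function() extdata("triticeae_polyploid_specificity.csv")
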