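#' Round half away from zero
#'
#' Fixed-point rounding with halves rounded up, matching how marker-table
#' percentages are conventionally printed (e.g. 36.565 -> 36.57), unlike
#' [base::round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, halves away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  # small guard against values like 36.565 stored as 36.56499999999999
  sign(x) * floor(abs(x) * f + 0.5 + sqrt(.Machine$double.eps)) / f
}

#' Wheat chromosome label set
#'
#' The 21 chromosomes of hexaploid bread wheat, `1A`..`7D`, the reference
#' frame DArT-style markers are commonly assigned to.
#'
#' @param subgenomes subgenome letters to include.
#' @return character vector of chromosome labels.
#' @export
wheat_chromosomes <- function(subgenomes = c("A", "B", "D")) {
  as.vector(t(outer(subgenomes, 1:7, function(g, n) paste0(n, g))))
}

# subgenome letter of a chromosome label ("3B" -> "B"); NA for "unassigned"
subgenome_of <- function(chromosome) {
  out <- ifelse(chromosome == "unassigned" | is.na(chromosome), NA_character_,
                sub("^[1-7]", "", chromosome))
  out
}

# chromosome number within its subgenome ("3B" -> 3L); NA for "unassigned"
chromosome_number_of <- function(chromosome) {
  num <- suppressWarnings(as.integer(substr(chromosome, 1L, 1L)))
  num[chromosome == "unassigned" | is.na(chromosome)] <- NA_integer_
  num
}

#' Normalize chromosome labels
#'
#' Upper-cases labels and maps anything outside the declared chromosome set
#' to `"unassigned"` (with a warning), so downstream subgenome logic sees a
#' clean label vocabulary.
#'
#' @param chromosome character vector of raw labels.
#' @param chromosomes allowed labels, default the 21 wheat chromosomes.
#' @return character vector over `chromosomes` plus `"unassigned"`.
#' @export
normalize_chromosome <- function(chromosome, chromosomes = wheat_chromosomes()) {
  x <- toupper(trimws(as.character(chromosome)))
  x[is.na(x) | x == "" | x == "-"] <- "unassigned"
  x[x == "UNASSIGNED"] <- "unassigned"
  bad <- !(x %in% c(chromosomes, "unassigned"))
  if (any(bad)) {
    warning(sprintf("%d chromosome label(s) outside the declared set (e.g. %s) mapped to \"unassigned\"",
                    sum(bad), paste(utils::head(unique(x[bad]), 3), collapse = ", ")),
            call. = FALSE)
    x[bad] <- "unassigned"
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ctx <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
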