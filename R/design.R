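#' Classify a cross from the two infection states
#'
#' In haplodiploid CI systems the biological class of a cross is fully
#' determined by the Wolbachia infection state of the two parents: sperm from
#' an infected male is only incompatible when the egg is uninfected, and an
#' infected female rescues the modification.
#'
#' @param male_infected,female_infected Logical vectors (recycled to common
#'   length).
#' @return A character vector with values `"incompatible"`,
#'   `"compatible_control"`, `"rescue"` or `"rescue_control"`.
#' @examples
#' cross_class(TRUE, FALSE)  # incompatible
#' cross_class(TRUE, TRUE)   # rescue
#' @export
cross_class <- function(male_infected, female_infected) {
  stopifnot(is.logical(male_infected), is.logical(female_infected))
  dplyr::case_when(
    male_infected & !female_infected ~ "incompatible",
    !male_infected & !female_infected ~ "compatible_control",
    male_infected & female_infected ~ "rescue",
    TRUE ~ "rescue_control"
  )
}

#' Enumerate a full diallel cross design
#'
#' Builds the complete factorial mating design used to screen for host
#' modulation of CI: every female genotype is crossed to every male genotype,
#' once with an infected male (an incompatible cross) and once with an
#' uninfected male (the matched compatible control). Females are uninfected
#' throughout. Five genotypes therefore give 50 cross types, 25 incompatible
#' and 25 compatible.
#'
#' @param genotypes Character vector of unique, non-empty genotype labels.
#' @return A tibble with one row per cross type and columns
#'   `female_genotype`, `male_genotype`, `male_infected`, `female_infected`
#'   and `cross_class`, ordered female-major, then male, with the infected
#'   (incompatible) member of each pair last.
#' @examples
#' enumerate_diallel(c("Beis", "LonX", "Scp", "Stt", "Temp"))
#' @export
enumerate_diallel <- function(genotypes) {
  genotypes <- as.character(genotypes)
  if (length(genotypes) < 1) {
    abort("`genotypes` must contain at least one label.")
  }
  if (anyDuplicated(genotypes)) {
    abort(paste0(
      "Duplicate genotype labels: ",
      paste(unique(genotypes[duplicated(genotypes)]), collapse = ", ")
    ))
  }
  if (any(!nzchar(genotypes)) || anyNA(genotypes)) {
    abort("Genotype labels must be non-empty and non-missing.")
  }
  design <- tidyr::expand_grid(
    female_genotype = genotypes,
    male_genotype = genotypes,
    male_infected = c(FALSE, TRUE)
  )
  design |>
    mutate(
      female_infected = FALSE,
      cross_class = cross_class(.data$male_infected, .data$female_infected)
    )
}
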