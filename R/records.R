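#' Derive the three CI response variables from brood counts
#'
#' Each brood replicate yields three binomial numerator/denominator pairs:
#' * `F`  — adult female offspring over all eggs (`f_num / f_den`);
#' * `MD` — adult male offspring over all eggs (`md_num / md_den`);
#' * `FM` — eggs that failed to produce an adult mite over the eggs that did
#'   not become adult males (`fm_num / fm_den`).
#'
#' The three numerators partition the eggs of a brood:
#' `f_num + md_num + fm_num = eggs`. A zero denominator (e.g. `FM` when every
#' egg became an adult male) is legal here; such rows are dropped per-response
#' at model-fitting time.
#'
#' @param records A data frame of brood records (see [read_brood_records()]
#'   for the schema).
#' @return The input tibble with the six columns `f_num`, `f_den`, `md_num`,
#'   `md_den`, `fm_num`, `fm_den` appended.
#' @examples
#' rec <- tibble::tibble(eggs = 20, adult_females = 8, adult_males = 6)
#' derive_responses(rec)
#' @export
derive_responses <- function(records) {
  validate_brood_counts(records)
  records |>
    as_tibble() |>
    mutate(
      f_num = .data$adult_females,
      f_den = .data$eggs,
      md_num = .data$adult_males,
      md_den = .data$eggs,
      fm_num = .data$eggs - .data$adult_females - .data$adult_males,
      fm_den = .data$eggs - .data$adult_males
    )
}

# Count sanity shared by derive_responses() and the readers: non-negative
# integers with adult_females + adult_males <= eggs.
validate_brood_counts <- function(records, call = rlang::caller_env()) {
  needed <- c("eggs", "adult_females", "adult_males")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    abort(paste0("Missing count column(s): ", paste(missing, collapse = ", ")),
      call = call
    )
  }
  for (col in needed) {
    x <- records[[col]]
    if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x != floor(x))) {
      abort(paste0("Column `", col, "` must contain non-negative integers."),
        call = call
      )
    }
  }
  bad <- which(records$adult_females + records$adult_males > records$eggs)
  if (length(bad)) {
    abort(paste0(
      "adult_females + adult_males exceeds eggs in row(s): ",
      paste(head(bad, 5), collapse = ", "),
      if (length(bad) > 5) " ..." else ""
    ), call = call)
  }
  invisible(records)
}

#' Validate a table of brood records against the package schema
#'
#' Checks column presence, count integrity (non-negative integers,
#' `adult_females + adult_males <= eggs`) and that infection flags are
#' logical. Problems are reported with row numbers.
#'
#' @param records A data frame.
#' @return The records, invisibly, as a tibble (errors otherwise).
#' @export
validate_brood_records <- function(records) {
  missing <- setdiff(record_columns, names(records))
  if (length(missing)) {
    abort(paste0(
      "Missing required column(s): ", paste(missing, collapse = ", ")
    ))
  }
  for (col in c("male_infected", "female_infected")) {
    if (!is.logical(records[[col]]) || anyNA(records[[col]])) {
      abort(paste0("Column `", col, "` must be logical (TRUE/FALSE)."))
    }
  }
  validate_brood_counts(records)
  dup <- records |>
    dplyr::count(
      .data$female_genotype, .data$male_genotype, .data$male_infected,
      .data$female_infected, .data$day, .data$replicate
    ) |>
    filter(.data$n > 1)
  if (nrow(dup)) {
    abort("Replicate identifiers must be unique within a cross type and day.")
  }
  invisible(as_tibble(records))
}

infection_to_string <- function(x) ifelse(x, "infected", "cured")

string_to_infection <- function(x, column) {
  lowered <- tolower(trimws(as.character(x)))
  out <- dplyr::case_when(
    lowered %in% c("infected", "w") ~ TRUE,
    lowered %in% c("cured", "uninfected", "c") ~ FALSE,
    TRUE ~ NA
  )
  if (anyNA(out)) {
    bad <- which(is.na(out))
    abort(paste0(
      "Column `", column, "` must be 'infected' or 'cured'; offending row(s): ",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  out
}

#' Read and write brood records
#'
#' Brood records travel as delimited text (UTF-8, `.` decimal) with one
#' header row and the columns `day, female_genotype, male_genotype,
#' male_infected, female_infected, replicate, eggs, adult_females,
#' adult_males` (extra columns such as pedigree annotations are preserved).
#' Infection states are written as the literal strings `"infected"` /
#' `"cured"` and parsed case-insensitively; in memory they are logicals.
#' Writing then reading a table reproduces it exactly.
#'
#' @param path File path.
#' @param delim Single-character field delimiter (default comma).
#' @param records A data frame of brood records.
#' @return `read_brood_records()` returns a validated tibble;
#'   `write_brood_records()` returns `records` invisibly.
#' @export
read_brood_records <- function(path, delim = ",") {
  raw <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  missing <- setdiff(record_columns, names(raw))
  if (length(missing)) {
    abort(paste0(
      "File ", path, " is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  parse_count <- function(x, column) {
    bad <- which(!grepl("^[0-9]+$", x))
    if (length(bad)) {
      abort(paste0(
        "Column `", column, "` must contain non-negative integers; ",
        "offending data row(s): ", paste(head(bad, 5), collapse = ", ")
      ))
    }
    as.integer(x)
  }
  out <- raw |>
    mutate(
      male_infected = string_to_infection(.data$male_infected, "male_infected"),
      female_infected = string_to_infection(
        .data$female_infected, "female_infected"
      ),
      eggs = parse_count(.data$eggs, "eggs"),
      adult_females = parse_count(.data$adult_females, "adult_females"),
      adult_males = parse_count(.data$adult_males, "adult_males")
    ) |>
    relocate(dplyr::all_of(record_columns))
  validate_brood_records(out)
  out |>
    mutate(cross_class = cross_class(.data$male_infected, .data$female_infected))
}

#' @rdname read_brood_records
#' @export
write_brood_records <- function(records, path, delim = ",") {
  validate_brood_records(records)
  extra <- setdiff(names(records), c(record_columns, "cross_class"))
  out <- records |>
    as_tibble() |>
    select(dplyr::all_of(c(record_columns, extra))) |>
    mutate(
      male_infected = infection_to_string(.data$male_infected),
      female_infected = infection_to_string(.data$female_infected)
    )
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(records)
}
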