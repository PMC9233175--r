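# Short MCMC settings for unit tests; posterior means at these lengths are
# stable to ~0.01 for the simple models used here.
quick <- list(chains = 2L, iter = 1200L, warmup = 400L)

# A tiny hand-built record table: one incompatible cross and its control.
toy_records <- function() {
  tibble::tibble(
    day = "d1",
    female_genotype = "A",
    male_genotype = "B",
    male_infected = c(TRUE, FALSE),
    female_infected = FALSE,
    replicate = "r1",
    eggs = c(100L, 100L),
    adult_females = c(15L, 60L),
    adult_males = c(30L, 30L)
  )
}

# A minimal hand-built ci_fit carrying known coefficient draws, for testing
# draw-level computations without running MCMC.
fake_ci_fit <- function(draws, formula = ~inf, day_levels = NULL,
                        genotypes = c("A", "B")) {
  X_template <- stats::model.matrix(
    formula,
    data.frame(
      inf = factor(c("cured", "infected"), levels = c("cured", "infected")),
      mgeno = factor(genotypes, levels = genotypes),
      fgeno = factor(genotypes, levels = genotypes)
    )
  )
  structure(
    list(
      draws = draws,
      chain = rep(1:2, length.out = nrow(draws)),
      spec = ci_model_spec("F", deparse(formula[[2]]),
        day_intercepts = !is.null(day_levels)
      ),
      terms = stats::terms(formula),
      xlevels = list(
        inf = c("cured", "infected"), mgeno = genotypes, fgeno = genotypes
      ),
      beta_names = colnames(X_template),
      assign = attr(X_template, "assign"),
      day_levels = day_levels
    ),
    class = "ci_fit"
  )
}
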