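# Small in-code fixtures.

random_table <- function(n = 10, metals = c("Cr", "Cu", "Zn"),
                         kind = "soil", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  df <- data.frame(sample_id = sprintf("S%03d", seq_len(n)))
  for (m in metals) df[[m]] <- stats::rlnorm(n, log(10), 0.5)
  if (kind == "plant")
    df$species <- rep(c("sp1", "sp2"), length.out = n)
  concentration_table(df, kind = kind, metals = metals)
}

example_survey_path <- function(file) {
  system.file("extdata", "example_survey", file, package = "metalsource")
}

kalamaili_path <- function(file) {
  system.file("extdata", "kalamaili", file, package = "metalsource")
}
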