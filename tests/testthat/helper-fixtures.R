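# Small deterministic fixtures built in code.

# A study with the given group sizes; optional per-gene case shift `effect`
# (named numeric) and fixed seed.
make_study <- function(n_genes = 50, n_case = 4, n_control = 4,
                       study_id = "s", effect = NULL, seed = 1,
                       noise_sd = 1) {
  withr::with_seed(seed, {
    genes <- sprintf("g%03d", seq_len(n_genes))
    groups <- c(rep("case", n_case), rep("control", n_control))
    vals <- matrix(rnorm(n_genes * length(groups), 7, noise_sd),
                   n_genes, length(groups),
                   dimnames = list(genes,
                                   paste0(study_id, "_a", seq_along(groups))))
    if (!is.null(effect))
      vals[names(effect), groups == "case"] <-
        vals[names(effect), groups == "case"] + effect
    expression_study(vals, groups, study_id)
  })
}

# Wrap a matrix + groups as an integrated_dataset without standardizing
# (for unit tests that need exact values).
make_integrated <- function(values, groups, study_id = "t") {
  structure(list(values = values,
                 samples = data.frame(sample_id = colnames(values),
                                      study_id = study_id, group = groups,
                                      stringsAsFactors = FALSE),
                 provenance = study_id),
            class = "integrated_dataset")
}
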