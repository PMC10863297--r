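# Shared fixtures, built in code.

# Desk-scale config for unit tests; acceptance tests use the defaults.
small_config <- function(seed = 42L, n_probes = 800, n_unique_under = 20,
                         n_unique_over = 5, n_corr_nonunique = 20,
                         samples_per_tissue = 10, ...) {
  synth_config(n_probes = n_probes, n_unique_under = n_unique_under,
               n_unique_over = n_unique_over,
               n_corr_nonunique = n_corr_nonunique,
               samples_per_tissue = samples_per_tissue,
               seed = seed, ...)
}

# A tiny hand-built beta matrix with dimnames.
tiny_matrix <- function(values, n_probes, n_samples) {
  matrix(values, nrow = n_probes, ncol = n_samples,
         dimnames = list(sprintf("cg%03d", seq_len(n_probes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

# Write a delimited file from a matrix of character cells.
write_tsv_lines <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

planted_ids <- function(truth,
                        classes = c("unique_under", "unique_over")) {
  truth$probe_id[truth$class %in% classes]
}
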