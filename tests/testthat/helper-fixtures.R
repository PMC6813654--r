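# programmatic fixtures

# small named expression matrix from a vector (filled by column)
toy_expr <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), ncol = length(samples),
         dimnames = list(genes, samples))
}

# random expression matrix with gene/sample names
rand_expr <- function(n_genes, n_samples, mean = 8, sd = 1) {
  toy_expr(stats::rnorm(n_genes * n_samples, mean, sd),
           sprintf("G%03d", seq_len(n_genes)),
           sprintf("S%03d", seq_len(n_samples)))
}

# minimal clinical table around given survival outcome
toy_clinical <- function(times, events, response_state = NULL,
                         sample_ids = sprintf("S%03d", seq_along(times))) {
  cl <- data.frame(sample_id = sample_ids, rfs_months = times, event = events,
                   stringsAsFactors = FALSE)
  if (!is.null(response_state)) cl$response_state <- response_state
  cl
}

# a random strictly increasing per-sample transform applied to a matrix
random_monotone <- function(expr) {
  fam <- sample(c("affine", "power", "softplus"), 1)
  apply_monotone_distortion(expr, fam, seed = sample.int(1e6, 1))
}
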