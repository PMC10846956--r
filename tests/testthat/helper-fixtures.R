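# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

# n x length(loadings) indicator matrix from a single latent factor.
one_factor_data <- function(n, loadings, seed = 1) {
  set.seed(seed)
  lat <- rnorm(n)
  sapply(loadings, function(l) l * lat + sqrt(1 - l^2) * rnorm(n))
}

# Trial records for one participant/form/condition with given latencies.
rt_records <- function(rt, participant = "P1", form = "A",
                       condition = "FA", block = 1,
                       error_label = "none") {
  n <- length(rt)
  tibble::tibble(
    participant_id = participant, form = form, block = block,
    position = seq_len(n),
    stimulus_id = sprintf("%s_s%03d", form, seq_len(n)),
    condition = condition, rt_sec = rt,
    response = sprintf("u%d_%s", seq_len(n), participant),
    error_label = rep(error_label, length.out = n))
}

# Tiny norms table from a list of respondent respondent -> responses.
norms_from_sequences <- function(seqs, stimulus = "s1") {
  rows <- lapply(seq_along(seqs), function(i) {
    tibble::tibble(respondent_id = sprintf("R%02d", i),
                   stimulus_id = stimulus,
                   slot = seq_along(seqs[[i]]),
                   response = seqs[[i]])
  })
  dplyr::bind_rows(rows)
}

# Unit-weight undirected igraph from an edge list matrix.
unit_graph <- function(edges, n_extra = 0) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- 1
  g
}
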