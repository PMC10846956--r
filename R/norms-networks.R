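#' Clean free-association norms
#'
#' Applies the standard norm-cleaning order: synonyms are first mapped to
#' their canonical terms (so variant spellings pool their counts), the
#' per-stimulus response frequencies are then recounted, and responses
#' whose total frequency within a stimulus is below 2 are dropped.
#' Responses on an optional exclusion list (e.g. flagged non-nouns) are
#' marked in a `flagged` column but not dropped automatically.
#'
#' @param norms Tibble in the canonical norms schema (`respondent_id`,
#'   `stimulus_id`, `slot`, `response`).
#' @param synonym_map Named character vector mapping variant responses to
#'   canonical terms. Chains are resolved transitively; a cyclic map is
#'   rejected.
#' @param exclude Character vector of responses to flag (not drop).
#' @param min_freq Minimum per-stimulus response frequency (default 2).
#' @return The cleaned norms tibble, with a `flagged` column.
#' @export
clean_norms <- function(norms, synonym_map = NULL, exclude = NULL,
                        min_freq = 2) {
  assert_cols(norms, c("respondent_id", "stimulus_id", "slot", "response"),
              "norms")
  resp <- norms$response
  if (!is.null(synonym_map) && length(synonym_map) > 0) {
    canon <- resolve_synonyms(synonym_map)
    hit <- resp %in% names(canon)
    resp[hit] <- canon[resp[hit]]
  }
  out <- norms
  out$response <- resp
  key <- paste(out$stimulus_id, out$response, sep = "\r")
  freq <- table(key)
  out <- out[freq[key] >= min_freq, , drop = FALSE]
  out$flagged <- out$response %in% (exclude %||% character(0))
  out
}

# Resolve a synonym map transitively; reject cycles.
resolve_synonyms <- function(map) {
  stopifnot(!is.null(names(map)), all(nzchar(names(map))))
  out <- map
  for (i in seq_along(out)) {
    seen <- names(out)[i]
    v <- out[[i]]
    while (v %in% names(map)) {
      if (v %in% seen) {
        stop("synonym map contains a cycle involving '", v, "'",
             call. = FALSE)
      }
      seen <- c(seen, v)
      v <- map[[v]]
    }
    out[[i]] <- v
  }
  out
}

# Per-stimulus response frequency table, descending.
norm_frequencies <- function(norms, stimulus) {
  resp <- norms$response[norms$stimulus_id == stimulus]
  sort(table(resp), decreasing = TRUE)
}

#' Associative-hierarchy statistics
#'
#' Describes the steepness of a stimulus's associative hierarchy from its
#' response frequency counts: the proportional dominance of the strongest
#' association (top frequency over the summed frequencies of all
#' associations), the frequency-decrease slope from an ordinary
#' least-squares regression of the top-10 frequencies on their ranks
#' (1 = most frequent), and the frequency intercept, defined as the mean
#' frequency of those top-10 responses. With fewer than 10 distinct
#' responses the available ranks are used.
#'
#' @param freqs Numeric vector of response frequencies (any order).
#' @return A one-row tibble: `prop_dominant`, `slope_beta`, `intercept`,
#'   `n_responses`.
#' @examples
#' hierarchy_stats(c(10, 8, 6, 4, 2))  # slope -2
#' @export
hierarchy_stats <- function(freqs) {
  freqs <- sort(as.numeric(freqs), decreasing = TRUE)
  if (length(freqs) < 1 || any(freqs < 0)) {
    stop("freqs must be non-negative counts", call. = FALSE)
  }
  prop_dom <- freqs[1] / sum(freqs)
  m <- min(10L, length(freqs))
  if (length(freqs) < 2) {
    return(tibble::tibble(prop_dominant = prop_dom, slope_beta = NA_real_,
                          intercept = freqs[1], n_responses = 1L))
  }
  top <- freqs[seq_len(m)]
  slope <- unname(coef(lm(top ~ seq_len(m)))[2])
  tibble::tibble(prop_dominant = prop_dom, slope_beta = slope,
                 intercept = mean(top), n_responses = length(freqs))
}

#' LogDice collocation strength
#'
#' \eqn{14 + \log_2(2 f_{xy} / (f_x + f_y))}: a frequency-normalized Dice
#' score bounded above by 14 (reached when both words occur only
#' together). A zero co-occurrence yields `NA` (no edge).
#'
#' @param f_xy Co-occurrence count(s).
#' @param f_x,f_y Marginal occurrence counts; `f_xy <= min(f_x, f_y)`
#'   must hold.
#' @return LogDice score(s).
#' @examples
#' logdice(5, 5, 5)   # 14
#' logdice(1, 2, 2)   # 13
#' @export
logdice <- function(f_xy, f_x, f_y) {
  if (any(f_xy < 0 | f_x < 0 | f_y < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(f_xy > pmin(f_x, f_y))) {
    stop("inconsistent counts: f_xy exceeds min(f_x, f_y)", call. = FALSE)
  }
  ifelse(f_xy == 0, NA_real_, 14 + log2(2 * f_xy / (f_x + f_y)))
}

#' Build a LogDice-weighted co-occurrence network for one stimulus
#'
#' Nodes are the unique associations given to the stimulus; an unordered
#' pair of associations gains one co-occurrence count each time both
#' appear within the same respondent's sequence for that stimulus. Edge
#' weights are [logdice()] scores of the co-occurrence count against the
#' two responses' marginal frequencies within that stimulus's norms.
#' Respondent sequences with fewer than 2 surviving responses contribute
#' no pairs (their number is recorded in the graph attribute
#' `n_skipped_sequences`).
#'
#' @param norms Cleaned norms tibble ([clean_norms()]).
#' @param stimulus Stimulus identifier to build the network for; may be
#'   omitted when `norms` contains a single stimulus.
#' @return An undirected `igraph` graph with vertex attribute `freq` and
#'   edge attributes `cooccurrence`, `logdice` and `weight` (= LogDice).
#' @export
build_network <- function(norms, stimulus = NULL) {
  assert_cols(norms, c("respondent_id", "stimulus_id", "response"), "norms")
  if (is.null(stimulus)) {
    stimulus <- unique(norms$stimulus_id)
    if (length(stimulus) != 1) {
      stop("norms contain several stimuli; name one via `stimulus`",
           call. = FALSE)
    }
  }
  d <- norms[norms$stimulus_id == stimulus, , drop = FALSE]
  if (nrow(d) == 0) stop("no norms for stimulus '", stimulus, "'",
                         call. = FALSE)
  freq <- table(d$response)

  seqs <- split(d$response, d$respondent_id)
  seqs <- lapply(seqs, unique)  # synonym merging may duplicate within sequence
  n_skipped <- sum(vapply(seqs, length, integer(1)) < 2)
  pair_keys <- unlist(lapply(seqs, function(s) {
    if (length(s) < 2) return(character(0))
    s <- sort(s)
    apply(combn(s, 2), 2, paste, collapse = "\r")
  }))
  if (length(pair_keys) == 0) {
    g <- igraph::make_empty_graph(n = length(freq), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = names(freq))
    g <- igraph::set_vertex_attr(g, "freq", value = as.integer(freq))
  } else {
    co <- table(pair_keys)
    parts <- do.call(rbind, strsplit(names(co), "\r", fixed = TRUE))
    edges <- tibble::tibble(
      from = parts[, 1], to = parts[, 2],
      cooccurrence = as.integer(co),
      logdice = logdice(as.integer(co),
                        as.integer(freq[parts[, 1]]),
                        as.integer(freq[parts[, 2]])))
    edges$weight <- edges$logdice
    verts <- tibble::tibble(name = names(freq), freq = as.integer(freq))
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = verts)
  }
  g <- igraph::set_graph_attr(g, "stimulus", stimulus)
  igraph::set_graph_attr(g, "n_skipped_sequences", n_skipped)
}

#' Graph metrics of a stimulus co-occurrence network
#'
#' Computes the four topology measures on the positive-weight subgraph:
#' Louvain modularity (resolution 1, best of 10 seeded restarts), average
#' shortest path length and global efficiency with edge distance
#' 1/weight (weights first normalized by the strongest edge, so both
#' measures are scale-free and efficiency lies in \[0, 1\]), and the
#' weighted global clustering coefficient. Disconnected node pairs are
#' excluded from the path length (their fraction is reported) and
#' contribute 0 to efficiency.
#'
#' @param net An `igraph` graph with a `weight` edge attribute (e.g. from
#'   [build_network()]); edges with non-positive weight are dropped
#'   before any computation.
#' @param seed Integer seed controlling the Louvain restarts.
#' @param distance `"inverse"` (1/weight, default) or `"max_minus"`
#'   (max weight minus weight) edge-distance transform.
#' @param clustering `"onnela"` (weighted transitivity, default) or
#'   `"binary"`.
#' @return A one-row tibble: `modularity`, `aspl`, `clustering`,
#'   `efficiency`, `disconnected_fraction`, `n_nodes`, `n_edges`.
#' @export
network_metrics <- function(net, seed = 1,
                            distance = c("inverse", "max_minus"),
                            clustering = c("onnela", "binary")) {
  distance <- match.arg(distance)
  clustering <- match.arg(clustering)
  stopifnot(igraph::is_igraph(net))
  w_all <- igraph::E(net)$weight
  g <- igraph::delete_edges(net, igraph::E(net)[w_all <= 0])
  n <- igraph::vcount(g)
  if (n < 3) {
    stop("metrics are undefined for networks with fewer than 3 nodes",
         call. = FALSE)
  }
  w <- igraph::E(g)$weight
  m <- igraph::ecount(g)

  # Louvain: igraph's implementation is stochastic; fix the RNG and keep
  # the best of 10 restarts (first-found on ties)
  best_q <- -Inf
  best_membership <- rep(1L, n)
  if (m > 0) {
    for (i in 1:10) {
      set.seed(seed_stream(seed, 7000 + i))
      cl <- igraph::cluster_louvain(g, weights = w, resolution = 1)
      q <- igraph::modularity(g, igraph::membership(cl), weights = w)
      if (q > best_q) {
        best_q <- q
        best_membership <- igraph::membership(cl)
      }
    }
  } else {
    best_q <- NA_real_
  }

  # distances use weights normalized by the strongest edge, so that one
  # hop along the strongest collocation has distance 1 and efficiency is
  # bounded by 1 regardless of the weight scale
  dist_w <- if (m == 0) numeric(0) else switch(distance,
    inverse = max(w) / w,
    max_minus = (max(w) - w) / max(w))
  D <- igraph::distances(g, weights = dist_w)
  ut <- upper.tri(D)
  dvals <- D[ut]
  finite <- is.finite(dvals)
  aspl <- if (any(finite)) mean(dvals[finite]) else NA_real_
  efficiency <- mean(ifelse(finite, 1 / dvals, 0))

  clust <- if (clustering == "binary") {
    tval <- igraph::transitivity(g, type = "global")
    if (is.nan(tval)) 0 else tval
  } else {
    onnela_clustering(g)
  }

  tibble::tibble(modularity = best_q, aspl = aspl, clustering = clust,
                 efficiency = efficiency,
                 disconnected_fraction = mean(!finite),
                 n_nodes = n, n_edges = m)
}

# Onnela weighted global clustering: local coefficients
# c_i = (W_hat^(1/3))^3_ii / (k_i (k_i - 1)) with weights normalized by
# the maximum, averaged over nodes of degree >= 2.
onnela_clustering <- function(g) {
  W <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  if (max(W) <= 0) return(0)
  What <- (W / max(W))^(1 / 3)
  cube <- What %*% What %*% What
  k <- rowSums(W > 0)
  use <- k >= 2
  if (!any(use)) return(0)
  mean(diag(cube)[use] / (k[use] * (k[use] - 1)))
}

#' Per-stimulus associative and network profiles
#'
#' Convenience wrapper running [hierarchy_stats()], [build_network()] and
#' [network_metrics()] for every stimulus in a cleaned norms table.
#'
#' @param norms Cleaned norms tibble.
#' @param seed Integer seed (Louvain restarts).
#' @param ... Passed to [network_metrics()].
#' @return A tibble with one row per stimulus: hierarchy statistics
#'   joined to network metrics (metrics are `NA` for networks with fewer
#'   than 3 nodes).
#' @export
stimulus_profiles <- function(norms, seed = 1, ...) {
  stims <- unique(norms$stimulus_id)
  rows <- lapply(seq_along(stims), function(i) {
    s <- stims[i]
    freqs <- norm_frequencies(norms, s)
    h <- hierarchy_stats(as.numeric(freqs))
    net <- build_network(norms, s)
    mets <- if (igraph::vcount(net) >= 3) {
      network_metrics(net, seed = seed_stream(seed, 50000 + i), ...)
    } else {
      tibble::tibble(modularity = NA_real_, aspl = NA_real_,
                     clustering = NA_real_, efficiency = NA_real_,
                     disconnected_fraction = NA_real_,
                     n_nodes = igraph::vcount(net), n_edges = 0L)
    }
    dplyr::bind_cols(tibble::tibble(stimulus_id = s), h, mets)
  })
  dplyr::bind_rows(rows)
}
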