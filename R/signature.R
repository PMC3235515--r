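#' @useDynLib dbcbin, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' All k-words in lexicographic order (A < C < G < T)
#'
#' @param k Word length.
#' @return Character vector of length `4^k`.
#' @keywords internal
kmer_words <- function(k) {
  sort(Biostrings::mkAllStrings(c("A", "C", "G", "T"), k))
}

#' Count double-stranded k-words and (k+1)-words of a sequence
#'
#' Slides windows of length `k` and `k+1` over every ACGT segment of the
#' sequence and of its reverse complement, so that every word count equals
#' the count of its reverse complement (double-stranded counting). Windows
#' never span an ambiguous position: the sequence is first split by
#' [sanitize_sequence()].
#'
#' @param record A sequence record (one row of a [read_fasta()] data frame)
#'   or a plain nucleotide string.
#' @param k Word length (chain order), an integer >= 1.
#' @return An object of class `kmer_count_table`: list with `k`,
#'   `node_counts` (named integer vector over all `4^k` words),
#'   `edge_counts` (over all `4^(k+1)` words) and `total_edges`.
#' @export
count_words <- function(record, k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    stop("k must be a single integer >= 1", call. = FALSE)
  }
  seq <- if (is.character(record)) record[1] else record$sequence[1]
  segs <- sanitize_sequence(seq)
  if (length(segs) == 0) {
    segs <- character(0)
    both <- Biostrings::DNAStringSet()
  } else {
    fwd <- Biostrings::DNAStringSet(segs)
    both <- c(fwd, Biostrings::reverseComplement(fwd))
  }
  count_width <- function(w) {
    if (length(both) == 0) {
      stats::setNames(integer(4^w), kmer_words(w))
    } else {
      colSums(Biostrings::oligonucleotideFrequency(both, width = w))
    }
  }
  node_counts <- count_width(k)
  edge_counts <- count_width(k + 1)
  structure(list(k = as.integer(k),
                 node_counts = node_counts,
                 edge_counts = edge_counts,
                 total_edges = sum(edge_counts)),
            class = "kmer_count_table")
}

#' Build the de Bruijn chain of a count table
#'
#' The observed nodes are the k-words occurring as the prefix or the suffix
#' of a counted (k+1)-word. The raw transition probability from node `u` to
#' node `v` is the count of the (k+1)-word `u + last(v)` divided by the total
#' count of (k+1)-words with prefix `u`; nodes with no counted outgoing edge
#' get a uniform raw row. The damped matrix mixes the raw matrix with the
#' uniform kernel over observed nodes, which makes the chain irreducible and
#' aperiodic so that a unique stationary distribution exists.
#'
#' Strongly connected components are computed on the observed-edge graph
#' (positive (k+1)-word counts only; the uniform fill of dangling rows is a
#' numerical device, not an observed transition). Each component's mass is
#' the share of total (k+1)-word count carried by edges leaving its nodes.
#'
#' @param counts A `kmer_count_table` with `total_edges > 0`.
#' @param lambda Damping weight in (0, 1); default 0.01.
#' @return An object of class `debruijn_chain`: list with `k`, `nodes`,
#'   `P_raw`, `P` (damped), `lambda`, `membership` (component id per node),
#'   `component_mass` and `total_edges`.
#' @export
build_chain <- function(counts, lambda = 0.01) {
  stopifnot(inherits(counts, "kmer_count_table"))
  if (!(lambda > 0 && lambda < 1)) {
    stop("lambda must lie strictly between 0 and 1", call. = FALSE)
  }
  if (counts$total_edges == 0) {
    stop(errorCondition(
      "sequence too short for this word length (no (k+1)-word observed)",
      class = c("dbcbin_unsignable", "error", "condition")))
  }
  k <- counts$k
  e <- counts$edge_counts[counts$edge_counts > 0]
  ew <- names(e)
  pre <- substr(ew, 1, k)
  suf <- substr(ew, 2, k + 1)
  nodes <- sort(unique(c(pre, suf)))
  n <- length(nodes)
  C <- matrix(0, n, n, dimnames = list(nodes, nodes))
  C[cbind(match(pre, nodes), match(suf, nodes))] <- e
  out_mass <- rowSums(C)
  P_raw <- C / ifelse(out_mass > 0, out_mass, 1)
  P_raw[out_mass == 0, ] <- 1 / n
  P <- (1 - lambda) * P_raw + lambda / n

  g <- igraph::graph_from_data_frame(
    data.frame(from = pre, to = suf, stringsAsFactors = FALSE),
    directed = TRUE, vertices = nodes)
  comp <- igraph::components(g, mode = "strong")
  membership <- comp$membership[nodes]
  component_mass <- as.numeric(tapply(out_mass, membership, sum)) /
    counts$total_edges
  names(component_mass) <- names(tapply(out_mass, membership, sum))

  structure(list(k = k, nodes = nodes, P_raw = P_raw, P = P,
                 lambda = lambda, membership = membership,
                 component_mass = component_mass,
                 total_edges = counts$total_edges),
            class = "debruijn_chain")
}

#' Stationary distribution of a damped de Bruijn chain
#'
#' Power iteration from the uniform vector; convergence is declared when
#' successive iterates differ by at most `tol` in the max norm. Because the
#' iterate update is `x P`, the final successive difference is also the
#' stationarity residual `||pi P - pi||_inf`.
#'
#' @param chain A `debruijn_chain` (damped, `lambda > 0`).
#' @param tol Convergence tolerance in max norm (default 1e-12).
#' @param max_iter Iteration cap (default 10000); exceeding it is an error,
#'   never a silent truncation.
#' @return Named numeric vector over `chain$nodes`, non-negative, sum 1.
#' @export
stationary_distribution <- function(chain, tol = 1e-12, max_iter = 10000) {
  stopifnot(inherits(chain, "debruijn_chain"))
  n <- length(chain$nodes)
  x <- rep(1 / n, n)
  for (i in seq_len(max_iter)) {
    x_new <- as.vector(x %*% chain$P)
    if (max(abs(x_new - x)) <= tol) {
      return(stats::setNames(x_new / sum(x_new), chain$nodes))
    }
    x <- x_new
  }
  stop("power iteration did not converge within ", max_iter,
       " iterations (tol = ", tol, ")", call. = FALSE)
}

#' Component-connectivity weight of every node
#'
#' Each node is weighted by the edge-count mass of its strongly connected
#' component: the share of all counted (k+1)-words whose prefix node lies in
#' that component. Nodes in one component share one weight; the weights of
#' distinct components sum to 1.
#'
#' @param chain A `debruijn_chain`.
#' @return Named numeric vector over `chain$nodes`, values in \[0, 1\].
#' @export
connectivity_weights <- function(chain) {
  stopifnot(inherits(chain, "debruijn_chain"))
  w <- chain$component_mass[as.character(chain$membership)]
  stats::setNames(as.numeric(w), chain$nodes)
}

#' Compute the de Bruijn chain signature of a sequence
#'
#' The signature entry of an observed node `u` is `pi(u) * w(u)` — the
#' stationary probability of the word times the connectivity weight of its
#' strongly connected component — renormalized to sum 1 and embedded at the
#' word's lexicographic index in a length-`4^k` vector. Unobserved words get
#' zero. Because word counting is double-stranded, a sequence and its
#' reverse complement yield identical signatures.
#'
#' @param record A sequence record or plain nucleotide string.
#' @param k Word length (2-4 is the intended range; any `k >= 1` works).
#' @param lambda Damping weight passed to [build_chain()].
#' @param tol Power-iteration tolerance passed to
#'   [stationary_distribution()].
#' @return An object of class `dbc_signature`: list with `k`, `s` (named
#'   length-`4^k` vector, non-negative, sum 1), and the provenance pieces
#'   `pi` and `w` over observed nodes.
#' @export
compute_signature <- function(record, k = 3, lambda = 0.01, tol = 1e-12) {
  counts <- count_words(record, k)
  chain <- build_chain(counts, lambda = lambda)
  pi_vec <- stationary_distribution(chain, tol = tol)
  w <- connectivity_weights(chain)
  raw <- pi_vec * w
  if (sum(raw) <= 0) {
    stop(errorCondition("degenerate signature: all node weights are zero",
                        class = c("dbcbin_unsignable", "error", "condition")))
  }
  s <- stats::setNames(numeric(4^k), kmer_words(k))
  s[chain$nodes] <- raw / sum(raw)
  structure(list(k = as.integer(k), s = s, pi = pi_vec, w = w,
                 lambda = lambda, tol = tol),
            class = "dbc_signature")
}

#' Distance between two signatures
#'
#' Euclidean distance between the two length-`4^k` vectors is the default;
#' cosine distance (`1 - cos`) is available as an alternative. Accepts
#' `dbc_signature` objects or bare numeric vectors (e.g. bin centroids).
#'
#' @param a,b Signatures of equal order.
#' @param metric `"euclidean"` (default) or `"cosine"`.
#' @return A non-negative scalar; zero iff the vectors are equal.
#' @export
signature_distance <- function(a, b, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  va <- if (inherits(a, "dbc_signature")) a$s else a
  vb <- if (inherits(b, "dbc_signature")) b$s else b
  if (length(va) != length(vb)) {
    stop("signature order mismatch: vectors of length ", length(va),
         " and ", length(vb), call. = FALSE)
  }
  if (metric == "euclidean") {
    sqrt(sum((va - vb)^2))
  } else {
    1 - sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
  }
}

#' @export
print.dbc_signature <- function(x, ...) {
  cat("DBC signature: k =", x$k, "|", sum(x$s > 0), "of", length(x$s),
      "words observed | lambda =", x$lambda, "\n")
  invisible(x)
}

#' @export
print.debruijn_chain <- function(x, ...) {
  cat("de Bruijn chain: k =", x$k, "|", length(x$nodes), "nodes |",
      length(x$component_mass), "strongly connected component(s) |",
      "lambda =", x$lambda, "\n")
  invisible(x)
}
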