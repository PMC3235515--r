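# Seed fanout: one user-facing seed yields independent, reproducible
# sub-streams per operation/index, so adding a model never shifts the
# sequences of the others. Kept below 2^31 - 1.
.sub_seed <- function(seed, index) {
  (as.numeric(seed) + 1000003 * as.numeric(index)) %% 2147483629
}

#' Generate a family of order-m genome composition models
#'
#' Each model is an order-`m` Markov chain over nucleotides: a
#' `4^m` x 4 row-stochastic matrix giving the probability of the next base
#' given the preceding `m` bases. All models share one base composition
#' (rows drawn once from a symmetric Dirichlet); each model then mixes that
#' shared row with its own random "preference" row:
#' `row = (1 - separation) * base + separation * preference`. The
#' preference rows are spiky (Dirichlet with concentration 0.3), so
#' `separation` interpolates from identical models (0) to strongly distinct,
#' near-deterministic base preferences (1). The total-variation distance
#' between corresponding rows of two models scales linearly with
#' `separation`.
#'
#' @param n_models Number of models (>= 1).
#' @param separation Real in (0, 1\]; also accepts 0 for the identical-model
#'   limit.
#' @param seed Integer seed; generation is deterministic given it.
#' @param m Model order (default 3).
#' @return List of objects of class `genome_model`, each with `model_id`,
#'   `m` and `transitions` (`4^m` x 4 matrix, rows summing to 1, rownames =
#'   contexts, colnames = A, C, G, T).
#' @export
make_models <- function(n_models, separation, seed, m = 3) {
  stopifnot(n_models >= 1, m >= 1)
  if (!(separation >= 0 && separation <= 1)) {
    stop("separation must lie in [0, 1]", call. = FALSE)
  }
  contexts <- kmer_words(m)
  n_ctx <- length(contexts)
  rdirichlet <- function(n, alpha) {
    g <- matrix(stats::rgamma(n * 4, shape = alpha), nrow = n)
    g / rowSums(g)
  }
  set.seed(.sub_seed(seed, 0))
  base <- rdirichlet(n_ctx, 5)
  lapply(seq_len(n_models), function(i) {
    set.seed(.sub_seed(seed, i))
    pref <- rdirichlet(n_ctx, 0.3)
    trans <- (1 - separation) * base + separation * pref
    dimnames(trans) <- list(contexts, c("A", "C", "G", "T"))
    structure(list(model_id = paste0("model_", i), m = as.integer(m),
                   transitions = trans),
              class = "genome_model")
  })
}

#' Sample a genome sequence from a composition model
#'
#' Base-by-base sampling from the order-`m` chain; the first `m` bases are
#' uniform. Deterministic given the seed.
#'
#' @param model A `genome_model`.
#' @param length Sequence length in bases (>= `m + 1`).
#' @param seed Integer seed.
#' @param id Record id (defaults to the model id).
#' @return A one-row sequence-record data frame (`id`, `description`,
#'   `sequence`, `length`).
#' @export
generate_genome <- function(model, length, seed, id = model$model_id) {
  stopifnot(inherits(model, "genome_model"))
  if (length < model$m + 1) {
    stop("length must be at least m + 1 = ", model$m + 1, call. = FALSE)
  }
  cum <- t(apply(model$transitions, 1, cumsum))
  set.seed(.sub_seed(seed, 0))
  u <- stats::runif(length)
  seq <- .sample_markov_cpp(cum, model$m, u)
  data.frame(id = id,
             description = paste0("synthetic order-", model$m,
                                  " Markov genome"),
             sequence = seq, length = nchar(seq), stringsAsFactors = FALSE)
}

#' Simulate a labeled metagenome with known bin membership
#'
#' Draws `n_per_model` contigs per model, with lengths log-uniform between
#' the bounds (echoing the length skew of assembled contigs), and records
#' the generating model of every contig in a truth table. Each contig is an
#' independent walk of its model, i.e. a fragment of a notional very long
#' genome.
#'
#' @param models List of `genome_model` objects.
#' @param n_per_model Contigs per model.
#' @param length_range Numeric `c(min, max)` contig length in bases
#'   (default 1000-20000).
#' @param seed Integer seed; all draws are reproducible from it.
#' @return An object of class `synthetic_metagenome`: list with `records`
#'   (sequence-record data frame), `truth` (a `truth_table` mapping each
#'   contig to its model id) and `params`.
#' @export
generate_metagenome <- function(models, n_per_model,
                                length_range = c(1000, 20000), seed) {
  stopifnot(is.list(models), length(models) >= 1,
            all(vapply(models, inherits, logical(1), "genome_model")),
            n_per_model >= 1)
  if (!(length(length_range) == 2 && length_range[1] >= 1 &&
        length_range[2] >= length_range[1])) {
    stop("length_range must be c(min, max) with 1 <= min <= max",
         call. = FALSE)
  }
  recs <- vector("list", length(models) * n_per_model)
  labels <- character(length(recs))
  idx <- 0
  for (mi in seq_along(models)) {
    model <- models[[mi]]
    set.seed(.sub_seed(seed, 100000 + mi))
    lens <- round(exp(stats::runif(n_per_model, log(length_range[1]),
                                   log(length_range[2]))))
    lens <- pmax(lens, model$m + 1)
    for (ci in seq_len(n_per_model)) {
      idx <- idx + 1
      id <- sprintf("%s_c%04d", model$model_id, ci)
      recs[[idx]] <- generate_genome(model, lens[ci],
                                     seed = .sub_seed(seed, 1000 * mi + ci),
                                     id = id)
      labels[idx] <- model$model_id
    }
  }
  records <- do.call(rbind, recs)
  structure(list(records = records,
                 truth = truth_table(stats::setNames(labels, records$id)),
                 params = list(n_models = length(models),
                               n_per_model = n_per_model,
                               length_range = length_range, seed = seed)),
            class = "synthetic_metagenome")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("Genome composition model '", x$model_id, "': order m = ", x$m,
      " (", nrow(x$transitions), " contexts)\n", sep = "")
  invisible(x)
}

#' @export
print.synthetic_metagenome <- function(x, ...) {
  cat("Synthetic metagenome:", nrow(x$records), "contig(s) from",
      x$params$n_models, "model(s), lengths",
      paste(x$params$length_range, collapse = "-"), "bp, seed",
      x$params$seed, "\n")
  invisible(x)
}
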