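# Shared fixture builders and independent oracles. Everything is generated
# in code under fixed seeds; no data files are read.

random_acgt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

write_tmp_fasta <- function(records, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = env)
  write_fasta(records, path)
  path
}

as_records <- function(seqs, ids = paste0("s", seq_along(seqs))) {
  data.frame(id = ids, description = "", sequence = seqs,
             length = nchar(seqs), stringsAsFactors = FALSE)
}

# Kosaraju-style strongly-connected-components oracle, independent of igraph:
# repeated forward/backward reachability by BFS over an adjacency list.
scc_oracle <- function(nodes, from, to) {
  adj <- split(to, factor(from, levels = nodes))
  radj <- split(from, factor(to, levels = nodes))
  reach <- function(start, edges) {
    seen <- start
    frontier <- start
    while (length(frontier) > 0) {
      nxt <- setdiff(unique(unlist(edges[frontier], use.names = FALSE)), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  }
  comp <- rep(NA_integer_, length(nodes))
  names(comp) <- nodes
  cid <- 0
  for (v in nodes) {
    if (is.na(comp[v])) {
      cid <- cid + 1
      members <- intersect(reach(v, adj), reach(v, radj))
      comp[members] <- cid
    }
  }
  comp
}

# leading left-eigenvector oracle for stationary distributions
stationary_eigen_oracle <- function(P) {
  e <- eigen(t(P))
  i <- which.max(Re(e$values))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  stats::setNames(v, rownames(P))
}

# build a bin_assignments object directly from a status/bin table, for
# evaluation tests that need hand-built confusion fixtures
manual_assignments <- function(df, report_top_n = max(
    as.integer(sub("^bin_", "", grep("^bin_", names(df), value = TRUE))))) {
  params <- binning_params(report_top_n = report_top_n)
  statuses <- c("binned", "unbinned_short", "unbinned_distance",
                "unbinned_unsignable")
  by_status <- vapply(statuses, function(s) sum(df$status == s), integer(1))
  structure(list(assignments = df,
                 summary = list(by_status = by_status, n_total = nrow(df)),
                 params = params),
            class = "bin_assignments")
}

# independent reimplementation of the scoring rules using explicit loops
score_oracle <- function(assignments, truth, top_n) {
  df <- assignments$assignments
  tp <- fp <- tn <- fn <- 0
  for (i in seq_len(nrow(df))) {
    tb <- truth$bin_of[[df$sequence_id[i]]]
    binned <- df$status[i] == "binned"
    tops <- unlist(df[i, paste0("bin_", seq_len(top_n))], use.names = FALSE)
    if (tb == "NO_BIN") {
      if (binned) fp <- fp + 1 else tn <- tn + 1
    } else {
      if (binned && tb %in% tops[!is.na(tops)]) tp <- tp + 1 else fn <- fn + 1
    }
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

# train one bin per model from freshly generated fragments (held out from
# any query set by using a disjoint seed stream)
train_library_from_models <- function(models, k = 3, n_frags = 20,
                                      frag_lengths = c(1000, 20000),
                                      seed = 990001) {
  bins <- lapply(seq_along(models), function(mi) {
    m <- models[[mi]]
    set.seed(seed + mi)
    lens <- round(exp(stats::runif(n_frags, log(frag_lengths[1]),
                                   log(frag_lengths[2]))))
    frs <- do.call(rbind, lapply(seq_len(n_frags), function(i) {
      generate_genome(m, lens[i], seed = seed + 1000 * mi + i,
                      id = sprintf("%s_train%02d", m$model_id, i))
    }))
    build_bin(m$model_id, frs, k = k)
  })
  list(bins = bins, library = build_library(bins))
}
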