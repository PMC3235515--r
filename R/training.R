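#' Build a named bin from training sequences
#'
#' Computes one DBC signature per qualifying training record and takes the
#' unweighted arithmetic mean as the bin centroid. Records shorter than
#' `min_train_length` (or too short to be signable at order `k`) are skipped
#' and counted; training fails only if no record qualifies. A
#' length-weighted centroid (weights proportional to record length) is
#' available but is not the default.
#'
#' @param name Bin name, a unique token.
#' @param records Data frame of sequence records ([read_fasta()] layout).
#' @param k,lambda,tol Signature parameters, see [compute_signature()].
#' @param min_train_length Minimum training-record length in bases
#'   (default 1000, the same cutoff used when binning).
#' @param taxon_label Optional free-text lineage string (e.g.
#'   `"Bacteria;Proteobacteria;Gammaproteobacteria"`).
#' @param weight_by_length If `TRUE`, centroid entries are the
#'   length-weighted mean of member entries.
#' @return An object of class `dbc_bin`: list with `name`, `taxon_label`,
#'   `k`, `centroid` (named length-`4^k` vector), `members` (matrix, one row
#'   per member signature), `member_ids`, `n_members`, `n_bases_trained`,
#'   `n_skipped`.
#' @export
build_bin <- function(name, records, k = 3, lambda = 0.01, tol = 1e-12,
                      min_train_length = 1000, taxon_label = "",
                      weight_by_length = FALSE) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name),
            is.data.frame(records), nrow(records) >= 1)
  ok <- records$length >= max(k + 1, min_train_length)
  n_skipped <- sum(!ok)
  use <- records[ok, , drop = FALSE]
  sigs <- list()
  ids <- character(0)
  for (i in seq_len(nrow(use))) {
    sig <- tryCatch(
      compute_signature(use$sequence[i], k = k, lambda = lambda, tol = tol),
      dbcbin_unsignable = function(e) NULL)
    if (is.null(sig)) {
      n_skipped <- n_skipped + 1
    } else {
      sigs[[length(sigs) + 1]] <- sig$s
      ids <- c(ids, use$id[i])
    }
  }
  if (length(sigs) == 0) {
    stop("bin '", name, "': no training record of length >= ",
         max(k + 1, min_train_length), " could be signed", call. = FALSE)
  }
  members <- do.call(rbind, sigs)
  rownames(members) <- ids
  lens <- use$length[match(ids, use$id)]
  centroid <- if (weight_by_length) {
    colSums(members * (lens / sum(lens)))
  } else {
    colMeans(members)
  }
  if (n_skipped > 0) {
    message("bin '", name, "': skipped ", n_skipped,
            " record(s) below the training length cutoff")
  }
  structure(list(name = name, taxon_label = taxon_label, k = as.integer(k),
                 centroid = centroid, members = members, member_ids = ids,
                 n_members = length(ids), n_bases_trained = sum(lens),
                 n_skipped = n_skipped),
            class = "dbc_bin")
}

#' Assemble bins into a signature library
#'
#' @param bins List of `dbc_bin` objects sharing one order `k`.
#' @param lambda,tol,metric Creation parameters recorded as metadata (the
#'   metric name is advisory: it is the distance used when classifying
#'   against this library).
#' @return An object of class `signature_library`: list with `k`, `lambda`,
#'   `tol`, `metric`, `version` and `bins`, a named list of per-bin entries
#'   (`name`, `taxon_label`, `n_members`, `n_bases_trained`, `centroid`).
#' @export
build_library <- function(bins, lambda = 0.01, tol = 1e-12,
                          metric = "euclidean") {
  stopifnot(is.list(bins), length(bins) >= 1,
            all(vapply(bins, inherits, logical(1), "dbc_bin")))
  ks <- vapply(bins, function(b) b$k, integer(1))
  if (length(unique(ks)) != 1) {
    stop("all bins in a library must share one word length k", call. = FALSE)
  }
  names_ <- vapply(bins, function(b) b$name, character(1))
  if (anyDuplicated(names_)) {
    stop("duplicate bin name: ", names_[duplicated(names_)][1], call. = FALSE)
  }
  entries <- lapply(bins, function(b) {
    list(name = b$name, taxon_label = b$taxon_label,
         n_members = b$n_members, n_bases_trained = b$n_bases_trained,
         centroid = b$centroid)
  })
  names(entries) <- names_
  structure(list(k = ks[1], lambda = lambda, tol = tol, metric = metric,
                 version = 1L, bins = entries),
            class = "signature_library")
}

#' Train a signature library from FASTA files
#'
#' One bin per distinct label; paths that share a label are pooled into a
#' single bin, so several isolate genomes can train one taxon's bin.
#'
#' @param fasta_paths Character vector of FASTA paths.
#' @param labels Bin name per path (same length as `fasta_paths`).
#' @param taxon_labels Optional lineage string per path; for pooled labels
#'   the first non-empty one is kept.
#' @inheritParams build_bin
#' @param metric Distance metric name recorded in the library metadata.
#' @return A `signature_library`.
#' @export
precompute_signatures <- function(fasta_paths, labels, k = 3, lambda = 0.01,
                                  tol = 1e-12, min_train_length = 1000,
                                  taxon_labels = NULL, metric = "euclidean") {
  stopifnot(length(fasta_paths) == length(labels), length(fasta_paths) >= 1)
  missing <- fasta_paths[!file.exists(fasta_paths)]
  if (length(missing) > 0) {
    stop("training FASTA not readable: ", missing[1], call. = FALSE)
  }
  if (is.null(taxon_labels)) taxon_labels <- rep("", length(fasta_paths))
  bins <- lapply(unique(labels), function(lab) {
    paths <- fasta_paths[labels == lab]
    recs <- do.call(rbind, lapply(paths, read_fasta))
    tl <- taxon_labels[labels == lab]
    tl <- if (any(nzchar(tl))) tl[nzchar(tl)][1] else ""
    build_bin(lab, recs, k = k, lambda = lambda, tol = tol,
              min_train_length = min_train_length, taxon_label = tl)
  })
  build_library(bins, lambda = lambda, tol = tol, metric = metric)
}

#' Save a signature library as tab-separated text
#'
#' The format is diff-able plain text: a commented header block carrying the
#' format version and creation parameters, a commented column line, then one
#' row per bin with `4^k` centroid values serialized at 17 significant
#' digits (bit-exact round trip for doubles).
#'
#' @param lib A `signature_library` with at least one bin.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_library <- function(lib, path) {
  stopifnot(inherits(lib, "signature_library"))
  if (length(lib$bins) == 0) {
    stop("refusing to save an empty library (must contain >= 1 bin)",
         call. = FALSE)
  }
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    "# dbcbin_signature_library\tversion=1",
    sprintf("# k=%d\tlambda=%s\ttol=%s\tmetric=%s",
            lib$k, format(lib$lambda, digits = 17),
            format(lib$tol, digits = 17), lib$metric),
    sprintf("# columns: name\ttaxon_label\tn_members\tn_bases_trained\ts1..s%d",
            4^lib$k)), con)
  for (b in lib$bins) {
    writeLines(paste(c(b$name, b$taxon_label, b$n_members, b$n_bases_trained,
                       sprintf("%.17g", b$centroid)), collapse = "\t"), con)
  }
  invisible(path)
}

#' Load a signature library written by [save_library()]
#'
#' @param path Path to a library file.
#' @return A `signature_library`. Malformed files (wrong version, centroid
#'   row length inconsistent with the declared `k`, unparsable values) are
#'   errors that name the offending line.
#' @export
load_library <- function(path) {
  if (!file.exists(path)) stop("library file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4) stop("malformed library file: ", path, call. = FALSE)
  if (!grepl("^# dbcbin_signature_library\tversion=1$", lines[1])) {
    stop("line 1: unrecognized library format/version in ", path,
         call. = FALSE)
  }
  meta <- regmatches(lines[2],
                     regexec("^# k=(\\d+)\tlambda=([^\t]+)\ttol=([^\t]+)\tmetric=(\\S+)$",
                             lines[2]))[[1]]
  if (length(meta) != 5) {
    stop("line 2: malformed metadata header in ", path, call. = FALSE)
  }
  k <- as.integer(meta[2])
  lambda <- as.numeric(meta[3])
  tol <- as.numeric(meta[4])
  metric <- meta[5]
  words <- kmer_words(k)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(body) == 0) stop("library file has no bins: ", path, call. = FALSE)
  entries <- list()
  for (ln in body) {
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 4 + 4^k) {
      stop("line ", ln, ": expected ", 4 + 4^k, " columns for k=", k,
           ", found ", length(fields), call. = FALSE)
    }
    centroid <- suppressWarnings(as.numeric(fields[-(1:4)]))
    if (anyNA(centroid)) {
      stop("line ", ln, ": unparsable centroid value", call. = FALSE)
    }
    name <- fields[1]
    if (name %in% names(entries)) {
      stop("line ", ln, ": duplicate bin name '", name, "'", call. = FALSE)
    }
    entries[[name]] <- list(name = name, taxon_label = fields[2],
                            n_members = as.integer(fields[3]),
                            n_bases_trained = as.numeric(fields[4]),
                            centroid = stats::setNames(centroid, words))
  }
  structure(list(k = k, lambda = lambda, tol = tol, metric = metric,
                 version = 1L, bins = entries),
            class = "signature_library")
}

#' Select bins whose taxon label starts with a prefix
#'
#' Stands in for picking a node of a taxonomy tree: all bins whose lineage
#' string begins with `prefix` (e.g. `"Bacteria;Proteobacteria"`) form the
#' returned sub-library.
#'
#' @param lib A `signature_library`.
#' @param prefix Lineage prefix to match.
#' @return A `signature_library` restricted to the matching bins.
#' @export
select_bins <- function(lib, prefix) {
  stopifnot(inherits(lib, "signature_library"))
  keep <- vapply(lib$bins, function(b) startsWith(b$taxon_label, prefix),
                 logical(1))
  if (!any(keep)) {
    stop("no bin has a taxon label starting with '", prefix, "'",
         call. = FALSE)
  }
  lib$bins <- lib$bins[keep]
  lib
}

#' Calibrate a distance cutoff from training bins
#'
#' Pools every member signature's distance to its own centroid and returns
#' a quantile of that pool. Used to turn on the `max_distance` cutoff so
#' that contigs unlike any training set are routed to the unbinned pool
#' rather than force-assigned to the nearest centroid.
#'
#' @param bins List of `dbc_bin` objects (with member signatures retained).
#' @param q Quantile of the pooled member-to-centroid distances
#'   (default 0.99).
#' @param metric Distance metric, see [signature_distance()].
#' @return A single non-negative number.
#' @export
calibrate_distance_cutoff <- function(bins, q = 0.99, metric = "euclidean") {
  stopifnot(is.list(bins), length(bins) >= 1)
  d <- unlist(lapply(bins, function(b) {
    apply(b$members, 1, function(m) signature_distance(m, b$centroid,
                                                       metric = metric))
  }))
  as.numeric(stats::quantile(d, q, names = FALSE, type = 7))
}

#' @export
print.signature_library <- function(x, ...) {
  cat("DBC signature library: k =", x$k, "|", length(x$bins), "bin(s) |",
      "metric =", x$metric, "\n")
  for (b in x$bins) {
    cat(sprintf("  %-20s members=%-4d bases=%.0f %s\n", b$name, b$n_members,
                b$n_bases_trained, b$taxon_label))
  }
  invisible(x)
}

#' @export
print.dbc_bin <- function(x, ...) {
  cat("DBC bin '", x$name, "': k = ", x$k, ", ", x$n_members,
      " member(s), ", x$n_bases_trained, " training bases\n", sep = "")
  invisible(x)
}
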