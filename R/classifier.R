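#' Binning parameters
#'
#' Bundles the knobs of nearest-centroid classification. The defaults mirror
#' the intended use on assembled contigs: word length 3 (middle of the 2-4
#' range), a 1000-base minimum contig length, the best two bins reported,
#' and no distance cutoff (every signable contig above the length cutoff is
#' assigned; enable `max_distance`, e.g. via
#' [calibrate_distance_cutoff()], to route distant contigs to the unbinned
#' pool).
#'
#' @param k Word length (chain order).
#' @param lambda Damping weight, see [build_chain()].
#' @param tol Power-iteration tolerance.
#' @param metric Distance metric, `"euclidean"` or `"cosine"`.
#' @param min_length Minimum contig length in bases (default 1000).
#' @param max_distance Distance cutoff; `Inf` disables it.
#' @param report_top_n Number of ranked bins reported per contig
#'   (default 2).
#' @return An object of class `binning_params`.
#' @export
binning_params <- function(k = 3, lambda = 0.01, tol = 1e-12,
                           metric = "euclidean", min_length = 1000,
                           max_distance = Inf, report_top_n = 2) {
  stopifnot(k >= 1, lambda > 0, lambda < 1, tol > 0,
            min_length >= k + 1, max_distance >= 0, report_top_n >= 1)
  structure(list(k = as.integer(k), lambda = lambda, tol = tol,
                 metric = match.arg(metric, c("euclidean", "cosine")),
                 min_length = min_length, max_distance = max_distance,
                 report_top_n = as.integer(report_top_n)),
            class = "binning_params")
}

# distances from one signature to every centroid, ranked; ties broken by
# bin name so output is independent of library map order
.ranked_distances <- function(sig, lib, metric) {
  d <- vapply(lib$bins,
              function(b) signature_distance(sig, b$centroid, metric = metric),
              numeric(1))
  ord <- order(d, names(d), method = "radix")
  d[ord]
}

#' Classify one contig against a signature library
#'
#' Computes the contig's DBC signature, its distance to every bin centroid,
#' and applies the length and distance cutoffs. Contigs failing a cutoff
#' are not silently dropped: the assignment status records why
#' (`unbinned_short`, `unbinned_unsignable`, `unbinned_distance`).
#'
#' @param record A sequence record (one row of a [read_fasta()] data frame)
#'   or a plain nucleotide string.
#' @param lib A `signature_library`.
#' @param params A `binning_params`; its `k` must match the library's.
#' @return An object of class `bin_assignment`: list with `sequence_id`,
#'   `status`, `ranked_bins` (named distance vector, non-decreasing, of
#'   length `report_top_n` when binned) and `best_distance`.
#' @export
classify_one <- function(record, lib, params = binning_params()) {
  stopifnot(inherits(lib, "signature_library"),
            inherits(params, "binning_params"))
  if (length(lib$bins) == 0) stop("library has no bins", call. = FALSE)
  if (params$k != lib$k) {
    stop("word-length mismatch: params k=", params$k, " but library k=",
         lib$k, call. = FALSE)
  }
  if (is.character(record)) {
    record <- data.frame(id = "query", sequence = record,
                         length = nchar(record), stringsAsFactors = FALSE)
  }
  id <- record$id[1]
  if (record$length[1] < params$min_length) {
    return(structure(list(sequence_id = id, status = "unbinned_short",
                          ranked_bins = NULL, best_distance = NA_real_),
                     class = "bin_assignment"))
  }
  sig <- tryCatch(
    compute_signature(record$sequence[1], k = params$k,
                      lambda = params$lambda, tol = params$tol),
    dbcbin_unsignable = function(e) NULL)
  if (is.null(sig)) {
    return(structure(list(sequence_id = id, status = "unbinned_unsignable",
                          ranked_bins = NULL, best_distance = NA_real_),
                     class = "bin_assignment"))
  }
  ranked <- .ranked_distances(sig, lib, params$metric)
  top <- ranked[seq_len(min(params$report_top_n, length(ranked)))]
  if (ranked[1] > params$max_distance) {
    return(structure(list(sequence_id = id, status = "unbinned_distance",
                          ranked_bins = top, best_distance = ranked[1]),
                     class = "bin_assignment"))
  }
  structure(list(sequence_id = id, status = "binned", ranked_bins = top,
                 best_distance = ranked[1]),
            class = "bin_assignment")
}

#' Bin a whole set of contigs
#'
#' Applies [classify_one()] to every record, preserving input order, and
#' tallies summary counts per status and per bin. Deterministic given the
#' inputs and parameters.
#'
#' @param records Data frame of sequence records.
#' @param lib A `signature_library`.
#' @param params A `binning_params`.
#' @return An object of class `bin_assignments`: list with `assignments`
#'   (data frame: `sequence_id`, `status`, `bin_1`, `distance_1`, ...,
#'   up to `report_top_n` ranked bins), `summary` (counts per status and
#'   per assigned bin) and `params`.
#' @export
bin_metagenome <- function(records, lib, params = binning_params()) {
  stopifnot(is.data.frame(records))
  n_top <- params$report_top_n
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    a <- tryCatch(
      classify_one(records[i, , drop = FALSE], lib, params),
      error = function(e) {
        stop("record '", records$id[i], "': ", conditionMessage(e),
             call. = FALSE)
      })
    bins <- rep(NA_character_, n_top)
    dists <- rep(NA_real_, n_top)
    if (!is.null(a$ranked_bins)) {
      m <- length(a$ranked_bins)
      bins[seq_len(m)] <- names(a$ranked_bins)
      dists[seq_len(m)] <- unname(a$ranked_bins)
    }
    row <- c(list(sequence_id = a$sequence_id, status = a$status),
             stats::setNames(as.list(bins), paste0("bin_", seq_len(n_top))),
             stats::setNames(as.list(dists),
                             paste0("distance_", seq_len(n_top))))
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  assignments <- if (nrow(records) == 0) {
    empty <- c(list(sequence_id = character(0), status = character(0)),
               stats::setNames(rep(list(character(0)), n_top),
                               paste0("bin_", seq_len(n_top))),
               stats::setNames(rep(list(numeric(0)), n_top),
                               paste0("distance_", seq_len(n_top))))
    as.data.frame(empty, stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  statuses <- c("binned", "unbinned_short", "unbinned_distance",
                "unbinned_unsignable")
  by_status <- vapply(statuses, function(s) sum(assignments$status == s),
                      integer(1))
  binned_rows <- assignments$status == "binned"
  by_bin <- vapply(names(lib$bins), function(b) {
    sum(binned_rows & assignments$bin_1 == b, na.rm = TRUE)
  }, integer(1))
  structure(list(assignments = assignments,
                 summary = list(by_status = by_status, by_bin = by_bin,
                                n_total = nrow(assignments)),
                 params = params),
            class = "bin_assignments")
}

#' Write assignments to a tab-separated file
#'
#' The file starts with `#` header lines recording the resolved parameters
#' for provenance, then a commented column line and one row per contig.
#'
#' @param x A `bin_assignments` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(x, path) {
  stopifnot(inherits(x, "bin_assignments"))
  p <- x$params
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    "# dbcbin_assignments\tversion=1",
    sprintf("# k=%d\tlambda=%s\ttol=%s\tmetric=%s\tmin_length=%s\tmax_distance=%s\ttop_n=%d",
            p$k, format(p$lambda, digits = 17), format(p$tol, digits = 17),
            p$metric, format(p$min_length), format(p$max_distance),
            p$report_top_n),
    paste0("# columns: ", paste(names(x$assignments), collapse = "\t"))), con)
  df <- x$assignments
  for (col in grep("^distance_", names(df))) {
    df[[col]] <- ifelse(is.na(df[[col]]), "NA", sprintf("%.17g", df[[col]]))
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, na = "NA")
  invisible(path)
}

#' Read an assignments file written by [write_assignments()]
#'
#' @param path Path to an assignments TSV.
#' @return A `bin_assignments` object (summary recomputed; `params` holds
#'   the values parsed from the header).
#' @export
read_assignments <- function(path) {
  if (!file.exists(path)) {
    stop("assignments file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^# dbcbin_assignments\tversion=1$",
                                   lines[1])) {
    stop("unrecognized assignments format in ", path, call. = FALSE)
  }
  kv <- strsplit(sub("^# ", "", lines[2]), "\t")[[1]]
  meta <- stats::setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
  cols <- strsplit(sub("^# columns: ", "", lines[3]), "\t")[[1]]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  df <- if (length(body) == 0) {
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                  cols), stringsAsFactors = FALSE)
  } else {
    utils::read.table(text = body, sep = "\t", col.names = cols,
                      stringsAsFactors = FALSE, na.strings = "NA",
                      colClasses = "character")
  }
  for (col in grep("^distance_", names(df))) df[[col]] <- as.numeric(df[[col]])
  params <- binning_params(
    k = as.integer(meta[["k"]]), lambda = as.numeric(meta[["lambda"]]),
    tol = as.numeric(meta[["tol"]]), metric = meta[["metric"]],
    min_length = as.numeric(meta[["min_length"]]),
    max_distance = as.numeric(meta[["max_distance"]]),
    report_top_n = as.integer(meta[["top_n"]]))
  statuses <- c("binned", "unbinned_short", "unbinned_distance",
                "unbinned_unsignable")
  by_status <- vapply(statuses, function(s) sum(df$status == s), integer(1))
  structure(list(assignments = df,
                 summary = list(by_status = by_status,
                                n_total = nrow(df)),
                 params = params),
            class = "bin_assignments")
}

#' @export
print.bin_assignments <- function(x, ...) {
  cat("Binning of", x$summary$n_total, "contig(s):\n")
  print(x$summary$by_status)
  invisible(x)
}
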