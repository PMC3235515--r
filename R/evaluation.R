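#' Read a truth table for cross-validation
#'
#' Two tab-separated columns: `sequence_id` and the true bin name. The
#' literal token `NO_BIN` marks contigs for which no trained bin exists
#' (the negative set used for specificity). `#`-prefixed lines are
#' comments.
#'
#' @param path Path to a truth TSV.
#' @return An object of class `truth_table`: list with `bin_of` (named
#'   character vector id -> true bin) and `no_bin_ids`.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("truth file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0) stop("empty truth table: ", path, call. = FALSE)
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) {
    ln <- which(lines == body[bad[1]])[1]
    stop("line ", ln, ": truth rows need exactly 2 tab-separated columns",
         call. = FALSE)
  }
  ids <- vapply(parts, `[`, character(1), 1)
  bins <- vapply(parts, `[`, character(1), 2)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in truth table: ", ids[duplicated(ids)][1],
         call. = FALSE)
  }
  truth_table(stats::setNames(bins, ids))
}

#' Construct a truth table from a named vector
#'
#' @param bin_of Named character vector mapping sequence id to true bin
#'   name; the value `"NO_BIN"` marks ids with no trained bin available.
#' @return A `truth_table`.
#' @export
truth_table <- function(bin_of) {
  stopifnot(is.character(bin_of), !is.null(names(bin_of)),
            all(nzchar(names(bin_of))))
  structure(list(bin_of = bin_of,
                 no_bin_ids = names(bin_of)[bin_of == "NO_BIN"]),
            class = "truth_table")
}

#' Mark truth entries with no matching library bin as negatives
#'
#' Any id whose true bin is absent from `bin_names` is moved to the
#' no-bin-available set (`NO_BIN`), e.g. after withholding a taxon's bin
#' from the training library.
#'
#' @param truth A `truth_table`.
#' @param bin_names Character vector of trained bin names (or a
#'   `signature_library`).
#' @return The updated `truth_table`.
#' @export
mark_missing_bins <- function(truth, bin_names) {
  stopifnot(inherits(truth, "truth_table"))
  if (inherits(bin_names, "signature_library")) {
    bin_names <- names(bin_names$bins)
  }
  b <- truth$bin_of
  b[!(b %in% bin_names)] <- "NO_BIN"
  truth_table(b)
}

#' Write a truth table as TSV
#'
#' @param truth A `truth_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_table"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("# dbcbin_truth\tcolumns: sequence_id\ttrue_bin", con)
  writeLines(paste(names(truth$bin_of), truth$bin_of, sep = "\t"), con)
  invisible(path)
}

#' Score assignments against a truth table
#'
#' A contig with a trained true bin counts as a true positive when its true
#' bin appears among its best `top_n` ranked bins, and as a false negative
#' when it is unbinned or its true bin is absent from the top `top_n`
#' (sensitivity is computed over contigs for which a bin exists). A contig
#' in the no-bin-available set counts as a true negative when it is
#' unbinned and as a false positive when it is binned anyway. Sensitivity
#' is `tp / (tp + fn)` and specificity `tn / (tn + fp)`; a zero denominator
#' leaves the ratio undefined (`NA`, printed as "n/a"), never coerced to 0
#' or 1.
#'
#' @param assignments A `bin_assignments` object.
#' @param truth A `truth_table` covering every assigned id.
#' @param top_n How many ranked bins may supply the correct match
#'   (default 1; 2 gives the best-two-bins rule). Must not exceed the
#'   `report_top_n` the assignments were produced with.
#' @return An object of class `evaluation_result`: counts `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity`, the confusion matrix (true bin x
#'   assigned bin, with an `<unbinned>` column) and `top_n`.
#' @export
score_assignments <- function(assignments, truth, top_n = 1) {
  stopifnot(inherits(assignments, "bin_assignments"),
            inherits(truth, "truth_table"))
  df <- assignments$assignments
  n_ranked <- length(grep("^bin_", names(df)))
  if (top_n > n_ranked) {
    stop("top_n = ", top_n, " exceeds the ", n_ranked,
         " ranked bins available in the assignments", call. = FALSE)
  }
  missing <- setdiff(df$sequence_id, names(truth$bin_of))
  if (length(missing) > 0) {
    stop("assignment id missing from truth table: ", missing[1],
         call. = FALSE)
  }
  true_bin <- truth$bin_of[df$sequence_id]
  binned <- df$status == "binned"
  top_cols <- paste0("bin_", seq_len(top_n))
  in_top <- rep(FALSE, nrow(df))
  for (col in top_cols) {
    in_top <- in_top | (!is.na(df[[col]]) & df[[col]] == true_bin)
  }
  has_bin <- true_bin != "NO_BIN"
  tp <- sum(has_bin & binned & in_top)
  fn <- sum(has_bin & !(binned & in_top))
  tn <- sum(!has_bin & !binned)
  fp <- sum(!has_bin & binned)

  assigned <- ifelse(binned, df$bin_1, "<unbinned>")
  confusion <- table(true = true_bin, assigned = assigned)

  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 confusion = confusion, top_n = top_n),
            class = "evaluation_result")
}

#' Sweep length and distance cutoffs
#'
#' Evaluates binning over a grid of `min_length` and `max_distance` values.
#' Signatures (and centroid distances) are computed once per contig and the
#' cutoffs are applied to the cached distances, so the sweep costs little
#' more than a single run.
#'
#' @param records Data frame of sequence records.
#' @param lib A `signature_library`.
#' @param truth A `truth_table`.
#' @param length_grid Numeric vector of `min_length` values.
#' @param distance_grid Numeric vector of `max_distance` values (`Inf`
#'   disables the cutoff).
#' @param params Base `binning_params` supplying `k`, `lambda`, `tol`,
#'   `metric` and `report_top_n`.
#' @param top_n `top_n` passed to [score_assignments()].
#' @return Data frame with one row per grid point: `min_length`,
#'   `max_distance`, `n_binned`, `sensitivity`, `specificity`.
#' @export
sweep_cutoffs <- function(records, lib, truth, length_grid, distance_grid,
                          params = binning_params(), top_n = 1) {
  stopifnot(length(length_grid) >= 1, length(distance_grid) >= 1)
  # cache: ranked distances per record, computed once
  cache <- lapply(seq_len(nrow(records)), function(i) {
    sig <- tryCatch(
      compute_signature(records$sequence[i], k = params$k,
                        lambda = params$lambda, tol = params$tol),
      dbcbin_unsignable = function(e) NULL)
    if (is.null(sig)) NULL else .ranked_distances(sig, lib, params$metric)
  })
  grid <- expand.grid(min_length = length_grid, max_distance = distance_grid,
                      KEEP.OUT.ATTRS = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(g) {
    p <- params
    p$min_length <- grid$min_length[g]
    p$max_distance <- grid$max_distance[g]
    asn <- .assignments_from_cache(records, cache, p)
    ev <- score_assignments(asn, truth, top_n = top_n)
    data.frame(min_length = p$min_length, max_distance = p$max_distance,
               n_binned = sum(asn$assignments$status == "binned"),
               sensitivity = ev$sensitivity, specificity = ev$specificity)
  })
  do.call(rbind, out)
}

# rebuild a bin_assignments object from cached ranked distances
.assignments_from_cache <- function(records, cache, params) {
  n_top <- params$report_top_n
  rows <- lapply(seq_len(nrow(records)), function(i) {
    ranked <- cache[[i]]
    bins <- rep(NA_character_, n_top)
    dists <- rep(NA_real_, n_top)
    if (records$length[i] < params$min_length) {
      status <- "unbinned_short"
    } else if (is.null(ranked)) {
      status <- "unbinned_unsignable"
    } else {
      m <- min(n_top, length(ranked))
      bins[seq_len(m)] <- names(ranked)[seq_len(m)]
      dists[seq_len(m)] <- unname(ranked)[seq_len(m)]
      status <- if (ranked[1] > params$max_distance) "unbinned_distance"
                else "binned"
    }
    c(list(sequence_id = records$id[i], status = status),
      stats::setNames(as.list(bins), paste0("bin_", seq_len(n_top))),
      stats::setNames(as.list(dists), paste0("distance_", seq_len(n_top))))
  })
  assignments <- do.call(rbind,
                         lapply(rows, as.data.frame,
                                stringsAsFactors = FALSE))
  statuses <- c("binned", "unbinned_short", "unbinned_distance",
                "unbinned_unsignable")
  by_status <- vapply(statuses, function(s) sum(assignments$status == s),
                      integer(1))
  structure(list(assignments = assignments,
                 summary = list(by_status = by_status,
                                n_total = nrow(assignments)),
                 params = params),
            class = "bin_assignments")
}

#' Write an evaluation report
#'
#' Confusion matrix as TSV plus a commented summary block.
#'
#' @param ev An `evaluation_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(ev, path) {
  stopifnot(inherits(ev, "evaluation_result"))
  con <- file(path, "wt")
  on.exit(close(con))
  fmt <- function(x) if (is.na(x)) "n/a" else sprintf("%.6f", x)
  writeLines(c(
    "# dbcbin_evaluation\tversion=1",
    sprintf("# top_n=%d\ttp=%d\tfp=%d\ttn=%d\tfn=%d", ev$top_n, ev$tp,
            ev$fp, ev$tn, ev$fn),
    sprintf("# sensitivity=%s\tspecificity=%s", fmt(ev$sensitivity),
            fmt(ev$specificity))), con)
  m <- as.data.frame.matrix(ev$confusion)
  writeLines(paste(c("true_bin", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], as.integer(m[i, ])), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' @export
print.evaluation_result <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "n/a" else sprintf("%.4f", v)
  cat("Binning evaluation (top-", x$top_n, " match):\n", sep = "")
  cat("  tp =", x$tp, " fp =", x$fp, " tn =", x$tn, " fn =", x$fn, "\n")
  cat("  sensitivity =", fmt(x$sensitivity),
      " specificity =", fmt(x$specificity), "\n")
  invisible(x)
}
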