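#' Construct a validated case set
#'
#' A case set holds the ground-truth labels for a diagnostic case
#' collection: one row per case, with an opaque unique `case_id` and a
#' strictly binary `label` (1 = disease present, 0 = absent). Optional
#' metadata columns (e.g. `group`, `site`) are carried along untouched.
#'
#' @param case_id character vector of unique, non-empty identifiers.
#' @param label binary vector (0/1) of disease status, positive class = 1.
#' @param ... optional equal-length metadata vectors, passed by name.
#' @return A `case_set`: a data frame with columns `case_id`, `label`
#'   (integer) and any metadata, carrying class `"case_set"`.
#' @examples
#' cs <- case_set(c("a", "b", "c"), c(1, 0, 0))
#' n_positive(cs)
#' @export
case_set <- function(case_id, label, ...) {
  case_id <- as.character(case_id)
  if (anyNA(case_id) || any(!nzchar(case_id)))
    stop("case_id must be non-empty and non-missing", call. = FALSE)
  if (anyDuplicated(case_id))
    stop("duplicate case_id: ",
         paste(unique(case_id[duplicated(case_id)]), collapse = ", "),
         call. = FALSE)
  if (length(label) != length(case_id))
    stop("label length must match case_id", call. = FALSE)
  if (anyNA(label) || !all(label %in% c(0, 1)))
    stop("labels must be strictly binary (0/1)", call. = FALSE)
  out <- data.frame(case_id = case_id, label = as.integer(label),
                    stringsAsFactors = FALSE)
  meta <- list(...)
  for (nm in names(meta)) out[[nm]] <- meta[[nm]]
  class(out) <- c("case_set", "data.frame")
  out
}

#' @rdname case_set
#' @param cases a `case_set`.
#' @export
n_positive <- function(cases) sum(cases$label == 1L)

#' @rdname case_set
#' @export
n_negative <- function(cases) sum(cases$label == 0L)

#' @export
print.case_set <- function(x, ...) {
  cat(sprintf("<case_set> %d cases: %d positive, %d negative\n",
              nrow(x), n_positive(x), n_negative(x)))
  invisible(x)
}

#' Construct a diagnosis set
#'
#' One source's probabilistic diagnoses: a map from case id to the
#' probability of disease, in the closed interval \[0, 1\]. The `kind`
#' records provenance (individual reader, crowd aggregate, swarm, machine
#' model, or the augmented human-in-the-loop combination); downstream
#' code uses it, e.g. to refuse AUC on mixed-scale augmented sets.
#'
#' @param source_id short label for the source.
#' @param probabilities named numeric vector, names are case ids.
#' @param kind one of `"reader"`, `"crowd_mean"`, `"crowd_majority"`,
#'   `"swarm"`, `"ml"`, `"augmented"`.
#' @param cases optional `case_set`; if given, every case id must be
#'   covered and vice versa.
#' @return A `diagnosis_set` object.
#' @export
diagnosis_set <- function(source_id, probabilities,
                          kind = c("reader", "crowd_mean", "crowd_majority",
                                   "swarm", "ml", "augmented"),
                          cases = NULL) {
  kind <- match.arg(kind)
  p <- probabilities
  if (is.null(names(p)) || any(!nzchar(names(p))))
    stop("probabilities must be named by case_id", call. = FALSE)
  if (anyDuplicated(names(p)))
    stop("duplicate case_id in probabilities", call. = FALSE)
  if (anyNA(p) || !is.numeric(p))
    stop("probabilities must be numeric and non-missing", call. = FALSE)
  if (any(p < 0 | p > 1))
    stop(sprintf("probability outside [0,1] for case '%s' in source '%s'",
                 names(p)[which(p < 0 | p > 1)[1L]], source_id),
         call. = FALSE)
  if (!is.null(cases)) {
    miss <- setdiff(cases$case_id, names(p))
    if (length(miss))
      stop(sprintf("source '%s' missing probability for case '%s'",
                   source_id, miss[1L]), call. = FALSE)
    extra <- setdiff(names(p), cases$case_id)
    if (length(extra))
      stop(sprintf("source '%s' has unknown case '%s'",
                   source_id, extra[1L]), call. = FALSE)
  }
  structure(list(source_id = as.character(source_id), kind = kind,
                 probabilities = p),
            class = "diagnosis_set")
}

#' @export
print.diagnosis_set <- function(x, ...) {
  cat(sprintf("<diagnosis_set> '%s' (%s), %d cases\n",
              x$source_id, x$kind, length(x$probabilities)))
  invisible(x)
}

#' Extract probabilities aligned to a case set
#'
#' @param diag a `diagnosis_set`.
#' @param cases a `case_set`; order of the result follows it.
#' @return numeric vector, one probability per case, named by case id.
#' @export
probs_for <- function(diag, cases) {
  p <- diag$probabilities[cases$case_id]
  if (anyNA(p))
    stop(sprintf("source '%s' missing probability for case '%s'",
                 diag$source_id, cases$case_id[which(is.na(p))[1L]]),
         call. = FALSE)
  p
}

same_coverage <- function(sets) {
  ids <- sort(names(sets[[1L]]$probabilities))
  for (s in sets[-1L])
    if (!identical(sort(names(s$probabilities)), ids)) return(FALSE)
  TRUE
}

#' Read a case/diagnosis table from CSV
#'
#' Fixed header contract: a `case_id` column, a binary `label` column,
#' then one column per source holding probabilities as decimals in
#' \[0, 1\] (never percent). Validation errors name the offending row and
#' column.
#'
#' @param path CSV file path.
#' @param kinds optional named character vector mapping source column
#'   names to diagnosis kinds; unnamed sources default to `"reader"`.
#' @return list with `cases` (a [case_set()]) and `diagnoses` (a named
#'   list of [diagnosis_set()], one per source column, row order
#'   preserved).
#' @export
read_case_table <- function(path, kinds = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(case_id = "character"))
  if (!all(c("case_id", "label") %in% names(df)))
    stop("case table must have 'case_id' and 'label' columns", call. = FALSE)
  cases <- case_set(df$case_id, df$label)
  src_cols <- setdiff(names(df), c("case_id", "label"))
  diagnoses <- list()
  for (col in src_cols) {
    v <- df[[col]]
    if (!is.numeric(v))
      stop(sprintf("column '%s': non-numeric probability", col),
           call. = FALSE)
    bad <- which(is.na(v) | v < 0 | v > 1)
    if (length(bad))
      stop(sprintf("column '%s', row %d: probability outside [0,1]",
                   col, bad[1L]), call. = FALSE)
    kind <- if (!is.null(kinds) && col %in% names(kinds)) kinds[[col]]
            else "reader"
    diagnoses[[col]] <- diagnosis_set(col, stats::setNames(v, df$case_id),
                                      kind = kind, cases = cases)
  }
  list(cases = cases, diagnoses = diagnoses)
}

#' Write a case/diagnosis table to CSV
#'
#' Inverse of [read_case_table()]: round-tripping reproduces identical
#' structures (probabilities to full double precision).
#'
#' @param cases a `case_set`.
#' @param diagnoses list of `diagnosis_set` covering the cases.
#' @param path output CSV path.
#' @export
write_case_table <- function(cases, diagnoses, path) {
  df <- data.frame(case_id = cases$case_id, label = cases$label,
                   stringsAsFactors = FALSE)
  for (d in diagnoses) df[[d$source_id]] <- unname(probs_for(d, cases))
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a metric report in human- and machine-readable form
#'
#' Emits `<stem>.json` (lossless, round-trips via [read_report()]) and
#' `<stem>.md` (an aligned markdown table mirroring the study's
#' per-source x per-metric layout: point \[lo, hi\]).
#'
#' @param report data frame of metric rows, as produced by
#'   [bootstrap_ci()] / [metric_table()].
#' @param stem output path without extension.
#' @return invisibly, the two file paths written.
#' @export
write_report <- function(report, stem) {
  json_path <- paste0(stem, ".json")
  md_path <- paste0(stem, ".md")
  jsonlite::write_json(report, json_path, digits = NA, na = "null")
  header <- c("source", "metric", "value", "ci_lo", "ci_hi")
  lines <- c(paste0("| ", paste(header, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(header)), collapse = "|"),
                    "|"))
  if (nrow(report)) {
    fmt <- function(x) ifelse(is.na(x), "", formatC(x, digits = 4,
                                                    format = "fg"))
    for (i in seq_len(nrow(report)))
      lines <- c(lines, paste0(
        "| ", report$source_id[i], " | ", report$metric[i], " | ",
        fmt(report$value[i]), " | ", fmt(report$ci_lo[i]), " | ",
        fmt(report$ci_hi[i]), " |"))
  }
  writeLines(lines, md_path)
  invisible(c(json = json_path, md = md_path))
}

#' @rdname write_report
#' @param path a `.json` report path written by [write_report()].
#' @export
read_report <- function(path) {
  df <- jsonlite::fromJSON(path)
  if (length(df) == 0L) return(empty_report())
  as.data.frame(df, stringsAsFactors = FALSE)
}

empty_report <- function() {
  data.frame(source_id = character(), metric = character(),
             value = numeric(), ci_lo = numeric(), ci_hi = numeric(),
             level = numeric(), n_boot = integer(),
             stringsAsFactors = FALSE)
}
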