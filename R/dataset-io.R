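# Plain-text I/O for signals and manifests, and stratified cross-validation
# fold assignment. Signal files are newline-delimited decimal text (one sample
# per line) for auditability; the manifest is a UTF-8 CSV with a header row.

#' Read a signal file (one decimal value per line)
#'
#' @param path file path
#' @return numeric vector of samples in file order
#' @export
read_signal_file <- function(path) {
  if (!file.exists(path)) stop("signal file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty signal file: ", path)
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop(sprintf("non-numeric value at line %d of %s: '%s'", bad, path, lines[bad]))
  }
  vals
}

#' Write a signal file readable by [read_signal_file()]
#'
#' @param samples finite numeric vector
#' @param path destination path
#' @export
write_signal_file <- function(samples, path) {
  if (length(samples) == 0) stop("refusing to write an empty signal")
  if (!is.numeric(samples) || !all(is.finite(samples)))
    stop("samples must all be finite before writing")
  writeLines(sprintf("%.12g", samples), path)
  invisible(path)
}

#' Write a signal set as per-signal files plus a manifest CSV
#'
#' @param set a [signal_set()]
#' @param dir destination directory (created if needed)
#' @return path of the manifest CSV
#' @export
write_dataset <- function(set, dir) {
  stopifnot(inherits(set, "signal_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(set$ids, ".txt"))
  for (i in seq_along(set$ids)) write_signal_file(set$signals[i, ], paths[i])
  man <- data.frame(id = set$ids, path = paste0(set$ids, ".txt"),
                    label = set$labels)
  for (col in c("material", "diameter_um", "seed"))
    if (col %in% names(set$meta)) man[[col]] <- set$meta[[col]]
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Load a dataset from a manifest CSV
#'
#' The manifest needs columns `id`, `path`, `label`; signal paths are resolved
#' relative to the manifest's directory unless absolute. All signals must have
#' the same length, and at most two classes are accepted (the classifiers are
#' binary).
#'
#' @param path manifest CSV path
#' @param positive_label class mapped to 1; default first alphabetically
#' @return a [signal_set()]
#' @export
load_manifest <- function(path, positive_label = NULL) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "path", "label")
  miss <- setdiff(need, names(man))
  if (length(miss)) stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  if (length(unique(man$label)) > 2)
    stop("manifest has ", length(unique(man$label)),
         " classes; binary classification requires exactly 2")
  base <- dirname(path)
  sigs <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    p <- man$path[i]
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    if (!file.exists(p))
      stop("signal file for id '", man$id[i], "' not found: ", p)
    sigs[[i]] <- read_signal_file(p)
  }
  lens <- lengths(sigs)
  if (length(unique(lens)) != 1)
    stop("signals have differing lengths: ", paste(unique(lens), collapse = ", "))
  meta <- man[setdiff(names(man), "path")]
  signal_set(do.call(rbind, sigs), man$label, ids = man$id, meta = meta,
             positive_label = positive_label)
}

#' Stratified k-fold assignment
#'
#' Partitions the signal ids into `k` folds so that within every class the
#' fold counts differ by at most one (label distributions are preserved and
#' every signal serves as a test sample exactly once). Classes are cycled with
#' staggered starting folds so total fold sizes also stay balanced. The
#' shuffle is deterministic under `seed`.
#'
#' @param set a [signal_set()]
#' @param k number of folds (study protocol: 3)
#' @param seed integer seed for the within-class shuffle
#' @return object of class `fold_assignment`: `k` and `fold_of`, a named
#'   integer vector mapping id to fold in `1..k`
#' @export
stratified_kfold <- function(set, k = 3L, seed = 1L) {
  stopifnot(inherits(set, "signal_set"))
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  classes <- sort(unique(set$labels))
  counts <- table(set$labels)
  small <- names(counts)[counts < k]
  if (length(small))
    stop("class(es) with fewer members than k: ", paste(small, collapse = ", "))
  fold_of <- integer(length(set$ids))
  names(fold_of) <- set$ids
  with_local_seed(seed, {
    for (ci in seq_along(classes)) {
      ids <- set$ids[set$labels == classes[ci]]
      ids <- sample(ids)
      fold_of[ids] <- ((seq_along(ids) - 1L + (ci - 1L)) %% k) + 1L
    }
  })
  structure(list(k = k, fold_of = fold_of), class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("<fold_assignment> k = %d; fold sizes: %s\n", x$k,
              paste(tabulate(x$fold_of, x$k), collapse = ", ")))
  invisible(x)
}
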