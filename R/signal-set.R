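# Labeled signal container shared by the simulator, I/O, denoising and
# evaluation modules.

#' Labeled set of backscattered signals
#'
#' Rows of `signals` are individual recordings; `labels` assigns each row a
#' class. For binary classification the class mapped to 1 is `positive_label`
#' (the class whose detection precision/recall is reported); by default the
#' first class in alphabetical order.
#'
#' @param signals numeric matrix, one signal per row, equal lengths
#' @param labels character or factor of class labels, one per row
#' @param ids unique signal identifiers; generated when missing
#' @param meta optional data.frame of per-signal metadata (diameters, seeds...)
#' @param positive_label class name mapped to 1; default first alphabetically
#' @param clean optional matrix of noise-free reference signals (same shape),
#'   available for simulated data
#' @param role one of NA, "train", "test"; augmentation refuses "test" sets
#' @return an object of class `signal_set`
#' @export
signal_set <- function(signals, labels, ids = NULL, meta = NULL,
                       positive_label = NULL, clean = NULL, role = NA_character_) {
  signals <- as.matrix(signals)
  if (!is.numeric(signals) || !all(is.finite(signals)))
    stop("signals must be a finite numeric matrix")
  labels <- as.character(labels)
  n <- nrow(signals)
  if (length(labels) != n) stop("one label per signal required")
  if (is.null(ids)) ids <- sprintf("sig%04d", seq_len(n))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("signal ids must be unique")
  classes <- sort(unique(labels))
  if (is.null(positive_label)) positive_label <- classes[1]
  if (!positive_label %in% classes)
    stop("positive_label '", positive_label, "' not among classes: ",
         paste(classes, collapse = ", "))
  if (!is.null(clean)) {
    clean <- as.matrix(clean)
    stopifnot(all(dim(clean) == dim(signals)))
  }
  if (is.null(meta)) meta <- data.frame(id = ids, label = labels)
  structure(list(signals = signals, labels = labels, ids = ids, meta = meta,
                 positive_label = positive_label, clean = clean, role = role),
            class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<signal_set> %d signals x %d samples; classes: %s; positive: %s%s\n",
              nrow(x$signals), ncol(x$signals),
              paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
              x$positive_label,
              if (is.na(x$role)) "" else paste0("; role: ", x$role)))
  invisible(x)
}

#' Binary 0/1 labels of a signal set
#'
#' 1 for the positive class, 0 otherwise. Requires exactly two classes.
#' @param set a [signal_set()]
#' @return integer vector of 0/1
#' @export
labels01 <- function(set) {
  stopifnot(inherits(set, "signal_set"))
  if (length(unique(set$labels)) != 2)
    stop("binary labels require exactly 2 classes, found ",
         length(unique(set$labels)))
  as.integer(set$labels == set$positive_label)
}

#' Subset a signal set by id or row index
#' @param set a [signal_set()]
#' @param which ids (character) or row indices
#' @param role role tag for the subset ("train"/"test"/NA)
#' @return a [signal_set()]
#' @export
subset_set <- function(set, which, role = set$role) {
  stopifnot(inherits(set, "signal_set"))
  idx <- if (is.character(which)) match(which, set$ids) else as.integer(which)
  if (anyNA(idx)) stop("unknown signal id(s): ",
                       paste(which[is.na(idx)], collapse = ", "))
  signal_set(set$signals[idx, , drop = FALSE], set$labels[idx], set$ids[idx],
             meta = set$meta[idx, , drop = FALSE],
             positive_label = set$positive_label,
             clean = if (!is.null(set$clean)) set$clean[idx, , drop = FALSE],
             role = role)
}

# per-signal normalization to unit maximum absolute amplitude
normalize_rows <- function(m) {
  s <- apply(abs(m), 1, max)
  s[s == 0] <- 1
  m / s
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  expr
}
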