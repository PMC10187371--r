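# Dataset container and plumbing: per-omics feature matrices, class labels,
# subject-by-omics availability mask, CSV readers/writers, mask synthesis at a
# target missing rate, and train/test splitting.

#' Construct a multi-omics dataset
#'
#' Bundles M per-omics feature matrices (rows = subjects, columns =
#' features), a vector of 0-based integer class labels, and an N x M logical
#' availability mask saying which omics layers each subject was assayed on.
#' Feature values for unavailable layers are placeholders (kept as zeros by
#' the writers) and are never read when the mask is \code{FALSE}.
#'
#' @param views list of numeric matrices, one per omics layer, all with the
#'   same number of rows (subjects, in identical order).
#' @param labels integer vector of class indices in \code{0..C-1}.
#' @param mask optional N x M logical (or 0/1) matrix; \code{NULL} means all
#'   layers available for all subjects.
#' @param view_names optional character vector naming the omics layers.
#' @param C optional class count; defaults to \code{max(labels) + 1}.
#' @return an object of class \code{omics_dataset} with elements
#'   \code{views}, \code{labels}, \code{mask}, \code{view_names}, \code{C}.
#' @export
omics_dataset <- function(views, labels, mask = NULL, view_names = NULL,
                          C = NULL) {
  stopifnot(is.list(views), length(views) >= 1L)
  views <- lapply(views, function(v) {
    v <- as.matrix(v)
    storage.mode(v) <- "double"
    v
  })
  N <- nrow(views[[1]])
  M <- length(views)
  for (i in seq_len(M)) {
    if (nrow(views[[i]]) != N)
      stop("dimension error: view ", i, " has ", nrow(views[[i]]),
           " rows but view 1 has ", N)
    if (ncol(views[[i]]) < 1L) stop("view ", i, " has no features")
    if (any(!is.finite(views[[i]])))
      stop("view ", i, " contains non-finite values")
  }
  labels <- as.integer(labels)
  if (length(labels) != N)
    stop("dimension error: ", length(labels), " labels for ", N, " subjects")
  if (any(labels < 0L)) stop("label error: labels must be non-negative")
  if (is.null(C)) C <- max(labels) + 1L
  C <- as.integer(C)
  if (C < 2L) stop("label error: need at least 2 classes")
  if (any(labels >= C))
    stop("label error: label ", max(labels), " outside 0..", C - 1L)
  if (is.null(mask)) {
    mask <- matrix(TRUE, N, M)
  } else {
    mask <- as.matrix(mask)
    mask <- mask != 0
    if (!all(dim(mask) == c(N, M)))
      stop("dimension error: mask must be ", N, " x ", M)
  }
  if (any(rowSums(mask) < 1L))
    stop("mask error: every subject needs at least one available omics layer")
  if (is.null(view_names)) view_names <- paste0("view", seq_len(M))
  structure(list(views = views, labels = labels, mask = mask,
                 view_names = view_names, C = C),
            class = "omics_dataset")
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat("omics_dataset:", nrow(x$mask), "subjects,", length(x$views),
      "omics layers,", x$C, "classes\n")
  for (i in seq_along(x$views))
    cat("  ", x$view_names[i], ": ", ncol(x$views[[i]]), " features\n", sep = "")
  cat("  missing rate:", format(mask_missing_rate(x$mask), digits = 3), "\n")
  invisible(x)
}

n_subjects <- function(ds) nrow(ds$mask)
n_views <- function(ds) length(ds$views)

mask_missing_rate <- function(mask) mean(rowSums(mask) < ncol(mask))

#' Generate an availability mask at a target missing rate
#'
#' The missing rate eta is the fraction of subjects lacking at least one
#' omics layer (eta = Nic / N). Exactly \code{round(eta * N)} subjects are
#' made incomplete; each incomplete subject drops a uniformly drawn number
#' of layers between 1 and M - 1, the layers themselves chosen uniformly
#' without replacement, so every subject retains at least one layer.
#'
#' @param N subject count.
#' @param M omics layer count.
#' @param eta target missing rate in \code{[0, 1]}.
#' @param seed integer seed controlling which subjects/layers are dropped.
#' @return an object of class \code{availability_mask}: a list with
#'   \code{entries} (N x M logical) and \code{eta} (achieved rate,
#'   \code{round(eta * N) / N}).
#' @examples
#' m <- make_missing_mask(10, 3, eta = 0.2, seed = 1)
#' sum(rowSums(m$entries) < 3)  # exactly 2 incomplete subjects
#' @export
make_missing_mask <- function(N, M, eta, seed = 0L) {
  if (!is.numeric(eta) || length(eta) != 1L || eta < 0 || eta > 1)
    stop("value error: eta must be a number in [0, 1]")
  stopifnot(N >= 1L, M >= 1L)
  if (M == 1L && eta > 0)
    stop("value error: a single omics layer cannot be dropped (M = 1, eta > 0)")
  n_ic <- round(eta * N)
  entries <- matrix(TRUE, N, M)
  if (n_ic > 0) {
    rng <- local_rng(seed)
    on.exit(rng(), add = TRUE)
    incomplete <- sample.int(N, n_ic)
    for (j in incomplete) {
      k <- if (M == 2L) 1L else sample.int(M - 1L, 1L)
      entries[j, sample.int(M, k)] <- FALSE
    }
  }
  structure(list(entries = entries, eta = n_ic / N),
            class = "availability_mask")
}

# Seed-scoped RNG: sets the seed, returns a restorer for the global state.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

# ---- CSV I/O ---------------------------------------------------------------

read_numeric_csv <- function(path) {
  first <- utils::read.csv(path, header = FALSE, nrows = 1,
                           colClasses = "character", check.names = FALSE)
  has_header <- any(is.na(suppressWarnings(as.numeric(unlist(first)))))
  df <- utils::read.csv(path, header = has_header, check.names = FALSE,
                        colClasses = "character")
  m <- suppressWarnings(matrix(as.numeric(as.matrix(df)), nrow(df), ncol(df)))
  if (any(is.na(m))) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("parse error in ", path, ": non-numeric cell at row ", bad[1L],
         ", column ", bad[2L])
  }
  colnames(m) <- if (has_header) colnames(df) else NULL
  m
}

#' Read a multi-omics dataset from CSV files
#'
#' Each feature file is a comma-separated matrix, one subject per row, with
#' an optional header of feature names. Labels are one non-negative integer
#' per line. The optional mask file is a 0/1 matrix with one column per
#' omics layer; absent mask means all layers are available.
#'
#' @param feature_paths character vector of per-omics CSV paths.
#' @param label_path path to the label CSV.
#' @param mask_path optional path to the availability-mask CSV.
#' @param view_names optional layer names; defaults to file base names.
#' @param C optional class count.
#' @return an \code{\link{omics_dataset}}.
#' @export
read_dataset <- function(feature_paths, label_path, mask_path = NULL,
                         view_names = NULL, C = NULL) {
  for (p in c(feature_paths, label_path, mask_path))
    if (!file.exists(p)) stop("file not found: ", p)
  views <- lapply(feature_paths, read_numeric_csv)
  ns <- vapply(views, nrow, 1L)
  if (length(unique(ns)) != 1L) {
    off <- which(ns != ns[1L])[1L]
    stop("dimension error: ", feature_paths[off], " has ", ns[off],
         " rows; expected ", ns[1L], " (from ", feature_paths[1L], ")")
  }
  lab <- read_numeric_csv(label_path)
  if (ncol(lab) != 1L) stop("label file must have a single column")
  labels <- as.vector(lab)
  if (any(labels != round(labels)) || any(labels < 0))
    stop("label error: labels must be non-negative integers")
  mask <- if (!is.null(mask_path)) read_numeric_csv(mask_path) else NULL
  if (is.null(view_names))
    view_names <- sub("\\.[^.]*$", "", basename(feature_paths))
  omics_dataset(views, labels, mask = mask, view_names = view_names, C = C)
}

#' Write a multi-omics dataset to CSV files plus a JSON manifest
#'
#' Inverse of \code{\link{read_dataset}}: writes one feature CSV per omics
#' layer (values at unavailable entries are zeroed), a one-column label CSV,
#' a 0/1 mask CSV, and \code{manifest.json} naming the files, layer names
#' and class count.
#'
#' @param ds an \code{\link{omics_dataset}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  feature_files <- paste0(ds$view_names, ".csv")
  for (i in seq_along(ds$views)) {
    v <- ds$views[[i]]
    v[!ds$mask[, i], ] <- 0  # placeholders, never read when mask is FALSE
    utils::write.table(v, file.path(dir, feature_files[i]), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(ds$labels, file.path(dir, "labels.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(ds$mask * 1L, file.path(dir, "mask.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  manifest <- list(feature_files = feature_files, label_file = "labels.csv",
                   mask_file = "mask.csv", view_names = ds$view_names,
                   C = ds$C, N = n_subjects(ds),
                   V = vapply(ds$views, ncol, 1L))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Read a dataset from a manifest directory written by write_dataset
#' @param dir directory containing \code{manifest.json}.
#' @return an \code{\link{omics_dataset}}.
#' @export
read_dataset_dir <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  read_dataset(file.path(dir, manifest$feature_files),
               file.path(dir, manifest$label_file),
               file.path(dir, manifest$mask_file),
               view_names = manifest$view_names, C = manifest$C)
}

# ---- subsetting / splitting ------------------------------------------------

subset_dataset <- function(ds, idx) {
  omics_dataset(lapply(ds$views, function(v) v[idx, , drop = FALSE]),
                ds$labels[idx], ds$mask[idx, , drop = FALSE],
                ds$view_names, ds$C)
}

# replace the availability mask (e.g. with a synthesized one)
set_mask <- function(ds, mask) {
  entries <- if (inherits(mask, "availability_mask")) mask$entries else mask
  omics_dataset(ds$views, ds$labels, entries, ds$view_names, ds$C)
}

#' Split a dataset into train and test subsets
#'
#' @param ds an \code{\link{omics_dataset}}.
#' @param train_fraction fraction of subjects assigned to training,
#'   strictly between 0 and 1.
#' @param seed integer seed for the shuffle.
#' @param stratified if \code{TRUE} (default) class proportions are
#'   preserved within one subject per class.
#' @return list with elements \code{train} and \code{test} (both
#'   \code{omics_dataset}) and the index vectors \code{train_idx},
#'   \code{test_idx}.
#' @export
split_dataset <- function(ds, train_fraction = 0.7, seed = 0L,
                          stratified = TRUE) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("value error: train_fraction must be strictly between 0 and 1")
  N <- n_subjects(ds)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  if (stratified) {
    train_idx <- integer(0)
    for (cl in sort(unique(ds$labels))) {
      members <- which(ds$labels == cl)
      if (length(members) < 2L)
        stop("stratification error: class ", cl, " has fewer than 2 subjects")
      n_tr <- round(train_fraction * length(members))
      n_tr <- min(max(n_tr, 1L), length(members) - 1L)
      train_idx <- c(train_idx, sample(members, n_tr))
    }
    train_idx <- sort(train_idx)
  } else {
    train_idx <- sort(sample.int(N, round(train_fraction * N)))
  }
  test_idx <- setdiff(seq_len(N), train_idx)
  list(train = subset_dataset(ds, train_idx),
       test = subset_dataset(ds, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}
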