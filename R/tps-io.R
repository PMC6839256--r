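#' Shape dataset container
#'
#' Bundles a `p x 2 x n` array of landmark configurations with per-specimen
#' metadata and the landmark scheme. This is the common currency of the
#' package: TPS readers produce it, the generator emits it, and the Procrustes
#' machinery consumes it.
#'
#' @param coords `p x 2 x n` numeric array; the third dimension indexes
#'   digitisations (one per metadata row).
#' @param meta data frame with one row per configuration; must contain
#'   `specimen_id`; columns `species`, `mode`, `pereopod`, `replicate_id` are
#'   used downstream when present. `mode` must be one of "external", "gill",
#'   "mouth".
#' @param scheme a [landmark_scheme()].
#' @param scale optional numeric vector (per configuration) of physical units
#'   per pixel, as recorded in TPS `SCALE=` lines; coordinates are stored in
#'   physical units (already multiplied by scale).
#' @return object of class `shape_dataset`.
#' @export
shape_dataset <- function(coords, meta, scheme = default_scheme(),
                          scale = NULL) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 2L)
  n <- dim(coords)[3L]
  meta <- as.data.frame(meta)
  if (nrow(meta) != n)
    stop("metadata has ", nrow(meta), " rows but there are ", n,
         " configurations")
  if (is.null(meta$specimen_id))
    stop("metadata must contain a specimen_id column")
  for (i in seq_len(n))
    validate_config_points(coords[, , i, drop = FALSE][, , 1L], scheme,
                           paste0("configuration ", meta$specimen_id[i]))
  if (!is.null(meta$mode)) {
    bad <- setdiff(unique(as.character(meta$mode)), MODE_LEVELS)
    if (length(bad))
      stop("unknown parasitic mode level(s): ", paste(bad, collapse = ", "),
           " (modes are a three-level factor: ",
           paste(MODE_LEVELS, collapse = ", "), ")")
    meta$mode <- factor(as.character(meta$mode), levels = MODE_LEVELS)
  }
  if (is.null(meta$replicate_id)) meta$replicate_id <- rep(1L, n)
  key <- paste(meta$specimen_id, meta$replicate_id)
  if (anyDuplicated(key))
    stop("duplicate (specimen_id, replicate_id): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (!is.null(scale))   # NA marks records without a SCALE line
    stopifnot(length(scale) == n, all(is.na(scale) | scale > 0))
  dimnames(coords)[[3L]] <- as.character(meta$specimen_id)
  structure(list(coords = coords, meta = meta, scheme = scheme,
                 scale = scale),
            class = "shape_dataset")
}

MODE_LEVELS <- c("external", "gill", "mouth")

#' @export
print.shape_dataset <- function(x, ...) {
  cat("Shape dataset:", dim(x$coords)[3L], "configurations of",
      dim(x$coords)[1L], "landmarks")
  if (!is.null(x$meta$species))
    cat(";", length(unique(x$meta$species)), "species")
  cat("\n")
  invisible(x)
}

#' Number of configurations in a dataset
#' @param ds a `shape_dataset`.
#' @export
n_configs <- function(ds) dim(ds$coords)[3L]

#' Subset a shape dataset by configuration index
#' @param ds a `shape_dataset`.
#' @param idx integer or logical index over configurations.
#' @export
subset_dataset <- function(ds, idx) {
  shape_dataset(ds$coords[, , idx, drop = FALSE],
                ds$meta[idx, , drop = FALSE], ds$scheme,
                if (!is.null(ds$scale)) ds$scale[idx])
}

#' Read landmark configurations from a TPS file
#'
#' Parses the tpsDig2 dialect: each record starts with `LM=<n>` followed by
#' `n` coordinate lines, optionally followed by `CURVES=`/`POINTS=` blocks
#' (whose coordinate lines are appended after the fixed landmarks) and
#' `IMAGE=`, `ID=`, `SCALE=` lines. When a `SCALE=` value is present the
#' record's coordinates are multiplied by it, so downstream geometry is in
#' physical units; the scale is retained so [write_tps()] can invert it.
#' Parsing is insensitive to CRLF line endings and trailing blank lines.
#'
#' When `CURVES=` blocks are present they define curve membership (fixed
#' points from the `LM=` block, curves in file order); otherwise membership
#' comes from `scheme`. In either case the total point count must match
#' `scheme$n_points`.
#'
#' @param path file path.
#' @param scheme a [landmark_scheme()]; configure a non-default scheme for
#'   files with other landmark counts.
#' @param flip_y if `TRUE`, negate y coordinates (for files digitised in
#'   image convention with the origin at the top-left). Orientation cancels
#'   in Procrustes superimposition, which disallows reflection, so this only
#'   matters for plotting raw configurations.
#' @return a [shape_dataset()] with minimal metadata (specimen ids from `ID=`
#'   lines, or `IMAGE=` basenames, or record numbers).
#' @export
read_tps <- function(path, scheme = default_scheme(), flip_y = FALSE) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  recs <- list()
  i <- 1L
  n_lines <- length(lines)
  read_points <- function(k, label) {
    if (i + k - 1L > n_lines)
      stop("TPS parse error: record ", label, " declares ", k,
           " points but the file ends early")
    block <- lines[i:(i + k - 1L)]
    pts <- matrix(NA_real_, k, 2L)
    for (j in seq_len(k)) {
      fields <- strsplit(trimws(block[j]), "[ \t,]+")[[1]]
      v <- suppressWarnings(as.numeric(fields))
      if (length(v) < 2L || anyNA(v[1:2]))
        stop("TPS parse error at line ", i + j - 1L,
             ": non-numeric coordinate '", block[j], "'")
      pts[j, ] <- v[1:2]
    }
    i <<- i + k
    pts
  }
  while (i <= n_lines) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", ln, ignore.case = TRUE))
      stop("TPS parse error at line ", i, ": expected LM= record, got '",
           ln, "'")
    n_lm <- as.integer(sub("^LM\\s*=\\s*", "", ln, ignore.case = TRUE))
    rec_label <- length(recs) + 1L
    i <- i + 1L
    fixed_pts <- if (n_lm > 0L) read_points(n_lm, rec_label) else
      matrix(numeric(0), 0L, 2L)
    curve_pts <- list()
    id <- NULL; image <- NULL; scale <- NULL; n_curves <- NULL
    while (i <= n_lines) {
      ln <- trimws(lines[i])
      if (ln == "") { i <- i + 1L; next }
      if (grepl("^LM\\s*=", ln, ignore.case = TRUE)) break
      if (grepl("^CURVES\\s*=", ln, ignore.case = TRUE)) {
        n_curves <- as.integer(sub("^CURVES\\s*=\\s*", "", ln,
                                   ignore.case = TRUE))
        i <- i + 1L
      } else if (grepl("^POINTS\\s*=", ln, ignore.case = TRUE)) {
        k <- as.integer(sub("^POINTS\\s*=\\s*", "", ln, ignore.case = TRUE))
        i <- i + 1L
        curve_pts[[length(curve_pts) + 1L]] <- read_points(k, rec_label)
      } else if (grepl("^IMAGE\\s*=", ln, ignore.case = TRUE)) {
        image <- sub("^IMAGE\\s*=\\s*", "", ln, ignore.case = TRUE)
        i <- i + 1L
      } else if (grepl("^ID\\s*=", ln, ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", ln, ignore.case = TRUE)
        i <- i + 1L
      } else if (grepl("^SCALE\\s*=", ln, ignore.case = TRUE)) {
        scale <- as.numeric(sub("^SCALE\\s*=\\s*", "", ln,
                                ignore.case = TRUE))
        i <- i + 1L
      } else {
        stop("TPS parse error at line ", i, ": unexpected line '", ln, "'")
      }
    }
    if (!is.null(n_curves) && length(curve_pts) != n_curves)
      stop("TPS parse error in record ", rec_label, ": CURVES=", n_curves,
           " but ", length(curve_pts), " POINTS blocks found")
    pts <- rbind(fixed_pts, do.call(rbind, curve_pts))
    if (nrow(pts) != scheme$n_points)
      stop("schema error in TPS record ", rec_label, ": ", nrow(pts),
           " points found, scheme expects ", scheme$n_points,
           " (configure a non-default scheme for other designs)")
    if (length(curve_pts) &&
        !identical(as.integer(vapply(curve_pts, nrow, 0L)),
                   scheme$curve_lengths))
      stop("schema error in TPS record ", rec_label,
           ": curve point counts do not match the scheme")
    if (!is.null(scale)) pts <- pts * scale
    if (flip_y) pts[, 2L] <- -pts[, 2L]
    recs[[rec_label]] <- list(points = pts,
                              id = id %||% (if (!is.null(image))
                                sub("\\.[^.]*$", "", basename(image)) else
                                  sprintf("record_%03d", rec_label)),
                              scale = scale)
  }
  if (!length(recs))
    return(shape_dataset(array(numeric(0),
                               c(scheme$n_points, 2L, 0L)),
                         data.frame(specimen_id = character(0)), scheme))
  coords <- array(NA_real_, c(scheme$n_points, 2L, length(recs)))
  for (r in seq_along(recs)) coords[, , r] <- recs[[r]]$points
  scl <- vapply(recs, function(r) r$scale %||% NA_real_, 0)
  ids <- vapply(recs, function(r) r$id, "")
  # a repeated ID means the same specimen digitised again: number the
  # occurrences as replicates in file order
  repl <- stats::ave(rep(1L, length(ids)), ids, FUN = seq_along)
  shape_dataset(coords,
                data.frame(specimen_id = ids, replicate_id = repl,
                           stringsAsFactors = FALSE),
                scheme,
                scale = if (!all(is.na(scl))) scl)
}

#' Write a shape dataset to a TPS file
#'
#' Emits one tpsDig2-dialect record per configuration, with `ID=` lines
#' carrying specimen ids. Where a scale was recorded at read time the
#' coordinates are divided back to image units and a `SCALE=` line is
#' written, so `read_tps(write_tps(x))` round-trips coordinates.
#'
#' @param ds a [shape_dataset()].
#' @param path output file path.
#' @param digits coordinate precision.
#' @return `path`, invisibly.
#' @export
write_tps <- function(ds, path, digits = 6L) {
  stopifnot(inherits(ds, "shape_dataset"))
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write TPS file: ", path)
  on.exit(close(con))
  n <- n_configs(ds)
  for (i in seq_len(n)) {
    pts <- ds$coords[, , i]
    scl <- if (!is.null(ds$scale)) ds$scale[i] else NA_real_
    if (!is.na(scl)) pts <- pts / scl
    writeLines(sprintf("LM=%d", nrow(pts)), con)
    writeLines(sprintf(paste0("%.", digits, "f %.", digits, "f"),
                       pts[, 1L], pts[, 2L]), con)
    writeLines(sprintf("ID=%s", ds$meta$specimen_id[i]), con)
    if (!is.na(scl)) writeLines(sprintf("SCALE=%g", scl), con)
  }
  invisible(path)
}

#' Read a specimen metadata table and join it to configurations
#'
#' The metadata file is delimited text (comma or tab, sniffed from the
#' header) with columns `specimen_id`, `species`, `mode`, `pereopod` and
#' optionally `replicate_id`. Every configuration in `ds` must have a
#' matching metadata row on (`specimen_id`, `replicate_id`).
#'
#' @param path metadata file path.
#' @param ds a [shape_dataset()] to join to (e.g. from [read_tps()]).
#' @return `ds` with its metadata replaced by the joined table.
#' @export
read_metadata <- function(path, ds) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  meta <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("specimen_id", "species", "mode", "pereopod")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(meta$replicate_id)) meta$replicate_id <- 1L
  bad <- setdiff(unique(meta$mode), MODE_LEVELS)
  if (length(bad))
    stop("unknown parasitic mode level(s): ", paste(bad, collapse = ", "))
  mkey <- paste(meta$specimen_id, meta$replicate_id)
  if (anyDuplicated(mkey))
    stop("duplicate (specimen_id, replicate_id) in metadata: ",
         paste(unique(mkey[duplicated(mkey)]), collapse = ", "))
  dkey <- paste(ds$meta$specimen_id, ds$meta$replicate_id)
  # When the metadata table has one row per specimen (no replicate
  # structure), join on id alone and keep the replicate numbering that
  # read_tps derived from repeated IDs.
  per_specimen <- all(meta$replicate_id == 1L) &&
    any(ds$meta$replicate_id > 1L)
  if (per_specimen) { mkey <- meta$specimen_id
                      dkey <- ds$meta$specimen_id }
  idx <- match(dkey, mkey)
  if (anyNA(idx))
    stop("configurations with no metadata row: ",
         paste(unique(ds$meta$specimen_id[is.na(idx)]), collapse = ", "))
  joined <- meta[idx, , drop = FALSE]
  if (per_specimen) joined$replicate_id <- ds$meta$replicate_id
  shape_dataset(ds$coords, joined, ds$scheme, ds$scale)
}

#' Export aligned coordinates as a wide table
#'
#' One row per configuration: `x1,y1,...,xp,yp` followed by centroid size.
#' @param fit a [gpa()] fit.
#' @return data frame.
#' @export
aligned_wide <- function(fit) {
  m <- coords_to_matrix(fit$coords)
  p <- dim(fit$coords)[1L]
  colnames(m) <- paste0(rep(c("x", "y"), p), rep(seq_len(p), each = 2L))
  data.frame(specimen_id = dimnames(fit$coords)[[3L]] %||%
               seq_len(nrow(m)), m, CS = fit$csize,
             row.names = NULL, check.names = FALSE)
}
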