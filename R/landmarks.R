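#' Landmark tables
#'
#' Throughout the package a set of 2D landmark configurations is represented
#' as a tidy tibble with one row per digitized point, carrying the columns
#' `specimen_id`, `taxon_id`, `point` (1-based index within the specimen),
#' `kind` (`"traditional"` or `"semilandmark"`), `curve` (curve index for
#' semilandmarks, `NA` for traditional landmarks), `x`, `y` (millimetres,
#' after scale calibration), `scale` (mm per raw digitizing unit) and
#' `provenance` (free text: photo / reconstruction / cast). This is the
#' exchange format read from TPS files and consumed by [gpa()].
#'
#' @param specimen_id,taxon_id Character identifiers.
#' @param xy Two-column numeric matrix of point coordinates in mm.
#' @param kind Per-point kind flags; recycled if length 1.
#' @param curve Per-point curve indices (`NA` for traditional landmarks).
#' @param scale Positive scale factor (mm per digitizing unit) already
#'   applied to `xy`.
#' @param provenance Free-text source description.
#' @return A landmark tibble (one row per point).
#' @export
#' @examples
#' landmark_tbl("s1", "taxon_a", cbind(c(0, 1, 0), c(0, 0, 1)))
landmark_tbl <- function(specimen_id, taxon_id, xy,
                         kind = "traditional", curve = NA_integer_,
                         scale = 1, provenance = "synthetic") {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2L)
  n <- nrow(xy)
  out <- tibble(
    specimen_id = as.character(specimen_id),
    taxon_id = as.character(taxon_id),
    point = seq_len(n),
    kind = rep_len(as.character(kind), n),
    curve = rep_len(as.integer(curve), n),
    x = as.numeric(xy[, 1]),
    y = as.numeric(xy[, 2]),
    scale = as.numeric(scale),
    provenance = as.character(provenance)
  )
  validate_landmarks(out)
  out
}

#' Validate a landmark table
#'
#' Checks the structural invariants of the tidy landmark format: required
#' columns, finite coordinates, positive scales, consecutive point indices
#' per specimen, and contiguous, ordered semilandmark curves.
#'
#' @param data A landmark tibble (see [landmark_tbl()]).
#' @return `data`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_landmarks <- function(data) {
  needed <- c("specimen_id", "taxon_id", "point", "kind", "curve", "x", "y")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("landmark table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(is.finite(data$x)) || !all(is.finite(data$y))) {
    abort("landmark coordinates must be finite")
  }
  if ("scale" %in% names(data) && any(data$scale <= 0)) {
    abort("landmark scale factors must be positive")
  }
  if (!all(data$kind %in% c("traditional", "semilandmark"))) {
    abort("landmark kind must be 'traditional' or 'semilandmark'")
  }
  split_pts <- split(data$point, data$specimen_id)
  ok <- vapply(split_pts, function(p) identical(as.integer(p),
                                                seq_along(p)), logical(1))
  if (!all(ok)) {
    abort("per-specimen point indices must be 1..n in file order")
  }
  # semilandmarks of one curve must form one contiguous ordered run
  for (sid in unique(data$specimen_id)) {
    d <- data[data$specimen_id == sid & data$kind == "semilandmark", ]
    if (nrow(d) == 0) next
    if (anyNA(d$curve)) abort("semilandmarks must carry a curve index")
    runs <- rle(d$curve)
    if (anyDuplicated(runs$values) > 0) {
      abort(paste0("specimen ", sid,
                   ": semilandmarks of one curve must be contiguous"))
    }
  }
  invisible(data)
}

# specimen-major p x 2 x n coordinate array from a landmark table;
# all specimens must share one point count
landmarks_to_array <- function(data) {
  validate_landmarks(data)
  ids <- unique(data$specimen_id)
  counts <- vapply(ids, function(s) sum(data$specimen_id == s), integer(1))
  if (length(unique(counts)) != 1) {
    abort("all configurations must have the same number of points")
  }
  p <- counts[[1]]
  arr <- array(NA_real_, dim = c(p, 2L, length(ids)),
               dimnames = list(NULL, c("x", "y"), ids))
  for (i in seq_along(ids)) {
    d <- data[data$specimen_id == ids[i], ]
    d <- d[order(d$point), ]
    arr[, , i] <- cbind(d$x, d$y)
  }
  arr
}

array_to_landmarks <- function(arr, template = NULL) {
  ids <- dimnames(arr)[[3]]
  if (is.null(ids)) ids <- paste0("spec_", seq_len(dim(arr)[3]))
  purrr::map_dfr(seq_along(ids), function(i) {
    tibble(specimen_id = ids[i], point = seq_len(dim(arr)[1]),
           x = arr[, 1, i], y = arr[, 2, i])
  })
}

#' Export a landmark table to CSV
#'
#' Writes the tidy per-point format (`specimen_id`, `taxon_id`,
#' `point_index`, `kind`, `curve`, `x_mm`, `y_mm`).
#'
#' @param data Landmark tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks_csv <- function(data, path) {
  validate_landmarks(data)
  out <- dplyr::transmute(data,
    specimen_id = .data$specimen_id,
    taxon_id = .data$taxon_id,
    point_index = .data$point,
    kind = .data$kind,
    curve = .data$curve,
    x_mm = .data$x,
    y_mm = .data$y
  )
  readr::write_csv(out, path)
  invisible(path)
}
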