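#' Read landmark configurations from a TPS file
#'
#' Parses the common tpsDig dialect: each record starts with `LM=<n>`,
#' followed by `n` whitespace-separated coordinate lines and optional
#' `IMAGE=`, `ID=` and `SCALE=` lines. Raw coordinates are multiplied by
#' the record's scale factor to yield millimetres; a record without a
#' `SCALE=` line is taken at scale 1 with a warning. Records are returned
#' in file order as one tidy landmark table (see [landmark_tbl()]).
#'
#' @param path Path to a TPS file.
#' @param taxon_from Optional function mapping a specimen id to a taxon id;
#'   defaults to the identity.
#' @return A landmark tibble; all points are flagged `"traditional"` (TPS
#'   files carry no kind information — reassign kinds with a
#'   [variant_spec()] via [apply_variant_kinds()] if needed).
#' @export
read_tps <- function(path, taxon_from = identity) {
  if (!file.exists(path)) abort(paste0("TPS file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  recs <- list()
  i <- 1L
  rec_no <- 0L
  while (i <= length(lines)) {
    header <- lines[[i]]
    m <- regmatches(header, regexec("^LM\\s*=\\s*([0-9]+)$", header,
                                    ignore.case = TRUE))[[1]]
    if (length(m) == 0) {
      abort(paste0("malformed TPS count header at line ", i, ": '",
                   header, "'"))
    }
    rec_no <- rec_no + 1L
    n_pts <- as.integer(m[2])
    i <- i + 1L
    coords <- matrix(NA_real_, n_pts, 2)
    for (k in seq_len(n_pts)) {
      if (i > length(lines) || grepl("=", lines[[i]], fixed = TRUE)) {
        abort(paste0("record ", rec_no, ": declared ", n_pts,
                     " landmarks but found ", k - 1L))
      }
      xy <- suppressWarnings(as.numeric(strsplit(lines[[i]], "\\s+")[[1]]))
      if (length(xy) != 2 || anyNA(xy)) {
        abort(paste0("record ", rec_no, ": bad coordinate line ", i,
                     ": '", lines[[i]], "'"))
      }
      coords[k, ] <- xy
      i <- i + 1L
    }
    id <- NULL; image <- NULL; scl <- NULL
    while (i <= length(lines) &&
           !grepl("^LM\\s*=", lines[[i]], ignore.case = TRUE)) {
      kv <- lines[[i]]
      if (grepl("^IMAGE\\s*=", kv, ignore.case = TRUE)) {
        image <- sub("^IMAGE\\s*=\\s*", "", kv, ignore.case = TRUE)
      } else if (grepl("^ID\\s*=", kv, ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", kv, ignore.case = TRUE)
      } else if (grepl("^SCALE\\s*=", kv, ignore.case = TRUE)) {
        scl <- as.numeric(sub("^SCALE\\s*=\\s*", "", kv, ignore.case = TRUE))
        if (is.na(scl) || scl <= 0) {
          abort(paste0("record ", rec_no, ": invalid SCALE line '", kv, "'"))
        }
      }
      i <- i + 1L
    }
    if (is.null(scl)) {
      warn(paste0("TPS record ", rec_no,
                  " has no SCALE line; assuming scale 1"))
      scl <- 1
    }
    sid <- if (!is.null(id) && nzchar(id)) id
           else if (!is.null(image) && nzchar(image)) image
           else paste0("record_", rec_no)
    recs[[rec_no]] <- landmark_tbl(
      specimen_id = sid, taxon_id = taxon_from(sid),
      xy = coords * scl, scale = scl,
      provenance = if (!is.null(image)) image else "tps"
    )
  }
  dplyr::bind_rows(recs)
}

#' Write landmark configurations to a TPS file
#'
#' Emits one `LM=`/coordinates/`ID=`/`SCALE=` record per specimen. The
#' file stores raw coordinates equal to the calibrated mm values with
#' `SCALE=1`, so [read_tps()] round-trips coordinates exactly.
#'
#' @param data Landmark tibble (see [landmark_tbl()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(data, path) {
  validate_landmarks(data)
  if (nrow(data) == 0) abort("cannot write an empty landmark set")
  ids <- unique(data$specimen_id)
  con <- file(path, "w")
  on.exit(close(con))
  for (sid in ids) {
    d <- data[data$specimen_id == sid, ]
    d <- d[order(d$point), ]
    writeLines(paste0("LM=", nrow(d)), con)
    writeLines(sprintf("%.9f %.9f", d$x, d$y), con)
    writeLines(paste0("ID=", sid), con)
    writeLines("SCALE=1.0", con)
  }
  invisible(path)
}
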