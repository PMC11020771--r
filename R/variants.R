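#' Dataset-variant specifications
#'
#' A dataset variant declares how a landmark configuration is organised:
#' the number of traditional landmarks and the number of semilandmark
#' curves, each with a fixed number of points. Four presets, `"a"` to
#' `"d"`, encode the nested designs commonly used to trade landmark
#' resolution against taxon coverage (totals 52, 76, 206 and 230);
#' custom variants with any total of at least 3 are allowed.
#'
#' @param variant_id One of `"a"`, `"b"`, `"c"`, `"d"`, or a custom label.
#' @param n_traditional,n_curves,points_per_curve Non-negative counts; for
#'   the presets these default to the preset values and, if supplied, must
#'   reproduce the preset total.
#' @param taxa Optional character vector of taxon ids the variant covers.
#' @return A `variant_spec` object.
#' @export
#' @examples
#' validate_variant(variant_spec("a"))  # 52
variant_spec <- function(variant_id, n_traditional = NULL, n_curves = NULL,
                         points_per_curve = NULL, taxa = character()) {
  presets <- list(
    a = c(n_traditional = 10L, n_curves = 6L, points_per_curve = 7L),
    b = c(n_traditional = 13L, n_curves = 9L, points_per_curve = 7L),
    c = c(n_traditional = 19L, n_curves = 17L, points_per_curve = 11L),
    d = c(n_traditional = 21L, n_curves = 19L, points_per_curve = 11L)
  )
  if (variant_id %in% names(presets)) {
    p <- presets[[variant_id]]
    if (is.null(n_traditional)) n_traditional <- p[["n_traditional"]]
    if (is.null(n_curves)) n_curves <- p[["n_curves"]]
    if (is.null(points_per_curve)) points_per_curve <- p[["points_per_curve"]]
  }
  if (is.null(n_traditional) || is.null(n_curves) ||
      is.null(points_per_curve)) {
    abort("custom variants must give n_traditional, n_curves, points_per_curve")
  }
  if (any(c(n_traditional, n_curves, points_per_curve) < 0)) {
    abort("variant counts must be non-negative")
  }
  out <- structure(
    list(variant_id = variant_id,
         n_traditional = as.integer(n_traditional),
         n_curves = as.integer(n_curves),
         points_per_curve = as.integer(points_per_curve),
         taxa = as.character(taxa)),
    class = "variant_spec"
  )
  validate_variant(out)
  out
}

#' @export
print.variant_spec <- function(x, ...) {
  cat(sprintf(
    "<variant_spec '%s'>: %d traditional + %d curves x %d = %d landmarks\n",
    x$variant_id, x$n_traditional, x$n_curves, x$points_per_curve,
    validate_variant(x)))
  invisible(x)
}

#' Total landmark count of a dataset variant
#'
#' Returns `n_traditional + n_curves * points_per_curve` after checking
#' the variant's invariants. The preset variants must reproduce their
#' declared totals (a: 52, b: 76, c: 206, d: 230); any variant with a
#' total below 3 is rejected because shape is undefined.
#'
#' @param spec A [variant_spec()].
#' @return Integer total landmark count.
#' @export
validate_variant <- function(spec) {
  stopifnot(inherits(spec, "variant_spec"))
  total <- spec$n_traditional + spec$n_curves * spec$points_per_curve
  preset_totals <- c(a = 52L, b = 76L, c = 206L, d = 230L)
  if (spec$variant_id %in% names(preset_totals) &&
      total != preset_totals[[spec$variant_id]]) {
    abort(sprintf(
      "variant '%s' must total %d landmarks, but components give %d",
      spec$variant_id, preset_totals[[spec$variant_id]], total))
  }
  if (total < 3) abort("a variant needs at least 3 landmarks (shape undefined)")
  as.integer(total)
}

#' Assign variant kinds and curve indices to a landmark table
#'
#' TPS files carry no landmark-kind information. This stamps a variant's
#' layout onto each configuration: the first `n_traditional` points become
#' traditional landmarks, the rest semilandmarks in consecutive curves of
#' `points_per_curve` points.
#'
#' @param data Landmark tibble.
#' @param spec A [variant_spec()]; each configuration must have exactly the
#'   variant's total point count.
#' @return The relabelled landmark tibble.
#' @export
apply_variant_kinds <- function(data, spec) {
  total <- validate_variant(spec)
  validate_landmarks(data)
  kinds <- c(rep("traditional", spec$n_traditional),
             rep("semilandmark", spec$n_curves * spec$points_per_curve))
  curves <- c(rep(NA_integer_, spec$n_traditional),
              rep(seq_len(spec$n_curves), each = spec$points_per_curve))
  out <- dplyr::group_by(data, .data$specimen_id)
  if (!all(dplyr::tally(out)$n == total)) {
    abort(sprintf("each configuration must have %d points for variant '%s'",
                  total, spec$variant_id))
  }
  out <- dplyr::mutate(out,
                       kind = kinds[.data$point],
                       curve = curves[.data$point])
  validate_landmarks(dplyr::ungroup(out))
}

#' Subset landmark configurations to a smaller variant
#'
#' Reduces every configuration to the mapped point indices and stamps the
#' target variant's kind/curve layout onto the result. The mapping length
#' must equal the target variant's total; this is how nested designs
#' (e.g. a 230-point set reduced to the 52-point preset) are built.
#'
#' @param data Landmark tibble conforming to the source layout.
#' @param target Target [variant_spec()].
#' @param mapping Integer vector of source point indices, one per target
#'   point, in target order.
#' @return Landmark tibble conforming to `target`.
#' @export
subset_to_variant <- function(data, target, mapping) {
  total <- validate_variant(target)
  validate_landmarks(data)
  mapping <- as.integer(mapping)
  if (length(mapping) != total) {
    abort(sprintf("mapping has %d indices but variant '%s' needs %d",
                  length(mapping), target$variant_id, total))
  }
  p_src <- max(data$point)
  if (any(mapping < 1 | mapping > p_src)) {
    abort("mapping contains out-of-range point indices")
  }
  picked <- dplyr::group_by(data, .data$specimen_id)
  picked <- dplyr::group_modify(picked, function(d, key) {
    d <- d[order(d$point), ]
    d <- d[mapping, ]
    d$point <- seq_len(nrow(d))
    d
  })
  apply_variant_kinds(dplyr::ungroup(picked), target)
}
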