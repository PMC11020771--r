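#' Jaw-closing mechanical advantage
#'
#' MA is the in-lever divided by the out-lever: the distance from the jaw
#' joint to the muscle insertion on the lower jaw, divided by the distance
#' from the jaw joint to the bite point. It is a dimensionless proxy for
#' the force/speed trade-off of a bite and is invariant under any
#' similarity transform of the lever points.
#'
#' @param joint,insertion,bite Length-2 numeric (x, y) points in mm.
#' @return Mechanical advantage (positive real).
#' @export
#' @examples
#' mechanical_advantage(c(0, 0), c(1, 0), c(2, 0))  # 0.5
mechanical_advantage <- function(joint, insertion, bite) {
  joint <- as.numeric(joint); insertion <- as.numeric(insertion)
  bite <- as.numeric(bite)
  stopifnot(length(joint) == 2, length(insertion) == 2, length(bite) == 2)
  out_lever <- sqrt(sum((bite - joint)^2))
  if (out_lever <= 0) abort("out-lever has zero length (bite point at joint)")
  in_lever <- sqrt(sum((insertion - joint)^2))
  if (in_lever <= 0) abort("in-lever has zero length (insertion at joint)")
  in_lever / out_lever
}

#' Difference between quadrate- and temporal-group mechanical advantage
#'
#' @param temporal_ma,quadrate_ma Finite MA values.
#' @return `quadrate_ma - temporal_ma`.
#' @export
#' @examples
#' delta_ma(0.18, 0.461)  # 0.281
delta_ma <- function(temporal_ma, quadrate_ma) {
  if (!all(is.finite(temporal_ma)) || !all(is.finite(quadrate_ma))) {
    abort("MA values must be finite")
  }
  quadrate_ma - temporal_ma
}

lever_roles <- c("jaw_joint", "temporal_insertion", "quadrate_insertion",
                 "anterior_bite", "posterior_bite")

#' Mechanical-advantage table for a set of taxa
#'
#' Takes lever points in long format (one row per anatomical point:
#' `taxon_id`, `role`, `x`, `y`, roles among `jaw_joint`,
#' `temporal_insertion`, `quadrate_insertion`, `anterior_bite` and the
#' optional `posterior_bite`) and returns one row per taxon with the
#' anterior MA of both adductor groups and their difference. If any taxon
#' carries a posterior bite point, posterior MA columns are added for the
#' taxa that have one. Values are unrounded; round only at presentation.
#'
#' @param levers Long tibble of lever points (mm).
#' @return Tibble with `taxon_id`, `temporal_ma`, `quadrate_ma`,
#'   `delta_ma` (and `temporal_ma_posterior`, `quadrate_ma_posterior` when
#'   posterior bite points are present).
#' @export
ma_table <- function(levers) {
  schema <- tibble(taxon_id = character(), temporal_ma = numeric(),
                   quadrate_ma = numeric(), delta_ma = numeric())
  if (is.null(levers) || nrow(levers) == 0) return(schema)
  stopifnot(all(c("taxon_id", "role", "x", "y") %in% names(levers)))
  bad <- setdiff(unique(levers$role), lever_roles)
  if (length(bad)) abort(paste0("unknown lever role(s): ",
                                paste(bad, collapse = ", ")))
  dup <- dplyr::count(levers, .data$taxon_id, .data$role)
  if (any(dup$n > 1)) abort("duplicate taxon/role lever points")
  has_posterior <- "posterior_bite" %in% levers$role
  rows <- purrr::map_dfr(unique(levers$taxon_id), function(tx) {
    d <- levers[levers$taxon_id == tx, ]
    pt <- function(role) {
      r <- d[d$role == role, ]
      if (nrow(r) == 0) {
        if (role == "posterior_bite") return(NULL)
        abort(sprintf("taxon '%s' lacks lever point '%s'", tx, role))
      }
      c(r$x[[1]], r$y[[1]])
    }
    joint <- pt("jaw_joint"); bite <- pt("anterior_bite")
    t_ma <- mechanical_advantage(joint, pt("temporal_insertion"), bite)
    q_ma <- mechanical_advantage(joint, pt("quadrate_insertion"), bite)
    row <- tibble(taxon_id = tx, temporal_ma = t_ma, quadrate_ma = q_ma,
                  delta_ma = delta_ma(t_ma, q_ma))
    if (has_posterior) {
      pb <- pt("posterior_bite")
      row$temporal_ma_posterior <- if (is.null(pb)) NA_real_ else
        mechanical_advantage(joint, pt("temporal_insertion"), pb)
      row$quadrate_ma_posterior <- if (is.null(pb)) NA_real_ else
        mechanical_advantage(joint, pt("quadrate_insertion"), pb)
    }
    row
  })
  rows
}
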