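# Synthetic skull studies: a parametric theropod-like lateral outline
# with four fenestrae, landmark/lever/attachment slots, controlled
# deformation modes, and full study generation (tree + BM-evolved mode
# weights + landmarks + meshes + levers) with ground truth recorded.

skull_anchors <- function() {
  rbind(
    jaw_joint      = c(5, 0),
    quadratojugal  = c(15, 2),
    jugal_ventral  = c(35, 4),
    maxilla_ventral = c(60, 6),
    tooth_row_ant  = c(85, 8),
    premax_tip     = c(98, 10),
    premax_dorsal  = c(100, 16),
    naris_dorsal   = c(88, 22),
    nasal_mid      = c(70, 28),
    lacrimal       = c(50, 34),
    frontal_dome   = c(35, 40),
    parietal       = c(20, 40),
    occiput_dorsal = c(8, 36),
    occiput_post   = c(3, 25),
    quadrate_post  = c(2, 10))
}

ellipse_poly <- function(center, rx, ry, n = 36) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + rx * cos(th), center[2] + ry * sin(th))
}

skull_fenestrae <- function() {
  list(
    naris = ellipse_poly(c(84, 16), 5, 3),
    antorbital = ellipse_poly(c(66, 16), 8, 5.5),
    orbit = ellipse_poly(c(42, 22), 9, 9),
    lateral_temporal = ellipse_poly(c(22, 20), 5, 8))
}

# n distinct, evenly spaced row indices into an m-row closed polygon
spaced_indices <- function(m, n, closed = TRUE) {
  if (n > m) abort("landmark count exceeds outline sampling density")
  if (closed) floor(m * (seq_len(n) - 1) / n) + 1L
  else unique(round(seq(1, m, length.out = n)))
}

#' Build a synthetic skull template
#'
#' Constructs a theropod-like lateral skull outline (about 100 mm long)
#' with four fenestrae (naris, antorbital, orbit, lateral temporal),
#' landmark slots matching a requested [variant_spec()], lever slots
#' (jaw joint, temporal and quadrate insertions on the lower jaw,
#' anterior and posterior bite points) and muscle attachment regions for
#' the temporal and quadrate adductor groups.
#'
#' Landmark slots index template vertices directly, so deformation of the
#' vertices moves landmarks, mesh geometry and lever points consistently.
#' Traditional landmarks are spread evenly along the outline; curves are
#' allocated one per fenestra with the remainder as contiguous outline
#' arcs (all on the outline if there are fewer curves than fenestrae).
#'
#' @param variant A [variant_spec()] declaring the landmark layout.
#' @param fenestra_fraction If not `NULL`, rescale the fenestrae about
#'   their centroids so their summed area is this fraction of the solid
#'   (outline minus holes) area; `0` removes all fenestrae.
#' @param outline_spacing Densification spacing of the outline (mm).
#' @return A `skull_template`.
#' @export
make_template <- function(variant = variant_spec("a"),
                          fenestra_fraction = NULL, outline_spacing = 2) {
  total <- validate_variant(variant)
  anchors <- skull_anchors()
  perimeter <- sum(sqrt(rowSums(diff(rbind(anchors, anchors[1, ]))^2)))
  # densify enough for the variant's outline landmark demand
  n_out_curves_est <- max(0L, variant$n_curves - 4L)
  needed <- max(64, 1.3 * variant$n_traditional,
                1.3 * n_out_curves_est * variant$points_per_curve)
  spacing <- min(outline_spacing, perimeter / needed)
  outline <- resample_boundary(anchors, spacing)
  fen <- skull_fenestrae()
  if (!is.null(fenestra_fraction)) {
    if (fenestra_fraction < 0 || fenestra_fraction >= 1) {
      abort("fenestra_fraction must be in [0, 1)")
    }
    if (fenestra_fraction == 0) {
      fen <- list()
    } else {
      h0 <- sum(vapply(fen, polygon_area, numeric(1)))
      o <- polygon_area(outline)
      s <- sqrt(fenestra_fraction * o / (h0 * (1 + fenestra_fraction)))
      fen <- lapply(fen, function(p) {
        ctr <- colMeans(p)
        sweep(sweep(p, 2, ctr) * s, 2, ctr, `+`)
      })
    }
  }

  m <- nrow(outline)
  slots <- list()
  if (variant$n_traditional > 0) {
    slots[[1]] <- tibble(kind = "traditional", curve = NA_integer_,
                         source = "outline",
                         index = spaced_indices(m, variant$n_traditional))
  }
  nc <- variant$n_curves
  ppc <- variant$points_per_curve
  if (nc > 0) {
    n_fen_curves <- if (nc > length(fen)) length(fen) else 0L
    n_out_curves <- nc - n_fen_curves
    ci <- 0L
    if (n_out_curves > 0) {
      arc_len <- m / n_out_curves
      if (ppc > floor(arc_len)) {
        abort("landmark count exceeds outline sampling density")
      }
      for (a in seq_len(n_out_curves)) {
        ci <- ci + 1L
        lo <- floor((a - 1) * arc_len) + 1L
        hi <- floor(a * arc_len)
        idx <- lo - 1L + spaced_indices(hi - lo + 1L, ppc, closed = FALSE)
        slots[[length(slots) + 1]] <-
          tibble(kind = "semilandmark", curve = ci, source = "outline",
                 index = idx)
      }
    }
    for (fn in names(fen)[seq_len(n_fen_curves)]) {
      ci <- ci + 1L
      slots[[length(slots) + 1]] <-
        tibble(kind = "semilandmark", curve = ci, source = fn,
               index = spaced_indices(nrow(fen[[fn]]), ppc))
    }
  }
  slots <- dplyr::bind_rows(slots)
  stopifnot(nrow(slots) == total)

  structure(
    list(outline = outline, fenestrae = fen, landmark_slots = slots,
         variant = variant,
         # insertions on the lower jaw placed so the quadrate-group
         # in-lever exceeds the temporal one, as in theropod jaws
         levers = rbind(jaw_joint = c(5, 0),
                        temporal_insertion = c(27, -6),
                        quadrate_insertion = c(45, -8),
                        anterior_bite = c(98, 10),
                        posterior_bite = c(60, 6)),
         attachments = list(
           temporal = list(center = c(26, 38), radius = 9),
           quadrate = list(center = c(4, 14), radius = 7))),
    class = "skull_template")
}

#' @export
print.skull_template <- function(x, ...) {
  cat(sprintf(
    "<skull_template>: %d outline vertices, %d fenestrae, %d landmark slots\n",
    nrow(x$outline), length(x$fenestrae), nrow(x$landmark_slots)))
  invisible(x)
}

#' Deformation modes
#'
#' Names of the supported template deformation modes: snout elongation
#' (anteroposterior stretching of the rostrum), snout depth
#' (dorsoventral deepening of the rostrum), fenestra size (radial
#' scaling of every fenestra about its centroid) and quadrate
#' inclination (posterior shear of the quadrate / occiput region).
#' Displacement fields are linear in the weight and mutually linearly
#' independent; weight zero leaves the template unchanged.
#'
#' @return Character vector of mode ids.
#' @export
deformation_modes <- function() {
  c("snout_elongation", "snout_depth", "fenestra_size",
    "quadrate_inclination")
}

# displacement (per unit weight) of arbitrary vertices for position-based
# modes; fenestra_size is handled structurally in deform_template
mode_field <- function(mode, xy) {
  x <- xy[, 1]; y <- xy[, 2]
  dx <- dy <- numeric(length(x))
  if (mode == "snout_elongation") {
    dx <- 0.25 * pmax(0, x - 45)
  } else if (mode == "snout_depth") {
    ramp <- pmin(1, pmax(0, (x - 45) / 35))
    dy <- 0.2 * (y - 16) * ramp
  } else if (mode == "quadrate_inclination") {
    w <- pmax(0, (25 - x) / 25)
    dx <- -3 * w * (y / 35)
  } else if (mode != "fenestra_size") {
    abort(paste0("unknown deformation mode: ", mode))
  }
  cbind(dx, dy)
}

#' Deform a skull template
#'
#' Applies a weighted sum of the deformation-mode displacement fields to
#' every template vertex (outline, fenestra boundaries, lever points),
#' then adds isotropic Gaussian vertex noise. Deterministic under a fixed
#' seed. Deformations that break the geometry (self-intersecting outline,
#' fenestrae escaping the outline, non-positive areas) are an error
#' naming the weights.
#'
#' @param template A [make_template()] result.
#' @param weights Named numeric vector of mode weights (subset of
#'   [deformation_modes()]); missing modes are 0.
#' @param noise_sd Isotropic Gaussian noise SD (mm) added to every vertex.
#' @param seed Optional integer seed (applied locally).
#' @return The deformed `skull_template`.
#' @export
deform_template <- function(template, weights = numeric(0), noise_sd = 0,
                            seed = NULL) {
  stopifnot(inherits(template, "skull_template"))
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  bad <- setdiff(names(weights), deformation_modes())
  if (length(bad)) abort(paste0("unknown mode(s): ", paste(bad, collapse = ", ")))
  if (length(weights) && any(!is.finite(weights))) {
    abort("mode weights must be finite")
  }
  w <- setNames(numeric(length(deformation_modes())), deformation_modes())
  w[names(weights)] <- weights

  move <- function(xy) {
    d <- matrix(0, nrow(xy), 2)
    for (mode in c("snout_elongation", "snout_depth",
                   "quadrate_inclination")) {
      if (w[[mode]] != 0) d <- d + w[[mode]] * mode_field(mode, xy)
    }
    xy + d
  }
  out <- template
  out$outline <- move(template$outline)
  out$levers <- move(template$levers)
  rownames(out$levers) <- rownames(template$levers)
  out$fenestrae <- lapply(template$fenestrae, function(p) {
    p2 <- move(p)
    if (w[["fenestra_size"]] != 0) {
      ctr <- colMeans(p2)
      p2 <- sweep(sweep(p2, 2, ctr) * (1 + 0.12 * w[["fenestra_size"]]),
                  2, ctr, `+`)
    }
    p2
  })
  out$attachments <- lapply(template$attachments, function(a) {
    list(center = drop(move(rbind(a$center))), radius = a$radius)
  })

  add_noise <- function(tmpl) {
    if (noise_sd == 0) return(tmpl)
    jitter <- function(xy) xy + matrix(rnorm(length(xy), 0, noise_sd),
                                       nrow(xy), 2)
    tmpl$outline <- jitter(tmpl$outline)
    tmpl$fenestrae <- lapply(tmpl$fenestrae, jitter)
    tmpl
  }
  out <- if (is.null(seed)) add_noise(out) else
    withr::with_seed(seed, add_noise(out))

  check_template_geometry(out, w)
  out
}

check_template_geometry <- function(tmpl, w = NULL) {
  wtxt <- if (is.null(w)) "" else
    paste0(" (weights: ", paste(names(w), signif(w, 3), sep = "=",
                                collapse = ", "), ")")
  if (polygon_area(tmpl$outline, signed = TRUE) <= 0) {
    abort(paste0("deformation produced a non-positive outline area", wtxt))
  }
  if (polygon_self_intersects(tmpl$outline)) {
    abort(paste0("deformation produced a self-intersecting outline", wtxt))
  }
  for (fn in names(tmpl$fenestrae)) {
    p <- tmpl$fenestrae[[fn]]
    if (!all(point_in_polygon(p, tmpl$outline))) {
      abort(paste0("deformation pushed fenestra '", fn,
                   "' outside the outline", wtxt))
    }
  }
  invisible(tmpl)
}

#' Rescale a template by a size factor
#'
#' Multiplies every coordinate (outline, fenestrae, levers, attachment
#' centres and radii) by `s`, giving taxa different absolute skull sizes.
#'
#' @param template A `skull_template`.
#' @param s Positive scale factor.
#' @return The scaled template.
#' @export
scale_template <- function(template, s) {
  stopifnot(inherits(template, "skull_template"), s > 0)
  template$outline <- template$outline * s
  template$fenestrae <- lapply(template$fenestrae, function(p) p * s)
  template$levers <- template$levers * s
  rownames(template$levers) <- c("jaw_joint", "temporal_insertion",
                                 "quadrate_insertion", "anterior_bite",
                                 "posterior_bite")
  template$attachments <- lapply(template$attachments, function(a) {
    list(center = a$center * s, radius = a$radius * s)
  })
  template
}

#' Extract the landmark configuration of a template
#'
#' Resolves the template's landmark slots against its (possibly deformed)
#' vertices.
#'
#' @param template A `skull_template`.
#' @param specimen_id,taxon_id Identifiers for the configuration.
#' @return A landmark tibble (see [landmark_tbl()]).
#' @export
template_landmarks <- function(template, specimen_id = "template",
                               taxon_id = specimen_id) {
  sl <- template$landmark_slots
  xy <- t(vapply(seq_len(nrow(sl)), function(i) {
    src <- sl$source[i]
    verts <- if (src == "outline") template$outline else
      template$fenestrae[[src]]
    if (is.null(verts)) abort(paste0("landmark slot references missing ",
                                     "fenestra '", src, "'"))
    verts[sl$index[i], ]
  }, numeric(2)))
  landmark_tbl(specimen_id, taxon_id, xy, kind = sl$kind, curve = sl$curve)
}

#' Lever points of a template in long format
#'
#' @param template A `skull_template`.
#' @param taxon_id Taxon label for the rows.
#' @return Long lever tibble (`taxon_id`, `role`, `x`, `y`) for
#'   [ma_table()].
#' @export
template_levers <- function(template, taxon_id = "template") {
  tibble(taxon_id = taxon_id, role = rownames(template$levers),
         x = template$levers[, 1], y = template$levers[, 2])
}

#' Mesh a skull template
#'
#' Triangulates the solid region of the (possibly deformed) template,
#' excluding the fenestra holes, via [mesh_polygon()].
#'
#' @param template A `skull_template` (or a bare outline polygon).
#' @param target_edge Target element edge length (mm).
#' @param ... Passed to [mesh_polygon()].
#' @return A [planar_mesh()].
#' @export
mesh_skull <- function(template, target_edge, ...) {
  if (inherits(template, "skull_template")) {
    mesh_polygon(template$outline, template$fenestrae, target_edge, ...)
  } else {
    mesh_polygon(template, list(), target_edge, ...)
  }
}

#' Generate a complete synthetic study
#'
#' Builds a ground-truth test bed for the whole pipeline: a pure-birth
#' tree rescaled to unit root-to-tip depth, per-taxon deformation-mode
#' weights evolved by Brownian motion on that tree, and per-taxon
#' landmark configurations, fenestrate meshes and lever points derived
#' from one deformed template per taxon (plus an independent log-normal
#' size factor). All randomness flows through the single `seed`;
#' regeneration with the same arguments is identical.
#'
#' @param n_taxa Number of taxa (>= 4).
#' @param seed Integer seed for the whole study.
#' @param mode_rates Named BM rates (variance per unit time) per
#'   deformation mode; modes absent from the vector do not vary.
#' @param noise_sd Per-vertex landmark/geometry noise SD (mm).
#' @param size_sd SD of log size factors (0 = all skulls the same size).
#' @param variant Landmark layout ([variant_spec()]).
#' @param target_edge Mesh edge length (mm) at unit size (scaled per
#'   taxon so element counts stay comparable).
#' @param mesh If `FALSE`, skip meshing (faster when only shape/lever
#'   stages are needed).
#' @return A `synthetic_study`: `landmarks`, `meshes` (named list),
#'   `levers`, `tree`, `true_weights`, `sizes`, `variant`, `seed`.
#' @export
generate_study <- function(n_taxa = 8, seed = 1,
                           mode_rates = c(snout_elongation = 1,
                                          snout_depth = 0.5,
                                          fenestra_size = 0.25,
                                          quadrate_inclination = 0.25),
                           noise_sd = 0.05, size_sd = 0.15,
                           variant = variant_spec("a"), target_edge = 4,
                           mesh = TRUE) {
  if (n_taxa < 4) abort("a study needs at least 4 taxa")
  bad <- setdiff(names(mode_rates), deformation_modes())
  if (length(bad)) abort(paste0("unknown mode(s): ",
                                paste(bad, collapse = ", ")))
  template <- make_template(variant)

  withr::with_seed(seed, {
    tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
    tree$tip.label <- sprintf("taxon_%02d", seq_len(n_taxa))
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length / depth
    weights <- vapply(names(mode_rates), function(mode) {
      drop(simulate_bm(tree, rate = mode_rates[[mode]]))
    }, numeric(n_taxa))
    rownames(weights) <- tree$tip.label
    sizes <- setNames(exp(rnorm(n_taxa, 0, size_sd)), tree$tip.label)
    noise_seeds <- sample.int(.Machine$integer.max, n_taxa)
  })

  taxa <- tree$tip.label
  per_taxon <- purrr::map(seq_along(taxa), function(i) {
    w_i <- setNames(as.numeric(weights[i, ]), colnames(weights))
    tmpl <- deform_template(template, w_i, noise_sd = noise_sd,
                            seed = noise_seeds[i])
    scale_template(tmpl, sizes[[i]])
  })
  names(per_taxon) <- taxa

  landmarks <- purrr::map_dfr(taxa, function(tx) {
    template_landmarks(per_taxon[[tx]], specimen_id = tx, taxon_id = tx)
  })
  levers <- purrr::map_dfr(taxa, function(tx) {
    template_levers(per_taxon[[tx]], taxon_id = tx)
  })
  meshes <- if (mesh) {
    purrr::map(taxa, function(tx) {
      mesh_skull(per_taxon[[tx]], target_edge * sizes[[tx]])
    })
  } else NULL
  if (!is.null(meshes)) names(meshes) <- taxa

  structure(
    list(variant = variant, landmarks = landmarks, meshes = meshes,
         levers = levers, tree = tree,
         true_weights = dplyr::bind_cols(tibble(taxon_id = taxa),
                                         as_tibble(weights)),
         sizes = sizes, templates = per_taxon, seed = seed,
         params = list(n_taxa = n_taxa, mode_rates = mode_rates,
                       noise_sd = noise_sd, size_sd = size_sd,
                       target_edge = target_edge)),
    class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study>: %d taxa, %d landmarks each, %s, seed %d\n",
    length(x$tree$tip.label), max(x$landmarks$point),
    if (is.null(x$meshes)) "no meshes" else "meshed", x$seed))
  invisible(x)
}

#' Write a synthetic study as a fixture bundle
#'
#' Writes the formats the analysis modules read: `landmarks.tps`,
#' `landmarks.csv`, `levers.csv`, `tree.nwk`, `true_weights.csv` and one
#' node/element CSV pair per taxon under `meshes/`.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tps(study$landmarks, file.path(dir, "landmarks.tps"))
  write_landmarks_csv(study$landmarks, file.path(dir, "landmarks.csv"))
  readr::write_csv(dplyr::rename(study$levers, x_mm = "x", y_mm = "y"),
                   file.path(dir, "levers.csv"))
  write_newick(study$tree, file.path(dir, "tree.nwk"))
  readr::write_csv(study$true_weights, file.path(dir, "true_weights.csv"))
  if (!is.null(study$meshes)) {
    mdir <- file.path(dir, "meshes")
    dir.create(mdir, showWarnings = FALSE)
    for (tx in names(study$meshes)) {
      write_mesh_csv(study$meshes[[tx]],
                     file.path(mdir, paste0(tx, "_nodes.csv")),
                     file.path(mdir, paste0(tx, "_elements.csv")))
    }
  }
  invisible(dir)
}
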