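#' Pipeline run configuration
#'
#' Assembles and validates the configuration for [run_pipeline()].
#' Exactly one of `synthetic` (parameters for [generate_study()]) or
#' `inputs` (paths to a TPS file, a long lever CSV, a Newick tree and a
#' directory of per-taxon node/element mesh CSV pairs) must be given.
#' Omitted FEA / PCM settings get the documented defaults: Young's
#' modulus 20490 MPa (20.49 GPa), Poisson's ratio 0.4, reference force
#' 30 N applied to the smallest model, equal temporal/quadrate force
#' partition, 4 strain intervals, 999 permutations.
#'
#' @param synthetic Named list of [generate_study()] arguments (may be
#'   empty for all defaults).
#' @param inputs Named list with `tps`, `levers`, `tree` and optionally
#'   `meshes_dir` paths.
#' @param fea,pcm Named lists overriding FEA / PCM defaults (unknown keys
#'   are an error).
#' @param seed Integer seed controlling every stochastic stage.
#' @return A validated `run_config`.
#' @export
run_config <- function(synthetic = NULL, inputs = NULL, fea = list(),
                       pcm = list(), seed = 1) {
  validate_config(list(synthetic = synthetic, inputs = inputs, fea = fea,
                       pcm = pcm, seed = seed))
}

#' Validate and normalize a pipeline configuration
#'
#' Fills documented defaults, rejects unknown keys and contradictory
#' settings (both or neither input source, negative reference force,
#' invalid partition).
#'
#' @param config A list shaped like the [run_config()] arguments.
#' @return The normalized `run_config` object.
#' @export
validate_config <- function(config) {
  known_top <- c("synthetic", "inputs", "fea", "pcm", "seed")
  bad <- setdiff(names(config), known_top)
  if (length(bad)) abort(paste0("unknown config key(s): ",
                                paste(bad, collapse = ", ")))
  has_syn <- !is.null(config$synthetic)
  has_inp <- !is.null(config$inputs)
  if (has_syn == has_inp) {
    abort("exactly one of 'synthetic' or 'inputs' must be provided")
  }
  fea_defaults <- list(young_modulus = 20490, poisson_ratio = 0.4,
                       reference_force = 30, partition = 0.5,
                       n_intervals = 4, intervals_upper = NULL,
                       attachment_radius = NULL)
  pcm_defaults <- list(n_perm = 999, include_outgroup = TRUE,
                       outgroup = NULL)
  merge_defaults <- function(given, defaults, where) {
    bad <- setdiff(names(given), names(defaults))
    if (length(bad)) abort(paste0("unknown ", where, " config key(s): ",
                                  paste(bad, collapse = ", ")))
    utils::modifyList(defaults, given)
  }
  fea <- merge_defaults(config$fea %||% list(), fea_defaults, "fea")
  pcm <- merge_defaults(config$pcm %||% list(), pcm_defaults, "pcm")
  if (fea$reference_force <= 0) abort("reference force must be positive")
  if (fea$partition < 0 || fea$partition > 1) {
    abort("partition must be in [0, 1]")
  }
  if (fea$n_intervals < 2) abort("n_intervals must be at least 2")
  if (pcm$n_perm < 1) abort("n_perm must be at least 1")
  material(fea$young_modulus, fea$poisson_ratio)  # validates E, nu
  if (has_inp) {
    needed <- c("tps", "levers", "tree")
    miss <- setdiff(needed, names(config$inputs))
    if (length(miss)) abort(paste0("inputs lacks: ",
                                   paste(miss, collapse = ", ")))
    for (p in unlist(config$inputs)) {
      if (!file.exists(p)) abort(paste0("input path does not exist: ", p))
    }
  }
  structure(list(synthetic = config$synthetic, inputs = config$inputs,
                 fea = fea, pcm = pcm,
                 seed = as.integer(config$seed %||% 1)),
            class = "run_config")
}

#' Run the full morphofunctional pipeline
#'
#' Executes every stage end to end: landmark acquisition, generalized
#' Procrustes superimposition, shape PCA, centroid sizes and Tukey-fence
#' outlier tests; mechanical advantage of both adductor groups; one
#' plane-strain finite element bite model per taxon with constant-stress
#' force scaling, MWAM equivalent strain, the intervals method and
#' fenestra ratios; and the phylogenetic battery (K_mult on shape, MA
#' and intervals data; Blomberg's K per PC; PGLS of each PC and of
#' centroid size against temporal MA, quadrate MA and MWAM strain; of
#' fenestra ratios against MA; and of skull length against MWAM strain,
#' raw and log-log). Deterministic under the configuration seed.
#'
#' @param config A [run_config()].
#' @return A `report_bundle`: tibbles `variant_summary`,
#'   `pca_and_signal`, `ma_fea_summary`, `pgls_table`, `intervals_table`,
#'   `outliers`, plus the fitted objects and a run `log`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) abort(paste0(
      "pipeline stage '", name, "' failed: ", conditionMessage(e))))
  }
  log_lines <- c(sprintf("skullmech %s pipeline run, seed %d",
                         as.character(utils::packageVersion("skullmech")),
                         config$seed))

  # ---- acquire study ------------------------------------------------
  study <- stage("input", {
    if (!is.null(config$synthetic)) {
      args <- config$synthetic
      if (!is.null(args$variant) && !inherits(args$variant, "variant_spec")) {
        args$variant <- variant_spec(args$variant)
      }
      args$seed <- args$seed %||% config$seed
      do.call(generate_study, args)
    } else {
      read_study_inputs(config$inputs)
    }
  })
  landmarks <- study$landmarks
  taxa <- unique(landmarks$taxon_id)
  log_lines <- c(log_lines, sprintf("%d taxa, %d landmarks", length(taxa),
                                    max(landmarks$point)))

  # ---- morphometrics ------------------------------------------------
  fit <- stage("gpa", gpa(landmarks))
  pca <- stage("pca", pca_shapes(fit))
  sizes <- centroid_sizes(landmarks)
  keep_pc <- which(pca$eigenvalues > 1e-10 * sum(pca$eigenvalues))
  pc_names <- paste0("PC", keep_pc)
  scores <- dplyr::left_join(pca$scores,
                             dplyr::left_join(sizes,
                                              dplyr::distinct(landmarks,
                                                              .data$specimen_id,
                                                              .data$taxon_id),
                                              by = c("specimen_id", "taxon_id")),
                             by = "specimen_id")
  outliers <- stage("outliers", dplyr::bind_rows(
    outlier_table(scores, dplyr::all_of(pc_names)),
    outlier_table(scores, "centroid_size")))

  # ---- lever mechanics ----------------------------------------------
  ma <- stage("mechanical_advantage", ma_table(study$levers))

  # ---- finite elements ----------------------------------------------
  mat <- material(config$fea$young_modulus, config$fea$poisson_ratio)
  fea_rows <- NULL; intervals_tbl <- NULL; fea_results <- NULL
  if (!is.null(study$meshes) && length(study$meshes) > 0) {
    areas <- vapply(study$meshes, function(m) sum(m$element_areas),
                    numeric(1))
    area_ref <- min(areas)
    fea_results <- stage("fea", purrr::imap(study$meshes, function(mesh, tx) {
      force <- scale_force(config$fea$reference_force, area_ref, areas[[tx]])
      case <- study_bite_case(study, tx, mesh, force, config$fea)
      solve_fea(mesh, mat, case)
    }))
    skull_len <- vapply(taxa, function(tx) {
      d <- landmarks[landmarks$taxon_id == tx, ]
      diff(range(d$x))
    }, numeric(1))
    mwams <- vapply(fea_results, function(r) mwam(r$strains$eps_eq,
                                                  r$strains$area), numeric(1))
    upper <- config$fea$intervals_upper %||% (2 * max(mwams))
    intervals_tbl <- purrr::imap_dfr(fea_results, function(r, tx) {
      iv <- intervals_method(r$strains$eps_eq, r$strains$area,
                             config$fea$n_intervals, upper)
      dplyr::bind_cols(tibble(taxon_id = tx),
                       tidyr::pivot_wider(iv[, c("interval", "percent_area")],
                                          names_from = "interval",
                                          values_from = "percent_area"))
    })
    fen_ratios <- purrr::imap_dfr(study$meshes, function(mesh, tx) {
      fr <- fenestra_ratio(mesh, per_fenestra = TRUE)
      dplyr::bind_cols(tibble(taxon_id = tx),
                       tidyr::pivot_wider(fr[, c("fenestra", "ratio")],
                                          names_from = "fenestra",
                                          values_from = "ratio",
                                          names_prefix = "ratio_"))
    })
    fea_rows <- tibble(taxon_id = names(mwams), mwam_strain = mwams,
                       model_area = as.numeric(areas[names(mwams)]),
                       applied_force = scale_force(
                         config$fea$reference_force, area_ref,
                         as.numeric(areas[names(mwams)])),
                       skull_length = as.numeric(skull_len[names(mwams)]))
    fea_rows <- dplyr::left_join(fea_rows, fen_ratios, by = "taxon_id")
    log_lines <- c(log_lines, sprintf(
      "FEA: %d models, reference area %.4g mm^2, intervals upper %.4g",
      length(fea_results), area_ref, upper))
  }

  ma_fea <- if (is.null(fea_rows)) ma else
    dplyr::left_join(ma, fea_rows, by = "taxon_id")

  # ---- phylogenetic comparative methods -----------------------------
  tree <- study$tree
  pcm_tbl <- NULL; pgls_tbl <- NULL
  if (!is.null(tree)) {
    n_perm <- config$pcm$n_perm
    if (!is.null(config$pcm$outgroup) && !config$pcm$include_outgroup) {
      tree <- ape::drop.tip(tree, config$pcm$outgroup)
    }
    keep_taxa <- intersect(tree$tip.label, taxa)
    shape_mat <- stage("pcm", {
      arr <- fit$aligned
      m <- t(apply(arr, 3, function(x) as.vector(t(x))))
      rownames(m) <- fit$specimen_ids
      m[keep_taxa, , drop = FALSE]
    })
    k_shape <- kmult(tree, shape_mat, n_perm, seed = config$seed + 101L)
    per_pc <- purrr::map_dfr(keep_pc, function(j) {
      tr <- setNames(scores[[paste0("PC", j)]], scores$taxon_id)[keep_taxa]
      kt <- blomberg_k(tree, tr, n_perm, seed = config$seed + 200L + j)
      tibble(variable = paste0("PC", j),
             variance_fraction = pca$variance_fraction[j],
             statistic = kt$statistic, p_value = kt$p_value,
             method = "K")
    })
    ma_mat <- as.matrix(ma[match(keep_taxa, ma$taxon_id),
                           c("temporal_ma", "quadrate_ma")])
    rownames(ma_mat) <- keep_taxa
    k_ma <- kmult(tree, ma_mat, n_perm, seed = config$seed + 102L)
    k_int <- NULL
    if (!is.null(intervals_tbl)) {
      im <- as.matrix(intervals_tbl[match(keep_taxa,
                                          intervals_tbl$taxon_id), -1])
      rownames(im) <- keep_taxa
      k_int <- tryCatch(kmult(tree, im, n_perm,
                              seed = config$seed + 103L),
                        error = function(e) NULL)
    }
    pcm_tbl <- dplyr::bind_rows(
      tibble(variable = "shape_all", variance_fraction = 1,
             statistic = k_shape$statistic, p_value = k_shape$p_value,
             method = "K_mult"),
      per_pc,
      tibble(variable = "ma_data", variance_fraction = NA_real_,
             statistic = k_ma$statistic, p_value = k_ma$p_value,
             method = "K_mult"),
      if (!is.null(k_int)) {
        tibble(variable = "intervals_data", variance_fraction = NA_real_,
               statistic = k_int$statistic, p_value = k_int$p_value,
               method = "K_mult")
      })

    # PGLS battery
    dat <- dplyr::left_join(scores, ma_fea, by = "taxon_id")
    dat <- dat[match(keep_taxa, dat$taxon_id), ]
    fit_one <- function(resp, pred) {
      tryCatch(
        glance(pgls(dat, tree, dplyr::all_of(resp), dplyr::all_of(pred))),
        error = function(e) NULL)
    }
    pairs <- list()
    for (resp in c("temporal_ma", "quadrate_ma",
                   if (!is.null(fea_rows)) "mwam_strain")) {
      for (pc in pc_names) pairs[[length(pairs) + 1]] <- c(resp, pc)
      pairs[[length(pairs) + 1]] <- c(resp, "centroid_size")
    }
    if (!is.null(fea_rows)) {
      ratio_cols <- grep("^ratio_", names(dat), value = TRUE)
      for (rc in ratio_cols) {
        pairs[[length(pairs) + 1]] <- c("temporal_ma", rc)
        pairs[[length(pairs) + 1]] <- c("quadrate_ma", rc)
      }
      dat$log_mwam <- log(dat$mwam_strain)
      dat$log_skull_length <- log(dat$skull_length)
      pairs[[length(pairs) + 1]] <- c("mwam_strain", "skull_length")
      pairs[[length(pairs) + 1]] <- c("log_mwam", "log_skull_length")
    }
    pgls_tbl <- purrr::map_dfr(pairs, function(p) {
      fit_one(p[1], p[2]) %||% tibble(
        response = p[1], predictor = p[2], slope = NA_real_,
        intercept = NA_real_, slope_p = NA_real_,
        pseudo_r2_adj = NA_real_, n = length(keep_taxa))
    })
    log_lines <- c(log_lines, sprintf(
      "PCM: %d permutations, %d PGLS fits over %d PCs", n_perm,
      nrow(pgls_tbl), length(keep_pc)))
  }

  variant_summary <- tibble(
    variant_id = study$variant$variant_id,
    n_traditional = study$variant$n_traditional,
    n_curves = study$variant$n_curves,
    points_per_curve = study$variant$points_per_curve,
    total_landmarks = validate_variant(study$variant),
    n_taxa = length(taxa))

  structure(
    list(variant_summary = variant_summary,
         pca_and_signal = pcm_tbl,
         ma_fea_summary = ma_fea,
         pgls_table = pgls_tbl,
         intervals_table = intervals_tbl,
         outliers = outliers,
         scores = scores,
         gpa = fit, pca = pca, fea = fea_results, study = study,
         n_pcs_used = length(keep_pc),
         config = config,
         log = log_lines),
    class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  for (ln in x$log) cat(" ", ln, "\n")
  invisible(x)
}

#' Write a report bundle's tables to a directory
#'
#' One CSV per table (variant summary, PCA and phylogenetic signal,
#' MA/FEA summary, PGLS battery, intervals, outliers, PC scores) plus a
#' plain-text run log with the seed.
#'
#' @param bundle A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("variant_summary", "pca_and_signal", "ma_fea_summary",
              "pgls_table", "intervals_table", "outliers", "scores")
  for (tb in tables) {
    if (!is.null(bundle[[tb]])) {
      readr::write_csv(bundle[[tb]], file.path(dir, paste0(tb, ".csv")))
    }
  }
  writeLines(bundle$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

# bite case for one taxon: synthetic studies carry template lever and
# attachment slots; file-based studies fall back to lever roles plus
# attachment regions provided in the lever table
study_bite_case <- function(study, tx, mesh, force, fea_cfg) {
  radius_default <- 0.08 * diff(range(mesh$nodes[, 1]))
  radius <- fea_cfg$attachment_radius %||% radius_default
  if (!is.null(study$templates)) {
    tmpl <- study$templates[[tx]]
    lv <- tmpl$levers
    att <- tmpl$attachments
    bite_load_case(
      mesh,
      bite_point = lv["anterior_bite", ],
      joint_point = lv["jaw_joint", ],
      temporal_nodes = nodes_near(mesh, att$temporal$center,
                                  att$temporal$radius),
      temporal_target = lv["temporal_insertion", ],
      quadrate_nodes = nodes_near(mesh, att$quadrate$center,
                                  att$quadrate$radius),
      quadrate_target = lv["quadrate_insertion", ],
      total_force = force, partition = fea_cfg$partition)
  } else {
    lv <- study$levers[study$levers$taxon_id == tx, ]
    pt <- function(role) {
      r <- lv[lv$role == role, ]
      if (nrow(r) == 0) abort(sprintf("taxon '%s' lacks lever role '%s'",
                                      tx, role))
      c(r$x[[1]], r$y[[1]])
    }
    att_pt <- function(role, fallback) {
      r <- lv[lv$role == role, ]
      if (nrow(r) > 0) c(r$x[[1]], r$y[[1]]) else fallback
    }
    xr <- range(mesh$nodes[, 1]); yr <- range(mesh$nodes[, 2])
    temporal_ctr <- att_pt("temporal_attachment",
                           c(xr[1] + 0.25 * diff(xr), yr[2]))
    quadrate_ctr <- att_pt("quadrate_attachment",
                           c(xr[1] + 0.03 * diff(xr),
                             yr[1] + 0.35 * diff(yr)))
    bite_load_case(
      mesh,
      bite_point = pt("anterior_bite"), joint_point = pt("jaw_joint"),
      temporal_nodes = nodes_near(mesh, temporal_ctr, radius),
      temporal_target = pt("temporal_insertion"),
      quadrate_nodes = nodes_near(mesh, quadrate_ctr, radius),
      quadrate_target = pt("quadrate_insertion"),
      total_force = force, partition = fea_cfg$partition)
  }
}

# file-based study: TPS landmarks, long lever CSV (taxon_id, role,
# x_mm, y_mm), Newick tree, optional directory of <taxon>_nodes.csv /
# <taxon>_elements.csv pairs
read_study_inputs <- function(inputs) {
  landmarks <- read_tps(inputs$tps)
  lv <- readr::read_csv(inputs$levers, show_col_types = FALSE)
  names(lv) <- sub("_mm$", "", names(lv))
  tree <- read_newick(inputs$tree)
  meshes <- NULL
  if (!is.null(inputs$meshes_dir)) {
    node_files <- list.files(inputs$meshes_dir, "_nodes\\.csv$",
                             full.names = TRUE)
    taxa <- sub("_nodes\\.csv$", "", basename(node_files))
    meshes <- lapply(seq_along(taxa), function(i) {
      read_mesh_csv(node_files[i],
                    file.path(inputs$meshes_dir,
                              paste0(taxa[i], "_elements.csv")))
    })
    names(meshes) <- taxa
  }
  p <- max(landmarks$point)
  variant <- variant_spec("file", n_traditional = p, n_curves = 0,
                          points_per_curve = 0)
  list(variant = variant, landmarks = landmarks, levers = lv,
       tree = tree, meshes = meshes, templates = NULL)
}
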