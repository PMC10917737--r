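#' Assemble and validate a pipeline run configuration
#'
#' Central, validated description of a full analysis run: where the
#' recordings come from (a synthetic cohort spec, a directory of columnar
#' files, or a directory of EDF files), how they are filtered, decomposed
#' and epoched, and how connectivity and group statistics are summarized.
#' Validation happens here, before any I/O or computation.
#'
#' @param input one of `"synth"`, `"columnar"`, `"edf"`.
#' @param synth_spec a [cohort_spec()] (required for `input = "synth"`).
#' @param path directory of `.tsv` / `.edf` / `.rec` files (file inputs).
#' @param channels channels to analyse, in order.
#' @param group_map named character vector mapping subject ids to
#'   `"OSA"`/`"HEALTHY"` (file inputs; columnar files may instead carry
#'   their group in metadata).
#' @param epoch_seconds epoch length, seconds (default 30).
#' @param filter a [filter_spec()].
#' @param wavelet a [wavelet_spec()].
#' @param bands band table, default [eeg_bands()].
#' @param edge_threshold minimum r for a graph edge (default 0:
#'   strictly positive correlations).
#' @param fisher_z average per-epoch correlations on the Fisher z scale?
#' @param summary per-subject scalar tested between groups:
#'   `"mean_abs_coeff"` (mean absolute wavelet coefficient, default) or
#'   `"mean_pos_r"` (mean positive inter-channel correlation).
#' @param report_bands bands carried into group tests and t-maps
#'   (default delta, theta, alpha, beta).
#' @param alpha significance level for flagging (default 0.05).
#' @param p_adjust Benjamini-Hochberg across bands? Default `FALSE`.
#' @param coords node coordinate table for graph export.
#' @param out_dir optional output directory for the report files.
#' @param seed seed echoed into the report (the synthetic generator has
#'   its own seed inside `synth_spec`).
#' @return A validated `run_config` list.
#' @export
run_config <- function(input = c("synth", "columnar", "edf"),
                       synth_spec = NULL, path = NULL, channels = NULL,
                       group_map = NULL, epoch_seconds = 30,
                       filter = filter_spec(), wavelet = wavelet_spec(),
                       bands = eeg_bands(), edge_threshold = 0,
                       fisher_z = FALSE,
                       summary = c("mean_abs_coeff", "mean_pos_r"),
                       report_bands = c("delta", "theta", "alpha", "beta"),
                       alpha = 0.05, p_adjust = FALSE,
                       coords = default_node_coords(), out_dir = NULL,
                       seed = 1L) {
  input <- match.arg(input)
  summary <- match.arg(summary)
  check_bands(bands)
  stopifnot(inherits(filter, "filter_spec"), inherits(wavelet, "wavelet_spec"),
            epoch_seconds > 0, edge_threshold >= 0, alpha > 0, alpha < 1)
  if (input == "synth") {
    if (!inherits(synth_spec, "cohort_spec")) {
      abort("`input = \"synth\"` requires a cohort_spec in `synth_spec`.")
    }
  } else if (is.null(path)) {
    abort(sprintf("`input = \"%s\"` requires `path`.", input))
  }
  if (input == "edf" && is.null(channels)) {
    abort("EDF input requires an explicit `channels` selection.")
  }
  bad <- setdiff(report_bands, as.character(bands$band))
  if (length(bad)) {
    abort(sprintf("Unknown report band(s): %s", paste(bad, collapse = ", ")))
  }
  structure(
    list(input = input, synth_spec = synth_spec, path = path,
         channels = channels, group_map = group_map,
         epoch_seconds = epoch_seconds, filter = filter, wavelet = wavelet,
         bands = bands, edge_threshold = edge_threshold,
         fisher_z = fisher_z, summary = summary,
         report_bands = report_bands, alpha = alpha, p_adjust = p_adjust,
         coords = coords, out_dir = out_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Thin front end over [run_config()]: recognised keys mirror its
#' arguments (`filter`, `wavelet`, `synth` and `bands` are nested maps);
#' unknown keys are rejected rather than ignored.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("input", "path", "channels", "group_map", "epoch_seconds",
             "filter", "wavelet", "bands", "edge_threshold", "fisher_z",
             "summary", "report_bands", "alpha", "p_adjust", "out_dir",
             "seed", "synth")
  bad <- setdiff(names(y), known)
  if (length(bad)) {
    abort(sprintf("Unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  args <- y[intersect(names(y), c("input", "path", "epoch_seconds",
                                  "edge_threshold", "fisher_z", "summary",
                                  "report_bands", "alpha", "p_adjust",
                                  "out_dir", "seed"))]
  if (!is.null(y$channels)) args$channels <- as.character(y$channels)
  if (!is.null(y$group_map)) args$group_map <- unlist(y$group_map)
  if (!is.null(y$filter)) args$filter <- do.call(filter_spec, y$filter)
  if (!is.null(y$wavelet)) args$wavelet <- do.call(wavelet_spec, y$wavelet)
  if (!is.null(y$bands)) {
    args$bands <- tibble(
      band = factor(names(y$bands), levels = names(y$bands)),
      f_low = vapply(y$bands, function(b) b[[1]], numeric(1)),
      f_high = vapply(y$bands, function(b) b[[2]], numeric(1))
    )
  }
  if (!is.null(y$synth)) args$synth_spec <- do.call(cohort_spec, y$synth)
  do.call(run_config, args)
}

#' Per-subject band connectivity and features
#'
#' One subject's full single-subject pass: preprocess, cut into epochs,
#' wavelet-packet decompose each channel of each epoch, collect each
#' band's absolute-coefficient matrices, and correlate channels per band.
#'
#' @param rec an [eeg_recording()].
#' @param config a [run_config()] (its filter/wavelet/band/epoch settings
#'   are used).
#' @return List: `connectivity` (named list of `osa_connectivity`, one
#'   per report band), `features` (tibble `band`, `mean_abs_coeff`,
#'   `mean_pos_r`), `degrees` (named numeric, node degree per channel
#'   per band in a `band.channel` nested tibble).
#' @export
subject_band_analysis <- function(rec, config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$channels)) rec <- select_channels(rec, config$channels)
  rec <- preprocess_recording(rec, config$filter)
  epochs <- make_epochs(rec, config$epoch_seconds)
  bands_used <- config$report_bands
  # per epoch, per channel decomposition; abs coeffs per band
  feats <- lapply(epochs, function(ep) {
    trees <- lapply(seq_len(nrow(ep$data)), function(i) {
      wpd_decompose(ep$data[i, ], config$wavelet)
    })
    out <- lapply(bands_used, function(b) {
      m <- do.call(rbind, lapply(trees, function(tr) {
        extract_band(tr, b, rec$fs, config$bands, reconstruct = FALSE)$abs_coeffs
      }))
      rownames(m) <- rec$channel_labels
      m
    })
    names(out) <- bands_used
    out
  })
  conn <- lapply(bands_used, function(b) {
    band_connectivity(lapply(feats, `[[`, b), band = b,
                      fisher_z = config$fisher_z)
  })
  names(conn) <- bands_used
  features <- purrr::map_dfr(bands_used, function(b) {
    offdiag <- conn[[b]]$r[upper.tri(conn[[b]]$r)]
    tibble(
      band = b,
      mean_abs_coeff = mean(unlist(lapply(feats, function(f) mean(f[[b]])))),
      mean_pos_r = if (any(offdiag > 0)) mean(offdiag[offdiag > 0]) else 0
    )
  })
  degrees <- purrr::map_dfr(bands_used, function(b) {
    g <- positive_edges(conn[[b]], config$edge_threshold, config$coords)
    tibble(band = b, node = g$nodes$label, degree = g$nodes$degree)
  })
  list(connectivity = conn, features = features, degrees = degrees)
}

load_cohort <- function(config) {
  if (config$input == "synth") {
    cohort <- generate_cohort(config$synth_spec)
    return(list(recordings = lapply(cohort$subjects, `[[`, "recording"),
                manifest = cohort$manifest))
  }
  ext <- if (config$input == "edf") "\\.edf$" else "\\.(tsv|txt|rec)$"
  files <- sort(list.files(config$path, pattern = ext, full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0) {
    abort(sprintf("No %s files found under %s.", config$input, config$path))
  }
  recs <- lapply(files, function(f) {
    sid <- sub("\\.[^.]+$", "", basename(f))
    grp <- unname(config$group_map[sid] %||% NA_character_)
    if (config$input == "edf") {
      read_edf(f, config$channels, subject_id = sid,
               group_label = if (is.na(grp)) "UNKNOWN" else grp)
    } else {
      r <- read_columnar(f)
      r$subject_id <- sid
      if (!is.na(grp)) r$group_label <- grp
      r
    }
  })
  grps <- vapply(recs, `[[`, character(1), "group_label")
  if (any(grps == "UNKNOWN")) {
    abort(sprintf("No group assignment for subject(s): %s",
                  paste(vapply(recs[grps == "UNKNOWN"], `[[`, character(1),
                               "subject_id"), collapse = ", ")))
  }
  manifest <- tibble(
    subject_id = vapply(recs, `[[`, character(1), "subject_id"),
    group = grps
  )
  list(recordings = recs, manifest = manifest)
}

#' Run the full connectivity analysis pipeline
#'
#' Ingests (or synthesizes) the cohort, runs the per-subject band
#' connectivity analysis, summarizes each group's positive-correlation
#' extremes, tests the per-band group contrast nonparametrically,
#' computes per-node Welch t-maps of degree, correlates each t-map with
#' the OSA group's mean degree map, and (optionally) writes a
#' machine-readable report plus BrainNet Viewer files.
#'
#' @param config a [run_config()].
#' @return An `osa_report`: `manifest`, `subject_features`,
#'   `group_summary`, `band_tests`, `degrees`, `tmaps`, `tmap_network_r`,
#'   `group_mean_connectivity`, `config`, `version`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- load_cohort(config)
  subjects <- cohort$recordings
  manifest <- cohort$manifest

  res <- vector("list", length(subjects))
  failed <- character(0)
  for (i in seq_along(subjects)) {
    res[i] <- list(tryCatch(
      subject_band_analysis(subjects[[i]], config),
      error = function(e) {
        warn(sprintf("Subject %s failed and was skipped: %s",
                     subjects[[i]]$subject_id, conditionMessage(e)))
        NULL
      }
    ))
    if (is.null(res[[i]])) failed <- c(failed, subjects[[i]]$subject_id)
  }
  ok <- !vapply(res, is.null, logical(1))
  if (!any(ok)) abort("Every subject failed; nothing to report.")
  res <- res[ok]
  manifest_ok <- manifest[ok, ]
  groups <- manifest_ok$group

  subject_features <- purrr::map2_dfr(res, seq_along(res), function(r, i) {
    dplyr::mutate(r$features,
                  subject_id = manifest_ok$subject_id[i],
                  group = groups[i], .before = 1)
  })
  degrees <- purrr::map2_dfr(res, seq_along(res), function(r, i) {
    dplyr::mutate(r$degrees,
                  subject_id = manifest_ok$subject_id[i],
                  group = groups[i], .before = 1)
  })

  group_summary <- purrr::map_dfr(config$report_bands, function(b) {
    purrr::map_dfr(unique(groups), function(g) {
      group_min_max(lapply(res[groups == g], function(r) r$connectivity[[b]]),
                    band = b, group = g)
    })
  })

  band_tests <- NULL
  tmaps <- list()
  tmap_network_r <- NULL
  both_groups <- all(c("OSA", "HEALTHY") %in% groups) &&
    sum(groups == "OSA") >= 1 && sum(groups == "HEALTHY") >= 1
  if (both_groups) {
    value_col <- config$summary
    band_tests <- compare_bands(
      dplyr::transmute(subject_features, subject_id = .data$subject_id,
                       group = .data$group, band = .data$band,
                       value = .data[[value_col]]),
      alpha = config$alpha, p_adjust = config$p_adjust
    )
    if (sum(groups == "OSA") >= 2 && sum(groups == "HEALTHY") >= 2) {
      deg_mat <- function(g, b) {
        d <- degrees[degrees$group == g & degrees$band == b, ]
        m <- tidyr::pivot_wider(d[, c("subject_id", "node", "degree")],
                                names_from = "node", values_from = "degree")
        as.matrix(m[, -1, drop = FALSE])
      }
      tmaps <- lapply(config$report_bands, function(b) {
        degree_t_map(deg_mat("OSA", b), deg_mat("HEALTHY", b))
      })
      names(tmaps) <- config$report_bands
      tmap_network_r <- purrr::map_dfr(config$report_bands, function(b) {
        ref <- dplyr::summarise(
          dplyr::group_by(degrees[degrees$group == "OSA" &
                                    degrees$band == b, ], .data$node),
          value = mean(.data$degree), .groups = "drop"
        )
        r <- tryCatch(correlate_t_with_network(tmaps[[b]], ref),
                      error = function(e) NA_real_)
        tibble(band = b, r_t_network = r)
      })
    }
  }

  # group-mean connectivity per band (element-wise mean of subject matrices)
  group_mean_connectivity <- list()
  for (g in unique(groups)) {
    group_mean_connectivity[[g]] <- lapply(config$report_bands, function(b) {
      ms <- lapply(res[groups == g], function(r) r$connectivity[[b]])
      rbar <- Reduce(`+`, lapply(ms, `[[`, "r")) / length(ms)
      new_connectivity(rbar, b, ms[[1]]$channel_labels, ms[[1]]$n_obs,
                       length(ms))
    })
    names(group_mean_connectivity[[g]]) <- config$report_bands
  }

  report <- structure(
    list(manifest = manifest_ok, failed_subjects = failed,
         subject_features = subject_features, degrees = degrees,
         group_summary = group_summary, band_tests = band_tests,
         tmaps = tmaps, tmap_network_r = tmap_network_r,
         group_mean_connectivity = group_mean_connectivity,
         config = config,
         version = as.character(utils::packageVersion("osaconnect"))),
    class = "osa_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$group_summary,
                   file.path(dir, "group_summary.csv"), row.names = FALSE)
  utils::write.csv(report$subject_features,
                   file.path(dir, "subject_features.csv"), row.names = FALSE)
  utils::write.csv(report$degrees, file.path(dir, "degrees.csv"),
                   row.names = FALSE)
  if (!is.null(report$band_tests)) {
    utils::write.csv(as.data.frame(report$band_tests),
                     file.path(dir, "band_tests.csv"), row.names = FALSE)
  }
  for (g in names(report$group_mean_connectivity)) {
    for (b in names(report$group_mean_connectivity[[g]])) {
      m <- report$group_mean_connectivity[[g]][[b]]
      utils::write.csv(m$r,
                       file.path(dir, sprintf("connectivity_%s_%s.csv", g, b)))
      gph <- positive_edges(m, report$config$edge_threshold,
                            report$config$coords)
      export_brainnet(gph,
                      file.path(dir, sprintf("%s_%s.node", g, b)),
                      file.path(dir, sprintf("%s_%s.edge", g, b)))
    }
  }
  json <- list(
    version = report$version,
    seed = report$config$seed,
    n_subjects = nrow(report$manifest),
    failed_subjects = report$failed_subjects,
    groups = as.list(table(report$manifest$group)),
    group_summary = report$group_summary,
    band_tests = if (!is.null(report$band_tests))
      as.data.frame(report$band_tests),
    tmap_network_r = report$tmap_network_r
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.osa_report <- function(x, ...) {
  cat(sprintf("<osa_report> %d subjects (%s)\n", nrow(x$manifest),
              paste(sprintf("%s: %d", names(table(x$manifest$group)),
                            table(x$manifest$group)), collapse = ", ")))
  cat("\nGroup positive-correlation extremes:\n")
  print(as.data.frame(x$group_summary), row.names = FALSE)
  if (!is.null(x$band_tests)) {
    cat("\nPer-band Mann-Whitney-Wilcoxon:\n")
    print(as.data.frame(x$band_tests), row.names = FALSE)
  }
  invisible(x)
}

#' One-row summary of a pipeline report
#'
#' @param x an `osa_report`.
#' @param ... unused.
#' @return Tibble with cohort sizes and the headline delta-band numbers.
#' @export
glance.osa_report <- function(x, ...) {
  gs <- x$group_summary
  delta_osa <- gs[gs$band == "delta" & gs$group == "OSA", ]
  delta_h <- gs[gs$band == "delta" & gs$group == "HEALTHY", ]
  tibble(
    n_subjects = nrow(x$manifest),
    n_osa = sum(x$manifest$group == "OSA"),
    n_healthy = sum(x$manifest$group == "HEALTHY"),
    delta_osa_max_pos_r = if (nrow(delta_osa)) delta_osa$max_pos_r else NA_real_,
    delta_healthy_max_pos_r = if (nrow(delta_h)) delta_h$max_pos_r else NA_real_,
    delta_p = if (!is.null(x$band_tests)) {
      x$band_tests$p_value[x$band_tests$band == "delta"]
    } else NA_real_,
    version = x$version
  )
}
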