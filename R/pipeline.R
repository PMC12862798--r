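#' Build a pipeline run configuration
#'
#' One structured object (round-trippable through YAML) holding every
#' parameter of the contacts -> cluster -> fit -> content chain.
#'
#' @param input list with either `distance_csvs` (character vector of
#'   distance-table CSVs, one per trajectory) or `trajectories` (+ optional
#'   `topology`) coordinate files with `dt_ns`; `transform` names the stored
#'   transform of CSV input.
#' @param contacts a [contact_criteria()].
#' @param mosaic a [mosaic_config()] plus `method` ("pearson_abs"/"nmi") and
#'   `stride` via the arguments below.
#' @param method correlation method for the cluster stage.
#' @param stride subsampling stride for the cluster stage.
#' @param maxent a [maxent_config()].
#' @param grid list with `per_decade` (default 10) and optional `t_min`,
#'   `t_max` (ns); when missing, the grid spans twice the frame interval to
#'   the extended data window.
#' @param output_dir directory for all stage outputs and the run manifest.
#' @param seed integer seed recorded in the config and used for clustering.
#' @param log_level `"info"`, `"debug"` or `"quiet"`.
#' @return list of class `"cd_run_config"`.
#' @export
run_config <- function(input, contacts = contact_criteria(),
                       mosaic = mosaic_config(), method = "pearson_abs",
                       stride = 5L, maxent = maxent_config(),
                       grid = list(per_decade = 10L), output_dir = "cd_run",
                       seed = 42L, log_level = "info") {
  stopifnot(is.list(input))
  if (is.null(input$distance_csvs) && is.null(input$trajectories)) {
    stop("input must provide distance_csvs or trajectories")
  }
  mosaic$seed <- as.integer(seed)
  structure(list(input = input, contacts = contacts, mosaic = mosaic,
                 method = method, stride = as.integer(stride),
                 maxent = maxent, grid = grid, output_dir = output_dir,
                 seed = as.integer(seed), log_level = log_level),
            class = "cd_run_config")
}

#' Write / read a run configuration as YAML
#' @param config a [run_config()].
#' @param file YAML path.
#' @return `file` (write) or the restored `"cd_run_config"` (read).
#' @export
strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

write_run_config <- function(config, file) {
  yaml::write_yaml(strip_classes(unclass(config)), file)
  invisible(file)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(file) {
  raw <- yaml::read_yaml(file)
  cc <- do.call(contact_criteria, raw$contacts)
  mc <- do.call(mosaic_config, raw$mosaic[c("gamma", "min_cluster_size",
                                            "n_restarts", "seed")])
  xc <- do.call(maxent_config, raw$maxent[!vapply(raw$maxent, is.null, TRUE)])
  run_config(input = raw$input, contacts = cc, mosaic = mc,
             method = raw$method, stride = raw$stride, maxent = xc,
             grid = raw$grid, output_dir = raw$output_dir, seed = raw$seed,
             log_level = raw$log_level)
}

cd_log <- function(config, level, ...) {
  lv <- c(quiet = 0, info = 1, debug = 2)
  if (lv[[config$log_level]] >= lv[[level]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
}

stage_paths <- function(config) {
  out <- config$output_dir
  list(
    contacts = c(contact_set = file.path(out, "contacts.tsv")),
    distances_dir = file.path(out, "distances"),
    cluster = c(correlation = file.path(out, "correlation.csv"),
                reordered = file.path(out, "correlation_reordered.csv"),
                partition_json = file.path(out, "partition.json"),
                partition_tsv = file.path(out, "partition.tsv")),
    fit = c(spectra = file.path(out, "spectra.csv"),
            diagnostics = file.path(out, "fit_diagnostics.json")),
    content = c(content = file.path(out, "content.csv"),
                peaks = file.path(out, "content_peaks.json")),
    manifest = file.path(out, "run_manifest.json"))
}

# files of one stage, all existing with checksums matching a prior manifest
stage_reusable <- function(files, manifest) {
  if (is.null(manifest)) return(FALSE)
  if (!all(file.exists(files))) return(FALSE)
  rec <- manifest$checksums
  cur <- unname(tools::md5sum(files))
  all(vapply(files, function(f) {
    !is.null(rec[[basename(f)]]) &&
      identical(rec[[basename(f)]], unname(tools::md5sum(f)))
  }, logical(1)))
}

pipeline_distance_files <- function(config, paths) {
  if (!is.null(config$input$distance_csvs)) {
    config$input$distance_csvs
  } else {
    list.files(paths$distances_dir, pattern = "\\.csv$", full.names = TRUE)
  }
}

#' Run the contact-cluster / timescale pipeline
#'
#' Executes the stages contacts -> cluster -> fit -> content, persisting
#' every intermediate under the configured output directory and writing a
#' run manifest (config snapshot, package version, per-file MD5 checksums,
#' timestamps, warnings) last. With `resume = TRUE`, stages whose outputs
#' exist and match the checksums of the previous manifest are skipped. Given
#' identical config, inputs and seed, the numeric output files are
#' byte-identical across runs.
#'
#' @param config a [run_config()].
#' @param resume reuse checksum-valid intermediates from a previous run.
#' @param stages subset of `c("contacts", "cluster", "fit", "content")` to
#'   run (in pipeline order).
#' @return the run manifest (list), invisibly written as JSON.
#' @export
run_pipeline <- function(config, resume = FALSE,
                         stages = c("contacts", "cluster", "fit", "content")) {
  stopifnot(inherits(config, "cd_run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  paths <- stage_paths(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  prev_manifest <- if (file.exists(paths$manifest)) {
    jsonlite::read_json(paths$manifest, simplifyVector = FALSE)
  } else NULL
  if (!is.null(prev_manifest)) {
    prev_manifest$checksums <- lapply(prev_manifest$checksums, unlist)
  }
  manifest <- list(config = strip_classes(unclass(config)),
                   version = as.character(utils::packageVersion("contactdyn")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list(), checksums = list(), warnings = list())
  record <- function(stage, files, status = "done") {
    files <- files[file.exists(files)]
    for (f in files) manifest$checksums[[basename(f)]] <<- unname(tools::md5sum(f))
    manifest$stages[[stage]] <<- list(status = status,
                                      outputs = basename(files),
                                      time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  }
  fail <- function(stage, err) {
    manifest$stages[[stage]] <- list(status = "failed", error = conditionMessage(err))
    manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(err),
         call. = FALSE)
  }

  ## stage: contacts -------------------------------------------------------
  if ("contacts" %in% stages) {
    dist_out <- pipeline_distance_files(config, paths)
    files <- c(paths$contacts, if (is.null(config$input$distance_csvs)) dist_out)
    if (resume && stage_reusable(files, prev_manifest)) {
      cd_log(config, "info", "contacts: reusing checksum-valid outputs")
      record("contacts", files, "reused")
    } else tryCatch({
      if (!is.null(config$input$distance_csvs)) {
        ser <- read_distance_csv(config$input$distance_csvs,
                                 transform = config$input$transform %||% "distance")
        cs <- unique(data.frame(
          res_a = vapply(ser, `[[`, integer(1), "res_a"),
          res_b = vapply(ser, `[[`, integer(1), "res_b"),
          population = NA_real_))
        cs <- cs[order(cs$res_a, cs$res_b), ]
        class(cs) <- c("cd_contact_set", "data.frame")
        write_contact_set(cs, paths$contacts[["contact_set"]])
        cd_log(config, "info", sprintf("contacts: %d features from %d CSV file(s)",
                                       nrow(cs), length(config$input$distance_csvs)))
        record("contacts", paths$contacts)
      } else {
        ens <- read_structure_ensemble(config$input$trajectories,
                                       dt_ns = config$input$dt_ns,
                                       topology_file = config$input$topology)
        cs <- identify_contacts(ens, config$contacts)
        write_contact_set(cs, paths$contacts[["contact_set"]])
        ser <- extract_series(ens, cs, config$contacts)
        dir.create(paths$distances_dir, showWarnings = FALSE)
        tids <- unique(vapply(ser, `[[`, "", "trajectory_id"))
        dist_out <- file.path(paths$distances_dir, paste0(tids, ".csv"))
        for (i in seq_along(tids)) {
          sub <- ser[vapply(ser, `[[`, "", "trajectory_id") == tids[i]]
          class(sub) <- "cd_series_list"
          write_distance_csv(sub, dist_out[i])
        }
        cd_log(config, "info", sprintf("contacts: %d features, %d trajectories",
                                       nrow(cs), length(tids)))
        record("contacts", c(paths$contacts, dist_out))
      }
    }, error = function(e) fail("contacts", e))
  }

  ## stage: cluster --------------------------------------------------------
  if ("cluster" %in% stages) {
    if (resume && stage_reusable(paths$cluster, prev_manifest)) {
      cd_log(config, "info", "cluster: reusing checksum-valid outputs")
      record("cluster", paths$cluster, "reused")
    } else tryCatch({
      ser <- read_distance_csv(pipeline_distance_files(config, paths),
                               transform = config$input$transform %||% "distance")
      x <- series_feature_matrix(ser, stride = config$stride)
      model <- withCallingHandlers(
        correlation_matrix(x, method = config$method),
        warning = function(w) {
          manifest$warnings[[length(manifest$warnings) + 1L]] <<- conditionMessage(w)
          invokeRestart("muffleWarning")
        })
      part <- leiden_cpm(model, config$mosaic)
      write_correlation_csv(model, paths$cluster[["correlation"]])
      write_correlation_csv(reorder_block_diagonal(model, part),
                            paths$cluster[["reordered"]])
      write_partition(part, paths$cluster[["partition_json"]])
      write_partition(part, paths$cluster[["partition_tsv"]])
      cd_log(config, "info", sprintf("cluster: %d clusters, %d noise features, CPM objective %.6g",
                                     length(part$clusters), length(part$noise),
                                     part$objective))
      record("cluster", paths$cluster)
    }, error = function(e) fail("cluster", e))
  }

  ## stage: fit ------------------------------------------------------------
  if ("fit" %in% stages) {
    if (resume && stage_reusable(paths$fit, prev_manifest)) {
      cd_log(config, "info", "fit: reusing checksum-valid outputs")
      record("fit", paths$fit, "reused")
    } else tryCatch({
      ser <- read_distance_csv(pipeline_distance_files(config, paths),
                               transform = config$input$transform %||% "distance")
      feats <- unique(vapply(ser, `[[`, "", "contact"))
      pr <- parse_contact_name(feats)
      feats <- feats[order(pr$res_a, pr$res_b)]
      spectra <- list()
      diags <- list()
      for (f in feats) {
        sub <- ser[vapply(ser, `[[`, "", "contact") == f]
        class(sub) <- "cd_series_list"
        resp <- ensemble_average(sub)
        prep <- preprocess(resp, config$maxent)
        dt <- min(diff(resp$times))
        t_min <- config$grid$t_min %||% (2 * dt)
        t_max <- config$grid$t_max %||% max(resp$times)
        grid <- build_tau_grid(t_min, t_max,
                               per_decade = config$grid$per_decade %||% 10L,
                               extend_decades = config$maxent$extend_decades)
        sp <- maxent_fit(prep, grid, config$maxent)
        spectra[[f]] <- sp
        diags[[f]] <- list(chi2 = sp$chi2, entropy = sp$entropy,
                           offset = sp$offset, lam = sp$lam,
                           converged = sp$converged)
      }
      write_spectra_csv(spectra, paths$fit[["spectra"]])
      jsonlite::write_json(diags, paths$fit[["diagnostics"]],
                           auto_unbox = TRUE, digits = NA)
      cd_log(config, "info", sprintf("fit: %d spectra, lambda = %g",
                                     length(spectra), config$maxent$lam))
      record("fit", paths$fit)
    }, error = function(e) fail("fit", e))
  }

  ## stage: content --------------------------------------------------------
  if ("content" %in% stages) {
    if (resume && stage_reusable(paths$content, prev_manifest)) {
      cd_log(config, "info", "content: reusing checksum-valid outputs")
      record("content", paths$content, "reused")
    } else tryCatch({
      spdf <- utils::read.csv(paths$fit[["spectra"]], check.names = FALSE)
      taus <- spdf$tau_ns
      grid <- structure(list(taus = taus, per_decade = config$grid$per_decade %||% 10L,
                             includes_constant = TRUE), class = "cd_tau_grid")
      spectra <- lapply(setdiff(names(spdf), "tau_ns"), function(f)
        structure(list(feature = f, grid = grid, taus = taus,
                       amplitudes = spdf[[f]]), class = "cd_spectrum"))
      part <- if (file.exists(stage_paths(config)$cluster[["partition_json"]])) {
        read_partition(stage_paths(config)$cluster[["partition_json"]])
      } else NULL
      ct <- dynamical_content(spectra, part)
      write_content_csv(ct, paths$content[["content"]])
      jsonlite::write_json(list(total_peaks = ct$peaks),
                           paths$content[["peaks"]], auto_unbox = TRUE,
                           digits = NA, dataframe = "columns")
      cd_log(config, "info", sprintf("content: %d peaks at tau = %s ns",
                                     nrow(ct$peaks),
                                     paste(signif(ct$peaks$tau, 3), collapse = ", ")))
      record("content", paths$content)
    }, error = function(e) fail("content", e))
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
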