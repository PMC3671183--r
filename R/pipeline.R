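# Config-driven pipeline: simulate -> scan -> average -> window stats -> qPCR.

#' Default pipeline configuration
#'
#' A complete configuration mirroring the cohort preset: three animals with
#' two images and two scans per image for each of the three probes, averaging
#' on 500- then 100-point grids, windowed statistics over \[0.63, 0.93\] for
#' the Gb1/Gg13 pair, and a qPCR block with designed relative expressions
#' (Gb1 1.3, Gg8 0.5, Gg13 9.3 against a Gapdh reference).
#'
#' @param seed global seed; every stochastic stage draws from a deterministic
#'   substream of it.
#' @return nested list understood by [run_pipeline()] / [validate_config()].
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = c("simulate", "scan", "average", "window_stats", "qpcr"),
    output_dir = "episcan_out",
    simulate = list(
      model = list(
        image_height_px = 256L, image_width_px = 512L,
        lamina_baseline_px = 180, lamina_amplitude_px = 12,
        lamina_wavelength_px = 480,
        noise_sd = 0.05, blob_density_per_um2 = 0
      ),
      probes = c("Gb1", "Gg13", "GAP43"),
      n_animals = 3L, images_per_animal = 2L, scans_per_image = 2L,
      step_px = 1
    ),
    average = list(n_points_animal = 500L, n_points_group = 100L),
    window_stats = list(window = c(0.63, 0.93), pair = c("Gb1", "Gg13"),
                        mode = "pointwise_values"),
    qpcr = list(
      reference_gene = "Gapdh",
      true_rel_expression = c(Gb1 = 1.3, Gg8 = 0.5, Gg13 = 9.3),
      n_biological = 3L, n_technical = 3L,
      ct_reference_mean = 18, ct_noise_sd = 0.2,
      mode = "delta_ct"
    )
  )
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("unreadable config file: ", config,
                                   call. = FALSE)
    ext <- tolower(tools::file_ext(config))
    cfg <- if (ext == "json") jsonlite::fromJSON(config, simplifyVector = TRUE)
           else yaml::read_yaml(config)
    attr(cfg, "base_dir") <- dirname(normalizePath(config))
    cfg
  } else if (is.list(config)) {
    attr(config, "base_dir") <- attr(config, "base_dir") %||% getwd()
    config
  } else stop("config must be a file path or a list", call. = FALSE)
}

#' Validate a pipeline configuration
#'
#' Checks the configuration without running anything and returns structured
#' findings; an empty result means the configuration is valid.
#'
#' @param config path to a YAML/JSON config or a config list
#'   (see [default_pipeline_config()]).
#' @return data.frame with columns `key`, `severity`, `message`
#'   (zero rows when valid).
#' @export
validate_config <- function(config) {
  cfg <- read_config(config)
  findings <- list()
  note <- function(key, message, severity = "error") {
    findings[[length(findings) + 1L]] <<- data.frame(
      key = key, severity = severity, message = message,
      stringsAsFactors = FALSE)
  }
  known <- c("simulate", "scan", "average", "window_stats", "qpcr")
  stages <- cfg$stages %||% character(0)
  if (length(stages) == 0L) note("stages", "no stages requested")
  bad <- setdiff(stages, known)
  if (length(bad)) note("stages", paste("unknown stage(s):",
                                        paste(bad, collapse = ", ")))
  if (is.null(cfg$seed) && any(c("simulate", "qpcr") %in% stages)) {
    note("seed", "seed is required when stochastic stages run")
  }
  if ("simulate" %in% stages) {
    sim <- cfg$simulate
    if (is.null(sim)) note("simulate", "simulate block missing")
    else {
      m <- try(do.call(moe_cohort_model,
                       c(sim$model %||% list(), list(seed = cfg$seed %||% 1L))),
               silent = TRUE)
      if (inherits(m, "try-error")) {
        note("simulate.model", conditionMessage(attr(m, "condition")))
      } else if (!all((sim$probes %||% names(m$probe_profiles)) %in%
                      names(m$probe_profiles))) {
        note("simulate.probes", "probe not defined in the model")
      }
    }
  }
  if ("window_stats" %in% stages) {
    w <- cfg$window_stats$window
    if (is.numeric(w) && length(w) == 2L && w[1] >= w[2]) {
      note("window_stats.window", "x1 < x2 violated")
    }
    if (is.null(cfg$window_stats$pair) ||
        length(cfg$window_stats$pair) != 2L) {
      note("window_stats.pair", "exactly two probes must be named")
    }
  }
  if ("qpcr" %in% stages) {
    q <- cfg$qpcr
    if (is.null(q$reference_gene)) {
      note("qpcr.reference_gene", "reference gene missing")
    }
    if (is.null(q$true_rel_expression)) {
      note("qpcr.true_rel_expression", "designed relative expressions missing")
    } else if (any(unlist(q$true_rel_expression) <= 0)) {
      note("qpcr.true_rel_expression", "relative expressions must be > 0")
    }
  }
  if (length(findings)) do.call(rbind, findings) else
    data.frame(key = character(0), severity = character(0),
               message = character(0), stringsAsFactors = FALSE)
}

#' Run the full pipeline from one configuration
#'
#' Executes the requested stages in dependency order, writing every
#' interchange file under `output_dir` (resolved relative to the config file)
#' and returning a machine-readable run report. All randomness derives from
#' deterministic, stage-named substreams of the global seed, so reruns with
#' an identical configuration reproduce identical summaries.
#'
#' Stage artifacts: `simulate` writes per-section TIFF images, lamina-trace
#' CSVs, expected-profile CSVs and a scan manifest; `scan` reads the manifest
#' and writes `profiles.csv`; `average` writes `averaged.csv`; `window_stats`
#' writes `stats.json`; `qpcr` writes `ct.csv`, `relative_expression.csv` and
#' `anova.json`. The report itself is written to `report_path` (default
#' `report.json` in `output_dir`).
#'
#' @param config path to a YAML/JSON configuration, or a config list.
#' @param report_path optional path for the JSON run report.
#' @return the run report, invisibly (a list; also serialized to JSON).
#' @export
run_pipeline <- function(config, report_path = NULL) {
  cfg <- read_config(config)
  findings <- validate_config(cfg)
  if (nrow(findings)) {
    stop("invalid config: ",
         paste(sprintf("[%s] %s", findings$key, findings$message),
               collapse = "; "), call. = FALSE)
  }
  base_dir <- attr(cfg, "base_dir")
  out_dir <- cfg$output_dir %||% "episcan_out"
  if (!grepl("^(/|[A-Za-z]:)", out_dir)) out_dir <- file.path(base_dir, out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- cfg$stages
  seed <- cfg$seed %||% 1L
  report <- list(seed = seed, stages = stages,
                 package_version = as.character(utils::packageVersion("episcan")),
                 outputs = list(), parameters = list(), summary = list())
  msg <- function(stage, ...) message(sprintf("[episcan:%s] %s", stage,
                                              paste0(...)))

  manifest_path <- file.path(out_dir, "scan_manifest.csv")
  profiles_path <- file.path(out_dir, "profiles.csv")
  averaged_path <- file.path(out_dir, "averaged.csv")

  if ("simulate" %in% stages) {
    msg("simulate", "generating synthetic sections")
    sim <- cfg$simulate
    model <- do.call(moe_cohort_model,
                     c(sim$model %||% list(),
                       list(seed = seed_substream(seed, "simulate"))))
    probes <- sim$probes %||% names(model$probe_profiles)
    n_a <- sim$n_animals %||% 3L
    n_i <- sim$images_per_animal %||% 2L
    n_s <- sim$scans_per_image %||% 2L
    step_px <- sim$step_px %||% 1
    rows <- list()
    for (p in probes) {
      for (a in seq_len(n_a)) {
        for (i in seq_len(n_i)) {
          s <- seed_substream(seed_substream(seed, "simulate"),
                              sprintf("%s/a%d/i%d", p, a, i))
          gen <- generate_epithelium_image(model, p, seed = s)
          stub <- sprintf("%s_a%d_i%d", p, a, i)
          img_path <- file.path(out_dir, paste0(stub, ".tif"))
          trace_path <- file.path(out_dir, paste0(stub, "_lamina.csv"))
          write_rish_image(as_brightfield(gen$image), img_path)
          write_lamina_trace(gen$truth$lamina_trace, trace_path)
          for (k in seq_len(n_s)) {
            rows[[length(rows) + 1L]] <- data.frame(
              probe = p, animal_id = sprintf("a%d", a),
              image_id = sprintf("i%d", i), scan_id = sprintf("s%d", k),
              image_path = basename(img_path),
              trace_path = basename(trace_path),
              anchor_index = scan_anchor_cols(model$image_width_px, n_s)[k] + 1L,
              pixel_size_um = model$pixel_size_um,
              step_px = step_px, stringsAsFactors = FALSE)
          }
        }
      }
    }
    # expected (ground-truth) profiles for reference
    exp_rows <- do.call(rbind, lapply(probes, function(p) {
      tr <- generate_epithelium_image(model, p, seed = 1L)$truth
      br <- tr$expected_profile$breaks; v <- tr$expected_profile$values
      data.frame(probe = p, x_from = br[-length(br)], x_to = br[-1],
                 intensity = v, stringsAsFactors = FALSE)
    }))
    utils::write.csv(exp_rows, file.path(out_dir, "expected_profiles.csv"),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, rows), manifest_path, row.names = FALSE)
    report$parameters$simulate <- sim
    report$outputs$simulate <- c("scan_manifest.csv", "expected_profiles.csv")
  }

  if ("scan" %in% stages) {
    msg("scan", "extracting line-intensity profiles")
    if (!file.exists(manifest_path)) {
      stop("missing upstream artifact: ", manifest_path, call. = FALSE)
    }
    man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
    profs <- vector("list", nrow(man))
    img_cache <- new.env(parent = emptyenv())
    for (r in seq_len(nrow(man))) {
      key <- man$image_path[r]
      if (is.null(img_cache[[key]])) {
        img <- read_rish_image(file.path(out_dir, man$image_path[r]),
                               pixel_size_um = man$pixel_size_um[r])
        img$pixels <- img$pixels / dtype_max(img$dtype)  # to real scale
        img$dtype <- "real"
        img_cache[[key]] <- list(
          img = invert_image(img),
          trace = read_lamina_trace(file.path(out_dir, man$trace_path[r])))
      }
      ic <- img_cache[[key]]
      sl <- scan_line(ic$trace, anchor_index = man$anchor_index[r],
                      length_um = NULL,
                      pixel_size_um = man$pixel_size_um[r],
                      step_um = man$step_px[r] * man$pixel_size_um[r])
      profs[[r]] <- extract_scan(ic$img, sl, meta = list(
        probe = man$probe[r], animal_id = man$animal_id[r],
        image_id = man$image_id[r], scan_id = man$scan_id[r]))
    }
    write_profiles(profs, profiles_path)
    report$outputs$scan <- "profiles.csv"
  }

  if ("average" %in% stages) {
    msg("average", "normalizing and averaging profiles")
    if (!file.exists(profiles_path)) {
      stop("missing upstream artifact: ", profiles_path, call. = FALSE)
    }
    profs <- read_profiles(profiles_path)
    profs <- lapply(profs, function(p) if (p$normalized) p else
      normalize_profile(p))
    cfg_avg <- averaging_config(
      n_points_animal = cfg$average$n_points_animal %||% 500L,
      n_points_group = cfg$average$n_points_group %||% 100L)
    curves <- group_curves(profs, cfg_avg)
    write_averaged(curves, averaged_path)
    report$parameters$average <- cfg$average
    report$outputs$average <- "averaged.csv"
  }

  if ("window_stats" %in% stages) {
    msg("window_stats", "windowed integrals and KS comparison")
    if (!file.exists(averaged_path)) {
      stop("missing upstream artifact: ", averaged_path, call. = FALSE)
    }
    curves <- read_averaged(averaged_path)
    ws <- cfg$window_stats
    win <- if (is.character(ws$window)) derive_window(curves[[ws$window]])
           else marker_window(ws$window[1], ws$window[2])
    pair <- ws$pair
    ints <- compare_windowed_integrals(curves[pair], win)
    ks <- ks_compare(curves[[pair[1]]], curves[[pair[2]]], win,
                     mode = ws$mode %||% "pointwise_values",
                     n_for_p = ws$n_for_p %||% "scans")
    stats_out <- list(
      window = c(x1 = win$x1, x2 = win$x2), window_source = win$source,
      integrals = stats::setNames(ints$integrals$value, ints$integrals$probe),
      ratio = unname(ints$integrals$value[1] / ints$integrals$value[2]),
      ks = list(D = ks$D, p_value = ks$p_value, mode = ks$mode,
                n1 = ks$n1, n2 = ks$n2, n_meaning = ks$n_meaning,
                p_value_defined = ks$p_value_defined))
    jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report$outputs$window_stats <- "stats.json"
    report$summary$window_stats <- stats_out
  }

  if ("qpcr" %in% stages) {
    msg("qpcr", "relative quantification and ANOVA")
    q <- cfg$qpcr
    design <- ct_design(
      true_rel_expression = unlist(q$true_rel_expression),
      reference_gene = q$reference_gene %||% "Gapdh",
      n_biological = q$n_biological %||% 3L,
      n_technical = q$n_technical %||% 3L,
      ct_reference_mean = q$ct_reference_mean %||% 18,
      ct_noise_sd = q$ct_noise_sd %||% 0.2,
      seed = seed_substream(seed, "qpcr"))
    ct <- generate_ct_table(design)
    write_ct_table(ct, file.path(out_dir, "ct.csv"))
    rel <- relative_expression(ct, mode = q$mode %||% "delta_ct",
                               calibrator_group = q$calibrator_group)
    utils::write.csv(as.data.frame(rel),
                     file.path(out_dir, "relative_expression.csv"),
                     row.names = FALSE)
    # per-sample folds among non-reference genes feed the ANOVA
    m <- delta_ct_per_sample(ct, design$reference_gene)
    m <- m[m$gene != design$reference_gene, ]
    m$fold_sample <- 2^-m$delta_ct
    av <- anova_tukey(m$fold_sample, m$gene)
    anova_out <- list(F = av$F, df_between = av$df_between,
                      df_within = av$df_within, p_value = av$p_value,
                      degenerate = av$degenerate, tukey = av$tukey)
    jsonlite::write_json(anova_out, file.path(out_dir, "anova.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report$parameters$qpcr <- q
    report$outputs$qpcr <- c("ct.csv", "relative_expression.csv", "anova.json")
    report$summary$qpcr <- list(
      folds = stats::setNames(rel$fold, paste(rel$gene, rel$group, sep = ":")),
      anova_F = av$F, anova_p = av$p_value)
  }

  # input digests for every declared artifact
  all_files <- unique(unlist(report$outputs))
  if (length(all_files)) {
    digests <- tools::md5sum(file.path(out_dir, all_files))
    report$digests <- stats::setNames(unname(digests), all_files)
  }
  report$output_dir <- out_dir
  report_path <- report_path %||% file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  msg("done", "report written to ", report_path)
  invisible(report)
}
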