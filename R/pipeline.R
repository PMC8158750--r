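# End-to-end orchestration: simulate -> preprocess -> extract -> analyze ->
# train-eval, with a flat serializable configuration, content-addressed
# stage caching, and a small command-line front end.

#' Pipeline configuration
#'
#' One flat key-value configuration covering every stage. Defaults are the
#' package's stated world; see the methods vignette for rationale.
#'
#' @param n_subjects cohort size.
#' @param sr_s,vf_s,ma_s per-subject extent durations, seconds.
#' @param ventilator simulate ventilator pulses in SR extents.
#' @param noise_level sensor-noise SD as a fraction of beat amplitude.
#' @param lms apply ventilator LMS cancellation during preprocessing.
#' @param lms_length,lms_alpha,lms_mu LMS taps / leakage / step size.
#' @param half_width pulse extraction half-width, samples.
#' @param sg_window,sg_order Savitzky-Golay parameters.
#' @param f_lo,f_hi S-transform band, Hz.
#' @param Q quantization levels.
#' @param hbl_lo,hbl_hi heartbeat-length search bounds, samples.
#' @param pi_prominence,pi_separation peak detection parameters.
#' @param fdr FDR level for feature relevance.
#' @param cut_height feature-cluster dendrogram cut.
#' @param feature_mode `"paper"` (fixed 13-feature subset) or
#'   `"data_driven"`.
#' @param model `"rf"` or `"lr"`.
#' @param paradigm `"kfold10"` or `"loso"`.
#' @param repeats evaluation repetitions.
#' @param ntree random-forest size.
#' @param seed master seed.
#' @return named list of class `bcg_pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 23L, sr_s = 84, vf_s = 14, ma_s = 27,
                            ventilator = TRUE, noise_level = 0.15,
                            lms = TRUE, lms_length = 64L, lms_alpha = 1,
                            lms_mu = 1e-8, half_width = 30L,
                            sg_window = 31L, sg_order = 3L,
                            f_lo = 1, f_hi = 20, Q = 10L,
                            hbl_lo = 44L, hbl_hi = 150L,
                            pi_prominence = 0.1, pi_separation = 20L,
                            fdr = 0.05, cut_height = 1,
                            feature_mode = "paper", model = "rf",
                            paradigm = "kfold10", repeats = 10L,
                            ntree = 100L, seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = c("bcg_pipeline_config", "list"))
}

#' Write / read a pipeline configuration as flat key=value text
#'
#' @param cfg a [pipeline_config()].
#' @param path file path.
#' @return the path / the configuration.
#' @export
write_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    sprintf("%s=%s", k, if (is.numeric(v)) formatC(v, digits = 17,
                                                   format = "g") else as.character(v))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  defaults <- pipeline_config()
  cfg <- defaults
  for (p in kv) {
    k <- trimws(p[1]); v <- trimws(paste(p[-1], collapse = "="))
    if (!k %in% names(defaults)) stop_invalid("unknown config key: ", k)
    proto <- defaults[[k]]
    cfg[[k]] <- if (is.logical(proto)) as.logical(v)
    else if (is.integer(proto)) as.integer(round(as.numeric(v)))
    else if (is.numeric(proto)) as.numeric(v)
    else v
  }
  structure(cfg, class = c("bcg_pipeline_config", "list"))
}

config_transform <- function(cfg) {
  transform_config(f_lo = cfg$f_lo, f_hi = cfg$f_hi,
                   hbl_search = c(cfg$hbl_lo, cfg$hbl_hi), Q = cfg$Q,
                   sg_window = cfg$sg_window, sg_order = cfg$sg_order,
                   pi_prominence = cfg$pi_prominence,
                   pi_separation = cfg$pi_separation)
}

config_tag <- function(cfg) {
  sprintf("%s_seed%d", substr(digest::digest(unclass(cfg)), 1, 8), cfg$seed)
}

#' Run the full pipeline
#'
#' Simulates the configured cohort, preprocesses and segments every
#' recording, extracts the 22-feature matrix, writes the relevance and
#' cluster tables, evaluates the configured classifier, and writes the
#' report. Stage outputs are cached on disk under names containing the
#' configuration hash and seed; an existing stage file is reused instead of
#' recomputed. The run is deterministic under a fixed configuration.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir artifact directory (created if needed).
#' @param quiet suppress progress messages.
#' @return the `bcg_report`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = tempfile("bcgvf_"),
                         quiet = FALSE) {
  stopifnot(inherits(cfg, "bcg_pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tag <- config_tag(cfg)
  say <- function(...) if (!quiet) message(...)
  write_config(cfg, file.path(out_dir, paste0("config_", tag, ".txt")))

  feat_path <- file.path(out_dir, paste0("features_", tag, ".csv"))
  if (file.exists(feat_path)) {
    say("[extract] cached: ", feat_path)
    feats <- read_features(feat_path)
  } else {
    say("[simulate] ", cfg$n_subjects, " subjects")
    cohort <- generate_cohort(cfg$n_subjects,
                              list(sr = cfg$sr_s, vf = cfg$vf_s,
                                   ma = cfg$ma_s),
                              seed = cfg$seed, ventilator = cfg$ventilator,
                              noise_level = cfg$noise_level)
    say("[preprocess] wavelet + ", if (cfg$lms) "LMS" else "no LMS")
    segs <- list()
    for (i in seq_along(cohort)) {
      pre <- preprocess_recording(
        cohort[[i]], lms = cfg$lms,
        state = lms_state(cfg$lms_length, cfg$lms_alpha, cfg$lms_mu,
                          seed = derive_seed(cfg$seed, i)),
        half_width = cfg$half_width, sg_window = cfg$sg_window,
        sg_order = cfg$sg_order)
      segs <- c(segs, segment_recording(pre))
    }
    say("[extract] ", length(segs), " segments")
    feats <- extract_feature_matrix(segs, config_transform(cfg))
    write_features(feats, feat_path)
  }

  rel_path <- file.path(out_dir, paste0("relevance_", tag, ".csv"))
  clu_path <- file.path(out_dir, paste0("clusters_", tag, ".csv"))
  if (!file.exists(rel_path)) {
    say("[analyze] relevance + clustering")
    rel <- relevance_table(feats)
    write.csv(rel, rel_path, row.names = FALSE)
    cl <- cluster_features(feature_correlation(feats), cfg$cut_height)
    write.csv(data.frame(feature = FEATURE_NAMES, cluster = cl$clusters),
              clu_path, row.names = FALSE)
  }

  idx <- if (cfg$feature_mode == "paper") {
    select_features("paper")
  } else {
    select_features("data_driven", feats, fdr = cfg$fdr,
                    cut_height = cfg$cut_height)
  }
  say("[train-eval] ", cfg$model, " / ", cfg$paradigm,
      " on features ", paste(idx, collapse = ","))
  report <- evaluate(feats, feature_idx = idx, model = cfg$model,
                     paradigm = cfg$paradigm, repeats = cfg$repeats,
                     seed = cfg$seed, ntree = cfg$ntree)
  rep_path <- file.path(out_dir, paste0("report_", tag, ".json"))
  jsonlite::write_json(
    list(paradigm = report$paradigm, model = report$model,
         repeats = report$repeats, feature_idx = report$feature_idx,
         counts = as.list(report$counts),
         mean = as.list(report$mean), sd = as.list(report$sd),
         per_repeat = as.data.frame(report$per_repeat)),
    rep_path, auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(t(report$counts)),
            file.path(out_dir, paste0("confusion_", tag, ".csv")),
            row.names = FALSE)
  say("[done] report: ", rep_path)
  invisible(report)
}

cli_parse <- function(args) {
  out <- list(flags = character(0), opts = list())
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        out$opts[[key]] <- args[i + 1L]
        i <- i + 2L
      } else {
        out$flags <- c(out$flags, key)
        i <- i + 1L
      }
    } else {
      out$flags <- c(out$flags, a)
      i <- i + 1L
    }
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort to CSV), `preprocess`
#' (filter + segment recordings), `extract` (feature matrix from segments),
#' `analyze` (relevance + cluster tables from features), `train-eval`
#' (classifier report from features), `run-all` (whole pipeline). Options
#' mirror [pipeline_config()] keys, e.g. `--seed 7 --subjects 23
#' --out DIR --model rf --paradigm loso --repeats 10`; `--config FILE`
#' loads a key=value file first. Returns the exit status (0 ok, 2 usage
#' error, 1 internal error) instead of quitting, so it is testable; wrap
#' with `quit(status = ...)` in a script.
#'
#' @param args character vector (default `commandArgs(trailingOnly=TRUE)`).
#' @return integer exit status, invisibly.
#' @export
bcgvf_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: bcgvf <simulate|preprocess|extract|analyze|train-eval|run-all>",
    "  common: --out DIR --seed N --config FILE",
    "  simulate: --subjects N --mix sr,vf,ma --ventilator --sr-s S --vf-s S --ma-s S",
    "  preprocess: --in DIR [--no-lms]",
    "  extract: --in SEGMENTS.csv", "  analyze: --in FEATURES.csv",
    "  train-eval: --in FEATURES.csv --model rf|lr --paradigm kfold|loso --repeats N",
    sep = "\n")
  status <- tryCatch({
    p <- cli_parse(args)
    cmd <- p$flags[1]
    if (is.na(cmd)) { cat(usage, "\n"); return(invisible(2L)) }
    cfg <- if (!is.null(p$opts$config)) read_config(p$opts$config)
           else pipeline_config()
    opt <- function(key, default) {
      if (!is.null(p$opts[[key]])) p$opts[[key]] else default
    }
    cfg$seed <- as.integer(opt("seed", cfg$seed))
    out_dir <- opt("out", ".")
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    switch(cmd,
      simulate = {
        cfg$n_subjects <- as.integer(opt("subjects", cfg$n_subjects))
        mix <- strsplit(opt("mix", "sr,vf,ma"), ",")[[1]]
        spec <- list(sr = as.numeric(opt("sr-s", cfg$sr_s)),
                     vf = as.numeric(opt("vf-s", cfg$vf_s)),
                     ma = as.numeric(opt("ma-s", cfg$ma_s)))
        spec[setdiff(names(spec), mix)] <- 0
        cohort <- generate_cohort(cfg$n_subjects, spec, seed = cfg$seed,
                                  ventilator = "ventilator" %in% p$flags ||
                                    cfg$ventilator,
                                  noise_level = cfg$noise_level)
        for (rec in cohort) write_recording(rec, out_dir)
        message("wrote ", length(cohort), " recordings to ", out_dir)
      },
      preprocess = {
        in_dir <- opt("in", out_dir)
        sigs <- list.files(in_dir, pattern = "_signal\\.csv$",
                           full.names = TRUE)
        if (!length(sigs)) stop_invalid("no *_signal.csv in ", in_dir)
        segs <- list()
        for (i in seq_along(sigs)) {
          rec <- read_recording(sigs[i],
                                sub("_signal\\.csv$", "_annotations.csv",
                                    sigs[i]))
          pre <- preprocess_recording(rec, lms = !("no-lms" %in% p$flags),
                                      state = lms_state(
                                        cfg$lms_length, cfg$lms_alpha,
                                        cfg$lms_mu,
                                        seed = derive_seed(cfg$seed, i)))
          segs <- c(segs, segment_recording(pre))
        }
        write_segments(segs, file.path(out_dir, "segments.csv"))
        message("wrote ", length(segs), " segments")
      },
      extract = {
        segs <- read_segments(opt("in", file.path(out_dir, "segments.csv")))
        feats <- extract_feature_matrix(segs, config_transform(cfg))
        write_features(feats, file.path(out_dir, "features.csv"))
        message("wrote ", nrow(feats), " feature rows")
      },
      analyze = {
        feats <- read_features(opt("in", file.path(out_dir, "features.csv")))
        rel <- relevance_table(feats)
        write.csv(rel, file.path(out_dir, "relevance.csv"),
                  row.names = FALSE)
        cl <- cluster_features(feature_correlation(feats), cfg$cut_height)
        write.csv(data.frame(feature = FEATURE_NAMES,
                             cluster = cl$clusters),
                  file.path(out_dir, "clusters.csv"), row.names = FALSE)
        message("wrote relevance.csv and clusters.csv")
      },
      `train-eval` = {
        feats <- read_features(opt("in", file.path(out_dir, "features.csv")))
        paradigm <- switch(opt("paradigm", "kfold"),
                           kfold = , kfold10 = "kfold10", loso = "loso",
                           stop_invalid("paradigm must be kfold or loso"))
        report <- evaluate(feats, model = opt("model", cfg$model),
                           paradigm = paradigm,
                           repeats = as.integer(opt("repeats", cfg$repeats)),
                           seed = cfg$seed, ntree = cfg$ntree)
        jsonlite::write_json(
          list(paradigm = report$paradigm, model = report$model,
               mean = as.list(report$mean), sd = as.list(report$sd),
               counts = as.list(report$counts)),
          file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
        print(report)
      },
      `run-all` = {
        report <- run_pipeline(cfg, out_dir)
        print(report)
      },
      { cat(usage, "\n"); return(invisible(2L)) })
    0L
  },
  bcgvf_invalid_argument = function(e) {
    message("error [", conditionMessage(e), "]")
    2L
  },
  error = function(e) {
    message("internal error [", conditionMessage(e), "]")
    1L
  })
  invisible(status)
}
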