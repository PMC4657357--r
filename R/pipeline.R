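# End-to-end orchestration: simulate or ingest a session, detect calls and
# pulses, attribute callers by TDOA, extract the nine parameters, run the
# individuality statistics, and emit a report bundle (CSV/JSON).

#' Integer category percentages
#'
#' Shares of each call category as integer percentages of the total.
#' Shares are floored (reported conservatively), matching how the
#' predominant-call-type share is conventionally quoted; with k
#' categories the floored shares sum to within [100 - k, 100].
#'
#' @param counts named integer vector of per-category call counts.
#' @return named integer vector of percentages.
#' @export
category_percentages <- function(counts) {
  if (any(counts < 0)) stop_arg("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop_arg("no calls to summarize")
  stats::setNames(as.integer(floor(100 * counts / total)), names(counts))
}

#' Summary of category counts and attribution totals
#'
#' @param category_counts named vector of per-category call counts.
#' @param attributed_counts optional named vector of per-individual
#'   attributed call counts.
#' @param analyzed_counts optional named vector of per-individual
#'   analyzed call counts.
#' @return list: `counts`, `percentages`, `total`, and (when given)
#'   `attributed_total`, `analyzed_total`.
#' @export
category_summary <- function(category_counts, attributed_counts = NULL,
                             analyzed_counts = NULL) {
  out <- list(counts = category_counts,
              percentages = category_percentages(category_counts),
              total = sum(category_counts))
  if (!is.null(attributed_counts))
    out$attributed_total <- sum(attributed_counts)
  if (!is.null(analyzed_counts))
    out$analyzed_total <- sum(analyzed_counts)
  out
}

#' Analyze a two-channel session recording
#'
#' Runs the detection half of the pipeline: noise estimation per channel,
#' call segmentation, per-call TDOA and caller verdict, pulse detection
#' on the better channel, and the nine-parameter feature vector per call.
#'
#' @param samples n x 2 numeric matrix.
#' @param fs sampling rate, Hz.
#' @param zone isolation-zone TDOA interval, s.
#' @param params detector parameters ([pulse_params()]).
#' @param detect_band band used for detection and TDOA envelopes, Hz.
#'   Defaults to 20-170 kHz: pulse energy is broadband across this range,
#'   while narrowband tonal call components (~13 kHz) and the elevated
#'   low-frequency noise floor both fall below 20 kHz and would otherwise
#'   ride above the pulse threshold on loud calls. Spectral measurement
#'   still uses the full 6-170 kHz analysis band.
#' @param spacing_m hydrophone spacing, m.
#' @param sound_speed m/s.
#' @param tolerance_s TDOA zone tolerance, s.
#' @return list: `features` (data.frame, one row per analyzable call),
#'   `assignments` (data.frame call_id / tdoa_ms / verdict / margin_ms),
#'   `calls` (segmentation table), `noise_level` per channel.
#' @export
analyze_session <- function(samples, fs, zone, params = pulse_params(),
                            detect_band = c(20e3, 170e3), spacing_m = 7.5,
                            sound_speed = 1500, tolerance_s = 2e-4) {
  band <- detect_band
  stopifnot(is.matrix(samples), ncol(samples) == 2)
  # filter and envelope each channel once; all stages reuse these
  env <- apply(samples, 2, function(x) envelope(band_pass(x, fs, band)))
  noise <- apply(env, 2, stats::median)
  segs <- segment_calls(samples[, 1], fs, noise_level = noise[1],
                        params = params, band = band, env = env[, 1])
  feats <- list()
  assigns <- list()
  for (k in seq_len(nrow(segs))) {
    pad <- 0.01 + spacing_m / sound_speed
    i0 <- max(1, floor((segs$start_s[k] - pad) * fs))
    i1 <- min(nrow(samples), ceiling((segs$end_s[k] + pad) * fs))
    td <- tdoa(samples[i0:i1, , drop = FALSE], fs,
               max_tdoa_s = spacing_m / sound_speed + 5e-4,
               band = band, env = env[i0:i1, , drop = FALSE])
    asg <- assign_caller(td$tdoa_s, zone, spacing_m, sound_speed,
                         tolerance_s, call_id = k)
    assigns[[k]] <- data.frame(
      call_id = k, tdoa_ms = (td$tdoa_s %||% NA_real_) * 1000,
      peak_corr = td$peak_corr, verdict = asg$verdict,
      margin_ms = asg$margin_s * 1000, stringsAsFactors = FALSE)
    # best channel by in-band envelope peak
    ch <- which.max(vapply(1:2, function(j) max(env[i0:i1, j]), numeric(1)))
    tr <- detect_pulses(samples[, ch], fs,
                        c(segs$start_s[k] - 0.005, segs$end_s[k] + 0.005),
                        noise_level = noise[ch], params = params,
                        band = band, call_id = k, channel = ch,
                        env = env[, ch])
    if (!tr$empty && length(tr$peak_times) >= 2) {
      cf <- tryCatch(call_features(samples[, ch], tr, fs),
                     error = function(e) NULL)
      if (!is.null(cf)) {
        cf$verdict <- asg$verdict
        feats[[length(feats) + 1]] <- cf
      }
    }
  }
  list(
    features = if (length(feats)) do.call(rbind, feats) else NULL,
    assignments = if (length(assigns)) do.call(rbind, assigns) else
      data.frame(),
    calls = segs,
    noise_level = noise)
}

#' Run the individuality analysis on a feature table
#'
#' Mirrors the statistical workflow: univariate group tests per
#' parameter, VIF screening of the nine candidates, robust outlier
#' flagging, the PIC table, class balancing, quadratic DFA with
#' leave-one-out cross-validation on the retained parameters, and
#' stepwise feature ranking.
#'
#' @param features data.frame containing [feature_names()] columns.
#' @param labels individual label per row.
#' @param balance_cap per-class subsampling cap; NULL caps at the
#'   smallest count that leaves every class unchanged except the largest
#'   (i.e. the second-largest class size), mirroring reduction of one
#'   dominant class. Use `Inf` to disable balancing.
#' @param seed seed for balancing and the MCD fit.
#' @param vif_threshold multicollinearity removal threshold.
#' @return list of class `individuality_report`: `pic`, `tests`,
#'   `screening`, `outliers`, `balance_idx`, `dfa`, `stepwise`.
#' @export
analyze_individuality <- function(features, labels, balance_cap = NULL,
                                  seed = 1, vif_threshold = 20.0) {
  labels <- factor(labels)
  cols <- intersect(feature_names(), names(features))
  x <- features[cols]
  cc <- stats::complete.cases(x)
  x <- x[cc, , drop = FALSE]
  labels <- droplevels(labels[cc])
  tests <- list(
    kruskal = lapply(stats::setNames(nm = c("avg_ipi_11_20",
                                            "avg_ipi_11_20_last",
                                            "duration_s", "n_pulses", "prr")),
                     function(p) kruskal_wallis(split(x[[p]], labels))),
    anova = lapply(stats::setNames(nm = c("peak_freq", "bw10", "lower10",
                                          "upper10")),
                   function(p) one_way_anova(split(x[[p]], labels))))
  screening <- vif_screen(x, threshold = vif_threshold)
  # features with (near-)zero variance inside any class make that class's
  # covariance (and the MCD scatter) singular; drop them from the
  # multivariate stages
  usable <- Filter(function(p) {
    all(vapply(levels(labels), function(l) {
      v <- x[[p]][labels == l]
      stats::sd(v) > 1e-10 * (abs(mean(v)) + 1e-12)
    }, logical(1)))
  }, screening$retained)
  if (length(dropped <- setdiff(screening$retained, usable)))
    message("dropped within-class-degenerate feature(s): ",
            paste(dropped, collapse = ", "))
  # spectral features are bin-quantized, which can still make the MCD
  # subset singular; outlier flagging is advisory, so degrade gracefully
  outl <- tryCatch(robust_outliers(x[usable], seed = seed),
                   error = function(e) {
                     message("outlier flagging skipped: ", conditionMessage(e))
                     NULL
                   })
  pic_tab <- pic_table(x, labels)
  sizes <- table(labels)
  cap <- balance_cap %||% sort(sizes, decreasing = TRUE)[2]
  idx <- if (is.finite(cap)) balance_classes(labels, cap, seed = seed)
         else seq_along(labels)
  xb <- x[idx, usable, drop = FALSE]
  lb <- droplevels(labels[idx])
  dfa <- qda_loocv(xb, lb)
  sw <- stepwise_select(xb, lb)
  structure(list(pic = pic_tab, tests = tests, screening = screening,
                 outliers = outl, balance_idx = idx, dfa = dfa,
                 stepwise = sw),
            class = "individuality_report")
}

#' Run the full pipeline
#'
#' `simulate`: render the scene, write audio/truth if requested.
#' `analyze`: detection + attribution + features on given samples.
#' `full`: simulate, analyze, run the individuality statistics and write
#' the report bundle (features CSV, assignments CSV, PIC table CSV, DFA
#' JSON, summary JSON) into `out_dir`.
#'
#' @param config list with elements `mode` ("simulate", "analyze",
#'   "full"), `scene` (a [session_scene] for simulate/full), `samples` +
#'   `fs` + `zone` (for analyze), `out_dir`, `seed`, optional
#'   `write_audio` (logical), detector `params`.
#' @return report bundle (list), invisibly. Components depend on mode.
#' @export
run_pipeline <- function(config) {
  mode <- match.arg(config$mode, c("simulate", "analyze", "full"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  bundle <- list(mode = mode)
  if (mode %in% c("simulate", "full")) {
    if (is.null(config$scene)) stop_arg("simulate/full mode needs a scene")
    if (is.null(config$scene$seed)) stop_arg("a seed is mandatory to simulate")
    rec <- render_session(config$scene)
    bundle$recording <- rec
    if (isTRUE(config$write_audio) && !is.null(out_dir)) {
      write_wav(rec$samples, file.path(out_dir, "session.wav"), rec$fs)
      write_truth_json(rec$truth, file.path(out_dir, "truth.json"))
    }
    if (mode == "simulate") return(invisible(bundle))
    samples <- rec$samples; fs <- rec$fs; zone <- rec$zone
  } else {
    samples <- config$samples; fs <- config$fs; zone <- config$zone
    if (is.null(samples) || is.null(fs) || is.null(zone))
      stop_arg("analyze mode needs samples, fs and zone")
  }
  params <- config$params %||% pulse_params()
  ana <- analyze_session(samples, fs, zone, params = params,
                         detect_band = config$detect_band %||%
                           c(20e3, 170e3))
  bundle$analysis <- ana
  if (mode == "full") {
    feats <- ana$features
    if (is.null(feats) || nrow(feats) < 10)
      stop_arg("too few analyzable calls for the individuality statistics")
    # per-individual analysis uses non-ambiguous calls only
    truth_labels <- config$truth_labels
    if (!is.null(truth_labels)) {
      feats$label <- truth_labels[feats$call_id]
    } else if (!is.null(bundle$recording)) {
      feats$label <- vapply(bundle$recording$truth, `[[`, character(1),
                            "label")[feats$call_id]
    }
    keep <- feats$verdict != "ambiguous"
    stats_in <- feats[keep & !is.na(feats$label), , drop = FALSE]
    bundle$report <- tryCatch(
      analyze_individuality(stats_in, stats_in$label,
                            seed = config$seed %||% 1),
      error = function(e) {
        message("individuality statistics skipped: ", conditionMessage(e))
        NULL
      })
    counts <- table(factor(rep("PS1", nrow(feats)),
                           levels = c("PS1", "C1", "S", "W", "O")))
    bundle$summary <- category_summary(
      c(counts),
      attributed_counts = table(stats_in$label))
  }
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  invisible(bundle)
}

# ---- report bundle writers --------------------------------------------

write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

write_report_bundle <- function(bundle, out_dir) {
  ana <- bundle$analysis
  if (!is.null(ana$features))
    utils::write.csv(ana$features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
  if (!is.null(ana$assignments) && nrow(ana$assignments) > 0)
    utils::write.csv(ana$assignments, file.path(out_dir, "assignments.csv"),
                     row.names = FALSE)
  rep <- bundle$report
  if (!is.null(rep)) {
    utils::write.csv(format_pic_table(rep$pic),
                     file.path(out_dir, "pic_table.csv"), row.names = FALSE)
    dfa <- rep$dfa
    jsonlite::write_json(list(
      confusion = as.data.frame.matrix(dfa$confusion),
      overall_pct = round_half_up(dfa$overall_pct, 1),
      per_class_pct = as.list(round_half_up(dfa$per_class_pct, 1)),
      prior = as.list(dfa$prior),
      features = dfa$features,
      stepwise = list(selected = rep$stepwise$selected,
                      criterion = rep$stepwise$criterion),
      screening = list(removed = rep$screening$removed,
                       retained = rep$screening$retained)
    ), file.path(out_dir, "dfa.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  }
  if (!is.null(bundle$summary))
    jsonlite::write_json(bundle$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Format a PIC table for reporting
#'
#' CVs and PIC rounded to 2 decimals (half-up), the conventional table
#' format.
#'
#' @param pt a `pic_table`.
#' @return data.frame with rounded values.
#' @export
format_pic_table <- function(pt) {
  out <- as.data.frame(pt)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round_half_up, digits = 2)
  out
}
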