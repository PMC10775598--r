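#' Full run configuration
#'
#' Bundles every knob of the end-to-end analysis. Defaults encode the
#' analysis cohort: 8 treatment phases (one per patient) of 4-6 fractions
#' each (43 in total, every phase >= 3 fractions), a 64^3 grid at 2 mm, a
#' 5 mm planning margin against a 3 mm adaptive margin, and the motion model
#' of [motion_config()]. The OAR exponent registry must name an exponent for
#' every organ at risk; parotid and larynx carry the registry defaults while
#' the spinal-cord value is a config-level choice with no registry default.
#'
#' @param phantom a [phantom_config()].
#' @param motion a [motion_config()].
#' @param fractions_per_phase integer vector, one phase per entry, all >= 3.
#' @param phase_course `"boost"`/`"initial"` label per phase.
#' @param tumor_a CTV gEUD exponent.
#' @param oar_exponents named exponents for each phantom OAR.
#' @param policy a [selection_policy()].
#' @param margins_mm erosion margins scanned by the margin table.
#' @param seed master seed; all sub-seeds derive from it.
#' @return a `run_config` list.
#' @export
run_config <- function(phantom = phantom_config(),
                       motion = motion_config(),
                       fractions_per_phase = c(6, 6, 6, 6, 5, 5, 5, 4),
                       phase_course = c("boost", "boost", "boost", "boost",
                                        "boost", "initial", "initial",
                                        "boost"),
                       tumor_a = -20,
                       oar_exponents = c(parotid_l = 1.43, parotid_r = 1.43,
                                         larynx = 9.1, cord = 9.1),
                       policy = selection_policy(),
                       margins_mm = 1:10,
                       seed = 1L) {
  if (any(fractions_per_phase < 3))
    stop("phases entering accumulation need >= 3 fractions")
  if (length(phase_course) != length(fractions_per_phase))
    stop("phase_course must match fractions_per_phase")
  for (nm in names(phantom$oars))
    if (!nm %in% names(oar_exponents) || is.na(oar_exponents[[nm]]))
      stop(sprintf("no gEUD exponent configured for OAR '%s'", nm))
  list(phantom = phantom, motion = motion,
       fractions_per_phase = as.integer(fractions_per_phase),
       phase_course = phase_course, tumor_a = tumor_a,
       oar_exponents = oar_exponents, policy = policy,
       margins_mm = margins_mm, seed = as.integer(seed))
}

phase_seed <- function(master, phase) {
  (as.integer(master) * 1009L + 7919L * as.integer(phase)) %% 2147483647L
}

#' Run the synthetic cohort end to end
#'
#' Generates the phantom and the per-phase fraction records, computes the
#' per-fraction metric panel for both candidate plans (evaluated on the
#' anatomy of the day, CBCT1), applies the selection policy, accumulates the
#' scheduled, adaptive and as-delivered courses per phase through the
#' ground-truth displacement fields, builds the margin-vs-EUD table, and
#' compiles the motion/dose statistics report. Fully deterministic under the
#' master seed.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, CSV/JSON artifacts are
#'   written there (see [write_cohort_outputs()]).
#' @param keep_fractions keep the per-fraction dose grids in the result
#'   (memory-heavy; default drops them after accumulation).
#' @return a `cohort_report` list.
#' @export
run_cohort <- function(config = run_config(), out_dir = NULL,
                       keep_fractions = FALSE) {
  phantom <- build_phantom(config$phantom, seed = config$seed)
  plan <- reference_plan(phantom)
  params_ctv <- eud_params(config$tumor_a, config$phantom$prescription)
  oar_params <- lapply(config$oar_exponents, eud_params,
                       prescription = config$phantom$prescription)
  n_phases <- length(config$fractions_per_phase)

  metrics <- list(); deviations <- list(); manifest <- list()
  phase_results <- vector("list", n_phases)
  quarantined <- list()

  for (ph in seq_len(n_phases)) {
    k <- config$fractions_per_phase[ph]
    shifts <- sample_shifts(k, config$motion, seed = phase_seed(config$seed, ph))
    fractions <- vector("list", k)
    for (i in seq_len(k)) {
      fid <- sprintf("p%02d_f%02d", ph, i)
      rec <- tryCatch(
        make_fraction(phantom, plan, shifts[i, ], fid, ph, params_ctv,
                      oar_params, config),
        error = function(e) e)
      if (inherits(rec, "error")) {
        quarantined[[fid]] <- conditionMessage(rec)
        next
      }
      fractions[[i]] <- rec
      metrics[[fid]] <- rbind(rec$metrics_scheduled, rec$metrics_adaptive)
      deviations[[fid]] <- fraction_deviation_rows(shifts[i, ], fid,
                                                   config$motion$landmarks)
      manifest[[fid]] <- data.frame(
        fraction_id = fid, patient_id = sprintf("pt%02d", ph),
        phase_id = ph, course = config$phase_course[ph],
        inter_mm = sqrt(sum(shifts[i, c("inter_z", "inter_y", "inter_x")]^2)),
        intra_mm = sqrt(sum(shifts[i, c("intra_z", "intra_y", "intra_x")]^2)),
        delivered = rec$delivered, stringsAsFactors = FALSE)
    }
    fractions <- Filter(Negate(is.null), fractions)
    phase_results[[ph]] <- if (length(fractions) >= 3)
      analyze_phase(fractions, phantom, params_ctv, config, ph)
    else list(phase_id = ph, skipped = TRUE)
    if (keep_fractions) phase_results[[ph]]$fractions <- fractions
  }

  metrics <- do.call(rbind, metrics)
  deviations <- do.call(rbind, deviations)
  manifest <- do.call(rbind, manifest)
  rownames(metrics) <- rownames(deviations) <- rownames(manifest) <- NULL

  report <- list(
    config_echo = config_echo(config),
    metrics = metrics,
    deviations = deviations,
    manifest = manifest,
    phases = phase_results,
    table2 = table2_summary(phase_results, config$margins_mm),
    min_margins = min_margin_summary(phase_results),
    stats = cohort_stats(metrics, deviations, config),
    summary = summarize_generated(manifest, config),
    quarantined = quarantined
  )
  class(report) <- "cohort_report"
  if (!is.null(out_dir)) write_cohort_outputs(report, out_dir)
  report
}

make_fraction <- function(phantom, plan, shift_row, fid, ph, params_ctv,
                          oar_params, config) {
  inter <- as.numeric(shift_row[c("inter_z", "inter_y", "inter_x")])
  intra <- as.numeric(shift_row[c("intra_z", "intra_y", "intra_x")])
  sched_dose <- make_scheduled_dose(phantom, plan, inter)
  adapt_dose <- make_adaptive_dose(phantom, plan, inter)
  day_ctv <- shifted_ctv(phantom, inter)              # CBCT1 anatomy
  delivered_ctv <- shifted_ctv(phantom, inter + intra) # CBCT2 anatomy
  row_for <- function(dose, mask, params, type) {
    metric_row(dose, mask, params, fraction_id = fid, plan_type = type)
  }
  # the plan choice is made on CBCT1, before residual intrafraction motion
  # can be known, so the decision compares both plans on the anatomy of the
  # day; the REPORTED adaptive metrics use the post-adaptation (CBCT2)
  # anatomy, where the residual shift has already degraded the plan
  ms <- row_for(sched_dose, day_ctv, params_ctv, "scheduled")
  ma_decision <- row_for(adapt_dose, day_ctv, params_ctv, "adaptive")
  ma <- row_for(adapt_dose, delivered_ctv, params_ctv, "adaptive")
  for (nm in names(phantom$oars)) {
    oar_s <- row_for(sched_dose, phantom$oars[[nm]], oar_params[[nm]],
                     "scheduled")
    oar_a <- row_for(adapt_dose, phantom$oars[[nm]], oar_params[[nm]],
                     "adaptive")
    ms <- rbind(ms, oar_s)
    ma_decision <- rbind(ma_decision, oar_a)
    ma <- rbind(ma, oar_a)
  }
  delivered <- select_delivered(ms, ma_decision, config$policy)
  list(fraction_id = fid, phase_id = ph, shift = list(inter = inter,
                                                      intra = intra),
       scheduled_dose = sched_dose, adaptive_dose = adapt_dose,
       metrics_scheduled = ms, metrics_adaptive = ma,
       delivered = delivered, field_shift = inter + intra)
}

fraction_deviation_rows <- function(shift_row, fid, landmarks) {
  data.frame(
    fraction_id = fid,
    parameter = landmarks$key,
    inter_mm = as.numeric(shift_row[paste0("inter_", landmarks$key)]),
    intra_mm = as.numeric(shift_row[paste0("intra_", landmarks$key)]),
    stringsAsFactors = FALSE
  )
}

analyze_phase <- function(fractions, phantom, params_ctv, config, ph) {
  res <- list(phase_id = ph, n_fractions = length(fractions), skipped = FALSE)
  for (pt in c("scheduled", "adaptive", "delivered")) {
    acc <- accumulate_phase(fractions, pt, phantom)
    tbl <- margin_table(acc, phantom$ptv, params_ctv, config$margins_mm)
    res[[pt]] <- list(margin_table = tbl,
                      min_margin = min_adequate_margin(tbl),
                      n_outside = attr(acc, "n_outside"))
  }
  res
}

table2_summary <- function(phase_results, margins_mm) {
  done <- Filter(function(p) isFALSE(p$skipped), phase_results)
  if (length(done) == 0L) return(NULL)
  out <- list()
  for (pt in c("adaptive", "scheduled")) {
    m <- sapply(done, function(p) p[[pt]]$margin_table$eud_pct)
    out[[pt]] <- data.frame(
      margin_mm = margins_mm,
      min = apply(m, 1, min, na.rm = TRUE),
      max = apply(m, 1, max, na.rm = TRUE),
      mean = rowMeans(m, na.rm = TRUE),
      median = apply(m, 1, stats::median, na.rm = TRUE))
  }
  merged <- merge(out$adaptive, out$scheduled, by = "margin_mm",
                  suffixes = c("_adaptive", "_scheduled"))
  merged[order(merged$margin_mm), ]
}

min_margin_summary <- function(phase_results) {
  done <- Filter(function(p) isFALSE(p$skipped), phase_results)
  if (length(done) == 0L) return(NULL)
  data.frame(
    phase_id = vapply(done, function(p) p$phase_id, numeric(1)),
    n_fractions = vapply(done, function(p) p$n_fractions, numeric(1)),
    scheduled = vapply(done, function(p) p$scheduled$min_margin, numeric(1)),
    adaptive = vapply(done, function(p) p$adaptive$min_margin, numeric(1)),
    delivered = vapply(done, function(p) p$delivered$min_margin, numeric(1))
  )
}

cohort_stats <- function(metrics, deviations, config) {
  ctv <- metrics[metrics$structure == "CTV", ]
  sc <- ctv[ctv$plan_type == "scheduled", ]
  ad <- ctv[ctv$plan_type == "adaptive", ]
  sc <- sc[order(sc$fraction_id), ]; ad <- ad[order(ad$fraction_id), ]
  per_param_scale <- lapply(split(deviations, deviations$parameter),
                            function(d) scale_test(d$inter_mm, d$intra_mm))
  per_param_delta <- lapply(split(deviations, deviations$parameter),
                            function(d) signed_rank_test(abs(d$inter_mm) -
                                                           abs(d$intra_mm)))
  list(
    fig1a = list(
      eud_scheduled = sort(sc$eud_pct), eud_adaptive = sort(ad$eud_pct),
      p2_5_scheduled = percentile_with_ci(sc$eud_pct, 0.025),
      p2_5_adaptive = percentile_with_ci(ad$eud_pct, 0.025),
      dispersion = scale_test(sc$eud_pct, ad$eud_pct),
      location = signed_rank_test(sc$eud_pct, ad$eud_pct)),
    fig1c = list(
      homogeneity_scheduled = sort(sc$homogeneity_pct),
      homogeneity_adaptive = sort(ad$homogeneity_pct),
      paired = signed_rank_test(sc$homogeneity_pct, ad$homogeneity_pct)),
    fig2 = lapply(split(deviations, deviations$parameter), function(d)
      correlations(abs(d$inter_mm), abs(d$intra_mm), "spearman")),
    fig3 = fig3_fits(sc, deviations),
    fig4 = list(scale_tests = per_param_scale,
                delta_signed_rank = per_param_delta,
                inter_p95 = percentile_summary(deviations, 0.95, "inter_mm"),
                intra_p95 = percentile_summary(deviations, 0.95, "intra_mm"))
  )
}

fig3_fits <- function(sc_ctv, deviations, params = c("g", "d", "e")) {
  n <- nrow(sc_ctv)
  if (n < 5) return(NULL)
  ranks <- rank(sc_ctv$eud_pct) / n
  out <- list()
  for (p in params) {
    d <- deviations[deviations$parameter == p, ]
    d <- d[match(sc_ctv$fraction_id, d$fraction_id), ]
    out[[p]] <- list(
      linear = rank_adaptation_fit(ranks, d$inter_mm),
      quadratic = rank_adaptation_fit(ranks, d$inter_mm, quadratic = TRUE),
      spearman = correlations(sc_ctv$eud_pct, d$inter_mm, "spearman"))
  }
  out
}

summarize_generated <- function(manifest, config) {
  list(n_patients = length(unique(manifest$patient_id)),
       n_fractions = nrow(manifest),
       n_applied_adaptive = sum(manifest$delivered == "adaptive"),
       pct_applied = round(100 * mean(manifest$delivered == "adaptive"), 1),
       pct_boost_course = round(100 * mean(
         vapply(split(manifest$course, manifest$patient_id),
                function(x) x[1] == "boost", logical(1))), 1))
}

config_echo <- function(config) {
  e <- config
  e$motion$landmarks <- NULL
  e
}

# ---- cohort summary on external manifests -----------------------------------

#' Summarize a treatment-registry manifest
#'
#' Plain cohort arithmetic on a patient manifest and a fraction manifest:
#' how many patients received at least one adaptive phase, the share of
#' adaptive-mode fractions actually delivered with the adaptive plan, and
#' the share of adaptive courses that were boost courses. Percentages are
#' rounded to one decimal; zero denominators yield `NA` with a warning.
#'
#' @param patients data.frame with columns `patient_id`, `art` (logical),
#'   `art_course` (`"boost"`/`"initial"`/`NA`).
#' @param fractions data.frame with columns `fraction_id`, `delivered`
#'   (`"adaptive"`/`"scheduled"`); all rows are adaptive-mode fractions.
#' @return list of counts and one-decimal percentages.
#' @export
summarize_cohort <- function(patients, fractions) {
  pct <- function(num, den) {
    if (is.na(den) || den == 0) {
      warning("zero denominator in cohort summary")
      return(NA_real_)
    }
    round(100 * num / den, 1)
  }
  n_pat <- nrow(patients)
  n_art <- sum(patients$art)
  n_frac <- nrow(fractions)
  n_applied <- sum(fractions$delivered == "adaptive")
  n_boost <- sum(patients$art & patients$art_course == "boost", na.rm = TRUE)
  list(n_patients = n_pat,
       n_art_patients = n_art,
       pct_art = pct(n_art, n_pat),
       n_adaptive_fractions = n_frac,
       n_applied_adaptive = n_applied,
       pct_applied = pct(n_applied, n_frac),
       pct_boost_course = pct(n_boost, n_art))
}

#' Read the shipped registry fixture manifests
#'
#' Two small CSVs encoding the published registry counts of the clinical
#' cohort the analysis mirrors (59 patients, 10 with at least one adaptive
#' phase, 46 adaptive-mode fractions of which 30 were delivered with the
#' adaptive plan).
#'
#' @return list with `patients` and `fractions` data.frames.
#' @export
fixture_manifest <- function() {
  dir <- system.file("extdata", package = "artdose")
  list(patients = utils::read.csv(file.path(dir, "registry_patients.csv"),
                                  stringsAsFactors = FALSE),
       fractions = utils::read.csv(file.path(dir, "registry_fractions.csv"),
                                   stringsAsFactors = FALSE))
}

# ---- output writing and schema ----------------------------------------------

#' Write the report bundle of a cohort run
#'
#' Emits `metrics.csv`, `deviations.csv`, `manifest.csv`, `table2.csv`,
#' `min_margins.csv`, `report.json` (statistics keyed by figure/table
#' analogue) and `config.json` (config echo with seed) into `out_dir`.
#'
#' @param report a `cohort_report`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir` invisibly.
#' @export
write_cohort_outputs <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                        row.names = FALSE)
  w(report$metrics, "metrics.csv")
  w(report$deviations, "deviations.csv")
  w(report$manifest, "manifest.csv")
  if (!is.null(report$table2)) w(report$table2, "table2.csv")
  if (!is.null(report$min_margins)) w(report$min_margins, "min_margins.csv")
  jsonlite::write_json(report_json(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report$config_echo, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

strip_tr <- function(t) list(method = t$method, statistic = t$statistic,
                             p_value = t$p_value, n = t$n,
                             estimate = t$estimate, ci = t$ci)

#' JSON-ready statistics report
#'
#' Flattens the statistics of a cohort run into the figure/table-keyed
#' structure described by the shipped schema
#' (`inst/schema/report_schema.json`).
#'
#' @param report a `cohort_report`.
#' @return a nested list ready for [jsonlite::write_json()].
#' @export
report_json <- function(report) {
  s <- report$stats
  list(
    percentile_ci_method = "order_statistic_inversion",
    fig1a = list(
      p2_5_scheduled = s$fig1a$p2_5_scheduled[c("estimate", "ci")],
      p2_5_adaptive = s$fig1a$p2_5_adaptive[c("estimate", "ci")],
      dispersion = strip_tr(s$fig1a$dispersion),
      location = strip_tr(s$fig1a$location)),
    fig1c = list(paired = strip_tr(s$fig1c$paired)),
    fig2 = lapply(s$fig2, strip_tr),
    fig4 = list(
      scale_tests = lapply(s$fig4$scale_tests, strip_tr),
      delta_signed_rank = lapply(s$fig4$delta_signed_rank, strip_tr),
      inter_p95 = s$fig4$inter_p95,
      intra_p95 = s$fig4$intra_p95),
    table2 = if (!is.null(report$table2)) report$table2,
    min_margins = if (!is.null(report$min_margins)) report$min_margins,
    summary = report$summary
  )
}

#' Validate a report against the shipped schema
#'
#' Structural check (required keys, types) against
#' `inst/schema/report_schema.json`; no external JSON-schema engine is
#' available offline, so the subset actually used is enforced directly.
#'
#' @param x a list as produced by [report_json()].
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(x) {
  schema <- jsonlite::read_json(system.file("schema", "report_schema.json",
                                            package = "artdose"))
  for (key in names(schema$required_keys)) {
    if (is.null(x[[key]]))
      stop(sprintf("report misses required key '%s'", key))
    for (sub in unlist(schema$required_keys[[key]]))
      if (is.null(x[[key]][[sub]]))
        stop(sprintf("report key '%s' misses '%s'", key, sub))
  }
  for (t in unlist(schema$test_result_paths)) {
    parts <- strsplit(t, "/", fixed = TRUE)[[1]]
    node <- x
    for (p in parts) node <- node[[p]]
    if (is.null(node$p_value) || is.null(node$method))
      stop(sprintf("'%s' is not a test result", t))
  }
  invisible(TRUE)
}

# ---- command-line interface --------------------------------------------------

#' Command-line entry point
#'
#' Subcommands: `run` (full pipeline), `generate` (cohort manifests),
#' `metrics`, `accumulate`, `stats` (their slices of a full run; the
#' generation is deterministic from config and seed, so each stage simply
#' re-runs the pipeline and writes its part), and `fixture` (summarize the
#' shipped registry manifests). Flags: `--config <json>`, `--seed <int>`,
#' `--out <dir>`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
artdose_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: artdose <run|generate|metrics|accumulate|stats|fixture>",
        "[--config f.json] [--seed n] [--out dir]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  out <- opt("--out", "artdose_out")
  cfg_path <- opt("--config")
  config <- if (!is.null(cfg_path)) run_config_from_json(cfg_path, seed)
  else run_config(seed = seed)
  if (cmd == "fixture") {
    fm <- fixture_manifest()
    s <- summarize_cohort(fm$patients, fm$fractions)
    cat(jsonlite::toJSON(s, auto_unbox = TRUE, pretty = TRUE, digits = NA),
        "\n")
    return(invisible(0L))
  }
  if (!cmd %in% c("run", "generate", "metrics", "accumulate", "stats")) {
    cat("unknown subcommand:", cmd, "\n")
    return(invisible(1L))
  }
  report <- run_cohort(config)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (cmd %in% c("run")) write_cohort_outputs(report, out)
  if (cmd == "generate") {
    utils::write.csv(report$manifest, file.path(out, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(report$deviations, file.path(out, "deviations.csv"),
                     row.names = FALSE)
  }
  if (cmd == "metrics")
    utils::write.csv(report$metrics, file.path(out, "metrics.csv"),
                     row.names = FALSE)
  if (cmd == "accumulate") {
    utils::write.csv(report$table2, file.path(out, "table2.csv"),
                     row.names = FALSE)
    utils::write.csv(report$min_margins, file.path(out, "min_margins.csv"),
                     row.names = FALSE)
  }
  if (cmd == "stats")
    jsonlite::write_json(report_json(report), file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  n_quar <- length(report$quarantined)
  if (n_quar > 0)
    message(n_quar, " fraction(s) quarantined; see report$quarantined")
  invisible(0L)
}

run_config_from_json <- function(path, seed) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(j$phantom)) args$phantom <- do.call(phantom_config, j$phantom)
  if (!is.null(j$motion)) args$motion <- do.call(motion_config, j$motion)
  for (nm in c("fractions_per_phase", "phase_course", "tumor_a",
               "oar_exponents", "margins_mm"))
    if (!is.null(j[[nm]])) args[[nm]] <- j[[nm]]
  if (!is.null(j$policy)) args$policy <- do.call(selection_policy, j$policy)
  args$seed <- if (!is.null(j$seed)) j$seed else seed
  do.call(run_config, args)
}
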