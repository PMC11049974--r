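#' Pipeline run configuration
#'
#' Collects every knob of an end-to-end run in one serializable object. A
#' copy is written into the output directory so any run can be reproduced
#' from its artifacts alone.
#'
#' @param mode `"simulate"` (generate the study in memory) or `"files"`
#'   (read a study directory written by [write_study()]).
#' @param input_dir Study directory for `mode = "files"`.
#' @param out_dir Optional output directory for the result tables; `NULL`
#'   keeps results in memory only.
#' @param seed Integer seed (simulate mode).
#' @param design A [study_design()] (simulate mode; its seed is overridden
#'   by `seed`).
#' @param fcc_true,noise,flux_model,grid Passed to [generate_study()].
#' @param nat_corr Natural-abundance correction method for the isoprene
#'   channels (see [correct_isoprene_channels()]).
#' @param p13 Natural 13C abundance.
#' @param pool_mode `"sample"` fits each leaf with its own plastidial pool
#'   estimates; `"mean"` uses genotype-by-condition mean pools.
#' @param cal_factor Optional PTR-MS calibration factor (nmol s^-1 per
#'   ncps) for emission computation.
#' @param leaf_area Enclosed leaf area, m^2.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(mode = c("simulate", "files"), input_dir = NULL,
                            out_dir = NULL, seed = 1L,
                            design = study_design(), fcc_true = 0.18,
                            noise = noise_config(),
                            flux_model = "control_law",
                            grid = seq(0, 50, by = 0.5),
                            nat_corr = "binomial", p13 = 0.011,
                            pool_mode = c("sample", "mean"),
                            cal_factor = NULL, leaf_area = 0.0057) {
  mode <- match.arg(mode)
  pool_mode <- match.arg(pool_mode)
  if (mode == "files" && is.null(input_dir)) {
    stop("'input_dir' required in files mode", call. = FALSE)
  }
  design$seed <- as.integer(seed)
  structure(list(mode = mode, input_dir = input_dir, out_dir = out_dir,
                 seed = as.integer(seed), design = design,
                 fcc_true = fcc_true, noise = noise, flux_model = flux_model,
                 grid = grid, nat_corr = nat_corr, p13 = p13,
                 pool_mode = pool_mode, cal_factor = cal_factor,
                 leaf_area = leaf_area),
            class = "run_config")
}

.serialize_config <- function(config) {
  flat <- c(
    mode = config$mode,
    input_dir = if (is.null(config$input_dir)) "" else config$input_dir,
    seed = config$seed, fcc_true = config$fcc_true,
    flux_model = config$flux_model, nat_corr = config$nat_corr,
    p13 = config$p13, pool_mode = config$pool_mode,
    leaf_area = config$leaf_area,
    cal_factor = if (is.null(config$cal_factor)) "" else config$cal_factor,
    grid_min = min(config$grid), grid_max = max(config$grid),
    grid_step = if (length(config$grid) > 1) diff(config$grid)[1] else NA,
    sd_v = config$noise$sd_v, sd_J = config$noise$sd_J,
    pool_cv = if (is.null(config$noise$pool_cv)) "published_se"
              else config$noise$pool_cv,
    channel_frac = config$noise$channel_frac,
    baseline_v = config$design$baseline_v,
    multipliers = paste(sprintf("%s=%g", names(config$design$multipliers),
                                config$design$multipliers), collapse = ",")
  )
  paste0(names(flat), "=", unlist(flat))
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage: data acquisition (simulate or read files),
#' PTR-MS channel processing into fractional labeling curves, pool
#' quantification with internal-standard and natural-abundance correction,
#' per-sample flux fitting with plastidial pools fixed, and per-condition
#' flux control coefficient regression. Every input sample either appears
#' in the flux table or in the exclusion log with a reason.
#'
#' @param config A [pipeline_config()].
#' @return List with `sample_table` (joined pools + activity + flux),
#'   `flux_table`, `fcc_table`, `pool_table`, `excluded` (data.frame of
#'   dropped samples with reasons), `config`, and (simulate mode) `truth`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  study <- if (config$mode == "simulate") {
    generate_study(design = config$design, fcc_true = config$fcc_true,
                   noise = config$noise, flux_model = config$flux_model,
                   grid = config$grid, p13 = config$p13)
  } else {
    read_study(config$input_dir)
  }
  # stage 1: PTR-MS channels -> fractional labeling curves
  curves <- lapply(study$runs, function(run) {
    tryCatch(ptrms_label_curve(run, background = study$background,
                               nat_corr = config$nat_corr),
             error = function(e) conditionMessage(e))
  })
  # stage 2: pool quantification
  pool_table <- estimate_pools(study$pool_measurements, study$standard_curves,
                               p13 = config$p13)
  pools_by_sample <- .plastidial_pools_by_sample(pool_table, config$pool_mode,
                                                 study$activity)
  # stage 3: per-sample flux fits
  flux_rows <- list(); excluded <- list()
  for (sid in names(study$runs)) {
    curve <- curves[[sid]]
    if (!inherits(curve, "label_curve")) {
      excluded[[sid]] <- data.frame(sample_id = sid, reason = paste(
        "labeling curve failed:", curve))
      next
    }
    p <- pools_by_sample[[sid]]
    if (is.null(p)) {
      excluded[[sid]] <- data.frame(sample_id = sid,
                                    reason = "no pool estimates")
      next
    }
    fit <- fit_flux(curve, p)
    if (!fit$converged) {
      excluded[[sid]] <- data.frame(sample_id = sid, reason = paste(
        "flux fit not converged:", fit$message))
      next
    }
    flux_rows[[sid]] <- data.frame(
      sample_id = sid, J = fit$J, se_J = fit$se_J, m = fit$m,
      se_m = fit$se_m, rss = fit$rss, n_points = fit$n_points,
      A = p$A, B = p$B, C = p$C)
  }
  flux_table <- do.call(rbind, c(flux_rows, make.row.names = FALSE))
  excluded <- if (length(excluded)) {
    do.call(rbind, c(excluded, make.row.names = FALSE))
  } else {
    data.frame(sample_id = character(), reason = character())
  }
  # stage 4: join and FCC regression per condition
  sample_table <- merge(study$activity, flux_table, by = "sample_id")
  records <- data.frame(sample_id = sample_table$sample_id,
                        genotype = sample_table$genotype,
                        condition = sample_table$condition,
                        J = sample_table$J, v = sample_table$activity)
  fcc_table <- fcc_regression(records, group_by_condition = TRUE)
  result <- list(sample_table = sample_table, flux_table = flux_table,
                 fcc_table = fcc_table, pool_table = pool_table,
                 excluded = excluded, config = config,
                 truth = study$truth)
  if (!is.null(config$out_dir)) .write_pipeline_outputs(result, config)
  result
}

# per-sample (or cell-mean) plastidial pools as pool_sizes objects
.plastidial_pools_by_sample <- function(pool_table, pool_mode, activity) {
  wide <- stats::reshape(
    pool_table[c("sample_id", "metabolite", "plastidial_pool")],
    idvar = "sample_id", timevar = "metabolite", direction = "wide")
  names(wide) <- sub("^plastidial_pool\\.", "", names(wide))
  if (!all(c("DXP", "MEcDP", "IDP+DMADP") %in% names(wide))) return(list())
  if (pool_mode == "mean") {
    key <- activity[match(wide$sample_id, activity$sample_id),
                    c("genotype", "condition")]
    cell <- interaction(key$genotype, key$condition)
    for (col in c("DXP", "MEcDP", "IDP+DMADP")) {
      wide[[col]] <- stats::ave(wide[[col]], cell)
    }
  }
  out <- lapply(seq_len(nrow(wide)), function(i) {
    tryCatch(pool_sizes(wide$DXP[i], wide$MEcDP[i], wide$`IDP+DMADP`[i]),
             error = function(e) NULL)
  })
  stats::setNames(out, wide$sample_id)
}

.write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) utils::write.table(
    d, file.path(config$out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wt(result$sample_table, "sample_table.tsv")
  wt(result$flux_table, "flux_table.tsv")
  wt(result$fcc_table, "fcc_table.tsv")
  wt(result$pool_table, "pool_table.tsv")
  wt(result$excluded, "excluded.tsv")
  writeLines(.serialize_config(config), file.path(config$out_dir,
                                                  "config.txt"))
  invisible(NULL)
}
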