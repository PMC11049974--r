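#' Reference parameter anchors for the grey poplar DXS study design
#'
#' Condition-by-genotype means (with standard errors and replicate counts)
#' of the maximal isoprene labeling plateau, the plastidial DXP, MEcDP and
#' IDP+DMADP pool sizes (pmol mg^-1 DW) and the MEP pathway flux
#' (pmol min^-1 mg^-1 DW) for empty-vector (EV), DXS-silenced (RNAi) and
#' DXS-overexpressing (OE) grey poplar lines under the four combinations of
#' light (1000 / 250 PPFD) and leaf temperature (30 / 21 degrees C). These
#' anchors parameterize the synthetic study generator.
#'
#' @return Data.frame with columns `ppfd`, `temp_c`, `condition`,
#'   `genotype`, `n`, `m`, `se_m`, `A`, `se_A`, `B`, `se_B`, `C`, `se_C`,
#'   `J`, `se_J`.
#' @export
reference_parameters <- function() {
  d <- data.frame(
    ppfd = rep(c(1000, 250, 1000, 250), each = 3),
    temp_c = rep(c(30, 30, 21, 21), each = 3),
    genotype = rep(c("EV", "RNAi", "OE"), 4),
    n = c(10, 14, 18, 10, 15, 20, 9, 13, 16, 8, 10, 19),
    m = c(0.912, 0.912, 0.902, 0.823, 0.870, 0.865,
          0.932, 0.929, 0.943, 0.946, 0.940, 0.957),
    se_m = c(0.007, 0.005, 0.006, 0.036, 0.008, 0.018,
             0.008, 0.009, 0.005, 0.009, 0.005, 0.006),
    A = c(41.65, 46.01, 58.61, 28.53, 25.61, 35.97,
          27.18, 28.64, 33.51, 21.99, 22.29, 24.59),
    se_A = c(2.22, 3.86, 3.21, 1.49, 1.29, 2.55,
             1.45, 1.96, 1.93, 1.29, 1.70, 0.97),
    B = c(85.59, 124.9, 139.4, 54.98, 46.99, 65.43,
          48.57, 48.19, 53.36, 35.74, 36.92, 43.21),
    se_B = c(14.43, 12.14, 15.89, 4.06, 2.66, 5.23,
             6.53, 3.39, 3.79, 4.54, 3.85, 3.37),
    C = c(38.09, 47.74, 41.20, 18.47, 22.03, 19.41,
          13.64, 19.44, 16.90, 13.31, 19.57, 13.18),
    se_C = c(4.01, 4.67, 4.76, 3.23, 1.68, 2.44,
             0.78, 1.35, 1.14, 1.89, 2.04, 1.32),
    J = c(28.65, 38.94, 38.52, 15.66, 16.49, 19.69,
          9.79, 12.15, 13.50, 7.43, 7.91, 9.55),
    se_J = c(2.95, 2.62, 2.56, 1.42, 0.96, 1.24,
             0.87, 0.55, 0.93, 0.65, 0.73, 0.64)
  )
  d$condition <- sprintf("%dPPFD_%dC", d$ppfd, d$temp_c)
  d
}

#' Synthetic study design
#'
#' The genotype-by-environment layout emulated by the generator: three
#' genotypes (empty vector at activity multiplier 1.00, RNAi-silenced at
#' 0.45, overexpressor at 1.25) crossed with four light/temperature
#' conditions.
#'
#' @param multipliers Named DXS activity multipliers per genotype.
#' @param n_per_cell Replicates per genotype-condition cell: `NULL` uses
#'   the published cell sizes ([reference_parameters()] `n`), a single
#'   integer uses that count everywhere.
#' @param seed Integer RNG seed; identical seeds give identical studies.
#' @param baseline_v Empty-vector DXS activity in arbitrary units (the FCC
#'   is invariant to this scale).
#' @return A `study_design` list.
#' @export
study_design <- function(multipliers = c(EV = 1.00, RNAi = 0.45, OE = 1.25),
                         n_per_cell = NULL, seed = 1L, baseline_v = 100) {
  if (any(multipliers <= 0)) stop("activity multipliers must be positive",
                                  call. = FALSE)
  if (!is.null(n_per_cell) && (length(n_per_cell) != 1L || n_per_cell < 1)) {
    stop("'n_per_cell' must be NULL or a single count >= 1", call. = FALSE)
  }
  structure(list(multipliers = multipliers, n_per_cell = n_per_cell,
                 seed = as.integer(seed), baseline_v = baseline_v),
            class = "study_design")
}

#' Noise configuration for the synthetic study
#'
#' Biological variability is multiplicative lognormal (activity, flux,
#' pools); instrument noise is additive Gaussian on the signal channels.
#'
#' @param sd_v Lognormal sdlog of DXS activity between replicates (default
#'   0.15).
#' @param sd_J Lognormal sdlog of flux around the control-law prediction
#'   (default 0.10).
#' @param pool_cv Lognormal sdlog of the pool sizes: `NULL` derives a
#'   per-cell coefficient of variation from the published standard errors
#'   (SE * sqrt(n) / mean); a number fixes it; 0 disables.
#' @param channel_frac Gaussian sd of channel signals as a fraction of the
#'   maximum channel signal (default 0.01).
#' @return A `noise_config` list.
#' @seealso [zero_noise()]
#' @export
noise_config <- function(sd_v = 0.15, sd_J = 0.10, pool_cv = NULL,
                         channel_frac = 0.01) {
  if (any(c(sd_v, sd_J, channel_frac) < 0) ||
      (!is.null(pool_cv) && pool_cv < 0)) {
    stop("noise standard deviations must be >= 0", call. = FALSE)
  }
  structure(list(sd_v = sd_v, sd_J = sd_J, pool_cv = pool_cv,
                 channel_frac = channel_frac), class = "noise_config")
}

#' All-zero noise configuration
#'
#' Convenience for noiseless round-trip testing: every stage's input equals
#' its generating model exactly.
#'
#' @return A `noise_config` with all standard deviations zero.
#' @export
zero_noise <- function() noise_config(sd_v = 0, sd_J = 0, pool_cv = 0,
                                      channel_frac = 0)

#' Generate one PTR-MS labeling run
#'
#' Simulates the six isoprene isotopologue channels over a labeling time
#' course. Each isoprene carbon is 13C with probability
#' `f(t) + (1 - f(t)) * p13` (tracer labeling plus natural abundance on the
#' remaining carbons), so the channel intensities follow a Binomial(5, .)
#' split of the total isoprene signal. Primary-ion channels and drift
#' pressure are emitted so the normalization stage is exercised; optional
#' flat background counts and additive Gaussian channel noise complete the
#' observation model.
#'
#' @param pools [pool_sizes()] generating the kinetics.
#' @param J,m Generating flux and plateau.
#' @param grid Time grid in minutes (default 0-50 by 0.5).
#' @param total_cps Total isoprene signal in cps (default 2000).
#' @param channel_frac Gaussian channel noise as a fraction of the maximum
#'   signal (default 0).
#' @param p13 Natural 13C abundance on unlabeled carbons (default 0.011).
#' @param background_cps Flat per-channel background added to each
#'   isotopologue channel (default 0).
#' @param primary_cps Named cps of the `mz21`, `mz37`, `mz55` primary-ion
#'   channels.
#' @param p_drift Drift-tube pressure in mbar.
#' @param seed Optional seed for standalone reproducibility.
#' @return Data.frame in the [read_ptrms_run()] schema.
#' @export
generate_label_run <- function(pools, J, m, grid = seq(0, 50, by = 0.5),
                               total_cps = 2000, channel_frac = 0,
                               p13 = 0.011, background_cps = 0,
                               primary_cps = c(mz21 = 1e6, mz37 = 2e5,
                                               mz55 = 5e4),
                               p_drift = 2.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pools <- as_pool_sizes(pools)
  f <- label_fraction(grid, pools, J, m)
  f_eff <- f + (1 - f) * p13
  probs <- t(vapply(f_eff, function(p) stats::dbinom(0:5, 5, p), numeric(6)))
  sig <- total_cps * probs + background_cps
  if (channel_frac > 0) {
    sig <- sig + matrix(stats::rnorm(length(sig), 0,
                                     channel_frac * max(sig)),
                        nrow = nrow(sig))
    sig <- pmax(sig, 0)
  }
  run <- data.frame(time_min = grid)
  for (i in 1:6) run[[paste0("mz", 68 + i)]] <- sig[, i]
  run$mz21 <- rep(primary_cps[["mz21"]], length(grid))
  run$mz37 <- rep(primary_cps[["mz37"]], length(grid))
  run$mz55 <- rep(primary_cps[["mz55"]], length(grid))
  run$p_drift_mbar <- rep(p_drift, length(grid))
  run
}

# mixture isotopologue distribution of a pool in which a fraction `frac`
# is labeled at level f_lab and the rest is unlabeled, both seen through
# natural abundance
.pool_channel_dist <- function(frac, f_lab, p13) {
  M <- natural_abundance_matrix(p13, 5L)
  lab <- stats::dbinom(0:5, 5, f_lab)
  unlab <- c(1, rep(0, 5))
  as.vector(M %*% (frac * lab + (1 - frac) * unlab))
}

#' Generate the full synthetic study
#'
#' Draws the complete genotype-by-environment experiment: per-replicate DXS
#' activities, pathway fluxes, pool sizes, PTR-MS labeling runs, paired
#' (with/without internal standard) LC-MS/MS pool measurements with a known
#' matrix suppression factor, and external standard curves - together with
#' the generating truth for recovery testing.
#'
#' Two flux models are available. `"control_law"` derives each replicate's
#' flux from its activity through a power law,
#' `J = J_EV(condition) * (v / v_EV)^fcc_true`, with lognormal noise - the
#' mode for control-coefficient recovery experiments. `"table1"` anchors
#' every genotype-condition cell's flux at its published mean
#' ([reference_parameters()]), reproducing the printed study values exactly
#' at zero noise.
#'
#' @param design A [study_design()].
#' @param fcc_true Generating flux control coefficient in [0, 1] (used by
#'   the control-law flux model).
#' @param noise A [noise_config()].
#' @param flux_model `"control_law"` or `"table1"`.
#' @param grid Labeling time grid in minutes.
#' @param p13 Natural 13C abundance.
#' @param frac_dxp,frac_mecdp Plastidial fractions of the total DXP and
#'   MEcDP pools (IDP+DMADP is entirely plastidial).
#' @param istd_pmol Internal-standard spike per metabolite, pmol.
#' @param background_cps Flat cuvette background on the isotopologue
#'   channels.
#' @return List with `runs` (named list of PTR-MS data.frames),
#'   `background` (empty-cuvette run), `pool_measurements`,
#'   `standard_curves`, `activity`, and `truth` data.frames.
#' @export
generate_study <- function(design = study_design(), fcc_true = 0.18,
                           noise = noise_config(),
                           flux_model = c("control_law", "table1"),
                           grid = seq(0, 50, by = 0.5), p13 = 0.011,
                           frac_dxp = 0.80, frac_mecdp = 0.85,
                           istd_pmol = 30, background_cps = 5) {
  flux_model <- match.arg(flux_model)
  if (fcc_true < 0 || fcc_true > 1) stop("'fcc_true' must lie in [0, 1]",
                                         call. = FALSE)
  stopifnot(inherits(noise, "noise_config"))
  set.seed(design$seed)
  anchors <- reference_parameters()
  slopes <- c(DXP = 120, MEcDP = 85, `IDP+DMADP` = 150)  # intensity per pmol
  curves <- do.call(rbind, lapply(names(slopes), function(met) {
    data.frame(metabolite = met, amount_pmol = c(0, 25, 50, 100, 200),
               intensity = slopes[[met]] * c(0, 25, 50, 100, 200))
  }))
  fracs <- c(DXP = frac_dxp, MEcDP = frac_mecdp, `IDP+DMADP` = 1)
  runs <- list(); truth <- list(); pm <- list(); act <- list()
  lnorm <- function(mu, sdlog) {
    if (sdlog <= 0) mu else mu * exp(stats::rnorm(1, 0, sdlog) - sdlog^2 / 2)
  }
  for (r in seq_len(nrow(anchors))) {
    row <- anchors[r, ]
    mult <- design$multipliers[[row$genotype]]
    n_cell <- if (is.null(design$n_per_cell)) row$n else design$n_per_cell
    ev <- anchors[anchors$condition == row$condition &
                    anchors$genotype == "EV", ]
    for (k in seq_len(n_cell)) {
      sid <- sprintf("%s_%s_%02d", row$condition, row$genotype, k)
      true_v <- lnorm(design$baseline_v * mult, noise$sd_v)
      true_J <- if (flux_model == "control_law") {
        lnorm(ev$J * (true_v / design$baseline_v)^fcc_true, noise$sd_J)
      } else {
        lnorm(row$J, noise$sd_J)
      }
      pool_sd <- function(mean, se) {
        cv <- if (is.null(noise$pool_cv)) se * sqrt(row$n) / mean
              else noise$pool_cv
        lnorm(mean, cv)
      }
      A <- pool_sd(row$A, row$se_A)
      B <- pool_sd(row$B, row$se_B)
      C <- pool_sd(row$C, row$se_C)
      p <- pool_sizes(A, B, C)
      runs[[sid]] <- generate_label_run(
        p, true_J, row$m, grid = grid, channel_frac = noise$channel_frac,
        p13 = p13, background_cps = background_cps)
      f_ref <- label_fraction(max(grid), p, true_J, row$m)
      mf <- stats::runif(1, 0.65, 0.95)  # matrix suppression factor
      totals <- c(DXP = A, MEcDP = B, `IDP+DMADP` = C) / fracs
      for (met in names(totals)) {
        ideal <- slopes[[met]] * totals[[met]] *
          .pool_channel_dist(fracs[[met]], f_ref, p13)
        unspiked <- ideal * mf
        spiked <- unspiked
        spiked[1] <- spiked[1] + slopes[[met]] * istd_pmol * mf
        if (noise$channel_frac > 0) {
          unspiked <- pmax(unspiked + stats::rnorm(6, 0, noise$channel_frac *
                                                     max(unspiked)), 0)
          spiked <- pmax(spiked + stats::rnorm(6, 0, noise$channel_frac *
                                                 max(spiked)), 0)
        }
        pm[[paste(sid, met, sep = "|")]] <- data.frame(
          sample_id = sid, metabolite = met,
          with_istd = c(FALSE, TRUE), istd_pmol = c(0, istd_pmol),
          rbind(stats::setNames(as.data.frame(t(unspiked)), paste0("a", 0:5)),
                stats::setNames(as.data.frame(t(spiked)), paste0("a", 0:5))))
      }
      act[[sid]] <- data.frame(sample_id = sid, genotype = row$genotype,
                               condition = row$condition, ppfd = row$ppfd,
                               temp_c = row$temp_c, activity = true_v)
      truth[[sid]] <- data.frame(
        sample_id = sid, genotype = row$genotype, condition = row$condition,
        ppfd = row$ppfd, temp_c = row$temp_c, true_v = true_v,
        true_J = true_J, A = A, B = B, C = C, m = row$m,
        frac_dxp = frac_dxp, frac_mecdp = frac_mecdp, matrix_factor = mf)
    }
  }
  background <- generate_label_run(
    pool_sizes(1, 2, 3), J = 1, m = 1, grid = grid, total_cps = 0,
    channel_frac = 0, p13 = p13, background_cps = background_cps)
  list(runs = runs, background = background,
       pool_measurements = do.call(rbind, c(pm, make.row.names = FALSE)),
       standard_curves = curves,
       activity = do.call(rbind, c(act, make.row.names = FALSE)),
       truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

#' Write a synthetic study to CSV/TSV files
#'
#' Emits `run_<sample_id>.csv` and `background.csv` in the PTR-MS run
#' schema, `pool_measurements.csv`, `standard_curves.csv`, `activity.csv`
#' and `truth.tsv` into `dir`.
#'
#' @param study Output of [generate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(study$runs)) {
    utils::write.csv(study$runs[[sid]],
                     file.path(dir, paste0("run_", sid, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(study$background, file.path(dir, "background.csv"),
                   row.names = FALSE)
  utils::write.csv(study$pool_measurements,
                   file.path(dir, "pool_measurements.csv"), row.names = FALSE)
  utils::write.csv(study$standard_curves,
                   file.path(dir, "standard_curves.csv"), row.names = FALSE)
  utils::write.csv(study$activity, file.path(dir, "activity.csv"),
                   row.names = FALSE)
  utils::write.table(study$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a study written by [write_study()]
#'
#' @param dir Directory containing the study files.
#' @return A study list in the [generate_study()] layout (truth included
#'   when present; it is never consumed by analysis stages).
#' @export
read_study <- function(dir) {
  run_files <- list.files(dir, pattern = "^run_.*\\.csv$", full.names = TRUE)
  runs <- lapply(run_files, read_ptrms_run)
  names(runs) <- sub("^run_(.*)\\.csv$", "\\1", basename(run_files))
  truth_path <- file.path(dir, "truth.tsv")
  list(
    runs = runs,
    background = read_ptrms_run(file.path(dir, "background.csv")),
    pool_measurements = utils::read.csv(
      file.path(dir, "pool_measurements.csv"), check.names = FALSE),
    standard_curves = utils::read.csv(
      file.path(dir, "standard_curves.csv"), check.names = FALSE),
    activity = utils::read.csv(file.path(dir, "activity.csv")),
    truth = if (file.exists(truth_path))
      utils::read.delim(truth_path) else NULL
  )
}
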