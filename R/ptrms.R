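# column layout of a PTR-MS run table
.ISO_COLS <- paste0("mz", 69:74)
.PRIMARY_COLS <- c("mz21", "mz37", "mz55")
.RUN_COLS <- c("time_min", .ISO_COLS, .PRIMARY_COLS, "p_drift_mbar")

#' Read a PTR-MS run from CSV
#'
#' The expected schema is one row per scan with columns
#' `time_min,mz69,mz70,mz71,mz72,mz73,mz74,mz21,mz37,mz55,p_drift_mbar`:
#' the six protonated isoprene isotopologue channels (0-5 13C atoms), the
#' hydronium primary-ion channels (H3O+ m/z 21, its water dimer m/z 37 and
#' trimer m/z 55) and the drift-tube pressure.
#'
#' @param path CSV file path.
#' @return A data.frame in the run schema.
#' @export
read_ptrms_run <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.RUN_COLS, names(d))
  if (length(missing)) {
    stop("PTR-MS run '", path, "' lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  d[.RUN_COLS]
}

#' Normalize raw PTR-MS count rates to the primary ion signal
#'
#' Converts raw counts per second (cps) on the isoprene isotopologue
#' channels into normalized counts (ncps) by dividing by the weighted
#' primary-ion sum (hydronium m/z 21 plus its water clusters m/z 37 and 55)
#' and rescaling to a reference drift-tube pressure:
#' \deqn{ncps = \frac{cps}{cps_{21} + w_{37} cps_{37} + w_{55} cps_{55}}
#'   \cdot \frac{p_{ref}}{p_{drift}} \cdot 10^6}
#' The primary-ion weights and the reference pressure depend on the
#' instrument configuration and are exposed as arguments. Normalization is
#' invariant to a common multiplicative gain on all channels.
#'
#' @param scan Data.frame in the run schema of [read_ptrms_run()] (one or
#'   more rows).
#' @param w37,w55 Weights of the hydronium-water cluster channels in the
#'   primary-ion sum (default 1).
#' @param p_ref Reference drift pressure in mbar (default 2.2).
#' @param scale Multiplier applied after normalization so ncps are of order
#'   counts per million primary ions (default 1e6).
#' @return Data.frame with `time_min`, `ncps69` .. `ncps74`, and a logical
#'   `rejected` column marking scans with a non-positive primary-ion sum
#'   (their ncps are NA, never silently zero).
#' @export
normalize_cps <- function(scan, w37 = 1, w55 = 1, p_ref = 2.2, scale = 1e6) {
  missing <- setdiff(setdiff(.RUN_COLS, "time_min"), names(scan))
  if (length(missing)) {
    stop("scan lacks columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(scan$p_drift_mbar <= 0)) {
    stop("drift pressure must be positive", call. = FALSE)
  }
  prim <- scan$mz21 + w37 * scan$mz37 + w55 * scan$mz55
  bad <- !is.finite(prim) | prim <= 0
  denom <- ifelse(bad, NA_real_, prim)
  out <- data.frame(time_min = if ("time_min" %in% names(scan))
    scan$time_min else seq_len(nrow(scan)))
  for (ch in .ISO_COLS) {
    out[[sub("mz", "ncps", ch)]] <-
      scan[[ch]] / denom * (p_ref / scan$p_drift_mbar) * scale
  }
  out$rejected <- bad
  if (any(bad)) {
    warning(sum(bad), " scan(s) rejected: non-positive primary ion sum",
            call. = FALSE)
  }
  out
}

#' Subtract an empty-cuvette background from a normalized series
#'
#' Elementwise subtraction of the background ncps (measured with an empty
#' chamber, no leaf) from the measurement series, channel by channel.
#' Negative results are clamped to zero; the number of clamped values is
#' recorded in the `clamped` attribute.
#'
#' @param series Data.frame with `ncps69` .. `ncps74` columns (output of
#'   [normalize_cps()]).
#' @param background Either a single-row data.frame / named numeric vector of
#'   per-channel background ncps, or a data.frame of background scans (its
#'   channel means are used). May not have more rows than `series`.
#' @return `series` with backgrounds removed.
#' @export
subtract_background <- function(series, background) {
  ncols <- sub("mz", "ncps", .ISO_COLS)
  if (!all(ncols %in% names(series))) {
    stop("series lacks ncps channels", call. = FALSE)
  }
  if (is.data.frame(background)) {
    if (nrow(background) > nrow(series)) {
      stop("background series longer than measurement series", call. = FALSE)
    }
    bg <- vapply(ncols, function(ch) mean(background[[ch]]), numeric(1))
  } else {
    bg <- background[ncols]
  }
  if (any(!is.finite(bg))) stop("non-finite background", call. = FALSE)
  clamped <- 0L
  for (ch in ncols) {
    v <- series[[ch]] - bg[[ch]]
    clamped <- clamped + sum(v < 0, na.rm = TRUE)
    series[[ch]] <- pmax(v, 0)
  }
  attr(series, "clamped") <- clamped
  series
}

#' Isoprene emission per unit leaf area
#'
#' Converts the mean normalized isoprene signal over the steady-state window
#' into an emission rate using an instrument calibration factor. The
#' calibration (nmol isoprene per second per ncps) comes from a gas-standard
#' calibration of the specific PTR-MS and must be supplied.
#'
#' @param mean_ncps Background-corrected mean ncps on the isoprene channel
#'   during steady state.
#' @param cal_factor Calibration factor, nmol s^-1 per ncps; > 0.
#' @param leaf_area Enclosed leaf area in m^2; > 0.
#' @return List with `emission` (nmol m^-2 s^-1), `leaf_area`, `mean_ncps`.
#' @export
emission_rate <- function(mean_ncps, cal_factor, leaf_area) {
  if (missing(cal_factor) || is.null(cal_factor) || !is.finite(cal_factor) ||
      cal_factor <= 0) {
    stop("a positive 'cal_factor' (nmol s-1 per ncps) must be configured",
         call. = FALSE)
  }
  if (!is.finite(leaf_area) || leaf_area <= 0) {
    stop("'leaf_area' must be positive (m^2)", call. = FALSE)
  }
  if (!is.finite(mean_ncps)) stop("non-finite mean signal", call. = FALSE)
  list(emission = max(mean_ncps, 0) * cal_factor / leaf_area,
       leaf_area = leaf_area, mean_ncps = mean_ncps)
}

#' Atom-weighted fractional 13C labeling from isotopologue intensities
#'
#' For a C5 molecule observed in six isotopologue channels S0..S5 (number of
#' 13C atoms), the fractional labeling is the total number of 13C atoms over
#' the total number of carbon atoms:
#' \deqn{f = \frac{\sum_{i=0}^{5} i\,S_i}{5 \sum_{i=0}^{5} S_i}}
#' The result is invariant to a common positive rescaling of the signals;
#' for signals proportional to Binomial(5, p) probabilities it returns p
#' exactly.
#'
#' @param iso_signals Numeric vector of 6 intensities (0-5 13C), or a matrix
#'   / data.frame with 6 columns (one row per time point).
#' @return Fractional labeling in [0, 1]; `NA` (flagged by warning) where all
#'   six signals are zero.
#' @export
#' @examples
#' fractional_labeling(c(10, 20, 30, 20, 10, 10))  # 0.46
fractional_labeling <- function(iso_signals) {
  if (is.data.frame(iso_signals)) iso_signals <- as.matrix(iso_signals)
  if (is.null(dim(iso_signals))) iso_signals <- matrix(iso_signals, nrow = 1)
  if (ncol(iso_signals) != 6L) {
    stop("expected 6 isotopologue channels (0-5 13C atoms)", call. = FALSE)
  }
  if (any(iso_signals < 0, na.rm = TRUE)) {
    stop("negative isotopologue intensities", call. = FALSE)
  }
  tot <- rowSums(iso_signals)
  wt <- as.vector(iso_signals %*% (0:5))
  f <- ifelse(tot > 0, wt / (5 * tot), NA_real_)
  if (anyNA(f)) {
    warning(sum(is.na(f)), " spectrum/spectra with all-zero signals: labeling undefined",
            call. = FALSE)
  }
  f
}

#' Correct isoprene isotopologue channels for natural 13C abundance
#'
#' Two methods are available. `"binomial"` (exact) inverts the binomial
#' convolution that natural abundance applies to each originally unlabeled
#' carbon, reusing the same linear-system correction as the metabolite
#' workflow ([natural_abundance_correct()]). `"mz70"` is the classical
#' quick correction: the natural 13C1 isotopologue of unlabeled isoprene
#' contributes about 5 x 1.1% of the m/z 69 intensity at m/z 70, and that
#' amount is subtracted from the m/z 70 channel (clamped at 0). `"none"`
#' returns the input.
#'
#' @param channels Matrix/data.frame with 6 isotopologue columns (0-5 13C),
#'   or a length-6 vector.
#' @param method `"binomial"`, `"mz70"`, or `"none"`.
#' @param p13 Natural 13C abundance (default 0.011).
#' @return Corrected channels, same shape as input.
#' @export
correct_isoprene_channels <- function(channels,
                                      method = c("binomial", "mz70", "none"),
                                      p13 = 0.011) {
  method <- match.arg(method)
  vec <- is.null(dim(channels)) && !is.data.frame(channels)
  if (vec) channels <- matrix(channels, nrow = 1)
  if (is.data.frame(channels)) channels <- as.matrix(channels)
  if (ncol(channels) != 6L) stop("expected 6 channels", call. = FALSE)
  out <- switch(method,
    none = channels,
    mz70 = {
      ch <- channels
      ch[, 2] <- pmax(ch[, 2] - 5 * p13 * ch[, 1], 0)
      ch
    },
    binomial = t(apply(channels, 1, natural_abundance_correct, p13 = p13))
  )
  if (vec) as.vector(out) else out
}

#' Assemble a fractional labeling curve from a PTR-MS run
#'
#' Full channel-level workflow: primary-ion/pressure normalization,
#' optional background subtraction, natural-abundance correction, and
#' atom-weighted labeling, yielding the f(t) curve that the flux model fits.
#' Scans rejected during normalization or with all-zero signals are dropped.
#'
#' @param run PTR-MS run data.frame ([read_ptrms_run()] schema).
#' @param background Optional background in the same schema (or NULL).
#' @param nat_corr Natural-abundance correction method, see
#'   [correct_isoprene_channels()].
#' @param ... Passed to [normalize_cps()].
#' @return A [label_curve()].
#' @export
ptrms_label_curve <- function(run, background = NULL,
                              nat_corr = c("binomial", "mz70", "none"), ...) {
  nat_corr <- match.arg(nat_corr)
  norm <- normalize_cps(run, ...)
  if (!is.null(background)) {
    bgn <- normalize_cps(background, ...)
    bg <- colMeans(bgn[sub("mz", "ncps", .ISO_COLS)][!bgn$rejected, ])
    norm <- subtract_background(norm, bg)
  }
  keep <- !norm$rejected
  ch <- as.matrix(norm[keep, sub("mz", "ncps", .ISO_COLS)])
  ch <- correct_isoprene_channels(ch, method = nat_corr)
  f <- suppressWarnings(fractional_labeling(ch))
  ok <- !is.na(f)
  label_curve(norm$time_min[keep][ok], f[ok])
}

#' Write a labeling curve to TSV
#'
#' Emits the two-column `time_min`, `f_label` table consumed by the flux
#' fitting stage.
#'
#' @param curve A [label_curve()].
#' @param path Output path.
#' @return The curve, invisibly.
#' @export
write_label_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve)[c("time_min", "f_label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(curve)
}
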