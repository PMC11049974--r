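#' Quantify an amount from an external standard curve
#'
#' Fits an ordinary linear regression of intensity on amount through the
#' calibration points and inversely predicts the amount giving the observed
#' response. Negative inverse predictions are clamped to zero and flagged
#' via the `clamped` attribute.
#'
#' @param response Observed intensity (scalar or vector).
#' @param curve Data.frame with columns `amount_pmol` and `intensity`
#'   (>= 2 points, strictly increasing amounts, increasing response).
#' @return Predicted amount(s) in pmol.
#' @export
#' @examples
#' sc <- data.frame(amount_pmol = c(0, 10), intensity = c(0, 100))
#' quantify_standard_curve(50, sc)  # 5
quantify_standard_curve <- function(response, curve) {
  if (!is.data.frame(curve) ||
      !all(c("amount_pmol", "intensity") %in% names(curve))) {
    stop("standard curve needs columns amount_pmol, intensity", call. = FALSE)
  }
  if (nrow(curve) < 2L || any(diff(curve$amount_pmol) <= 0)) {
    stop("standard curve needs >= 2 points with strictly increasing amounts",
         call. = FALSE)
  }
  fit <- stats::lm(intensity ~ amount_pmol, data = curve)
  slope <- stats::coef(fit)[["amount_pmol"]]
  if (!is.finite(slope) || slope <= 0) {
    stop("standard curve is non-monotone or singular", call. = FALSE)
  }
  amount <- (response - stats::coef(fit)[["(Intercept)"]]) / slope
  clamped <- amount < 0
  amount <- pmax(amount, 0)
  attr(amount, "clamped") <- sum(clamped)
  amount
}

# intensity increment expected per pmol (curve slope)
.curve_slope <- function(curve) {
  fit <- stats::lm(intensity ~ amount_pmol, data = curve)
  stats::coef(fit)[["amount_pmol"]]
}

#' Internal-standard matrix/recovery factor from paired runs
#'
#' Each extract is analyzed twice, once with and once without a spike of
#' `istd_pmol` of unlabeled internal standard. In a post-labeling extract
#' the channels carrying 3, 4 and 5 13C atoms are dominated by biologically
#' labeled material and are unaffected by the (unlabeled) spike, so the
#' ratio of those heavy channels between the two runs estimates the
#' endogenous scale `s` between runs. The spike's contribution to the
#' unlabeled channel is then `spiked[1] - s * unspiked[1]`, and the matrix
#' factor is that contribution divided by the intensity the standard curve
#' predicts for `istd_pmol` in a clean matrix. A factor below 1 means signal
#' loss to matrix suppression; pool amounts quantified from the extract are
#' divided by it.
#'
#' @param spiked,unspiked Numeric vectors of 6 channel areas (0-5 13C) for
#'   the run with and without internal standard.
#' @param istd_pmol Amount of internal standard spiked (> 0).
#' @param curve Standard curve data.frame (see
#'   [quantify_standard_curve()]); its slope gives the expected intensity
#'   increment per pmol.
#' @return The recovery factor (> 0), with attribute `low_confidence = TRUE`
#'   when the heavy channels were empty and the endogenous scale could not
#'   be estimated (scale 1 assumed).
#' @export
istd_matrix_factor <- function(spiked, unspiked, istd_pmol, curve) {
  if (length(spiked) != 6L || length(unspiked) != 6L) {
    stop("expected 6-channel area vectors", call. = FALSE)
  }
  if (any(spiked < 0) || any(unspiked < 0)) {
    stop("negative channel areas", call. = FALSE)
  }
  if (!is.finite(istd_pmol) || istd_pmol <= 0) {
    stop("'istd_pmol' must be positive", call. = FALSE)
  }
  expected <- .curve_slope(curve) * istd_pmol
  if (expected <= 0) stop("standard curve slope must be positive", call. = FALSE)
  heavy <- 4:6  # channels with 3, 4, 5 13C atoms
  low_conf <- FALSE
  if (all(unspiked[heavy] == 0)) {
    s <- 1
    low_conf <- TRUE
  } else {
    # signal-weighted ratio of sums: stable when single heavy channels are
    # near empty, unlike a plain mean of per-channel ratios
    s <- sum(spiked[heavy]) / sum(unspiked[heavy])
  }
  contribution <- spiked[1] - s * unspiked[1]
  factor <- contribution / expected
  if (!is.finite(factor) || factor <= 0) {
    stop("ISTD contribution non-positive; cannot estimate recovery factor",
         call. = FALSE)
  }
  attr(factor, "endogenous_scale") <- s
  if (low_conf) attr(factor, "low_confidence") <- TRUE
  factor
}

#' Correct an isotopologue distribution for natural 13C abundance
#'
#' Natural abundance turns a molecule with `j` tracer-labeled carbons into
#' the observed channel `i >= j` with probability
#' `dbinom(i - j, n_carbons - j, p13)`. Stacking these probabilities gives a
#' lower-triangular convolution matrix `M`; the corrected distribution is
#' the solution of `M x = areas`, clamped at zero and renormalized to the
#' observed total signal.
#'
#' @param areas Non-negative vector of `n_carbons + 1` channel areas.
#' @param p13 Per-atom natural 13C probability (default 0.011); must be
#'   < 0.5 for a well-conditioned system.
#' @param n_carbons Number of carbon atoms (default 5).
#' @return Corrected channel vector of the same length and total.
#' @export
natural_abundance_correct <- function(areas, p13 = 0.011, n_carbons = 5L) {
  if (length(areas) != n_carbons + 1L) {
    stop("expected ", n_carbons + 1L, " channels", call. = FALSE)
  }
  if (any(areas < 0) || any(!is.finite(areas))) {
    stop("areas must be finite and non-negative", call. = FALSE)
  }
  if (p13 < 0 || p13 >= 0.5) {
    stop("'p13' must lie in [0, 0.5) for a well-conditioned correction",
         call. = FALSE)
  }
  if (p13 == 0) return(areas)
  M <- natural_abundance_matrix(p13, n_carbons)
  x <- solve(M, areas)
  x <- pmax(x, 0)
  tot <- sum(areas)
  if (sum(x) > 0) x <- x * tot / sum(x)
  x
}

#' Natural-abundance convolution matrix
#'
#' `M[i, j] = P(observe i-1 heavy atoms | j-1 tracer-labeled atoms)` under
#' independent per-atom natural abundance `p13` on the unlabeled atoms.
#' Multiplying a true labeling distribution by `M` simulates the observed
#' channels; [natural_abundance_correct()] inverts it.
#'
#' @inheritParams natural_abundance_correct
#' @return A `(n_carbons+1) x (n_carbons+1)` lower-triangular matrix with
#'   unit column sums.
#' @export
natural_abundance_matrix <- function(p13 = 0.011, n_carbons = 5L) {
  n <- n_carbons + 1L
  M <- matrix(0, n, n)
  for (j in seq_len(n)) {
    k <- j - 1L                       # tracer-labeled atoms
    M[j:n, j] <- stats::dbinom(0:(n_carbons - k), n_carbons - k, p13)
  }
  M
}

#' Atom-weighted label fraction of a metabolite isotopologue distribution
#'
#' Identical algebra to the isoprene computation
#' ([fractional_labeling()]): total 13C atoms over total carbon atoms,
#' for a C5 metabolite observed in 6 channels. Apply
#' [natural_abundance_correct()] first.
#'
#' @param areas 6-channel area vector (or matrix, one row per spectrum).
#' @return Fraction(s) in [0, 1].
#' @export
metabolite_label_fraction <- function(areas) {
  fractional_labeling(areas)
}

#' Plastidial pool size from final label incorporation
#'
#' DXP and MEcDP occur in plastidic and extra-plastidic pools, but only the
#' plastidic pool becomes labeled on the time scale of the experiment, while
#' the IDP+DMADP pool is assumed entirely plastidic. The plastidial share of
#' a metabolite's total pool is therefore estimated as the ratio of its
#' final 13C label incorporation to that of IDP+DMADP:
#' `plastidial = total * final_label_met / final_label_ref`, capped at the
#' total.
#'
#' @param total Total measured pool, pmol mg^-1 DW.
#' @param final_label_met Final label fraction of the metabolite.
#' @param final_label_ref Final label fraction of IDP+DMADP (> 0).
#' @return Plastidial pool size, pmol mg^-1 DW.
#' @export
#' @examples
#' plastidial_pool(50, 0.45, 0.90)  # 25
plastidial_pool <- function(total, final_label_met, final_label_ref) {
  if (!is.finite(final_label_ref) || final_label_ref <= 0) {
    stop("reference (IDP+DMADP) final label must be positive; plastidial pool undefined",
         call. = FALSE)
  }
  if (total < 0 || final_label_met < 0) {
    stop("negative inputs", call. = FALSE)
  }
  est <- total * final_label_met / final_label_ref
  if (est > total) {
    warning("metabolite label exceeds IDP+DMADP reference; plastidial pool capped at total",
            call. = FALSE)
    est <- total
  }
  est
}

#' Process a table of paired isotopologue measurements into pool estimates
#'
#' Runs the full quantification workflow per sample and metabolite:
#' internal-standard matrix factor from the spiked/unspiked run pair,
#' total pool from the unspiked unlabeled-equivalent signal via the
#' standard curve (corrected by the matrix factor), natural-abundance
#' correction, final label fraction, and plastidial pool estimation with
#' IDP+DMADP as the labeling reference.
#'
#' @param measurements Data.frame with columns `sample_id`, `metabolite`
#'   (`DXP`, `MEcDP`, `IDP+DMADP`), `with_istd` (logical), `istd_pmol`,
#'   `a0` .. `a5` (channel areas), plus optional passthrough columns.
#' @param curves Named list of standard-curve data.frames (one per
#'   metabolite) or a single data.frame with a `metabolite` column.
#' @param p13 Natural 13C abundance used in the correction.
#' @param mass_mg Dry mass extracted per sample, mg (default 1: amounts are
#'   already per mg DW).
#' @return Data.frame `sample_id, metabolite, matrix_factor, total_pool,
#'   plastidial_pool, final_label`.
#' @export
estimate_pools <- function(measurements, curves, p13 = 0.011, mass_mg = 1) {
  need <- c("sample_id", "metabolite", "with_istd", "istd_pmol",
            paste0("a", 0:5))
  missing <- setdiff(need, names(measurements))
  if (length(missing)) {
    stop("measurement table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.data.frame(curves)) {
    curves <- split(curves[c("amount_pmol", "intensity")], curves$metabolite)
  }
  achn <- paste0("a", 0:5)
  rows <- list()
  for (sid in unique(measurements$sample_id)) {
    sub <- measurements[measurements$sample_id == sid, ]
    per_met <- list()
    for (met in unique(sub$metabolite)) {
      ms <- sub[sub$metabolite == met, ]
      unspiked <- ms[!ms$with_istd, ][1, ]
      spiked <- ms[ms$with_istd, ]
      curve <- curves[[met]]
      if (is.null(curve)) stop("no standard curve for ", met, call. = FALSE)
      areas <- as.numeric(unspiked[achn])
      factor <- if (nrow(spiked)) {
        tryCatch(
          istd_matrix_factor(as.numeric(spiked[1, achn]), areas,
                             spiked$istd_pmol[1], curve),
          error = function(e) {
            warning("sample ", sid, " / ", met, ": ", conditionMessage(e),
                    "; pool left unquantified", call. = FALSE)
            NA_real_
          })
      } else 1
      corrected <- natural_abundance_correct(areas, p13 = p13)
      flabel <- metabolite_label_fraction(corrected)
      raw_amount <- quantify_standard_curve(sum(areas), curve)
      total <- as.numeric(raw_amount) / as.numeric(factor) / mass_mg
      per_met[[met]] <- data.frame(sample_id = sid, metabolite = met,
                                   matrix_factor = as.numeric(factor),
                                   total_pool = total,
                                   plastidial_pool = NA_real_,
                                   final_label = flabel)
    }
    ref <- per_met[["IDP+DMADP"]]
    for (met in names(per_met)) {
      r <- per_met[[met]]
      r$plastidial_pool <- if (met == "IDP+DMADP") {
        r$total_pool
      } else if (!is.null(ref)) {
        plastidial_pool(r$total_pool, r$final_label, ref$final_label)
      } else NA_real_
      rows[[paste(sid, met)]] <- r
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
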