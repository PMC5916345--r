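#' Specification of a synthetic multi-tracer PET cohort
#'
#' Defines the population a synthetic cohort is drawn from: per-ROI means and
#' SDs of the net influx rate `Ki` (1/min), baseline binding potential
#' `BPnd`, and drug-induced percent release; the cross-measure correlation
#' structure; the body-weight distribution (fixed 30 mg oral dose context);
#' TAC noise; and the RNG seed. The defaults reproduce the study conditions of
#' a 40-subject healthy-adult striatal cohort: whole striatum
#' `Ki = 0.015 +/- 0.002`, baseline `BPnd = 2.19 +/- 0.18`, release
#' `8.78 +/- 4.23 %`, with subregion rows for dorsal caudate, dorsal putamen
#' and ventral striatum, and a `Ki`-baseline-`BPnd` correlation of 0.46.
#'
#' @param n_subjects cohort size (default 40).
#' @param rois data frame with columns `roi`, `ki_mean`, `ki_sd`, `bp_mean`,
#'   `bp_sd`, `release_mean`, `release_sd` (percent), `vol_mean`, `vol_sd`
#'   (mm^3). Default: the four striatal ROIs above.
#' @param cor_measures 3x3 correlation matrix over (Ki, baseline BPnd,
#'   release fraction); must be symmetric PSD with unit diagonal.
#' @param dose_mg fixed oral drug amount (mg), default 30.
#' @param mgkg_mean,mgkg_sd population mg-per-kg distribution (0.46 +/- 0.08);
#'   body weight is `dose_mg / (mg per kg)`.
#' @param noise_scale TAC noise scale passed to [add_frame_noise()]
#'   (default 0.05, a low-noise regime).
#' @param patlak_V distribution-volume intercept of the irreversible tissue
#'   model (default 0.5).
#' @param R1,k2 SRTM nuisance truth shared by all subjects (defaults 1, 0.3).
#' @param tacs generate per-subject TACs (default `TRUE`); `FALSE` draws the
#'   truth table only, which is cheap enough for very large moment checks.
#' @param reference_check include per-subject occipital-reference TACs for
#'   [sanity_check_reference()] (default `FALSE`).
#' @param ref_change systematic fractional change of the cerebellar
#'   reference-region binding between the two raclopride scans (default 0;
#'   used to exercise the reference sanity check).
#' @param seed integer RNG seed.
#' @return A `cohort_spec` object (list).
#' @export
cohort_spec <- function(n_subjects = 40,
                        rois = default_roi_table(),
                        cor_measures = default_measure_cor(),
                        dose_mg = 30, mgkg_mean = 0.46, mgkg_sd = 0.08,
                        noise_scale = 0.05,
                        patlak_V = 0.5, R1 = 1, k2 = 0.3,
                        tacs = TRUE,
                        reference_check = FALSE, ref_change = 0,
                        seed = 1L) {
  stopifnot(n_subjects >= 1, noise_scale >= 0)
  cor_measures <- as.matrix(cor_measures)
  if (!isTRUE(all.equal(cor_measures, t(cor_measures))) ||
      any(abs(diag(cor_measures) - 1) > 1e-12)) {
    stop("cor_measures must be symmetric with unit diagonal")
  }
  if (min(eigen(cor_measures, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-10) {
    stop("cor_measures must be positive semi-definite")
  }
  need <- c("roi", "ki_mean", "ki_sd", "bp_mean", "bp_sd",
            "release_mean", "release_sd", "vol_mean", "vol_sd")
  if (!all(need %in% names(rois))) {
    stop("rois must have columns ", paste(need, collapse = ", "))
  }
  if (any(rois$ki_sd < 0 | rois$bp_sd < 0 | rois$release_sd < 0)) {
    stop("SDs must be >= 0")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), rois = rois,
      cor_measures = cor_measures, dose_mg = dose_mg,
      mgkg_mean = mgkg_mean, mgkg_sd = mgkg_sd,
      noise_scale = noise_scale, patlak_V = patlak_V, R1 = R1, k2 = k2,
      tacs = isTRUE(tacs),
      reference_check = isTRUE(reference_check), ref_change = ref_change,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Default striatal ROI population table
#'
#' Per-ROI population means and SDs for the synthetic cohort: net influx rate
#' `Ki`, baseline `BPnd`, percent release, and ROI volume, for whole striatum
#' and the three manually-drawn subregions.
#'
#' @return A data frame, one row per ROI.
#' @export
default_roi_table <- function() {
  data.frame(
    roi = c("whole_striatum", "dorsal_caudate", "dorsal_putamen",
            "ventral_striatum"),
    ki_mean = c(0.015, 0.019, 0.024, 0.018),
    ki_sd = c(0.002, 0.002, 0.002, 0.002),
    bp_mean = c(2.19, 3.02, 3.85, 2.61),
    bp_sd = c(0.18, 0.27, 0.27, 0.22),
    release_mean = c(8.78, 7.48, 9.63, 8.12),
    release_sd = c(4.23, 3.78, 5.88, 4.13),
    vol_mean = c(7097, 2042, 3759, 1788),
    vol_sd = c(0, 377, 608, 330)
  )
}

#' Default cross-measure correlation matrix
#'
#' Correlation across subjects among (Ki, baseline BPnd, release fraction).
#' Default: `cor(Ki, BPnd) = 0.46`; release uncorrelated with either
#' (the whole-striatum Ki-release correlation is essentially zero).
#'
#' @param r_ki_bp,r_ki_release,r_bp_release pairwise correlations.
#' @return 3x3 correlation matrix with dimnames (ki, bp, release).
#' @export
default_measure_cor <- function(r_ki_bp = 0.46, r_ki_release = 0,
                                r_bp_release = 0) {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- r_ki_bp
  m[1, 3] <- m[3, 1] <- r_ki_release
  m[2, 3] <- m[3, 2] <- r_bp_release
  dimnames(m) <- list(c("ki", "bp", "release"), c("ki", "bp", "release"))
  m
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort spec: n = %d, noise scale = %g, seed = %d\n",
              x$n_subjects, x$noise_scale, x$seed))
  print(x$rois, row.names = FALSE)
  invisible(x)
}

# Draw one (ki, bp, release-fraction) triple for one ROI; release fraction is
# normal truncated to [0, 0.9) by rejection (the whole triple is redrawn so
# the cross-measure correlation is preserved conditionally), and ki/bp must be
# positive.  L is the lower-triangular Cholesky factor of the correlation.
draw_triple <- function(mu, sd, L) {
  repeat {
    v <- mu + sd * as.numeric(L %*% stats::rnorm(3))
    if (v[1] > 0 && v[2] > 0 && v[3] >= 0 && v[3] < 0.9) return(v)
  }
}

#' Simulate a multi-tracer PET cohort
#'
#' Draws per-subject true parameters (per-ROI `Ki`, baseline `BPnd`, release
#' fraction; body weight; ROI volumes) from the population defined by a
#' [cohort_spec()], then forward-simulates per-subject TACs: an
#' irreversible-tracer tissue TAC per ROI on the 90-min schedule
#' (graphical-exact mode at the subject's true `Ki`), and paired
#' placebo/post-drug reversible-tracer TACs per ROI on the 60-min schedule
#' (SRTM forward model; the post-drug true `BPnd` is
#' `baseline * (1 - release fraction)`). Frame-weighted Gaussian noise is
#' added to every observed TAC, including the reference-region TACs. The whole
#' draw is performed under the spec's seed in an isolated RNG scope, so a
#' fixed spec yields a bit-identical cohort.
#'
#' @param spec a [cohort_spec()].
#' @return A `pet_cohort` object: `spec`; `truth` (data frame, one row per
#'   subject x ROI, with true and derived quantities); `subjects` (list with
#'   observed TACs per subject); `refs` (the noiseless reference TACs).
#' @examples
#' co <- simulate_cohort(cohort_spec(n_subjects = 2, seed = 7))
#' head(co$truth)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  make_tacs <- spec$tacs %||% TRUE
  sched_fmt <- frame_schedule("FMT")
  sched_rac <- frame_schedule("RAC")
  ref_fmt <- simulate_reference_tac(schedule = sched_fmt)
  ref_rac <- simulate_reference_tac(schedule = sched_rac)
  occ_rac <- if (spec$reference_check) {
    simulate_reference_tac(K1p = 0.09, k2p = 0.11, schedule = sched_rac)
  } else NULL
  L <- t(chol(spec$cor_measures + diag(1e-12, 3)))

  withr::with_seed(spec$seed, {
    rois <- spec$rois
    subjects <- vector("list", spec$n_subjects)
    rows <- vector("list", spec$n_subjects)
    for (s in seq_len(spec$n_subjects)) {
      mgkg <- 0
      while (mgkg < 0.2) mgkg <- stats::rnorm(1, spec$mgkg_mean, spec$mgkg_sd)
      weight <- spec$dose_mg / mgkg
      tr <- lapply(seq_len(nrow(rois)), function(i) {
        v <- draw_triple(
          c(rois$ki_mean[i], rois$bp_mean[i], rois$release_mean[i] / 100),
          c(rois$ki_sd[i], rois$bp_sd[i], rois$release_sd[i] / 100),
          L
        )
        vol <- -1
        while (vol <= 0) {
          vol <- if (rois$vol_sd[i] > 0) {
            stats::rnorm(1, rois$vol_mean[i], rois$vol_sd[i])
          } else rois$vol_mean[i]
        }
        data.frame(
          subject = s, roi = rois$roi[i], weight = weight,
          ki_true = v[1], bp_placebo_true = v[2],
          release_frac_true = v[3],
          bp_drug_true = v[2] * (1 - v[3]),
          release_pct_true = 100 * v[3], volume_mm3 = vol
        )
      })
      tr <- do.call(rbind, tr)
      if (!make_tacs) {
        subjects[[s]] <- list(id = s, weight = weight)
        rows[[s]] <- tr
        next
      }
      ns <- spec$noise_scale
      fmt_tis <- lapply(seq_len(nrow(tr)), function(i) {
        add_frame_noise(
          simulate_irreversible_tac(ref_fmt, Ki = tr$ki_true[i],
                                    V = spec$patlak_V), ns)
      })
      rac1_tis <- lapply(seq_len(nrow(tr)), function(i) {
        add_frame_noise(
          simulate_srtm_tac(ref_rac, R1 = spec$R1, k2 = spec$k2,
                            BPnd = tr$bp_placebo_true[i]), ns)
      })
      rac2_tis <- lapply(seq_len(nrow(tr)), function(i) {
        add_frame_noise(
          simulate_srtm_tac(ref_rac, R1 = spec$R1, k2 = spec$k2,
                            BPnd = tr$bp_drug_true[i]), ns)
      })
      names(fmt_tis) <- names(rac1_tis) <- names(rac2_tis) <- rois$roi
      subj <- list(
        id = s, weight = weight,
        fmt = list(ref = add_frame_noise(ref_fmt, ns), tissue = fmt_tis),
        rac1 = list(ref = add_frame_noise(ref_rac, ns), tissue = rac1_tis),
        rac2 = list(ref = add_frame_noise(ref_rac, ns), tissue = rac2_tis)
      )
      if (spec$reference_check) {
        # cerebellar gray as target region against an occipital reference,
        # with a small residual binding; scan 2 binding shifted by ref_change
        bp_cb <- 0.1
        subj$refcheck <- list(
          occ1 = add_frame_noise(occ_rac, ns),
          occ2 = add_frame_noise(occ_rac, ns),
          cb1 = add_frame_noise(
            simulate_srtm_tac(occ_rac, R1 = 1.05, k2 = 0.25, BPnd = bp_cb), ns),
          cb2 = add_frame_noise(
            simulate_srtm_tac(occ_rac, R1 = 1.05, k2 = 0.25,
                              BPnd = bp_cb * (1 - spec$ref_change)), ns)
        )
      }
      subjects[[s]] <- subj
      rows[[s]] <- tr
    }
    structure(
      list(
        spec = spec, truth = do.call(rbind, rows), subjects = subjects,
        refs = list(fmt = ref_fmt, rac = ref_rac, occ = occ_rac)
      ),
      class = "pet_cohort"
    )
  })
}

#' @export
print.pet_cohort <- function(x, ...) {
  cat(sprintf("Synthetic PET cohort: %d subjects x %d ROIs (seed %d)\n",
              x$spec$n_subjects, nrow(x$spec$rois), x$spec$seed))
  invisible(x)
}

#' Write the cohort truth table to CSV
#'
#' @param cohort a `pet_cohort`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "pet_cohort"))
  utils::write.csv(cohort$truth, path, row.names = FALSE)
  invisible(path)
}
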