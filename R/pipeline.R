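#' Per-subject kinetic fits for a whole cohort
#'
#' Runs the full kinetic stage on a synthetic (or ingested) cohort: a
#' reference-Patlak fit of the 90-min irreversible-tracer TAC per ROI, and
#' basis-function SRTM fits of the placebo and post-drug 60-min TACs per ROI,
#' from which the per-subject percent-change release statistic is computed.
#' SRTM basis sets are computed once per subject and scan and shared across
#' ROIs.
#'
#' @param cohort a `pet_cohort` from [simulate_cohort()].
#' @param t_star Patlak start time (min, default 25).
#' @param theta3 SRTM grid (default [theta3_grid()]).
#' @param weights SRTM weights (see [srtm_fit()]).
#' @param refine SRTM continuous theta3 refinement (default `TRUE`).
#' @return Data frame, one row per subject x ROI: estimated `ki`,
#'   `bp_placebo`, `bp_drug`, `release_pct`, plus `weight` and `volume_mm3`.
#' @export
fit_cohort <- function(cohort, t_star = 25, theta3 = theta3_grid(),
                       weights = NULL, refine = TRUE) {
  stopifnot(inherits(cohort, "pet_cohort"))
  rois <- cohort$spec$rois$roi
  rows <- lapply(cohort$subjects, function(subj) {
    b1 <- srtm_basis_set(subj$rac1$ref, theta3)
    b2 <- srtm_basis_set(subj$rac2$ref, theta3)
    w <- resolve_weights(weights, subj$rac1$ref$schedule)
    do.call(rbind, lapply(rois, function(roi) {
      ki <- patlak_fit(subj$fmt$tissue[[roi]], subj$fmt$ref, t_star)$Ki
      bp1 <- srtm_fit_engine(subj$rac1$tissue[[roi]]$activity, b1, w,
                             refine)$BPnd
      bp2 <- srtm_fit_engine(subj$rac2$tissue[[roi]]$activity, b2, w,
                             refine)$BPnd
      tr <- cohort$truth[cohort$truth$subject == subj$id &
                           cohort$truth$roi == roi, ]
      data.frame(
        subject = subj$id, roi = roi, weight = subj$weight,
        volume_mm3 = tr$volume_mm3, ki = ki,
        bp_placebo = bp1, bp_drug = bp2,
        release_pct = percent_change(bp1, bp2)
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Study configuration
#'
#' Bundles every knob of [run_study()]: the cohort source, kinetic settings,
#' statistics settings, and the master seed that every stochastic stage
#' derives from.
#'
#' @param cohort_spec a [cohort_spec()] (simulated mode), or `NULL` when
#'   `estimates` are supplied directly.
#' @param estimates optional precomputed per-subject estimate table (as
#'   returned by [fit_cohort()]) for ingest mode.
#' @param t_star,theta3,weights,refine kinetic settings (see [fit_cohort()]).
#' @param n_boot bootstrap resamples for correlation CIs (default 1000).
#' @param alpha significance level (default 0.05).
#' @param bonferroni_m comparisons for the subregion Bonferroni family
#'   (default 3, the three striatal subregions).
#' @param seed master seed (propagated to bootstrap stages; the cohort keeps
#'   the seed of its own spec).
#' @return A `study_config` list.
#' @export
study_config <- function(cohort_spec = NULL, estimates = NULL, t_star = 25,
                         theta3 = theta3_grid(), weights = NULL,
                         refine = TRUE, n_boot = 1000, alpha = 0.05,
                         bonferroni_m = 3, seed = 1L) {
  if (is.null(cohort_spec) && is.null(estimates)) {
    stop("supply a cohort_spec or an estimates table")
  }
  structure(
    list(cohort_spec = cohort_spec, estimates = estimates, t_star = t_star,
         theta3 = theta3, weights = weights, refine = refine,
         n_boot = n_boot, alpha = alpha, bonferroni_m = bonferroni_m,
         seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Run the full multi-tracer study pipeline
#'
#' Simulates (or ingests) a cohort, performs all per-subject kinetic fits,
#' and produces the two study-style reports: per-ROI mean +/- SD of `Ki`,
#' placebo and post-drug `BPnd`, and percent change ("table 1"), and the
#' per-ROI cross-measure correlations with bootstrap CIs and Bonferroni
#' survival flags ("table 2"), plus per-ROI multiple regressions of post-drug
#' `BPnd` on `Ki`, baseline `BPnd` and region volume. Normality of each
#' measure is gated by Shapiro-Wilk; a non-normal member demotes the pair to
#' Spearman. The release-vs-Ki correlation is corrected for body weight
#' (partial correlation). Region volume is omitted from the whole-striatum
#' regression (that ROI is a fixed group-level mask), and the whole-striatum
#' correlations are not Bonferroni-corrected (primary analysis); subregion
#' rows use the `bonferroni_m`-comparison family.
#'
#' Every stochastic stage (cohort draw, bootstrap) is seeded, so a fixed
#' config yields byte-identical reports.
#'
#' @param config a [study_config()].
#' @return A `study_result`: `table1`, `table2`, `regressions`, `estimates`,
#'   `logs`, `config`.
#' @examples
#' \donttest{
#' cfg <- study_config(cohort_spec(n_subjects = 8, seed = 3), n_boot = 200)
#' res <- run_study(cfg)
#' res$table1
#' }
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  logs <- character(0)
  say <- function(fmt, ...) {
    logs <<- c(logs, sprintf(fmt, ...))
  }
  est <- config$estimates
  if (is.null(est)) {
    say("stage simulate: n = %d, seed = %d",
        config$cohort_spec$n_subjects, config$cohort_spec$seed)
    cohort <- tryCatch(simulate_cohort(config$cohort_spec),
                       error = function(e) stop("stage simulate: ",
                                                conditionMessage(e)))
    say("stage fit: Patlak t* = %g min, SRTM grid of %d", config$t_star,
        length(config$theta3))
    est <- tryCatch(
      fit_cohort(cohort, config$t_star, config$theta3, config$weights,
                 config$refine),
      error = function(e) stop("stage fit: ", conditionMessage(e))
    )
  } else {
    say("stage ingest: %d estimate rows", nrow(est))
  }

  rois <- unique(est$roi)
  table1 <- do.call(rbind, lapply(rois, function(r) {
    d <- est[est$roi == r, ]
    data.frame(
      roi = r, n = nrow(d),
      ki_mean = mean(d$ki), ki_sd = stats::sd(d$ki),
      bp_placebo_mean = mean(d$bp_placebo),
      bp_placebo_sd = stats::sd(d$bp_placebo),
      bp_drug_mean = mean(d$bp_drug), bp_drug_sd = stats::sd(d$bp_drug),
      release_pct_mean = mean(d$release_pct),
      release_pct_sd = stats::sd(d$release_pct)
    )
  }))
  say("stage table1: %d ROIs", nrow(table1))

  gate <- function(x) shapiro_gate(x, config$alpha)$verdict
  table2 <- do.call(rbind, lapply(seq_along(rois), function(i) {
    r <- rois[i]
    d <- est[est$roi == r, ]
    seed_r <- config$seed + 1000L * i
    meth1 <- if (gate(d$ki) == "normal" &&
                 gate(d$bp_placebo) == "normal") "pearson" else "spearman"
    c1 <- correlate(d$ki, d$bp_placebo, meth1, config$n_boot, seed_r)
    meth2 <- if (gate(d$bp_placebo) == "normal" &&
                 gate(d$bp_drug) == "normal") "pearson" else "spearman"
    c2 <- correlate(d$bp_placebo, d$bp_drug, meth2, config$n_boot,
                    seed_r + 1L)
    meth3 <- if (gate(d$ki) == "normal" &&
                 gate(d$release_pct) == "normal") "pearson" else "spearman"
    c3 <- partial_correlate(d$ki, d$release_pct, d$weight, meth3,
                            config$n_boot, seed_r + 2L)
    m <- if (r == "whole_striatum") 1 else config$bonferroni_m
    row <- function(cmp, res) {
      data.frame(roi = r, comparison = cmp, method = res$method, r = res$r,
                 ci_low = res$ci_low, ci_high = res$ci_high, p = res$p,
                 n = res$n,
                 bonferroni = bonferroni_flags(res$p, m, config$alpha))
    }
    rbind(row("ki_vs_bp_placebo", c1),
          row("bp_placebo_vs_bp_drug", c2),
          row("ki_vs_release", c3))
  }))
  say("stage table2: %d correlations, n_boot = %d", nrow(table2),
      config$n_boot)

  regressions <- lapply(rois, function(r) {
    d <- est[est$roi == r, ]
    X <- d[, c("ki", "bp_placebo")]
    if (r != "whole_striatum") X$volume <- d$volume_mm3
    ols_regression(d$bp_drug, X)
  })
  names(regressions) <- rois
  say("stage regression: %d models", length(regressions))

  structure(
    list(table1 = table1, table2 = table2, regressions = regressions,
         estimates = est, logs = logs, config = config),
    class = "study_result"
  )
}

#' @export
print.study_result <- function(x, digits = 3, ...) {
  cat("Multi-tracer study result\n\n")
  cat("Per-ROI signal (mean +/- SD):\n")
  t1 <- x$table1
  for (i in seq_len(nrow(t1))) {
    cat(sprintf(
      "  %-17s Ki %.4f+/-%.4f  BP %.2f+/-%.2f -> %.2f+/-%.2f  release %.2f+/-%.2f %%\n",
      t1$roi[i], t1$ki_mean[i], t1$ki_sd[i], t1$bp_placebo_mean[i],
      t1$bp_placebo_sd[i], t1$bp_drug_mean[i], t1$bp_drug_sd[i],
      t1$release_pct_mean[i], t1$release_pct_sd[i]))
  }
  cat("\nCorrelations:\n")
  t2 <- x$table2
  for (i in seq_len(nrow(t2))) {
    cat(sprintf("  %-17s %-22s %-16s r = %+.2f (%+.2f, %+.2f), p = %.3g%s\n",
                t2$roi[i], t2$comparison[i], t2$method[i], t2$r[i],
                t2$ci_low[i], t2$ci_high[i], t2$p[i],
                if (isTRUE(t2$bonferroni[i])) " *" else ""))
  }
  invisible(x)
}

#' Write study reports to CSV
#'
#' @param result a `study_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_csv <- function(result, dir) {
  stopifnot(inherits(result, "study_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$table1, file.path(dir, "table1.csv"),
                   row.names = FALSE)
  utils::write.csv(result$table2, file.path(dir, "table2.csv"),
                   row.names = FALSE)
  utils::write.csv(result$estimates, file.path(dir, "estimates.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Reference-region stability sanity check
#'
#' Verifies that the chosen reference region is not itself displaced by the
#' drug: the cerebellar region is treated as a *target* and quantified with
#' SRTM against an alternate (occipital) reference on both raclopride scans,
#' and the paired t-test of scan-1 vs scan-2 `BPnd` (with Cohen's dz) is
#' reported. A significant change would invalidate the cerebellar reference.
#' Requires a cohort simulated with `reference_check = TRUE`.
#'
#' @param cohort a `pet_cohort` with reference-check TACs.
#' @param theta3 SRTM grid (the cerebellar residual binding is small, so the
#'   default grid is fine).
#' @return List: `test` (a [paired_ttest()] result), `bp_scan1`, `bp_scan2`.
#' @export
sanity_check_reference <- function(cohort, theta3 = theta3_grid()) {
  stopifnot(inherits(cohort, "pet_cohort"))
  if (is.null(cohort$subjects[[1]]$refcheck)) {
    stop("cohort lacks alternate-reference data; ",
         "simulate with reference_check = TRUE")
  }
  bp <- vapply(cohort$subjects, function(subj) {
    rc <- subj$refcheck
    c(srtm_fit(rc$cb1, rc$occ1, theta3)$BPnd,
      srtm_fit(rc$cb2, rc$occ2, theta3)$BPnd)
  }, numeric(2))
  d <- bp[1, ] - bp[2, ]
  test <- if (all(d == 0)) {
    # scans identical (e.g. a noiseless cohort with no reference change):
    # report the degenerate no-change result rather than a 0/0 statistic
    structure(list(t = 0, df = length(d) - 1L, p = 1, dz = 0,
                   mean_diff = 0, n = length(d)),
              class = "paired_ttest")
  } else {
    paired_ttest(bp[1, ], bp[2, ])
  }
  list(test = test, bp_scan1 = bp[1, ], bp_scan2 = bp[2, ])
}
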