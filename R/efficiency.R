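#' Detection-rate (power) curves
#'
#' Extracts one analysis's detection-rate curve — mean flagged fraction
#' versus patients per hospital under scenario A — from an aggregated or
#' per-replicate detection summary. Raw Monte-Carlo curves can dip
#' non-monotonically at modest replicate counts, so consumers smooth them
#' with isotonic regression before interpolating.
#'
#' @param summary a `detection_summary` or the output of
#'   [aggregate_detection()].
#' @param analysis analysis label.
#' @param scenario scenario to extract (default `"A"`).
#' @return Object of class `power_curve`: `data.frame` with columns `n`,
#'   `power`, `mc_se`.
#' @export
power_curve <- function(summary, analysis, scenario = "A") {
  agg <- if ("frac_flagged" %in% names(summary)) summary
         else aggregate_detection(summary)
  sel <- agg$scenario == scenario & agg$analysis == analysis
  if (!any(sel))
    stop(sprintf("no scenario-%s cells for analysis '%s'", scenario,
                 analysis))
  out <- data.frame(n = agg$n_per_hospital[sel],
                    power = agg$frac_flagged[sel], mc_se = agg$mc_se[sel])
  out <- out[order(out$n), ]
  rownames(out) <- NULL
  if (any(out$power < 0 | out$power > 1)) stop("fractions must lie in [0, 1]")
  structure(out, class = c("power_curve", "data.frame"),
            analysis = analysis)
}

# isotonic (non-decreasing) smoothing of a power curve
.iso_power <- function(curve) {
  stats::isoreg(curve$n, curve$power)$yf
}

#' Patients per hospital required to reach a target detection rate
#'
#' Smooths the curve with isotonic regression, then finds the smallest `n`
#' at which the smoothed curve reaches `target` by monotone piecewise-linear
#' interpolation. Exact at grid points of a monotone curve. Returns `NA`
#' (undefined) when the target exceeds the curve's maximum; targets at or
#' below the smallest achieved power return the smallest evaluated `n`.
#'
#' @param curve a [power_curve()].
#' @param target detection fraction in \[0, 1\].
#' @return Required patients per hospital (possibly fractional), or `NA`.
#' @export
required_n <- function(curve, target) {
  stopifnot(inherits(curve, "power_curve"), nrow(curve) >= 1L)
  if (!is.numeric(target) || length(target) != 1L || is.na(target) ||
      target < 0 || target > 1)
    stop("'target' must be a single fraction in [0, 1]")
  yf <- .iso_power(curve)
  n <- curve$n
  if (target > max(yf)) return(NA_real_)
  if (target <= yf[1L]) return(as.numeric(n[1L]))
  j <- which(yf >= target)[1L]                 # first point at/above target
  i <- max(which(yf[seq_len(j - 1L)] < target))  # last point strictly below
  as.numeric(n[i] + (target - yf[i]) / (yf[j] - yf[i]) * (n[j] - n[i]))
}

#' Equal-power sample-size reduction
#'
#' The fraction by which the comparator analysis's required sample size
#' undercuts the reference analysis's at the same detection power:
#' `1 - n_comp / n_ref`. Positive when the comparator needs fewer patients.
#'
#' @param n_comp,n_ref required patients per hospital for the comparator
#'   and reference analyses; both positive.
#' @return Reduction fraction (at most 1; negative if the comparator needs
#'   more patients).
#' @export
efficiency_gain <- function(n_comp, n_ref) {
  if (!is.numeric(n_comp) || !is.numeric(n_ref) ||
      any(!is.finite(c(n_comp, n_ref))) || any(c(n_comp, n_ref) <= 0))
    stop("'n_comp' and 'n_ref' must be positive numbers")
  1 - n_comp / n_ref
}

#' Equal-power efficiency summary
#'
#' Converts scenario-A detection-rate curves into equal-power sample-size
#' reductions of the ordinal analysis relative to each dichotomized
#' analysis. For every target power (by default, the reference curve's
#' smoothed detection rate at each of its grid points) the required
#' patients-per-hospital is interpolated on both curves and the reduction
#' `1 - n_ordinal / n_reference` recorded; the headline figure is the
#' maximum reduction over targets. Comparisons whose target is unreachable
#' on either curve are reported as undefined and excluded from the maximum.
#'
#' @param summary a `detection_summary` (or aggregated summary) containing
#'   scenario-A cells for the analyses involved.
#' @param targets optional vector of target detection fractions; default
#'   described above.
#' @param references reference (dichotomized) analyses to compare against.
#' @param comparator comparator analysis (default `"ordinal"`).
#' @return Object of class `efficiency_result`: list with `comparisons`
#'   (data.frame: reference, target, n_ref, n_comp, reduction) and
#'   `max_reduction` (named by reference analysis).
#' @export
summarize_efficiency <- function(summary, targets = NULL,
                                 references = c("favorable", "mortality"),
                                 comparator = "ordinal") {
  curves <- lapply(stats::setNames(nm = c(comparator, references)),
                   function(a) power_curve(summary, a))
  comp_curve <- curves[[comparator]]
  rows <- list()
  for (ref in references) {
    ref_curve <- curves[[ref]]
    tgt <- if (is.null(targets)) unique(.iso_power(ref_curve))
           else targets
    tgt <- tgt[tgt > 0 & tgt <= 1]
    for (t in tgt) {
      n_ref <- required_n(ref_curve, t)
      n_comp <- required_n(comp_curve, t)
      rows[[length(rows) + 1L]] <- data.frame(
        reference = ref, comparator = comparator, target = t,
        n_ref = n_ref, n_comp = n_comp,
        reduction = if (is.na(n_ref) || is.na(n_comp)) NA_real_
                    else efficiency_gain(n_comp, n_ref),
        stringsAsFactors = FALSE)
    }
  }
  comparisons <- do.call(rbind, rows)
  max_red <- vapply(references, function(ref) {
    r <- comparisons$reduction[comparisons$reference == ref]
    if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)
  }, numeric(1))
  structure(list(comparisons = comparisons,
                 max_reduction = max_red, comparator = comparator),
            class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("Equal-power sample-size reductions (%s vs dichotomized):\n",
              x$comparator))
  for (ref in names(x$max_reduction)) {
    v <- x$max_reduction[[ref]]
    cat(sprintf("  vs %-10s max reduction %s\n", paste0(ref, ":"),
                if (is.na(v)) "undefined"
                else sprintf("%.1f%%", 100 * v)))
  }
  invisible(x)
}

#' Plot detection-rate curves
#'
#' Base-graphics plot of scenario-A detection rate versus patients per
#' hospital, one line per analysis.
#'
#' @param x a `detection_summary`.
#' @param scenario scenario to plot.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.detection_summary <- function(x, scenario = "A", ...) {
  agg <- aggregate_detection(x)
  agg <- agg[agg$scenario == scenario, ]
  analyses <- unique(agg$analysis)
  ns <- sort(unique(agg$n_per_hospital))
  m <- sapply(analyses, function(a)
    agg$frac_flagged[agg$analysis == a][order(agg$n_per_hospital[agg$analysis == a])])
  graphics::matplot(ns, m, type = "b", pch = 19, lty = 1,
                    xlab = "patients per hospital",
                    ylab = "fraction of hospitals flagged",
                    main = sprintf("Outlier detection rate (scenario %s)",
                                   scenario), ...)
  graphics::legend("topleft", legend = analyses, col = seq_along(analyses),
                   lty = 1, pch = 19, bty = "n")
  invisible(x)
}
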