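# Alignment-frame RMSD observables, distribution summaries, and the
# contact-area vs RMSD correlation. The protocol mirrors standard MD
# practice: superpose each frame on a reference frame using the C-alpha
# atoms of one domain, then measure the unfitted RMSD of another domain
# against its reference position. Which atoms are "C-alpha" is entirely
# encoded in the selection strings, so coarse-grained bead systems work
# unchanged.

#' Construct a MetricSeries
#'
#' A `(time, value)` observable stream with a label and units. Times must be
#' strictly increasing and of the same length as the values.
#'
#' @param times numeric times (ns).
#' @param values numeric observable values.
#' @param label text label.
#' @param units text units.
#' @return object of class `MetricSeries`.
#' @export
metric_series <- function(times, values, label = "metric", units = "") {
  if (length(times) != length(values)) {
    stop("times and values must have equal length")
  }
  if (length(times) == 0L) stop("empty metric series")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 label = label, units = units),
            class = "MetricSeries")
}

#' @export
print.MetricSeries <- function(x, ...) {
  cat(sprintf("MetricSeries '%s' [%s]: %d points, t = %.4g .. %.4g ns\n",
              x$label, x$units, length(x$values), x$times[1],
              x$times[length(x$times)]))
  invisible(x)
}

#' Convert a MetricSeries to a data.frame
#' @param x a `MetricSeries`.
#' @param ... unused.
#' @return data.frame with columns `time`, `value`.
#' @export
as.data.frame.MetricSeries <- function(x, ...) {
  data.frame(time = x$times, value = x$values)
}

#' Define an RMSD observable preset
#'
#' The four canonical observables for a membrane-anchored GTPase/plexin
#' system, each an align-then-measure pair of selections:
#' \describe{
#'   \item{gtpase_vs_gap}{align on the GAP domain, measure the GTPase
#'     catalytic domain (GTPase position relative to the plexin).}
#'   \item{gtpase_vs_rbd}{align on the RBD, measure the GTPase.}
#'   \item{rbd_vs_gap}{align on the GAP domain, measure the RBD.}
#'   \item{dimer_helices}{align and measure the two dimerization helices
#'     (the Kabsch-minimal RMSD of the helix pair, a dimer-interface
#'     stability gauge).}
#' }
#' `custom` leaves both selections free.
#'
#' @param name one of `gtpase_vs_gap`, `gtpase_vs_rbd`, `rbd_vs_gap`,
#'   `dimer_helices`, `custom`.
#' @param align_sel selection text for the alignment atoms.
#' @param measure_sel selection text for the measured atoms; for
#'   `dimer_helices` it defaults to `align_sel`.
#' @return object of class `RmsdPreset`.
#' @export
rmsd_preset <- function(name = c("custom", "gtpase_vs_gap", "gtpase_vs_rbd",
                                 "rbd_vs_gap", "dimer_helices"),
                        align_sel, measure_sel = NULL) {
  name <- match.arg(name)
  if (name == "dimer_helices" && is.null(measure_sel)) measure_sel <- align_sel
  if (is.null(measure_sel)) stop("measure_sel is required")
  structure(list(name = name, align_sel = align_sel,
                 measure_sel = measure_sel),
            class = "RmsdPreset")
}

#' Alignment-frame RMSD time series
#'
#' For each frame: superpose the frame onto the reference frame by a Kabsch
#' fit over the alignment selection, then compute the unfitted RMSD of the
#' measured selection against its reference position. When the alignment
#' and measured selections coincide (the `dimer_helices` preset) the value
#' is the Kabsch-minimal RMSD of that atom set.
#'
#' @param traj a `Trajectory`.
#' @param preset an `RmsdPreset`, or anything accepted by `align_sel` (in
#'   which case `measure_sel` must be given).
#' @param measure_sel measured selection when `preset` is a raw selection.
#' @param reference reference frame index (default 1: initial positions).
#' @return a `MetricSeries` in Angstrom.
#' @export
rmsd_series <- function(traj, preset, measure_sel = NULL, reference = 1L) {
  s <- traj$topology
  if (inherits(preset, "RmsdPreset")) {
    align <- resolve_selection(preset$align_sel, s)
    measure <- resolve_selection(preset$measure_sel, s)
    label <- paste0("rmsd_", preset$name)
  } else {
    if (is.null(measure_sel)) stop("measure_sel is required")
    align <- resolve_selection(preset, s)
    measure <- resolve_selection(measure_sel, s)
    label <- "rmsd_custom"
  }
  if (length(align$indices) < 3L) {
    stop("degenerate alignment selection: fewer than 3 atoms")
  }
  if (length(measure$indices) == 0L) stop("measured selection is empty")
  nf <- n_frames(traj)
  if (reference < 1L || reference > nf) stop("reference frame out of range")
  ref <- traj$frames[[reference]]
  vals <- vapply(traj$frames, function(fr) {
    fitted <- superpose_frame(fr, align, ref)
    rmsd(fitted[measure$indices, , drop = FALSE],
         ref[measure$indices, , drop = FALSE])
  }, numeric(1))
  metric_series(traj$times, vals, label = label, units = "A")
}

#' Summarize a metric series distribution
#'
#' Mean and population standard deviation (the "spread" reported next to
#' trajectory observable distributions; not the n-1 sample estimator) of
#' the values retained after burn-in, with a fixed-width histogram over
#' `[min, max]`.
#'
#' @param series a `MetricSeries`.
#' @param burn_in_fraction fraction of initial frames discarded.
#' @param n_bins histogram bin count.
#' @return object of class `DistributionSummary`: list with `mean`,
#'   `spread`, `n`, `breaks`, `counts` (counts sum to `n`), `label`,
#'   `units`.
#' @export
summarize_series <- function(series, burn_in_fraction = 0, n_bins = 50) {
  stopifnot(inherits(series, "MetricSeries"))
  from <- burn_in_start(length(series$values), burn_in_fraction)
  v <- series$values[from:length(series$values)]
  if (length(v) == 0L) stop("series empty after burn-in")
  rng <- range(v)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  structure(list(mean = mean(v), spread = sqrt(mean((v - mean(v))^2)),
                 n = length(v), breaks = breaks, counts = counts,
                 label = series$label, units = series$units),
            class = "DistributionSummary")
}

#' @export
print.DistributionSummary <- function(x, ...) {
  cat(sprintf("DistributionSummary '%s': mean %.4g, spread %.4g %s (n = %d)\n",
              x$label, x$mean, x$spread, x$units, x$n))
  invisible(x)
}

#' Correlate two metric series frame-by-frame
#'
#' Pearson and Spearman correlation over paired values. The two series must
#' share their time axes exactly; no interpolation is performed (both
#' series are expected to derive from the same frames). If either series
#' has zero variance the correlations are undefined and reported as `NA`.
#' Spearman uses average ranks for ties.
#'
#' @param a,b `MetricSeries` objects over identical times.
#' @return list with `pearson_r`, `spearman_rho`, `n`, and `pairs` (the
#'   paired scatter table, a data.frame `time`/`a`/`b`).
#' @export
correlate_series <- function(a, b) {
  stopifnot(inherits(a, "MetricSeries"), inherits(b, "MetricSeries"))
  if (length(a$times) != length(b$times) ||
      any(abs(a$times - b$times) > 0)) {
    stop("time mismatch: series must share times exactly (resample explicitly)")
  }
  n <- length(a$values)
  zero_var <- stats::var(a$values) == 0 || stats::var(b$values) == 0
  pearson <- if (zero_var) NA_real_ else
    stats::cor(a$values, b$values, method = "pearson")
  spearman <- if (zero_var) NA_real_ else
    stats::cor(a$values, b$values, method = "spearman")
  list(pearson_r = pearson, spearman_rho = spearman, n = n,
       pairs = data.frame(time = a$times, a = a$values, b = b$values))
}

#' Export a MetricSeries as TSV
#' @param series a `MetricSeries`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_series <- function(series, path) {
  write_table(as.data.frame(series), path)
}
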