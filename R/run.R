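# Pipeline orchestration: one configuration drives simulate -> metrics ->
# tables with fail-fast selection resolution, plus the paired-system
# contrast used to compare a charged-patch/short-tail (RhoD-like) against a
# neutral/long-tail (RND1-like) tether system.

config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "")
  h <- 17
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Standard observable bundle for a synthetic tether trajectory
#'
#' Computes the package's membrane observables on a [simulate_tether()]
#' trajectory: membrane contact-area series, contact-residue count series,
#' anionic-lipid enrichment, the positional RMSD of the domain in the
#' membrane (lab) frame, their burn-in summaries, and the contact-area vs
#' RMSD Pearson correlation.
#'
#' @param traj a `Trajectory` from [simulate_tether()].
#' @param burn_in_fraction initial fraction discarded for the summary
#'   statistics.
#' @param cutoff lipid-contact cutoff, Angstrom.
#' @param probe SASA probe radius, Angstrom.
#' @param n_points SASA quadrature points per atom.
#' @param anionic residue names of the anionic lipid class.
#' @return list with the series objects (`area`, `count`, `enrichment`,
#'   `rmsd`), the summaries, the correlation, and `row`, a one-row
#'   data.frame of scalar run statistics (`mean_area`, `mean_count`,
#'   `mean_enrichment`, `rmsd_spread`, `pearson_r`).
#' @export
tether_metrics <- function(traj, burn_in_fraction = 0.3, cutoff = 5,
                           probe = 1.4, n_points = 960,
                           anionic = c("POPS", "PIP2")) {
  sys <- attr(traj, "system")
  if (is.null(sys)) stop("trajectory carries no synthetic system attribute")
  rt <- synth_radius_table(sys$config)
  protein <- "chain A"
  lipids <- "resname POPC POPS PIP2"
  area <- membrane_contact_area_series(traj, protein, lipids, probe = probe,
                                       n_points = n_points, radius_table = rt)
  cnt <- contact_residue_count_series(traj, protein, lipids, cutoff = cutoff)
  enr <- lipid_enrichment(traj, protein, lipids, lipid_type = anionic,
                          cutoff = cutoff)
  pos <- rmsd_series(traj, "chain M", measure_sel = protein)
  area_sum <- summarize_series(area, burn_in_fraction = burn_in_fraction)
  cnt_sum <- summarize_series(cnt, burn_in_fraction = burn_in_fraction)
  pos_sum <- summarize_series(pos, burn_in_fraction = burn_in_fraction)
  corr <- correlate_series(area, pos)
  from <- burn_in_start(nrow(enr), burn_in_fraction)
  enr_mean <- mean(enr$enrichment[from:nrow(enr)], na.rm = TRUE)
  list(area = area, count = cnt, enrichment = enr, rmsd = pos,
       area_summary = area_sum, count_summary = cnt_sum,
       rmsd_summary = pos_sum, correlation = corr,
       row = data.frame(mean_area = area_sum$mean,
                        mean_count = cnt_sum$mean,
                        mean_enrichment = enr_mean,
                        rmsd_spread = pos_sum$spread,
                        pearson_r = corr$pearson_r))
}

#' Contrast charged-patch/short-tail vs neutral/long-tail tether systems
#'
#' Runs [simulate_tether()] for the RhoD-like and RND1-like presets over
#' `n_seeds` independent seeds each, computes [tether_metrics()] per run,
#' and tests the mechanistic directions with one-sided Mann-Whitney
#' (Wilcoxon rank-sum) tests: the charged system is expected to show
#' greater mean membrane contact area, greater contact-residue count,
#' larger positional-RMSD spread and a stronger contact-area/RMSD Pearson
#' correlation, and its anionic-lipid enrichment ratio is expected to
#' exceed 1.
#'
#' @param n_seeds independent seeds per system (>= 5 for the standard
#'   contrast).
#' @param n_sweeps Monte Carlo sweeps per run.
#' @param base_seed base of the per-run seed sequence.
#' @param n_points SASA quadrature points per atom (reduce for speed).
#' @param ... further overrides forwarded to both presets.
#' @return list with `runs` (per-run statistics, one row per run) and
#'   `p_values` (named one-sided Mann-Whitney p-values `area`, `count`,
#'   `spread`, `correlation`, plus `enrichment_t_p`, a one-sided t-test
#'   p-value that the charged system's enrichment exceeds 1).
#' @export
compare_tether_systems <- function(n_seeds = 5, n_sweeps = 2000,
                                   base_seed = 1, n_points = 480, ...) {
  rows <- list()
  for (i in seq_len(n_seeds)) {
    seed_i <- (base_seed * 1000L + i) %% 2147483000L
    for (sysname in c("charged_short", "neutral_long")) {
      cfg <- if (sysname == "charged_short") {
        rhod_like_config(seed = seed_i, n_sweeps = n_sweeps, ...)
      } else {
        rnd1_like_config(seed = seed_i, n_sweeps = n_sweeps, ...)
      }
      tm <- tether_metrics(simulate_tether(cfg), n_points = n_points)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(system = sysname, seed = seed_i), tm$row)
    }
  }
  runs <- do.call(rbind, rows)
  a <- runs[runs$system == "charged_short", ]
  b <- runs[runs$system == "neutral_long", ]
  one_sided <- function(x, y) {
    # ties (e.g. identical counts) force the normal approximation; the
    # warning is expected and harmless at these sample sizes
    suppressWarnings(
      stats::wilcox.test(x, y, alternative = "greater")$p.value)
  }
  enr <- a$mean_enrichment[is.finite(a$mean_enrichment)]
  enr_p <- if (length(enr) >= 2 && stats::sd(enr) > 0) {
    stats::t.test(enr, mu = 1, alternative = "greater")$p.value
  } else {
    NA_real_
  }
  list(runs = runs,
       p_values = c(area = one_sided(a$mean_area, b$mean_area),
                    count = one_sided(a$mean_count, b$mean_count),
                    spread = one_sided(a$rmsd_spread, b$rmsd_spread),
                    correlation = one_sided(a$pearson_r, b$pearson_r),
                    enrichment_t_p = enr_p))
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  config
}

#' Run the metric pipeline from one configuration
#'
#' The configuration (an R list or a JSON file) provides either input files
#' (`topology`, `trajectory` paths) or a `synthetic` block of
#' [synth_config()] overrides; `selections` with at least `protein` and
#' `lipid` selection strings plus optional named RMSD `presets`
#' (`list(align = ..., measure = ...)`); and optional `burn_in_fraction`,
#' `cutoff`, `probe`, `n_points`, `lipid_type`, `metrics` (enabled subset
#' of `area`, `count`, `profile`, `map`, `enrichment`, `rmsd`). Every
#' enabled selection is resolved against the topology before any
#' computation starts (fail fast); outputs are plain TSV plus a JSON
#' manifest recording the package version, a configuration hash, the seed
#' and the completed outputs.
#'
#' @param config configuration list or JSON path.
#' @param outdir output directory, created if needed.
#' @return invisibly, the manifest list.
#' @export
run_metrics <- function(config, outdir = config$outdir) {
  config <- read_run_config(config)
  if (is.null(outdir)) stop("config error: no output directory")
  enabled <- config$metrics
  if (is.null(enabled)) {
    enabled <- c("area", "count", "profile", "map", "enrichment", "rmsd")
  }
  burn <- config$burn_in_fraction %||% 0.3
  cutoff <- config$cutoff %||% 5
  probe <- config$probe %||% 1.4
  n_points <- config$n_points %||% 960
  lipid_type <- config$lipid_type %||% c("POPS", "PIP2")

  radius_table <- bondi_radii()
  if (!is.null(config$synthetic)) {
    scfg <- do.call(synth_config, as.list(config$synthetic))
    traj <- simulate_tether(scfg)
    radius_table <- synth_radius_table(scfg)
    seed <- scfg$seed
  } else {
    if (is.null(config$topology) || is.null(config$trajectory)) {
      stop("config error: need topology and trajectory paths, or a synthetic block")
    }
    topo <- read_structure(config$topology)
    traj <- read_trajectory(config$trajectory, topo,
                            stride = config$stride %||% 1)
    seed <- config$seed %||% NA_integer_
  }

  sels <- config$selections
  if (is.null(sels$protein) || is.null(sels$lipid)) {
    stop("config error: selections must name 'protein' and 'lipid'")
  }
  # fail fast: resolve every enabled selection before computing anything
  s <- traj$topology
  protein <- parse_selection(sels$protein, s)
  lipid <- parse_selection(sels$lipid, s)
  presets <- list()
  if ("rmsd" %in% enabled) {
    for (nm in names(sels$presets)) {
      p <- sels$presets[[nm]]
      presets[[nm]] <- list(align = parse_selection(p$align, s),
                            measure = parse_selection(p$measure, s))
    }
  }

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    outputs <<- c(outputs, name)
  }

  summaries <- list()
  series <- list()
  if ("area" %in% enabled) {
    area <- membrane_contact_area_series(traj, protein, lipid, probe = probe,
                                         n_points = n_points,
                                         radius_table = radius_table)
    series$area <- area
    summaries$area <- summarize_series(area, burn_in_fraction = burn)
    emit("contact_area_series.tsv", function(p) write_series(area, p))
  }
  if ("count" %in% enabled) {
    cnt <- contact_residue_count_series(traj, protein, lipid, cutoff = cutoff)
    series$count <- cnt
    summaries$count <- summarize_series(cnt, burn_in_fraction = burn)
    emit("contact_residue_count.tsv", function(p) write_series(cnt, p))
  }
  if ("profile" %in% enabled) {
    prof <- residue_lipid_contacts(traj, protein, lipid, cutoff = cutoff,
                                   burn_in_fraction = burn)
    emit("residue_contact_profile.tsv",
         function(p) write_table(as.data.frame(prof), p))
  }
  if ("map" %in% enabled) {
    cm <- contact_map(traj, protein, lipid, cutoff = cutoff)
    emit("contact_map.tsv", function(p) write_contact_map(cm, p))
  }
  if ("enrichment" %in% enabled) {
    enr <- lipid_enrichment(traj, protein, lipid, lipid_type = lipid_type,
                            cutoff = cutoff)
    emit("enrichment.tsv", function(p) write_table(as.data.frame(enr), p))
  }
  for (nm in names(presets)) {
    rs <- rmsd_series(traj, presets[[nm]]$align,
                      measure_sel = presets[[nm]]$measure)
    series[[paste0("rmsd_", nm)]] <- rs
    summaries[[paste0("rmsd_", nm)]] <-
      summarize_series(rs, burn_in_fraction = burn)
    emit(paste0("rmsd_", nm, ".tsv"), function(p) write_series(rs, p))
  }
  if (length(summaries) > 0L) {
    stab <- do.call(rbind, lapply(names(summaries), function(nm) {
      su <- summaries[[nm]]
      data.frame(label = nm, mean = su$mean, spread = su$spread, n = su$n)
    }))
    emit("summaries.tsv", function(p) write_table(stab, p))
  }
  if (!is.null(series$area) && length(series) > 1L) {
    rmsd_names <- grep("^rmsd_", names(series), value = TRUE)
    if (length(rmsd_names) > 0L) {
      co <- correlate_series(series$area, series[[rmsd_names[1]]])
      emit("correlation.tsv", function(p) {
        write_table(data.frame(a = "area", b = rmsd_names[1],
                               pearson_r = co$pearson_r,
                               spearman_rho = co$spearman_rho, n = co$n), p)
      })
      emit("scatter.tsv", function(p) write_table(co$pairs, p))
    }
  }

  manifest <- list(package = "memtether",
                   version = as.character(utils::packageVersion("memtether")),
                   config_hash = config_hash(config),
                   seed = seed,
                   n_frames = n_frames(traj),
                   burn_in_fraction = burn,
                   outputs = outputs,
                   complete = TRUE)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Run the sequence charge census from a configuration
#'
#' Thin orchestration over [read_alignment()] and [census_table()]; the
#' interface window and exclusion list are configuration, not code.
#'
#' @param alignment path to the aligned FASTA/Clustal file.
#' @param ref_id reference sequence id for window numbering.
#' @param ranges list of inclusive residue-number ranges (reference
#'   ungapped numbering), e.g. `list(c(130, 146))`.
#' @param ref_catalytic_end catalytic-domain end residue of the reference.
#' @param tail_threshold long/short tail boundary (orchestration default 8
#'   residues; the library itself has none).
#' @param exclude sequence ids dropped from the census.
#' @param out optional TSV output path.
#' @return the census data.frame, invisibly when `out` is given.
#' @export
run_census <- function(alignment, ref_id, ranges, ref_catalytic_end,
                       tail_threshold = 8,
                       exclude = c("RHBT1", "RHBT2", "RHBT3"),
                       out = NULL) {
  msa <- read_alignment(alignment)
  win <- interface_window(ref_id, ranges)
  tab <- census_table(msa, win, ref_catalytic_end, tail_threshold,
                      exclude = exclude)
  if (!is.null(out)) {
    write_table(tab, out)
    return(invisible(tab))
  }
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
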