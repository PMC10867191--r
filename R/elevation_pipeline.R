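## End-to-end analysis across elevational zones: zone assignment, per-zone
## signal summaries, PGLS model fitting/selection and phylogenetic-signal
## tests, mirroring the tabular outputs of a community-level flower-signal
## study.

zone_levels <- c("Foothills", "Submontane", "Montane",
                 "Upper-montane", "Alpine")
zone_edges <- c(0, 500, 1500, 2500, 3000, Inf)

#' Assign elevational zones
#'
#' Five vegetation zones by mean elevation (m a.s.l.), half-open bins:
#' Foothills [0, 500), Submontane [500, 1500), Montane [1500, 2500),
#' Upper-montane [2500, 3000), Alpine [3000, Inf).  The 3000 m boundary
#' goes to Alpine so that every elevation has exactly one zone.
#'
#' @param elev_mean numeric vector of mean elevations in m a.s.l.
#' @return factor with levels Foothills, Submontane, Montane,
#'   Upper-montane, Alpine.
#' @export
assign_zone <- function(elev_mean) {
  if (any(elev_mean < 0, na.rm = TRUE)) stop("negative elevation")
  cut(elev_mean, breaks = zone_edges, labels = zone_levels, right = FALSE)
}

## kernel-density mode: Gaussian kernel, Silverman bandwidth, argmax on a
## 512-point grid over the data range
kde_mode <- function(x) {
  d <- stats::density(x, bw = "nrd0", n = 512, from = min(x), to = max(x))
  d$x[which.max(d$y)]
}

t_ci <- function(x, level = 0.95) {
  n <- length(x); m <- mean(x)
  if (n < 2 || stats::sd(x) == 0) return(c(m, m))
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * stats::sd(x) / sqrt(n)
  c(m - half, m + half)
}

#' Per-zone summaries of flower signals
#'
#' For each zone, reports n, the most frequently observed value (mode) of
#' green contrast, colour contrast and size — estimated as the peak of a
#' Gaussian kernel density (Silverman bandwidth, 512 grid points) — and
#' the mean with its t-based 95% confidence interval.  Modes need at
#' least 3 species; smaller zones get NA with a warning.  Constant
#' samples return mode = mean = the constant with a zero-width CI.
#'
#' @param records data.frame with columns `zone`, `gc`, `cc`, `size_mm`.
#' @return data.frame, one row per zone present.
#' @export
summarize_zones <- function(records) {
  stopifnot(all(c("zone", "gc", "cc", "size_mm") %in% names(records)))
  zones <- intersect(zone_levels, unique(as.character(records$zone)))
  rows <- lapply(zones, function(z) {
    d <- records[records$zone == z, ]
    n <- nrow(d)
    if (n < 3) warning("zone ", z, ": n < 3, mode omitted")
    one <- function(x) {
      mode <- if (length(unique(x)) == 1) x[1]
      else if (n >= 3) kde_mode(x)
      else NA_real_
      ci <- t_ci(x)
      c(mode = mode, mean = mean(x), lo = ci[1], hi = ci[2])
    }
    g <- one(d$gc); cc <- one(d$cc); s <- one(d$size_mm)
    data.frame(zone = z, n = n,
               mode_gc = g[1], mode_cc = cc[1], mode_size = s[1],
               mean_gc = g[2], gc_lo = g[3], gc_hi = g[4],
               mean_cc = cc[2], cc_lo = cc[3], cc_hi = cc[4],
               mean_size = s[2], size_lo = s[3], size_hi = s[4],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a species trait table
#'
#' CSV keyed by species with flower size (mm) and an elevational range
#' (`elev_min`/`elev_max` in m a.s.l., or a precomputed `elev_mean`).
#' The mean of the range determines the single zone each species belongs
#' to.
#'
#' @param path CSV file.
#' @return data.frame with `species`, `size_mm`, `elev_mean`, `zone`.
#' @export
read_traits <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"species" %in% names(tr)) stop("trait table needs a 'species' column")
  if (!"size_mm" %in% names(tr)) {
    sz <- intersect(c("size", "flower_size", "diameter_mm"), names(tr))
    if (!length(sz)) stop("trait table needs a 'size_mm' column")
    tr$size_mm <- tr[[sz[1]]]
  }
  if (!"elev_mean" %in% names(tr)) {
    if (!all(c("elev_min", "elev_max") %in% names(tr)))
      stop("trait table needs elev_mean or elev_min + elev_max")
    tr$elev_mean <- (tr$elev_min + tr$elev_max) / 2
  }
  if (any(tr$size_mm <= 0, na.rm = TRUE)) stop("non-positive flower size")
  tr$zone <- assign_zone(tr$elev_mean)
  tr
}

fit_zone_models <- function(dat, cov) {
  fits <- list(
    cc_linear = pgls_fit(gc ~ cc, dat, cov),
    cc_quadratic = pgls_fit(gc ~ I(cc^2) + cc, dat, cov),
    cc_log = pgls_fit(gc ~ log(cc), dat, cov))
  sel <- compare_models(fits)
  size_fit <- pgls_fit(gc ~ size_mm, dat, cov)
  list(fits = fits, selection = sel, size_fit = size_fit)
}

tidy_fit <- function(fit, zone, model) {
  co <- fit$coefficients
  data.frame(zone = zone, model = model, term = rownames(co),
             estimate = co$estimate, se = co$se, t = co$t, p = co$p,
             lambda = fit$lambda,
             lambda_lo = fit$lambda_ci[1], lambda_hi = fit$lambda_ci[2],
             loglik = fit$loglik, AIC = fit$AIC, r2_adj = fit$r2_adj,
             n = fit$n, row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the full flower-signal analysis
#'
#' Orchestrates the whole pipeline: read and average reflectance spectra,
#' model them through the bee colour hexagon, join with the trait table,
#' assign elevational zones, prune the phylogeny to each zone's species,
#' fit the PGLS models of green contrast on colour contrast (linear,
#' quadratic, log) plus the linear model on flower size, select the best
#' colour-contrast model by AIC/adjusted R^2, estimate single-trait
#' phylogenetic signal (green contrast, colour contrast, size) per zone,
#' and summarise each zone (modes, means, CIs).  Species that lack a
#' spectrum, a trait row or a tip in the tree are listed in the
#' reconciliation report and excluded.  Zones with too few species for a
#' model are skipped with a note.  The join is keyed by (normalized)
#' species label, so row order in any input is irrelevant.
#'
#' @param spectra_path file or directory of reflectance spectra (see
#'   [read_spectra]).
#' @param tree_path Newick file.
#' @param traits_path trait CSV (see [read_traits]).
#' @param config optional list: `dialect` (column mapping for spectra),
#'   `achromatic_radius`, `grid` (wavelength grid), `min_zone_n` (default
#'   10, smallest zone that gets PGLS fits), `average_loci` (FALSE:
#'   replicates are averaged as spectra before visual modelling, the
#'   default; TRUE: every replicate is modelled and the hexagon loci are
#'   averaged instead).
#' @param out_dir if non-NULL, write `signals.csv`, `zone_summary.csv`,
#'   `pgls_fits.csv`, `phylo_signal.csv` and `reconciliation.csv` there.
#' @return list of class `hexaflora_run`: `signals`, `records` (joined
#'   per-species table), `zone_summary`, `pgls` (per-zone fit objects),
#'   `pgls_table`, `signal_table`, `dropped` (reconciliation report).
#' @export
run_pipeline <- function(spectra_path, tree_path, traits_path,
                         config = list(), out_dir = NULL) {
  grid <- config$grid %||% 300:700
  min_zone_n <- config$min_zone_n %||% 10
  curves <- standard_curves(grid)

  specs <- read_spectra(spectra_path, dialect = config$dialect)
  specs <- resample(specs, grid)
  radius <- config$achromatic_radius %||% 0.11
  if (isTRUE(config$average_loci)) {
    ## alternative order: model every replicate, then average the loci
    per_rep <- spectrum_to_signals(specs, curves, achromatic_radius = radius)
    agg <- stats::aggregate(per_rep[c("E_uv", "E_b", "E_g", "x", "y",
                                      "cc", "gc")],
                            by = list(species = per_rep$species), mean)
    ang <- atan2(agg$y, agg$x) %% (2 * pi)
    agg$sector <- hexagon_sectors[findInterval(
      ang, seq(0, 2 * pi, by = pi / 3), rightmost.closed = TRUE)]
    agg$achromatic <- agg$cc < radius
    signals <- agg
  } else {
    by_sp <- average_replicates(specs)
    signals <- spectrum_to_signals(by_sp, curves, achromatic_radius = radius)
  }
  traits <- read_traits(traits_path)
  tree <- read_newick(tree_path)

  key_sig <- norm_label(signals$species)
  key_tr <- norm_label(traits$species)
  key_tip <- norm_label(tree$tip.label)
  common <- Reduce(intersect, list(key_sig, key_tr, key_tip))
  if (!length(common)) stop("no species shared by spectra, traits and tree")
  dropped <- data.frame(
    species = c(signals$species[!key_sig %in% common],
                traits$species[!key_tr %in% common],
                tree$tip.label[!key_tip %in% common]),
    source = c(rep("spectra", sum(!key_sig %in% common)),
               rep("traits", sum(!key_tr %in% common)),
               rep("tree", sum(!key_tip %in% common))),
    stringsAsFactors = FALSE)

  recs <- signals[match(common, key_sig), ]
  tr <- traits[match(common, key_tr), ]
  recs$size_mm <- tr$size_mm
  recs$elev_mean <- tr$elev_mean
  recs$zone <- tr$zone
  rownames(recs) <- NULL

  tree <- prune_to(tree, recs$species)
  zone_sum <- summarize_zones(recs)

  pgls <- list(); pgls_rows <- list(); sig_rows <- list(); notes <- character()
  for (z in intersect(zone_levels, unique(as.character(recs$zone)))) {
    dat <- recs[recs$zone == z, ]
    if (nrow(dat) < max(min_zone_n, 6)) {
      notes <- c(notes, sprintf("zone %s skipped: n = %d too small",
                                z, nrow(dat)))
      next
    }
    cov_z <- phylo_cov(prune_to(tree, dat$species))
    zm <- fit_zone_models(dat, cov_z)
    pgls[[z]] <- zm
    pgls_rows[[z]] <- rbind(
      do.call(rbind, Map(tidy_fit, zm$fits, z, names(zm$fits))),
      tidy_fit(zm$size_fit, z, "size_linear"))
    sig_rows[[z]] <- do.call(rbind, lapply(
      c(gc = "gc", cc = "cc", size = "size_mm"), function(tr_name) {
        ps <- phylo_signal(stats::setNames(dat[[tr_name]], dat$species), cov_z)
        data.frame(zone = z, trait = tr_name, lambda = ps$lambda,
                   p_lrt = ps$p_lrt, loglik = ps$loglik, n = ps$n,
                   stringsAsFactors = FALSE)
      }))
  }
  pgls_table <- do.call(rbind, pgls_rows)
  signal_table <- do.call(rbind, sig_rows)
  rownames(pgls_table) <- rownames(signal_table) <- NULL

  out <- structure(list(signals = signals, records = recs,
                        zone_summary = zone_sum, pgls = pgls,
                        pgls_table = pgls_table,
                        signal_table = signal_table,
                        dropped = dropped, notes = notes),
                   class = "hexaflora_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(signals, file.path(out_dir, "signals.csv"),
                     row.names = FALSE)
    utils::write.csv(zone_sum, file.path(out_dir, "zone_summary.csv"),
                     row.names = FALSE)
    if (!is.null(pgls_table))
      utils::write.csv(pgls_table, file.path(out_dir, "pgls_fits.csv"),
                       row.names = FALSE)
    if (!is.null(signal_table))
      utils::write.csv(signal_table, file.path(out_dir, "phylo_signal.csv"),
                       row.names = FALSE)
    utils::write.csv(dropped, file.path(out_dir, "reconciliation.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.hexaflora_run <- function(x, ...) {
  cat("flower-signal pipeline run\n")
  cat(sprintf("  species analysed: %d (%d dropped in reconciliation)\n",
              nrow(x$records), nrow(x$dropped)))
  print(table(x$records$zone))
  for (z in names(x$pgls))
    cat(sprintf("  %s: selected %s model (lambda = %.3f)\n", z,
                x$pgls[[z]]$selection$best,
                x$pgls[[z]]$fits[[x$pgls[[z]]$selection$best]]$lambda))
  if (length(x$notes)) cat(paste(" ", x$notes, collapse = "\n"), "\n")
  invisible(x)
}
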