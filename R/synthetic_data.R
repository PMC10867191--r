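## Synthetic study-shaped data: ultrametric trees with polytomies,
## lambda-structured colour/size traits along an elevational gradient, and
## flower-like reflectance spectra inverse-designed so the bee-vision
## pipeline recovers each species' target colour and green contrast.

#' Simulation configuration
#'
#' Defaults describe a community of the shape this pipeline analyses: 714
#' species spread over five elevational zones in the observed proportions
#' (183/258/170/67/36), an ultrametric unit-height phylogeny with 20%
#' of internal nodes collapsed to polytomies, colour contrast evolving as
#' lambda-transformed Brownian motion squashed into its bounded range,
#' green contrast depending linearly (optionally quadratically) on colour
#' contrast with phylogenetically structured noise, and log-normal flower
#' sizes whose location declines linearly with elevation (about -9e-5
#' log-mm per metre, i.e. roughly 14 mm at sea level down to 10-11 mm at
#' 3,300 m).
#'
#' @param n_species number of species.
#' @param seed integer RNG seed.
#' @param zone_props proportions of species per zone (Foothills ...
#'   Alpine); must sum to 1.
#' @param polytomy_frac fraction of internal nodes collapsed.
#' @param lambda true Pagel's lambda of the trait-generating process.
#' @param bm_rate Brownian rate on the unit-height tree.
#' @param beta regression c(b0, b1, b2) for gc on cc (b2 = 0 gives a
#'   purely linear generator).
#' @param noise_sd marginal sd of the phylogenetically structured
#'   residual of gc.
#' @param cc_max upper bound of the logistic squash for cc.
#' @param size_log_intercept,size_log_slope,size_sdlog log-normal size
#'   model: meanlog = intercept + slope * elevation (m).
#' @param n_reps_range replicate flowers per species (inclusive range).
#' @param rep_noise_sd relative sd of the smooth multiplicative
#'   replicate noise.
#' @param design_tol acceptable |achieved - target| for cc and gc in the
#'   spectral inverse design.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_species = 714, seed = 1,
                       zone_props = c(183, 258, 170, 67, 36) / 714,
                       polytomy_frac = 0.2,
                       lambda = 0.5, bm_rate = 1,
                       beta = c(0.22, 0.22, 0), noise_sd = 0.03,
                       cc_max = 0.65,
                       size_log_intercept = log(14.5),
                       size_log_slope = -9e-5, size_sdlog = 0.45,
                       n_reps_range = c(3, 5), rep_noise_sd = 0.02,
                       design_tol = 0.02) {
  stopifnot(n_species >= 2, abs(sum(zone_props) - 1) < 1e-8,
            bm_rate > 0, noise_sd > 0, size_sdlog > 0,
            lambda >= 0, polytomy_frac >= 0, polytomy_frac < 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate an ultrametric tree with polytomies
#'
#' Yule (pure-birth) tree rescaled to unit height; a fraction of the
#' internal non-root nodes is then collapsed into polytomies by pushing
#' each collapsed node's parent-edge length down onto its children, which
#' preserves all root-to-tip distances (the tree stays ultrametric).
#'
#' @param n number of tips.
#' @param polytomy_frac fraction of internal non-root nodes to collapse.
#' @return an [ape::phylo] tree, tips labelled sp001, sp002, ...
#' @export
sim_tree <- function(n, polytomy_frac = 0.2) {
  stopifnot(n >= 2)
  tr <- ape::rphylo(n, birth = 1, death = 0)
  depths <- ape::node.depth.edgelength(tr)
  tr$edge.length <- tr$edge.length / max(depths[seq_len(n)])
  tr$tip.label <- sprintf("sp%03d", seq_len(n))
  if (polytomy_frac > 0 && tr$Nnode > 1) {
    internal <- setdiff(n + seq_len(tr$Nnode), n + 1)  # non-root
    k <- floor(polytomy_frac * length(internal))
    if (k > 0) {
      drop <- sample(internal, k)
      ## collapse shallower nodes first so a collapsed parent's length,
      ## pushed onto the edge of a collapsed child, is pushed on again
      node_depth <- ape::node.depth.edgelength(tr)
      drop <- drop[order(node_depth[drop])]
      for (nd in drop) {
        pe <- which(tr$edge[, 2] == nd)
        ce <- which(tr$edge[, 1] == nd)
        tr$edge.length[ce] <- tr$edge.length[ce] + tr$edge.length[pe]
        tr$edge.length[pe] <- 0
      }
      tr <- ape::di2multi(tr, tol = 1e-12)
    }
  }
  tr
}

## draw one multivariate normal with covariance rate * V(lambda)
rlambda_bm <- function(cov, lambda, rate) {
  V <- lambda_transform(cov, lambda)
  L <- t(chol(rate * V))
  as.vector(L %*% stats::rnorm(length(cov$taxa)))
}

#' Simulate species traits on a tree
#'
#' Colour contrast: lambda-transformed Brownian motion mapped into
#' (0, cc_max) by a logistic squash (slope 1, so with unit rate the
#' central 95% of values stay clear of both bounds).  Green contrast:
#' beta0 + beta1 cc + beta2 cc^2 plus lambda-structured noise, clipped to
#' [0, 0.5].  Elevation: zone drawn from `zone_props`, mean elevation
#' uniform within the zone's bin (Alpine capped at 3,300 m), min/max as
#' a random spread around the mean.  Size: log-normal with location
#' declining linearly in elevation.
#'
#' @param tree an [ape::phylo] tree (e.g. from [sim_tree]).
#' @param config a [sim_config].
#' @return data.frame (species, cc, gc, size_mm, elev_min, elev_mean,
#'   elev_max, zone) with the generating values in attribute `truth`.
#' @export
sim_traits <- function(tree, config = sim_config()) {
  n <- length(tree$tip.label)
  cov <- phylo_cov(tree)
  z <- rlambda_bm(cov, config$lambda, config$bm_rate)
  cc <- config$cc_max * stats::plogis(z)
  b <- config$beta
  eps <- rlambda_bm(cov, config$lambda, config$noise_sd^2)
  gc <- b[1] + b[2] * cc + b[3] * cc^2 + eps
  gc <- pmin(pmax(gc, 0), 0.5)
  if (all(gc %in% c(0, 0.5)))
    stop("config error: all gc values clipped at the bounds")

  edges <- c(0, 500, 1500, 2500, 3000, 3300)
  zone_i <- sample.int(5, n, replace = TRUE, prob = config$zone_props)
  elev_mean <- stats::runif(n, edges[zone_i], edges[zone_i + 1])
  spread_lo <- stats::runif(n, 0, 200)
  spread_hi <- stats::runif(n, 0, 200)
  elev_min <- pmax(elev_mean - spread_lo, 0)
  elev_max <- elev_mean + spread_hi
  size_mm <- stats::rlnorm(n, config$size_log_intercept +
                             config$size_log_slope * elev_mean,
                           config$size_sdlog)
  out <- data.frame(species = cov$taxa, cc = cc, gc = gc, size_mm = size_mm,
                    elev_min = elev_min, elev_mean = elev_mean,
                    elev_max = elev_max,
                    zone = assign_zone(elev_mean),
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(lambda = config$lambda, beta = config$beta,
                             noise_sd = config$noise_sd,
                             bm_rate = config$bm_rate)
  out
}

## fast quantum catch for a raw reflectance vector on the curves grid
catch_raw <- function(refl, curves, denom) {
  wl <- curves$wl
  vapply(1:3, function(i)
    trapz(wl, refl * curves$illuminant * curves$S[, i]), numeric(1)) / denom
}

signals_raw <- function(refl, curves, denom) {
  E <- excitation(catch_raw(refl, curves, denom))
  x <- sqrt(3) / 2 * (E[3] - E[1])
  y <- E[2] - (E[1] + E[3]) / 2
  c(cc = sqrt(x^2 + y^2), E_g = E[3])
}

## one species: find (brightness v, absorption depth h) so that the curve
## v * background * (1 - h * band) hits the target cc and green-receptor
## excitation.  Flowers are modelled on the bright branch (E_g > 0.5).
design_curve <- function(cc_target, gc_target, curves, denom,
                         max_tries = 5, tol = 0.02) {
  wl <- curves$wl
  eg_target <- 0.5 + gc_target
  v0 <- min(eg_target / (1 - eg_target), 11)
  best <- NULL
  for (try in seq_len(max_tries)) {
    ## two absorption shapes: a Gaussian UV/blue band (subtle chromatic
    ## shifts) or a sigmoidal short-wavelength cut-off (absorbs UV and
    ## blue together, reaching the high-colour-contrast range)
    band <- if (try %% 2 == 1) {
      edge <- stats::runif(1, 430, 520)
      stats::plogis((edge - wl) / 20)
    } else {
      centre <- stats::runif(1, 330, 460)
      width <- stats::runif(1, 30, 80)
      exp(-((wl - centre) / width)^2)
    }
    make <- function(par) pmin(par[1] * curves$background * (1 - par[2] * band),
                               1.25)
    obj <- function(par) {
      s <- signals_raw(make(par), curves, denom)
      (s["cc"] - cc_target)^2 + (s["E_g"] - eg_target)^2
    }
    fit <- stats::optim(c(v0, 0.5), obj, method = "L-BFGS-B",
                        lower = c(0.02, 0), upper = c(11.5, 1))
    refl <- make(fit$par)
    s <- signals_raw(refl, curves, denom)
    err <- c(cc = abs(s["cc"] - cc_target),
             gc = abs((s["E_g"] - 0.5) - gc_target))
    cand <- list(refl = refl, err = err, par = fit$par)
    if (is.null(best) || max(err) < max(best$err)) best <- cand
    if (max(err) <= tol) break
  }
  best$flagged <- max(best$err) > tol
  best
}

#' Simulate replicate flower reflectance spectra for a trait table
#'
#' For each species a smooth flower-like curve (the foliage-background
#' shape scaled in brightness, minus a Gaussian UV/blue absorption band)
#' is inverse-designed by bounded 2-D search so that, run through the
#' bee-vision model, its colour contrast and green contrast match the
#' species' trait values within `design_tol`.  Species whose targets are
#' unreachable after `max_tries` random band placements are flagged (see
#' attribute `flagged`).  Each species then gets 3-5 replicate curves
#' perturbed multiplicatively by smooth Gaussian-process noise (length
#' scale 50 nm, relative sd `rep_noise_sd`), mimicking the
#' replicate-to-replicate structure of spectrometer measurements
#' (smooth illumination/geometry variation) rather than white noise.
#'
#' @param traits data.frame from [sim_traits] (needs `species`, `cc`,
#'   `gc`).
#' @param config a [sim_config].
#' @param curves a [standard_curves] bundle.
#' @return a [spectra] object with per-replicate curves; attributes
#'   `flagged` (species not meeting the tolerance) and `design_error`
#'   (achieved |error| per species).
#' @export
sim_spectra <- function(traits, config = sim_config(),
                        curves = standard_curves()) {
  wl <- curves$wl
  denom <- vapply(1:3, function(i)
    trapz(wl, curves$background * curves$illuminant * curves$S[, i]),
    numeric(1))
  n_wl <- length(wl)
  kern <- stats::dnorm(seq(-150, 150, by = wl[2] - wl[1]), sd = 50)
  kern <- kern / sum(kern)
  pad <- (length(kern) - 1) / 2
  smooth_noise <- function(sd_target) {
    if (sd_target <= 0) return(numeric(n_wl))
    e <- stats::rnorm(n_wl + 2 * pad)
    sm <- stats::filter(e, kern, sides = 2)[(pad + 1):(pad + n_wl)]
    as.numeric(sm) / stats::sd(sm) * sd_target
  }
  cols <- list(); ids <- character(); err <- list(); flagged <- character()
  for (i in seq_len(nrow(traits))) {
    des <- design_curve(traits$cc[i], traits$gc[i], curves, denom,
                        tol = config$design_tol)
    if (des$flagged) flagged <- c(flagged, traits$species[i])
    err[[i]] <- des$err
    rng <- seq(config$n_reps_range[1], config$n_reps_range[2])
    n_rep <- rng[sample.int(length(rng), 1)]
    for (r in seq_len(n_rep)) {
      cols[[length(cols) + 1]] <-
        pmax(des$refl * (1 + smooth_noise(config$rep_noise_sd)), 0)
      ids <- c(ids, sprintf("%s__%d", traits$species[i], r))
    }
  }
  refl <- do.call(cbind, cols)
  colnames(refl) <- ids
  meta <- data.frame(id = ids, species = sub("__[^_]*$", "", ids),
                     replicate = sub("^.*__", "", ids),
                     stringsAsFactors = FALSE)
  out <- spectra(wl, refl, meta)
  attr(out, "flagged") <- flagged
  attr(out, "design_error") <- do.call(rbind, err)
  out
}

#' Simulate a complete study-shaped dataset
#'
#' Tree, traits and replicate spectra under one seed; fully deterministic
#' for a given configuration.
#'
#' @param config a [sim_config].
#' @return list of class `sim_dataset`: `tree`, `traits`, `spectra`,
#'   `truth`, `config`.
#' @export
sim_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  tree <- sim_tree(config$n_species, config$polytomy_frac)
  traits <- sim_traits(tree, config)
  specs <- sim_spectra(traits, config)
  structure(list(tree = tree, traits = traits, spectra = specs,
                 truth = attr(traits, "truth"), config = config),
            class = "sim_dataset")
}

#' Write a simulated dataset to disk
#'
#' Long-format spectra CSV, Newick tree, trait CSV and the
#' true-parameter JSON used by recovery tests.
#'
#' @param sim a [sim_dataset].
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_sim <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(sim$tree, file.path(out_dir, "tree.nwk"))
  utils::write.csv(
    sim$traits[c("species", "size_mm", "elev_min", "elev_max")],
    file.path(out_dir, "traits.csv"), row.names = FALSE)
  sp <- sim$spectra
  long <- data.frame(
    wl = rep(sp$wl, ncol(sp$refl)),
    reflectance = as.vector(sp$refl),
    species = rep(sp$meta$species, each = length(sp$wl)),
    replicate = rep(sp$meta$replicate, each = length(sp$wl)))
  utils::write.csv(long, file.path(out_dir, "spectra.csv"),
                   row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
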