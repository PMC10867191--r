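test_that("elevational zones use the half-open study bins", {
  expect_equal(as.character(assign_zone(250)), "Foothills")
  expect_equal(as.character(assign_zone(499.9)), "Foothills")
  expect_equal(as.character(assign_zone(500)), "Submontane")
  expect_equal(as.character(assign_zone(1500)), "Montane")
  expect_equal(as.character(assign_zone(2499)), "Montane")
  expect_equal(as.character(assign_zone(2500)), "Upper-montane")
  expect_equal(as.character(assign_zone(2999.9)), "Upper-montane")
  expect_equal(as.character(assign_zone(3000)), "Alpine")
  expect_equal(as.character(assign_zone(4000)), "Alpine")
  expect_error(assign_zone(-5), "negative")
})

test_that("kernel-density modes find the peak of a known density", {
  set.seed(50)
  x <- rnorm(1000, 0.3, 0.01)
  rec <- data.frame(zone = "Alpine", gc = x, cc = x, size_mm = exp(x))
  zs <- summarize_zones(rec)
  expect_lt(abs(zs$mode_gc - 0.3), 0.005)
  expect_equal(zs$n, 1000)
  expect_true(zs$gc_lo < zs$mean_gc && zs$mean_gc < zs$gc_hi)
})

test_that("degenerate samples get closed-form summaries", {
  const <- data.frame(zone = "Montane", gc = rep(0.2, 5),
                      cc = rep(0.1, 5), size_mm = rep(12, 5))
  zs <- summarize_zones(const)
  expect_equal(zs$mode_gc, 0.2)
  expect_equal(zs$mean_gc, 0.2)
  expect_equal(zs$gc_lo, zs$gc_hi)

  two <- data.frame(zone = "Alpine", gc = c(0.1, 0.5),
                    cc = c(0.1, 0.5), size_mm = c(10, 20))
  expect_warning(zs2 <- summarize_zones(two), "n < 3")
  expect_true(is.na(zs2$mode_gc))
  expect_equal(zs2$mean_gc, 0.3)
  half <- qt(0.975, df = 1) * sd(c(0.1, 0.5)) / sqrt(2)
  expect_equal(zs2$gc_lo, 0.3 - half)
  expect_equal(zs2$gc_hi, 0.3 + half)
})

## one small simulated dataset on disk, reused by the pipeline tests
sim_small <- sim_dataset(sim_config(n_species = 70, seed = 99,
                                    zone_props = c(.4, .4, .2, 0, 0)))
dir_small <- file.path(tempdir(), "sim_small")
write_sim(sim_small, dir_small)

test_that("the pipeline joins, assigns one zone per species and accounts for all of them", {
  res <- run_pipeline(file.path(dir_small, "spectra.csv"),
                      file.path(dir_small, "tree.nwk"),
                      file.path(dir_small, "traits.csv"),
                      config = list(min_zone_n = 10))
  expect_s3_class(res, "hexaflora_run")
  expect_equal(nrow(res$records), 70)
  expect_equal(sum(table(res$records$zone)), 70)
  expect_equal(anyDuplicated(res$records$species), 0)
  expect_equal(sum(res$zone_summary$n), 70)
  # zones consistent with the bin edges
  expect_equal(as.character(res$records$zone),
               as.character(assign_zone(res$records$elev_mean)))
  # recomputed signals track the generating traits
  m <- merge(res$records, sim_small$traits, by = "species")
  expect_lt(sqrt(mean((m$cc.x - m$cc.y)^2)), 0.03)
  expect_lt(sqrt(mean((m$gc.x - m$gc.y)^2)), 0.03)
  # per-zone fits exist for the populated zones with tables to match
  expect_true(all(c("zone", "model", "term", "estimate", "lambda")
                  %in% names(res$pgls_table)))
  expect_setequal(unique(res$signal_table$trait), c("gc", "cc", "size_mm"))
})

test_that("shuffling trait rows leaves the pipeline output identical", {
  tr <- read.csv(file.path(dir_small, "traits.csv"))
  set.seed(1)
  shuf <- file.path(tempdir(), "traits_shuffled.csv")
  write.csv(tr[sample(nrow(tr)), ], shuf, row.names = FALSE)
  a <- run_pipeline(file.path(dir_small, "spectra.csv"),
                    file.path(dir_small, "tree.nwk"),
                    file.path(dir_small, "traits.csv"))
  b <- run_pipeline(file.path(dir_small, "spectra.csv"),
                    file.path(dir_small, "tree.nwk"), shuf)
  expect_equal(a$pgls_table, b$pgls_table)
  expect_equal(a$zone_summary, b$zone_summary)
  expect_equal(a$signal_table, b$signal_table)
})

test_that("species missing from the tree or traits are reported and excluded", {
  tr <- read.csv(file.path(dir_small, "traits.csv"))
  cut1 <- file.path(tempdir(), "traits_cut.csv")
  write.csv(tr[-(1:3), ], cut1, row.names = FALSE)
  res <- run_pipeline(file.path(dir_small, "spectra.csv"),
                      file.path(dir_small, "tree.nwk"), cut1)
  expect_equal(nrow(res$records), 67)
  expect_true(all(tr$species[1:3] %in% res$dropped$species))
})

test_that("a one-zone dataset yields outputs for that zone only", {
  sim1 <- sim_dataset(sim_config(n_species = 40, seed = 7,
                                 zone_props = c(0, 0, 1, 0, 0)))
  d1 <- file.path(tempdir(), "sim_onezone")
  write_sim(sim1, d1)
  res <- run_pipeline(file.path(d1, "spectra.csv"),
                      file.path(d1, "tree.nwk"),
                      file.path(d1, "traits.csv"))
  expect_equal(unique(as.character(res$records$zone)), "Montane")
  expect_equal(names(res$pgls), "Montane")
  expect_equal(unique(res$signal_table$zone), "Montane")
})

test_that("averaging loci instead of spectra gives nearly identical signals at low replicate noise", {
  a <- run_pipeline(file.path(dir_small, "spectra.csv"),
                    file.path(dir_small, "tree.nwk"),
                    file.path(dir_small, "traits.csv"))
  b <- run_pipeline(file.path(dir_small, "spectra.csv"),
                    file.path(dir_small, "tree.nwk"),
                    file.path(dir_small, "traits.csv"),
                    config = list(average_loci = TRUE))
  m <- merge(a$signals, b$signals, by = "species")
  expect_lt(max(abs(m$cc.x - m$cc.y)), 0.01)
  expect_lt(max(abs(m$gc.x - m$gc.y)), 0.01)
})

test_that("pipeline CSV outputs are written when requested", {
  out <- file.path(tempdir(), "pipe_out")
  run_pipeline(file.path(dir_small, "spectra.csv"),
               file.path(dir_small, "tree.nwk"),
               file.path(dir_small, "traits.csv"), out_dir = out)
  expect_true(all(file.exists(file.path(out,
    c("signals.csv", "zone_summary.csv", "pgls_fits.csv",
      "phylo_signal.csv", "reconciliation.csv")))))
})
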