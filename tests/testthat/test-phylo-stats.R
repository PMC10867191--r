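test_that("Newick reading keeps polytomies and enforces branch lengths", {
  two <- read_newick(write_newick("(A:1,B:1);"))
  expect_equal(sort(two$tip.label), c("A", "B"))
  expect_equal(unname(ape::node.depth.edgelength(two)[1:2]), c(1, 1))

  tri <- read_newick(write_newick("((A:1,B:1):1,C:2);"))
  expect_true(ape::is.ultrametric(tri))
  expect_equal(ape::cophenetic.phylo(tri)["A", "C"], 4)

  poly <- read_newick(write_newick("(A:1,B:1,C:1);"))
  expect_equal(length(poly$tip.label), 3)
  expect_equal(poly$Nnode, 1)

  expect_error(read_newick(write_newick("(A:1,B);")), "branch length")
  expect_error(read_newick(tempfile()), "no such file")
})

test_that("pruning preserves path lengths and collapses unifurcations", {
  tr <- read_newick(write_newick("((A:1,B:1):1,C:2);"))
  expect_equal(ape::cophenetic.phylo(prune_to(tr, c("A", "B", "C"))),
               ape::cophenetic.phylo(tr))
  ac <- prune_to(tr, c("A", "C"))
  d <- ape::node.depth.edgelength(ac)
  expect_equal(unname(d[1:2]), c(2, 2))
  expect_equal(ape::cophenetic.phylo(ac)["A", "C"], 4)

  set.seed(31)
  big <- ape::rcoal(50)
  keep <- sample(big$tip.label, 20)
  sub <- prune_to(big, keep)
  expect_equal(ape::cophenetic.phylo(sub)[keep, keep],
               ape::cophenetic.phylo(big)[keep, keep])
})

test_that("label matching normalizes case, spaces and infraspecific ranks", {
  tr <- read_newick(write_newick("((Aster_alpinus:1,Viola_biflora_var._major:1):1,Poa_annua:2);"))
  pr <- prune_to(tr, c("aster alpinus", "Viola biflora"))
  expect_setequal(pr$tip.label, c("Aster_alpinus", "Viola_biflora_var._major"))
  expect_error(prune_to(tr, c("Aster alpinus", "Missing species")),
               "Missing species")
})

test_that("Brownian covariance is the shared-path matrix with a valid lambda_max", {
  tr <- read_newick(write_newick("((A:1,B:1):1,C:2);"))
  cv <- phylo_cov(tr)
  expect_equal(unname(cv$C[c("A", "B", "C"), c("A", "B", "C")]),
               rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)))
  expect_equal(cv$lambda_max, 2)  # V(2) is singular: corr(A,B) hits 1

  star <- read_newick(write_newick("(A:1,B:1,C:1,D:1);"))
  expect_equal(unname(phylo_cov(star)$C), diag(4))
  expect_equal(phylo_cov(star)$lambda_max, Inf)
})

test_that("C matches the covariance of simulated Brownian tip values", {
  set.seed(32)
  tr <- sim_tree(30, polytomy_frac = 0)
  cv <- phylo_cov(tr)
  L <- t(chol(cv$C))
  Z <- L %*% matrix(rnorm(30 * 50000), 30)
  emp <- tcrossprod(Z) / 50000
  expect_lt(max(abs(emp - cv$C)), 0.05)  # ~5 Monte-Carlo sds
})

test_that("lambda transform scales off-diagonals only", {
  set.seed(33)
  cv <- phylo_cov(sim_tree(12, 0))
  V <- lambda_transform(cv, 0.4)
  expect_equal(diag(V), diag(cv$C))
  off <- upper.tri(V)
  expect_equal(V[off], 0.4 * cv$C[off])
})

test_that("PGLS at lambda 0 and on a star tree equals ordinary least squares", {
  set.seed(34)
  star_newick <- paste0("(", paste(sprintf("t%d:1", 1:40), collapse = ","), ");")
  star <- phylo_cov(read_newick(write_newick(star_newick)))
  d <- data.frame(species = star$taxa, x = rnorm(40))
  d$y <- 0.3 + 0.8 * d$x + rnorm(40, 0, 0.4)
  ols <- summary(lm(y ~ x, d))$coefficients

  for (lam in list(0, 0.7, "ML")) {
    f <- pgls_fit(y ~ x, d, star, lambda = lam)
    expect_equal(f$coefficients$estimate, unname(ols[, 1]), tolerance = 1e-8)
    expect_equal(f$coefficients$se, unname(ols[, 2]), tolerance = 1e-8)
    expect_equal(f$coefficients$t, unname(ols[, 3]), tolerance = 1e-8)
  }

  cv <- phylo_cov(sim_tree(40, 0.2))
  d2 <- data.frame(species = cv$taxa, x = rnorm(40))
  d2$y <- 0.1 + 0.5 * d2$x + rnorm(40, 0, 0.3)
  f0 <- pgls_fit(y ~ x, d2, cv, lambda = 0)
  ols2 <- summary(lm(y ~ x, d2))$coefficients
  expect_equal(f0$coefficients$estimate, unname(ols2[, 1]), tolerance = 1e-8)
  expect_equal(f0$coefficients$se, unname(ols2[, 2]), tolerance = 1e-8)
})

test_that("GLS estimates match the direct matrix formula on random instances", {
  set.seed(35)
  for (rep in 1:3) {
    cv <- phylo_cov(sim_tree(50, 0.2))
    X <- cbind(1, rnorm(50), runif(50))
    y <- X %*% c(0.2, 0.4, -0.3) +
      t(chol(lambda_transform(cv, 0.6))) %*% rnorm(50, 0, 0.5)
    d <- data.frame(species = cv$taxa, y = as.vector(y),
                    x1 = X[, 2], x2 = X[, 3])
    f <- pgls_fit(y ~ x1 + x2, d, cv, lambda = 0.6)
    ref <- oracle_gls(d$y, X, lambda_transform(cv, 0.6))
    expect_equal(f$coefficients$estimate, unname(ref$beta), tolerance = 1e-8)
    expect_equal(f$coefficients$se, unname(ref$se), tolerance = 1e-8)
  }
})

test_that("ML lambda, coefficients and likelihood agree with nlme::gls(corPagel)", {
  skip_if_not_installed("nlme")
  set.seed(36)
  tr <- sim_tree(80, 0)
  cv <- phylo_cov(tr)
  d <- data.frame(species = cv$taxa, x = rnorm(80))
  d$y <- 0.2 + 0.4 * d$x +
    as.vector(t(chol(lambda_transform(cv, 0.6) * 0.2)) %*% rnorm(80))
  rownames(d) <- d$species
  f <- pgls_fit(y ~ x, d, cv)
  g <- nlme::gls(y ~ x, data = d, method = "ML",
                 correlation = ape::corPagel(0.5, tr, form = ~species))
  expect_equal(f$lambda, as.numeric(g$modelStruct$corStruct[[1]]),
               tolerance = 1e-3)
  expect_equal(f$coefficients$estimate, unname(coef(g)), tolerance = 1e-5)
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-5)
})

test_that("profile likelihood at the ML lambda dominates the endpoints; whitened residuals centre on zero", {
  set.seed(37)
  tr <- sim_tree(100, 0.2)
  cv <- phylo_cov(tr)
  d <- data.frame(species = cv$taxa, x = rnorm(100))
  d$y <- 0.1 + 0.3 * d$x +
    as.vector(t(chol(lambda_transform(cv, 0.5) * 0.1)) %*% rnorm(100))
  f <- pgls_fit(y ~ x, d, cv)
  f0 <- pgls_fit(y ~ x, d, cv, lambda = 0)
  f1 <- pgls_fit(y ~ x, d, cv, lambda = 1)
  expect_gte(f$loglik, f0$loglik)
  expect_gte(f$loglik, f1$loglik)
  expect_lt(abs(mean(f$residuals)) ,
            3 * sd(f$residuals) / sqrt(f$n))
  expect_true(f$lambda_ci[1] <= f$lambda && f$lambda <= f$lambda_ci[2])
})

test_that("log-model predictors must be strictly positive", {
  set.seed(38)
  cv <- phylo_cov(sim_tree(20, 0))
  d <- data.frame(species = cv$taxa, x = c(0, runif(19, 0.1, 1)))
  d$y <- rnorm(20)
  expect_error(pgls_fit(y ~ log(x), d, cv), "log")
})

test_that("model comparison ranks by AIC with adjusted-R2 tie-breaking", {
  set.seed(39)
  cv <- phylo_cov(sim_tree(60, 0))
  d <- data.frame(species = cv$taxa, x = runif(60, 0.1, 1))
  d$y <- 0.2 + 0.5 * d$x + rnorm(60, 0, 0.05)
  f <- pgls_fit(y ~ x, d, cv)
  # identical fits: dAIC = 0, equal R2 -> first listed wins
  cmp <- compare_models(list(a = f, b = f))
  expect_equal(cmp$best, "a")
  expect_equal(cmp$table$dAIC, c(0, 0))
  # differing sample sizes refuse to compare
  cv2 <- phylo_cov(sim_tree(30, 0))
  d2 <- data.frame(species = cv2$taxa, x = runif(30, 0.1, 1))
  d2$y <- 0.2 + 0.5 * d2$x + rnorm(30, 0, 0.05)
  expect_error(compare_models(list(a = f, b = pgls_fit(y ~ x, d2, cv2))),
               "sample sizes")
})

test_that("a strongly curved generator is preferred over its nested linear model", {
  set.seed(40)
  wins <- 0L
  for (r in 1:10) {
    cv <- phylo_cov(sim_tree(100, 0))
    x <- runif(100, 0.05, 0.6)
    y <- 0.1 - 0.3 * x + 1.2 * x^2 + rnorm(100, 0, 0.03)
    d <- data.frame(species = cv$taxa, x = x, y = y)
    cmp <- compare_models(list(
      linear = pgls_fit(y ~ x, d, cv),
      quadratic = pgls_fit(y ~ I(x^2) + x, d, cv)))
    # nested linear model never beats the true wider model by > 2 AIC
    tab <- cmp$table
    expect_lt(tab$AIC[tab$model == "quadratic"],
              tab$AIC[tab$model == "linear"] + 2)
    wins <- wins + (cmp$best == "quadratic")
  }
  expect_gte(wins, 8)
})

test_that("phylo_signal matches phytools::phylosig and rejects degenerate traits", {
  skip_if_not_installed("phytools")
  set.seed(41)
  tr <- sim_tree(120, 0.2)
  cv <- phylo_cov(tr)
  y <- as.vector(t(chol(lambda_transform(cv, 0.7))) %*% rnorm(120))
  names(y) <- cv$taxa
  ps <- phylo_signal(y, cv)
  ref <- phytools::phylosig(tr, y, method = "lambda", test = TRUE)
  expect_equal(ps$lambda, ref$lambda, tolerance = 1e-3)
  expect_equal(ps$loglik, ref$logL, tolerance = 1e-5)
  expect_equal(ps$p_lrt, ref$P, tolerance = 1e-4)

  expect_error(phylo_signal(setNames(rep(1, 120), cv$taxa), cv),
               "constant")
})

test_that("an iid trait shows no phylogenetic signal", {
  set.seed(42)
  cv <- phylo_cov(sim_tree(150, 0.2))
  y <- setNames(rnorm(150), cv$taxa)
  ps <- phylo_signal(y, cv)
  expect_lt(ps$lambda, 0.15)
  expect_gt(ps$p_lrt, 0.2)
})
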