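## Phylogenetic statistics: lambda-scaled Brownian covariance, PGLS with
## maximum-likelihood estimation of Pagel's lambda, AIC model comparison
## and single-trait phylogenetic-signal tests.
##
## Pagel's lambda multiplies the off-diagonal elements of the Brownian
## covariance C while leaving the diagonal unchanged:
##   V(lambda) = lambda * C + (1 - lambda) * diag(diag(C)).
## Writing D = diag(diag(C)) and M = D^{-1/2} C D^{-1/2} - I with
## eigendecomposition M = Q L Q', we get
##   V(lambda) = D^{1/2} Q (I + lambda L) Q' D^{1/2},
## so after the one-off rotation z = Q' D^{-1/2} y (and likewise for the
## design matrix) every GLS quantity at any lambda reduces to weighted
## least squares with weights 1/(1 + lambda * L_i) and
## log|V| = log|D| + sum(log(1 + lambda * L_i)).  This makes the profile
## likelihood over lambda cheap after a single O(n^3) decomposition.

#' Read a phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree] that enforces the contracts the
#' downstream statistics need: branch lengths must be present and
#' non-missing, and polytomies are kept as-is (never randomly resolved).
#' Zero-length terminal branches are counted in the attribute
#' `zero_terminal` (they make species pairs perfectly correlated under
#' Brownian motion, which is worth knowing about but not an error).
#'
#' @param path Newick file path.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tr <- tryCatch(ape::read.tree(path), error = function(e)
    stop("unparseable Newick file ", path, ": ", conditionMessage(e)))
  if (is.null(tr)) stop("unparseable Newick file ", path)
  if (is.null(tr$edge.length))
    stop("tree in ", path, " has no branch lengths")
  bad <- which(is.na(tr$edge.length))
  if (length(bad))
    stop("missing branch length on edge to node ",
         paste(tr$edge[bad, 2], collapse = ", "))
  term <- tr$edge[, 2] <= length(tr$tip.label)
  attr(tr, "zero_terminal") <- sum(tr$edge.length[term] == 0)
  tr
}

norm_label <- function(x) {
  x <- gsub("[ ]+", "_", trimws(x))
  tolower(x)
}

strip_infra <- function(x) {
  sub("_(var|subsp|ssp|f|forma|cv)\\.?_.*$", "", x)
}

#' Prune a tree to a set of taxa
#'
#' Induced subtree on `taxa`: internal unifurcations are collapsed and
#' root-to-tip path lengths are preserved.  Labels are matched exactly
#' after case-folding and space/underscore normalization; only where that
#' fails are infraspecific rank markers (var., subsp., f.) stripped and
#' matching retried.  The match table is attached as attribute
#' `match_report`.
#'
#' @param tree an [ape::phylo] tree.
#' @param taxa character vector of tip labels to keep.
#' @return the pruned tree (tip labels as in the input tree).
#' @export
prune_to <- function(tree, taxa) {
  tips_n <- norm_label(tree$tip.label)
  want_n <- norm_label(taxa)
  hit <- match(want_n, tips_n)
  retry <- which(is.na(hit))
  if (length(retry)) {
    hit[retry] <- match(strip_infra(want_n[retry]), strip_infra(tips_n))
  }
  if (anyNA(hit))
    stop("taxa not found in tree: ", paste(taxa[is.na(hit)], collapse = ", "))
  if (!length(hit)) stop("no taxa to keep")
  out <- ape::keep.tip(tree, tree$tip.label[hit])
  attr(out, "match_report") <- data.frame(
    requested = taxa, matched_tip = tree$tip.label[hit],
    stringsAsFactors = FALSE)
  out
}

#' Among-species Brownian covariance of a tree
#'
#' C[i, j] is the shared root-to-MRCA path length between species i and j
#' (the expected trait covariance under Brownian motion with unit rate).
#' The object caches the eigendecomposition that makes Pagel's-lambda
#' likelihoods cheap, and records `lambda_max`, the largest lambda for
#' which V(lambda) stays positive definite (can exceed 1 on non-star
#' trees, and is Inf for a star phylogeny).
#'
#' @param tree a rooted [ape::phylo] tree with branch lengths.
#' @return object of class `phylo_cov`.
#' @export
phylo_cov <- function(tree) {
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  C <- ape::vcv(tree)
  dd <- diag(C)
  if (any(dd <= 0)) stop("zero root-to-tip distance for some tip")
  sd_ <- sqrt(dd)
  M <- C / tcrossprod(sd_)
  diag(M) <- diag(M) - 1  # off-diagonal correlations; diag 0
  e <- eigen(M, symmetric = TRUE)
  neg <- e$values[e$values < -1e-12]
  lambda_max <- if (length(neg)) min(-1 / neg) else Inf
  structure(list(taxa = rownames(C), C = C, dd = dd,
                 Q = e$vectors, mu = e$values,
                 logdetD = sum(log(dd)), lambda_max = lambda_max),
            class = "phylo_cov")
}

#' @export
print.phylo_cov <- function(x, ...) {
  cat(sprintf("phylo_cov: %d taxa, tree height %.4g, lambda_max %.4g\n",
              length(x$taxa), max(x$dd), x$lambda_max))
  invisible(x)
}

#' Lambda-transformed covariance matrix
#'
#' @param cov a [phylo_cov] object.
#' @param lambda scaling of the off-diagonal covariances.
#' @return the matrix V(lambda) = lambda C + (1 - lambda) diag(diag(C)).
#' @export
lambda_transform <- function(cov, lambda) {
  V <- lambda * cov$C
  diag(V) <- cov$dd
  V
}

## rotate data into the eigenbasis (one-off per fit)
rotate_data <- function(cov, y, X) {
  s <- sqrt(cov$dd)
  list(z = crossprod(cov$Q, y / s),
       W = crossprod(cov$Q, X / s))
}

## ML log-likelihood and WLS pieces at a fixed lambda, in the rotated basis
lambda_loglik <- function(rot, cov, lambda) {
  w <- 1 + lambda * cov$mu
  if (any(w <= 0)) return(list(loglik = -Inf))
  sw <- sqrt(w)
  Xs <- rot$W / sw
  ys <- rot$z / sw
  fit <- stats::lm.fit(Xs, ys)
  rss <- sum(fit$residuals^2)
  n <- length(ys)
  logdetV <- cov$logdetD + sum(log(w))
  loglik <- -n / 2 * (log(2 * pi * rss / n) + 1) - logdetV / 2
  list(loglik = loglik, rss = rss, coef = fit$coefficients,
       qr = fit$qr, n = n)
}

profile_lambda <- function(rot, cov, bounds, grid_n = 32, tol = 1e-6) {
  lo <- bounds[1]; hi <- bounds[2]
  grid <- seq(lo, hi, length.out = grid_n)
  ll <- vapply(grid, function(l) lambda_loglik(rot, cov, l)$loglik,
               numeric(1))
  i <- which.max(ll)
  left <- grid[max(1, i - 1)]
  right <- grid[min(grid_n, i + 1)]
  opt <- stats::optimize(function(l) lambda_loglik(rot, cov, l)$loglik,
                         c(left, right), maximum = TRUE, tol = tol)
  # the bracketing endpoints are candidates too
  cand <- c(opt$maximum, left, right, grid[i])
  cll <- c(opt$objective, ll[max(1, i - 1)], ll[min(grid_n, i + 1)], ll[i])
  j <- which.max(cll)
  list(lambda = cand[j], loglik = cll[j])
}

lambda_ci <- function(rot, cov, lambda_hat, loglik_hat, bounds) {
  cut <- loglik_hat - stats::qchisq(0.95, 1) / 2
  f <- function(l) lambda_loglik(rot, cov, l)$loglik - cut
  lo <- bounds[1]; hi <- bounds[2]
  lower <- if (f(lo) >= 0) lo else
    stats::uniroot(f, c(lo, lambda_hat), tol = 1e-6)$root
  upper <- if (f(hi) >= 0) hi else
    stats::uniroot(f, c(lambda_hat, hi), tol = 1e-6)$root
  c(lower = lower, upper = upper)
}

align_to_taxa <- function(data, taxa) {
  key <- if ("species" %in% names(data)) data$species else rownames(data)
  idx <- match(norm_label(taxa), norm_label(key))
  if (anyNA(idx))
    stop("taxa missing from data: ", paste(taxa[is.na(idx)], collapse = ", "))
  data[idx, , drop = FALSE]
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits `formula` by GLS with error covariance proportional to the
#' lambda-transformed Brownian covariance of the tree.  With
#' `lambda = "ML"` (default), lambda is estimated by maximising the
#' profile log-likelihood with a 32-point grid pre-scan followed by
#' golden-section refinement (tolerance 1e-6), and a 95%
#' profile-likelihood confidence interval is reported (chi-square(1)
#' cutoff).  Coefficient standard errors use the unbiased residual
#' variance; t tests have n - p degrees of freedom.  At lambda = 0 the
#' fit coincides with ordinary least squares.
#'
#' AIC counts the regression coefficients plus the residual rate sigma^2
#' plus lambda as parameters.  Adjusted R^2 compares the whitened
#' residual sum of squares against an intercept-only GLS fit at the same
#' lambda.
#'
#' @param formula model formula, e.g. `gc ~ cc` or `gc ~ I(cc^2) + cc` or
#'   `gc ~ log(cc)`.  Predictors must be finite after transformation
#'   (a zero predictor under `log()` is an error, not silently offset).
#' @param data data.frame with a `species` column (or species rownames)
#'   covering all taxa in `cov`.
#' @param cov a [phylo_cov] object; defines the species set of the fit.
#' @param lambda `"ML"` or a fixed value in [0, lambda_max].
#' @param lambda_bounds search interval for ML; default c(0, 1), the
#'   convention of comparative-regression software (single-trait signal
#'   tests use [phylo_signal], which searches up to lambda_max).
#' @return object of class `pgls_fit`: list with `coefficients` table
#'   (estimate, se, t, p), `lambda`, `lambda_ci`, `sigma2`, `loglik`,
#'   `AIC`, `r2_adj`, `n`, `k`, `formula`, `residuals` (whitened).
#' @export
pgls_fit <- function(formula, data, cov, lambda = "ML",
                     lambda_bounds = c(0, 1)) {
  stopifnot(inherits(cov, "phylo_cov"))
  data <- align_to_taxa(data, cov$taxa)
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (any(!is.finite(X)))
    stop("non-finite values in design matrix (zero or negative predictor under log?)")
  n <- length(y); p <- ncol(X)
  if (n <= p + 1) stop("too few species (n = ", n, ") for ", p, " coefficients")
  if (qr(X)$rank < p) stop("singular design matrix")

  bounds <- c(max(0, lambda_bounds[1]),
              min(lambda_bounds[2], cov$lambda_max * (1 - 1e-8), 10))
  rot <- rotate_data(cov, y, X)
  est_lambda <- identical(lambda, "ML")
  ci <- c(lower = NA_real_, upper = NA_real_)
  if (est_lambda) {
    prof <- profile_lambda(rot, cov, bounds)
    lam <- prof$lambda
    ci <- lambda_ci(rot, cov, lam, prof$loglik, bounds)
  } else {
    lam <- as.numeric(lambda)
    if (lam < 0 || lam > cov$lambda_max)
      stop("lambda = ", lam, " outside [0, lambda_max]")
  }
  at <- lambda_loglik(rot, cov, lam)
  if (!is.finite(at$loglik))
    stop("covariance not positive definite at lambda = ", lam)
  beta <- at$coef
  sigma2_ml <- at$rss / n
  sigma2_unb <- at$rss / (n - p)
  w <- 1 + lam * cov$mu
  Xs <- rot$W / sqrt(w)
  XtXinv <- chol2inv(chol(crossprod(Xs)))
  se <- sqrt(diag(XtXinv) * sigma2_unb)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  ## null (intercept-only) fit at the same lambda for R^2
  rot0 <- rotate_data(cov, y, matrix(1, n, 1))
  rss0 <- lambda_loglik(rot0, cov, lam)$rss
  r2 <- 1 - at$rss / rss0
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - p)
  k <- p + 2  # betas + sigma^2 + lambda
  coefs <- data.frame(estimate = beta, se = se, t = tval, p = pval,
                      row.names = colnames(X))
  structure(list(coefficients = coefs, lambda = lam, lambda_ci = ci,
                 lambda_ml = est_lambda, sigma2 = sigma2_ml,
                 loglik = at$loglik, AIC = 2 * k - 2 * at$loglik,
                 r2_adj = r2_adj, n = n, k = k, formula = formula,
                 taxa = cov$taxa,
                 residuals = (rot$z - rot$W %*% beta) / sqrt(w)),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit:", deparse(x$formula), "\n")
  cat(sprintf("n = %d, lambda = %.3f", x$n, x$lambda))
  if (x$lambda_ml)
    cat(sprintf(" (95%% CI %.3f, %.3f)", x$lambda_ci[1], x$lambda_ci[2]))
  cat(sprintf(", logLik = %.3f, AIC = %.2f, adj R2 = %.4f\n",
              x$loglik, x$AIC, x$r2_adj))
  stats::printCoefmat(as.matrix(x$coefficients), P.values = TRUE,
                      has.Pvalue = TRUE)
  invisible(x)
}

#' @export
logLik.pgls_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
AIC.pgls_fit <- function(object, ...) object$AIC

#' Compare PGLS fits by AIC with adjusted-R2 tie-breaking
#'
#' Ranks the fits by AIC (ascending).  Models within 2 AIC units of the
#' best are considered tied and the tie is broken by higher adjusted R^2
#' (equal values keep the first-listed model).  All fits must share the
#' same response and sample size.
#'
#' @param fits named list of [pgls_fit] objects (or several fits passed
#'   via `...`).
#' @return object of class `model_comparison`: list with `best` (name of
#'   the selected model) and `table` (model, AIC, dAIC, logLik, r2_adj,
#'   lambda, k), ranked.
#' @export
compare_models <- function(fits, ...) {
  if (inherits(fits, "pgls_fit")) fits <- c(list(fits), list(...))
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- sprintf("model%d", seq_along(fits))
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) > 1)
    stop("fits use differing sample sizes: ", paste(ns, collapse = ", "))
  tab <- data.frame(
    model = names(fits),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
    logLik = vapply(fits, `[[`, numeric(1), "loglik"),
    r2_adj = vapply(fits, `[[`, numeric(1), "r2_adj"),
    lambda = vapply(fits, `[[`, numeric(1), "lambda"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$AIC), ]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  tied <- which(tab$dAIC < 2)
  best_row <- tied[which.max(tab$r2_adj[tied])]
  # equal r2 among tied models: keep the first listed in the input
  ties_eq <- tied[tab$r2_adj[tied] == tab$r2_adj[best_row]]
  if (length(ties_eq) > 1) {
    orig <- match(tab$model[ties_eq], names(fits))
    best_row <- ties_eq[which.min(orig)]
  }
  structure(list(best = tab$model[best_row], table = tab),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("model comparison (AIC, dAIC < 2 tie broken by adjusted R2)\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat("selected:", x$best, "\n")
  invisible(x)
}

#' Phylogenetic signal of a single trait (Pagel's lambda)
#'
#' Intercept-only maximum-likelihood fit of lambda under a
#' lambda-transformed Brownian model, searched over [0, lambda_max] (so
#' estimates slightly above 1 are possible on trees that allow them,
#' following the convention of single-trait signal software).  Reports a
#' likelihood-ratio test against lambda = 0 (phylogenetic independence):
#' p = P(chi-square(1) >= 2 (lnL(lambda_hat) - lnL(0))).
#'
#' @param y named numeric trait vector, or a data.frame column; names (or
#'   the data.frame's `species` column) must cover `cov$taxa`.
#' @param cov a [phylo_cov] object.
#' @return object of class `phylo_signal`: list with `lambda`, `loglik`,
#'   `loglik0`, `p_lrt`, `n`.
#' @export
phylo_signal <- function(y, cov) {
  stopifnot(inherits(cov, "phylo_cov"))
  if (is.data.frame(y)) {
    trait <- setdiff(names(y), "species")[1]
    yy <- y[[trait]]
    names(yy) <- if ("species" %in% names(y)) y$species else rownames(y)
    y <- yy
  }
  if (!is.null(names(y))) {
    idx <- match(norm_label(cov$taxa), norm_label(names(y)))
    if (anyNA(idx)) stop("trait missing for some taxa")
    y <- y[idx]
  }
  n <- length(y)
  if (n != length(cov$taxa)) stop("trait length != number of taxa")
  if (n < 4) stop("need at least 4 species")
  if (stats::var(y) == 0) stop("degenerate trait: constant across species")
  bounds <- c(0, min(cov$lambda_max * (1 - 1e-8), 10))
  rot <- rotate_data(cov, y, matrix(1, n, 1))
  prof <- profile_lambda(rot, cov, bounds)
  ll0 <- lambda_loglik(rot, cov, 0)$loglik
  lrt <- max(0, 2 * (prof$loglik - ll0))
  structure(list(lambda = prof$lambda, loglik = prof$loglik, loglik0 = ll0,
                 p_lrt = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
                 n = n),
            class = "phylo_signal")
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat(sprintf("Pagel's lambda = %.3f (n = %d), logLik = %.3f, LRT vs lambda=0: p = %.4g\n",
              x$lambda, x$n, x$loglik, x$p_lrt))
  invisible(x)
}
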