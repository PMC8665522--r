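# Separability evaluation of a DE gene panel: PCA, K-means and a
# two-component Gaussian mixture with shared diagonal covariance.

#' Evaluate how well a gene panel separates the two conditions
#'
#' Restricts the matrix to `deGenes`, z-scores `log2(FPKM + 1)` per gene
#' and evaluates the sample space three ways: PCA (SVD of the centered
#' sample-by-gene matrix), K-means with `k` clusters and multiple
#' restarts, and a `k`-component Gaussian mixture with a shared diagonal
#' covariance fitted by EM (tolerance 1e-6 on the relative log-likelihood
#' change, at most 500 iterations, initialized from the K-means labels).
#' Cluster labels are aligned to the conditions by majority before the
#' concordance is computed.
#'
#' @param object an [ExpressionMatrix-class] with unit `"fpkm"`.
#' @param deGenes character vector of gene ids (>= 2 after intersection).
#' @param k number of clusters/components (default 2).
#' @param posteriorThreshold posterior probability above which a sample
#'   counts as confidently assigned (default 0.8).
#' @param seed seed for the K-means restarts.
#' @return a `SeparationReport` list: `pca` (`coords` samples x 2,
#'   `explained_var` fractions), `kmeans` (`cluster` labels, `inertia`),
#'   `gmm` (`posterior` matrix, `loglik_trace`, `assigned_posterior`),
#'   `concordance` (fraction of samples whose cluster matches the
#'   majority cluster of their condition, in \[0.5, 1\]),
#'   `high_posterior_fraction` per condition, and the inputs' metadata.
#' @export
evaluateSeparation <- function(object, deGenes, k = 2,
                               posteriorThreshold = 0.8, seed = 1) {
  stopifnot(is(object, "ExpressionMatrix"))
  if (exprUnit(object) != "fpkm")
    stop("evaluateSeparation expects FPKM values")
  deGenes <- intersect(deGenes, rownames(object))
  if (length(deGenes) < 2) stop("need at least 2 DE genes")
  cond <- SummarizedExperiment::colData(object)$condition
  if (min(table(factor(cond, levels = VALID_CONDITIONS))) < 2)
    stop("each condition needs at least 2 samples")
  if (ncol(object) < k) stop("fewer samples than components")
  z <- zscoreGenes(log2p1(exprValues(object)[deGenes, , drop = FALSE]))
  if (nrow(z) == 0) stop("feature matrix is constant")
  x <- t(z)  # samples x genes

  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  ncomp <- min(2L, ncol(pc$x))
  coords <- pc$x[, seq_len(ncomp), drop = FALSE]

  km <- withSeed(seed, stats::kmeans(x, centers = k, nstart = 10))
  gmm <- gmmSharedDiag(x, k, init = km$cluster)

  post_lab <- max.col(gmm$posterior)
  concordance <- alignConcordance(post_lab, cond)
  assigned <- gmm$posterior[cbind(seq_len(nrow(x)), post_lab)]
  hp <- vapply(VALID_CONDITIONS, function(cc) {
    mean(assigned[cond == cc] > posteriorThreshold)
  }, numeric(1))

  structure(list(
    pca = list(coords = coords, explained_var = ev),
    kmeans = list(cluster = stats::setNames(km$cluster, rownames(x)),
                  inertia = km$tot.withinss),
    gmm = list(posterior = gmm$posterior,
               loglik_trace = gmm$loglik_trace,
               assigned_posterior = stats::setNames(assigned,
                                                    rownames(x))),
    concordance = concordance,
    high_posterior_fraction = hp,
    condition = stats::setNames(cond, rownames(x)),
    posterior_threshold = posteriorThreshold),
    class = "SeparationReport")
}

# Majority-aligned concordance between cluster labels and conditions.
# For the two-cluster case this is the best agreement over the two
# cluster->condition mappings (hence >= 0.5); for k > 2 each cluster is
# mapped to its majority condition.
alignConcordance <- function(labels, cond) {
  cond <- factor(cond)
  if (length(unique(labels)) <= 2 && nlevels(cond) == 2) {
    agree <- mean(labels == as.integer(cond))
    return(max(agree, 1 - agree))
  }
  maj <- tapply(as.character(cond), labels, function(v)
    names(sort(table(v), decreasing = TRUE))[1])
  mean(as.character(cond) == maj[as.character(labels)])
}

# EM for a k-component Gaussian mixture with one diagonal covariance
# shared across components. Returns posteriors and the per-iteration
# log-likelihood trace (non-decreasing by construction of EM).
gmmSharedDiag <- function(x, k = 2, init = NULL, tol = 1e-6,
                          maxIter = 500) {
  n <- nrow(x); p <- ncol(x)
  if (is.null(init)) init <- rep(seq_len(k), length.out = n)
  resp <- matrix(0, n, k)
  resp[cbind(seq_len(n), init)] <- 1
  loglik <- -Inf
  trace <- numeric(0)
  varfloor <- 1e-6
  for (it in seq_len(maxIter)) {
    # M-step
    nk <- colSums(resp) + 1e-12
    w <- nk / n
    mu <- t(resp) %*% x / nk                      # k x p
    ss <- numeric(p)
    for (j in seq_len(k)) {
      d <- sweep(x, 2, mu[j, ])
      ss <- ss + colSums(resp[, j] * d^2)
    }
    sigma2 <- pmax(ss / n, varfloor)
    # E-step (log densities, log-sum-exp)
    logd <- vapply(seq_len(k), function(j) {
      d <- sweep(x, 2, mu[j, ])
      -0.5 * (sum(log(2 * pi * sigma2)) +
                rowSums(sweep(d^2, 2, sigma2, "/"))) + log(w[j])
    }, numeric(n))
    logd <- matrix(logd, n, k)
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    resp <- exp(logd - lse)
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (is.finite(loglik) &&
        abs(ll - loglik) <= tol * (abs(loglik) + tol)) break
    loglik <- ll
  }
  list(posterior = resp, loglik_trace = trace,
       means = mu, sigma2 = sigma2, weights = w)
}

#' @export
print.SeparationReport <- function(x, ...) {
  cat(sprintf("SeparationReport: %d samples, concordance %.3f\n",
              length(x$condition), x$concordance))
  cat(sprintf("  PC1/PC2 explained variance: %.1f%% / %.1f%%\n",
              100 * x$pca$explained_var[1],
              100 * (x$pca$explained_var[2] %||% NA)))
  cat(sprintf("  high-posterior fraction (>%.2f): tumor %.2f, control %.2f\n",
              x$posterior_threshold,
              x$high_posterior_fraction[["tumor"]],
              x$high_posterior_fraction[["control"]]))
  invisible(x)
}
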