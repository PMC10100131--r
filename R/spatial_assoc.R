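#' Prepare regional expression and frequency for PLS
#'
#' The response is the z-scored square root of the regional tumor frequency
#' (the square root reduces the skewness of frequency values); predictor
#' columns (genes) are z-scored.  Regions with any missing expression are
#' dropped pairwise and logged; constant genes cannot be z-scored and are
#' dropped with a log note.
#'
#' @param expression Region x gene numeric matrix (gene ids as column
#'   names).
#' @param regional_frequency Nonnegative per-region frequency vector of
#'   matching length.
#' @return List with `X` (z-scored expression), `y` (z-scored sqrt
#'   frequency) and `regions_kept` (indices into the input rows).
#' @export
prepare_xy <- function(expression, regional_frequency) {
  expression <- as.matrix(expression)
  R <- nrow(expression)
  stopifnot(length(regional_frequency) == R)
  if (any(regional_frequency < 0)) stop("frequency must be nonnegative")
  keep <- !apply(expression, 1L, anyNA) & !is.na(regional_frequency)
  if (sum(!keep) > 0) {
    gf_log("prepare_xy: dropping %d region(s) with missing values", sum(!keep))
  }
  expression <- expression[keep, , drop = FALSE]
  freq <- regional_frequency[keep]
  if (sd(sqrt(freq)) == 0) stop("constant frequency: z-score undefined")
  y <- as.numeric(scale(sqrt(freq)))
  sds <- apply(expression, 2L, sd)
  if (any(sds == 0)) {
    gf_log("prepare_xy: dropping %d constant gene column(s)", sum(sds == 0))
    expression <- expression[, sds > 0, drop = FALSE]
  }
  X <- scale(expression)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  list(X = X, y = y, regions_kept = which(keep))
}

#' Cross-covariance PLS of expression against tumor frequency
#'
#' Performs the singular value decomposition of the gene-by-response
#' cross-covariance matrix `t(X) %*% Y / (R - 1)` (inputs z-scored, so this
#' is a correlation-scale covariance).  Components maximize the covariance
#' between linear combinations of gene expression and the tumor
#' distribution.  With a single response the decomposition is rank one:
#' component 1's gene loadings are the normalized cross-covariance vector
#' `X'y` and the singular value is its Euclidean norm.
#'
#' @param X Z-scored region x gene matrix (at least 10 rows).
#' @param y Z-scored response vector or region x q response matrix.
#' @param n_components Number of components to retain (default: all).
#' @return A `pls_result` with `singular_values`, `gene_loadings` (gene x
#'   component, unit-norm columns), `region_scores` (`X %*% loadings`),
#'   `covariance_explained`, and slots for spin-test p-values.
#' @export
pls_cross_covariance <- function(X, y, n_components = NULL) {
  X <- as.matrix(X)
  Y <- as.matrix(y)
  R <- nrow(X)
  stopifnot(R >= 10, nrow(Y) == R)
  if (!all(is.finite(X)) || !all(is.finite(Y))) {
    stop("non-finite entries in X or y")
  }
  C <- crossprod(X, Y) / (R - 1)           # genes x q
  sv <- svd(C)
  k_full <- length(sv$d)
  k <- if (is.null(n_components)) k_full else min(n_components, k_full)
  loadings <- sv$u[, seq_len(k), drop = FALSE]
  rownames(loadings) <- colnames(X)
  colnames(loadings) <- paste0("PLS", seq_len(k))
  structure(list(
    singular_values = sv$d[seq_len(k)],
    gene_loadings = loadings,
    region_scores = X %*% loadings,
    covariance_explained = (sv$d^2 / sum(sv$d^2))[seq_len(k)],
    spin_p = rep(NA_real_, k),
    n_null = 0L,
    seed = NA_integer_
  ), class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  k <- length(x$singular_values)
  cat(sprintf("<pls_result> %d component(s); singular values: %s\n", k,
              paste(signif(x$singular_values, 4), collapse = ", ")))
  if (!all(is.na(x$spin_p))) {
    cat(sprintf("  spin p (n_null=%d): %s\n", x$n_null,
                paste(signif(x$spin_p, 3), collapse = ", ")))
  }
  invisible(x)
}

#' Spatial-autocorrelation-preserving surrogate maps
#'
#' Generates surrogate regional maps that preserve the original map's mean,
#' variance and spatial autocorrelation structure without assuming a
#' spherical surface, by Moran spectral randomization: the map is expanded
#' in the orthonormal eigenbasis of the doubly centered spatial kernel over
#' region centroids (Moran eigenvectors, ordered from large-scale smooth
#' gradients to fine-grained contrasts), and each surrogate randomly
#' sign-flips the expansion coefficients (optionally also permuting them
#' among eigenvectors with adjacent eigenvalues, `block_size > 1`).  Every
#' surrogate therefore has exactly the original's variance and spatial
#' frequency content (its squared coefficient spectrum, preserved exactly
#' for the default pure sign flips, to block resolution otherwise), but a
#' random realization of it.  Deterministic given `seed`.
#'
#' @param regional_map Non-constant per-region vector (length R >= 20).
#' @param centroids R x 3 matrix of region centroids in mm.
#' @param n_null Number of surrogates, at least 100.
#' @param seed RNG seed.
#' @param bandwidth_mm Gaussian kernel bandwidth defining the spatial
#'   weight matrix; default half the median pairwise centroid distance.
#' @param block_size Number of adjacent eigencomponents whose coefficients
#'   are permuted together before sign-flipping.  The default 1 permutes
#'   nothing (pure sign flips), which preserves the spectrum exactly and
#'   gives the best-calibrated spin test; larger blocks decorrelate the
#'   surrogates from the original more strongly at some cost in spectral
#'   fidelity.
#' @return R x n_null matrix of surrogate maps.
#' @export
spatial_null_maps <- function(regional_map, centroids, n_null = 1000,
                              seed = 1L, bandwidth_mm = NULL,
                              block_size = 1) {
  R <- length(regional_map)
  stopifnot(R >= 20, n_null >= 100, nrow(centroids) == R)
  if (sd(regional_map) == 0) stop("constant map: surrogates undefined")
  D <- as.matrix(dist(centroids))
  if (is.null(bandwidth_mm)) bandwidth_mm <- median(D[upper.tri(D)]) / 2
  W <- exp(-D^2 / (2 * bandwidth_mm^2))
  diag(W) <- 0
  Cmat <- diag(R) - matrix(1 / R, R, R)
  H <- Cmat %*% W %*% Cmat
  E <- eigen((H + t(H)) / 2, symmetric = TRUE)$vectors
  m0 <- mean(regional_map)
  coef <- as.numeric(crossprod(E, regional_map - m0))
  # the eigencomponent spanning the constant direction carries no variance
  # and is held out of the permutation blocks
  idx_const <- which.max(abs(as.numeric(crossprod(E, rep(1, R)))))
  free <- setdiff(seq_len(R), idx_const)
  blocks <- split(free, ceiling(seq_along(free) / block_size))
  with_seed(seed, {
    out <- matrix(NA_real_, R, n_null)
    for (s in seq_len(n_null)) {
      cs <- coef
      for (blk in blocks) {
        cs[blk] <- coef[blk[sample.int(length(blk))]]
      }
      cs <- cs * sample(c(-1, 1), R, replace = TRUE)
      out[, s] <- E %*% cs + m0
    }
    gf_log("spatial_null_maps: seed %d, %d surrogates, kernel %.1f mm",
           seed, n_null, bandwidth_mm)
    out
  })
}

#' Spin-test p-values for PLS components
#'
#' Re-runs the cross-covariance PLS against each spatial surrogate of the
#' tumor map (expression held fixed; only the tumor distribution is
#' randomized) and reports, per component, the proportion of null singular
#' values at least as large as the observed one, with the usual +1
#' correction: `p = (1 + #[S_null >= S_obs]) / (n_null + 1)`.
#'
#' @param pls_observed A `pls_result` from [pls_cross_covariance()].
#' @param X The z-scored expression matrix used for the observed fit.
#' @param null_maps R x n_null surrogate matrix from [spatial_null_maps()]
#'   applied to the (pre-z-score) response map.
#' @return `pls_observed` with `spin_p` and `n_null` filled in.
#' @export
spin_pvalue <- function(pls_observed, X, null_maps) {
  X <- as.matrix(X)
  R <- nrow(X)
  stopifnot(nrow(null_maps) == R)
  n_null <- ncol(null_maps)
  k <- length(pls_observed$singular_values)
  Yn <- scale(null_maps)
  s_null <- matrix(NA_real_, k, n_null)
  if (k == 1L) {
    Cn <- crossprod(X, Yn) / (R - 1)
    s_null[1L, ] <- sqrt(colSums(Cn^2))
  } else {
    for (s in seq_len(n_null)) {
      d <- svd(crossprod(X, Yn[, s]) / (R - 1))$d
      s_null[, s] <- d[seq_len(k)]
    }
  }
  p <- vapply(seq_len(k), function(comp) {
    (1 + sum(s_null[comp, ] >= pls_observed$singular_values[comp])) /
      (n_null + 1)
  }, numeric(1))
  pls_observed$spin_p <- p
  pls_observed$n_null <- n_null
  pls_observed$null_singular_values <- s_null
  pls_observed
}

#' Rank genes by PLS loading
#'
#' Orders genes in descending order of their signed loading on the chosen
#' component (ties broken by gene id).
#'
#' @param pls A `pls_result`.
#' @param component Component index (default 1).
#' @return Data.frame with `gene`, `loading` and `rank`, ordered by
#'   descending loading.
#' @export
rank_genes <- function(pls, component = 1L) {
  k <- length(pls$singular_values)
  if (component < 1 || component > k) stop("component out of range")
  loading <- pls$gene_loadings[, component]
  ord <- order(-loading, names(loading))
  data.frame(gene = names(loading)[ord], loading = unname(loading[ord]),
             rank = seq_along(loading), stringsAsFactors = FALSE)
}

#' Permutation gene-set enrichment on PLS loadings
#'
#' For each gene set, the statistic is the two-sample t of member versus
#' non-member loadings; its p-value comes from set-size-preserving random
#' resampling of gene labels (two-sided), and q-values are
#' Benjamini-Hochberg adjusted across sets.  Sets with fewer than 5 genes
#' in the background, or identical to the whole background, are skipped
#' with a warning.
#'
#' @param loadings Named per-gene loading vector (the background).
#' @param gene_sets Named list of character vectors of gene ids.
#' @param n_perm Number of label resamplings (default 1000).
#' @param seed RNG seed.
#' @param alpha Significance level on q (default 0.05).
#' @return Data.frame (class `enrichment_result`) with one row per tested
#'   set: `set`, `n_genes`, `statistic`, `p`, `q`, `significant`.
#' @export
gene_set_enrichment <- function(loadings, gene_sets, n_perm = 1000,
                                seed = 1L, alpha = 0.05) {
  stopifnot(!is.null(names(loadings)))
  bg <- names(loadings)
  rows <- list()
  set_stat <- function(member) {
    unname(t.test(loadings[member], loadings[!member],
                  var.equal = TRUE)$statistic)
  }
  seeds <- derive_seeds(seed, length(gene_sets))
  for (i in seq_along(gene_sets)) {
    nm <- names(gene_sets)[i]
    genes <- intersect(gene_sets[[i]], bg)
    if (length(genes) < 5) {
      warning(sprintf("set '%s' has fewer than 5 background genes; skipped",
                      nm))
      next
    }
    if (length(genes) == length(bg)) {
      warning(sprintf("set '%s' equals the full background; skipped", nm))
      next
    }
    member <- bg %in% genes
    t_obs <- set_stat(member)
    t_null <- with_seed(seeds[i], {
      vapply(seq_len(n_perm), function(p) {
        set_stat(sample(member))
      }, numeric(1))
    })
    p <- (1 + sum(abs(t_null) >= abs(t_obs))) / (n_perm + 1)
    rows[[nm]] <- data.frame(set = nm, n_genes = length(genes),
                             statistic = t_obs, p = p,
                             stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no testable gene sets")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < alpha
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Spearman correlation with a receptor map, spatial-null p-value
#'
#' Spearman rank correlation between the regional tumor frequency and a
#' regional receptor density map, with significance assessed against
#' variogram-matching surrogates of the tumor map (two-sided, +1
#' corrected).
#'
#' @param tumor_regional Per-region tumor frequency vector (non-constant).
#' @param receptor_regional Per-region receptor density vector
#'   (non-constant, same length).
#' @param centroids R x 3 region centroids in mm.
#' @param n_null Number of surrogates (default 1000).
#' @param seed RNG seed.
#' @return List with `spearman_rho` and `p_spatial`.
#' @export
receptor_correlation <- function(tumor_regional, receptor_regional,
                                 centroids, n_null = 1000, seed = 1L) {
  stopifnot(length(tumor_regional) == length(receptor_regional))
  if (sd(tumor_regional) == 0 || sd(receptor_regional) == 0) {
    stop("constant input: correlation undefined")
  }
  rho <- cor(tumor_regional, receptor_regional, method = "spearman")
  nulls <- spatial_null_maps(tumor_regional, centroids, n_null = n_null,
                             seed = seed)
  rho_null <- apply(nulls, 2L, cor, y = receptor_regional,
                    method = "spearman")
  p <- (1 + sum(abs(rho_null) >= abs(rho))) / (n_null + 1)
  list(spearman_rho = rho, p_spatial = p)
}

#' Screen a panel of receptor maps against the tumor map
#'
#' Runs [receptor_correlation()] for each column of a receptor matrix and
#' Benjamini-Hochberg adjusts the spatial p-values across the panel.
#'
#' @param tumor_regional Per-region tumor frequency vector.
#' @param receptor_matrix R x n_receptor matrix (named columns).
#' @inheritParams receptor_correlation
#' @return Data.frame with `receptor`, `rho`, `p`, `q`.
#' @export
receptor_screen <- function(tumor_regional, receptor_matrix, centroids,
                            n_null = 1000, seed = 1L) {
  receptor_matrix <- as.matrix(receptor_matrix)
  nulls <- spatial_null_maps(tumor_regional, centroids, n_null = n_null,
                             seed = seed)
  res <- lapply(colnames(receptor_matrix), function(nm) {
    rec <- receptor_matrix[, nm]
    rho <- cor(tumor_regional, rec, method = "spearman")
    rho_null <- apply(nulls, 2L, cor, y = rec, method = "spearman")
    data.frame(receptor = nm, rho = rho,
               p = (1 + sum(abs(rho_null) >= abs(rho))) / (n_null + 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
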