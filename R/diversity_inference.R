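#' Alpha diversity of epiallele tables
#'
#' Two metrics per sample: the number of observed epialleles (patterns
#' with non-zero count) and the Shannon index of the pattern frequency
#' distribution, in bits (log base 2, the convention of the microbial
#' ecology toolchain this analysis mirrors; configurable).
#'
#' @param table An [epiallele_count_table()]; a warning is issued when it
#'   has not been rarefied (metrics are then not comparable across
#'   samples of unequal depth).
#' @param base Logarithm base for the Shannon index.
#' @return data.frame of class `alpha_diversity`: sample_id,
#'   observed_epialleles, shannon.
#' @export
alpha_diversity <- function(table, base = 2) {
  stopifnot(inherits(table, "epiallele_count_table"))
  if (is.null(table$rarefaction_depth))
    warning("table is not rarefied; alpha metrics are depth-dependent")
  counts <- table$counts
  out <- data.frame(
    sample_id = rownames(counts),
    observed_epialleles = as.integer(rowSums(counts > 0)),
    shannon = as.numeric(vegan::diversity(counts, index = "shannon", base = base)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("alpha_diversity", "data.frame")
  out
}

#' Bray-Curtis beta diversity
#'
#' Pairwise Bray-Curtis dissimilarity between samples:
#' BC(u, v) = 1 - 2 * sum(min(u, v)) / (sum(u) + sum(v)).
#'
#' @param table An [epiallele_count_table()] (conventionally rarefied) or
#'   a numeric count matrix (samples x patterns).
#' @return A symmetric `matrix` of class `beta_diversity_matrix` with
#'   zero diagonal and entries in [0, 1]. Samples with zero total count
#'   yield NA rows/columns and a warning.
#' @export
bray_curtis <- function(table) {
  counts <- if (inherits(table, "epiallele_count_table")) table$counts else table
  stopifnot(is.matrix(counts), nrow(counts) >= 2L)
  empty <- rowSums(counts) == 0
  # vegdist's own empty-row warning is superseded by the NA handling below
  d <- as.matrix(suppressWarnings(vegan::vegdist(counts, method = "bray")))
  if (any(empty)) {
    warning("zero-sum sample(s): ", paste(rownames(counts)[empty], collapse = ", "),
            "; their dissimilarities are undefined (NA)")
    d[empty, ] <- NA_real_; d[, empty] <- NA_real_; diag(d) <- 0
  }
  class(d) <- c("beta_diversity_matrix", class(d))
  d
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Eigendecomposition of the double-centred squared-dissimilarity matrix.
#' Axes are ordered by eigenvalue; negative eigenvalues (non-Euclidean
#' input) are reported, never silently dropped, and variance fractions
#' are computed over the positive eigenvalues only.
#'
#' @param d A dissimilarity matrix (e.g. from [bray_curtis()]) or `dist`.
#' @param k Number of axes to return (default: all positive-eigenvalue
#'   axes).
#' @return List of class `pcoa_result`: `points` (samples x axes),
#'   `eigenvalues` (all n - 1), `variance_fraction` (per returned axis,
#'   of the positive-eigenvalue total), `negative_eigenvalues`.
#' @export
pcoa <- function(d, k = NULL) {
  if (!inherits(d, "dist")) {
    m <- unclass(as.matrix(d))
    if (!isSymmetric(m, tol = 1e-8)) stop("dissimilarity matrix must be symmetric")
    d <- stats::as.dist(m)
  }
  n <- attr(d, "Size")
  # cmdscale's note about < k positive eigenvalues is expected for
  # Bray-Curtis input; negative eigenvalues are reported in the result
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1L, eig = TRUE))
  eig <- fit$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig))
  n_pos <- sum(pos)
  if (is.null(k)) k <- n_pos
  k <- min(k, n_pos)
  pts <- fit$points[, seq_len(k), drop = FALSE]
  colnames(pts) <- paste0("PC", seq_len(k))
  structure(list(points = pts,
                 eigenvalues = eig,
                 variance_fraction = eig[seq_len(k)] / sum(eig[pos]),
                 negative_eigenvalues = eig[eig < 0]),
            class = "pcoa_result")
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of group structure in a dissimilarity
#' matrix: R = (mean between-group rank - mean within-group rank) /
#' (M / 2) with M = n(n-1)/2 pairs and average ranks for ties; the
#' p-value counts permuted R values at least as large as the observed one
#' under random relabelling, with the observed labelling included:
#' p = (1 + #[R* >= R]) / (n_permutations + 1).
#'
#' @param d Dissimilarity matrix or `dist`.
#' @param groups Factor (or coercible) of group labels, >= 2 groups with
#'   >= 2 samples each.
#' @param n_permutations Number of label permutations (default 999), or a
#'   permutation matrix (one permutation per row) for exhaustive tests.
#' @param seed Integer seed for the permutations.
#' @return List of class `anosim_result`: statistic (R), p_value,
#'   n_permutations, seed, groups.
#' @export
anosim <- function(d, groups, n_permutations = 999, seed = 1L) {
  if (!inherits(d, "dist")) d <- stats::as.dist(unclass(as.matrix(d)))
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) < 2L)) stop("every group needs at least two samples")
  fit <- with_seed(seed, vegan::anosim(d, groups, permutations = n_permutations))
  n_perm <- if (is.matrix(n_permutations)) nrow(n_permutations) else n_permutations
  structure(list(statistic = unname(fit$statistic),
                 p_value = unname(fit$signif),
                 n_permutations = n_perm,
                 seed = seed,
                 groups = groups),
            class = "anosim_result")
}

#' Cramér two-sample test for multivariate distributions
#'
#' Nonparametric test of equality of two multivariate distributions based
#' on inter-point Euclidean distances:
#' T = (m n / (m + n)) * (2/(m n) sum phi(|x_i - y_j|)
#'       - 1/m^2 sum phi(|x_i - x_j|) - 1/n^2 sum phi(|y_i - y_j|)),
#' with the kernel phi(z) = z/2 of the original Cramér statistic
#' (configurable). The p-value comes from resampling: label permutation
#' by default, or a pooled bootstrap; both use the inclusive convention
#' p = (1 + #[T* >= T]) / (n_resamples + 1).
#'
#' In the epiallele analysis each observation is one sample's class
#' frequency vector, so the test compares class profiles between groups.
#'
#' @param x,y Numeric matrices (rows = observations) or vectors (treated
#'   as 1-D observations).
#' @param n_resamples Number of resamples (default 1000).
#' @param seed Integer seed.
#' @param kernel Function applied to inter-point distances.
#' @param method "permutation" or "bootstrap".
#' @return List of class `cramer_result`: statistic, p_value,
#'   n_resamples, seed, method, m, n.
#' @export
cramer_test <- function(x, y, n_resamples = 1000, seed = 1L,
                        kernel = function(z) z / 2,
                        method = c("permutation", "bootstrap")) {
  method <- match.arg(method)
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  if (is.vector(y)) y <- matrix(y, ncol = 1L)
  stopifnot(ncol(x) == ncol(y))
  m <- nrow(x); n <- nrow(y)
  if (m + n < 2L || m < 1L || n < 1L) stop("need at least one observation per group")
  phi <- kernel(unclass(as.matrix(stats::dist(rbind(x, y)))))
  t_obs <- .cramer_T(phi, seq_len(m), m + seq_len(n))
  hits <- 0L
  with_seed(seed, {
    for (b in seq_len(n_resamples)) {
      if (method == "permutation") {
        ix <- sample.int(m + n, m)
        iy <- setdiff(seq_len(m + n), ix)
      } else {
        ix <- sample.int(m + n, m, replace = TRUE)
        iy <- sample.int(m + n, n, replace = TRUE)
      }
      if (.cramer_T(phi, ix, iy) >= t_obs) hits <- hits + 1L
    }
  })
  structure(list(statistic = t_obs,
                 p_value = (1 + hits) / (n_resamples + 1),
                 n_resamples = n_resamples, seed = seed, method = method,
                 m = m, n = n),
            class = "cramer_result")
}

.cramer_T <- function(phi, ix, iy) {
  m <- length(ix); n <- length(iy)
  (m * n / (m + n)) * (2 * mean(phi[ix, iy, drop = FALSE]) -
                         mean(phi[ix, ix, drop = FALSE]) -
                         mean(phi[iy, iy, drop = FALSE]))
}

#' Univariate group comparisons with multiplicity control
#'
#' The routine comparison layer: per-CpG-site two-sample Student t tests
#' (pooled variance by default, Welch by flag) with Bonferroni adjustment
#' over the locus's sites, and one-way ANOVA of an alpha-diversity metric
#' across areas followed by Tukey HSD (Tukey-Kramer at unequal n).
#'
#' @param site_percent Numeric matrix, samples x CpG sites (per-site
#'   percent methylation per sample).
#' @param groups Two-level factor over the samples (e.g. CTRL/SCZ).
#' @param alpha_metric Optional numeric vector over samples (e.g. Shannon
#'   index) for the ANOVA layer.
#' @param areas Optional factor over samples (>= 2 levels) for the ANOVA
#'   layer.
#' @param welch Use Welch's t instead of pooled-variance Student's t.
#' @return List of class `group_comparison_table`: `t_table` (data.frame:
#'   site, t, df, p_raw, p_bonferroni; NA with a flag where both groups
#'   have zero variance), and when requested `anova` (F, df, p) and
#'   `tukey` (pairwise adjusted p data.frame).
#' @export
group_comparisons <- function(site_percent, groups,
                              alpha_metric = NULL, areas = NULL,
                              welch = FALSE) {
  stopifnot(is.matrix(site_percent))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("t tests need exactly two groups")
  g1 <- groups == levels(groups)[1]
  m_sites <- ncol(site_percent)
  rows <- lapply(seq_len(m_sites), function(j) {
    a <- site_percent[g1, j]; b <- site_percent[!g1, j]
    if (stats::var(a) == 0 && stats::var(b) == 0)
      return(data.frame(site = colnames(site_percent)[j] %||% as.character(j),
                        t = NA_real_, df = NA_real_, p_raw = NA_real_,
                        degenerate = TRUE))
    tt <- stats::t.test(a, b, var.equal = !welch)
    data.frame(site = colnames(site_percent)[j] %||% as.character(j),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value, degenerate = FALSE)
  })
  t_table <- do.call(rbind, rows)
  t_table$p_bonferroni <- stats::p.adjust(t_table$p_raw, method = "bonferroni")
  out <- list(t_table = t_table)
  if (!is.null(alpha_metric) && !is.null(areas)) {
    areas <- as.factor(areas)
    fit <- stats::aov(alpha_metric ~ areas)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$areas
    out$anova <- list(F = an[["F value"]][1],
                      df = unname(an[["Df"]]),
                      p_value = an[["Pr(>F)"]][1])
    out$tukey <- data.frame(comparison = rownames(tk),
                            diff = tk[, "diff"], p_adjusted = tk[, "p adj"],
                            row.names = NULL)
  }
  class(out) <- "group_comparison_table"
  out
}
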