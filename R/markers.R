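# Abundance-based disease-marker detection: presence filtering, a native
# exact negative-binomial test with median-of-ratios normalization and
# moment dispersion shrunk toward a mean-dispersion trend, BH correction,
# marker selection at adjusted p < 0.01 and |log2FC| > 1, and a
# co-occurrence network at |r| > 0.3.

#' Construct an abundance study
#' @param counts Nonnegative integer matrix, genomes x samples.
#' @param groups Factor or character of length `ncol(counts)` with two
#'   levels; the second level is treated as "case".
#' @param library_sizes Optional per-sample totals of the full (pre-filter)
#'   table; defaults to `colSums(counts)`.
#' @return An `abundance_study` list.
#' @export
abundance_study <- function(counts, groups, library_sizes = colSums(counts)) {
  stopifnot(is.matrix(counts), ncol(counts) == length(groups))
  if (any(counts < 0)) stop("negative counts")
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (any(table(groups) == 0L)) stop("both groups must be nonempty")
  structure(list(counts = counts, groups = groups,
                 library_sizes = library_sizes),
            class = "abundance_study")
}

#' Presence filter for an abundance study
#'
#' All-zero samples and all-zero genomes are dropped first. A genome is
#' present in a sample iff `count / library_size >= min_relative_abundance`;
#' genomes present in at least `min_occurrence` of the remaining samples
#' (inclusive boundary) are retained.
#'
#' @param study An `abundance_study`.
#' @param min_relative_abundance Relative-abundance floor (default `1e-5`,
#'   i.e. 0.001%).
#' @param min_occurrence Minimum fraction of samples (default 0.10).
#' @return A filtered `abundance_study` (library sizes are kept from the
#'   pre-filter table).
#' @export
presence_filter <- function(study, min_relative_abundance = 1e-5,
                            min_occurrence = 0.10) {
  if (length(study$counts) == 0L || nrow(study$counts) == 0L) stop("empty table")
  counts <- study$counts
  lib <- study$library_sizes
  keep_s <- colSums(counts) > 0
  counts <- counts[, keep_s, drop = FALSE]
  lib <- lib[keep_s]
  groups <- droplevels(study$groups[keep_s])
  keep_g <- rowSums(counts) > 0
  counts <- counts[keep_g, , drop = FALSE]
  if (nrow(counts) == 0L) stop("no genomes left after zero filtering")
  rel <- sweep(counts, 2L, lib, "/")
  present <- rel >= min_relative_abundance
  occ <- rowMeans(present)
  counts <- counts[occ >= min_occurrence, , drop = FALSE]
  structure(list(counts = counts, groups = groups, library_sizes = lib),
            class = "abundance_study")
}

# Median-of-ratios size factors (geometric-mean reference); falls back to
# library-size ratios when no genome has all-positive counts.
size_factors <- function(counts) {
  pos <- rowSums(counts == 0) == 0
  if (any(pos)) {
    lg <- log(counts[pos, , drop = FALSE])
    ref <- rowMeans(lg)
    sf <- apply(lg, 2L, function(col) exp(median(col - ref)))
  } else {
    ls <- colSums(counts)
    sf <- ls / exp(mean(log(ls[ls > 0])))
  }
  sf / exp(mean(log(sf)))
}

#' Exact negative-binomial differential-abundance test
#'
#' Per-sample size factors are estimated by median-of-ratios; per-genome
#' dispersions by the method of moments on normalized counts (pooled within
#' groups), shrunk 50% toward a lowess mean-dispersion trend. The p value is
#' a two-sided exact NB test on group total counts at equalized effective
#' library sizes (the sum over n samples of NB(mu, phi) is NB(n mu, phi/n);
#' conditioning on the overall total, probabilities at most that of the
#' observed split are summed). log2 fold-changes come from normalized group
#' means with a prior count of 0.5, capped at +/- 20.
#'
#' @param study An `abundance_study` (usually [presence_filter()] output).
#' @param normalization `"median_of_ratios"` (default) or `"library_size"`.
#' @return A `marker_table` data frame: `genome`, `log2FC`, `p`,
#'   `adjusted_p`, `mean_control`, `mean_case`, `dispersion`.
#' @export
nb_test <- function(study, normalization = c("median_of_ratios", "library_size")) {
  normalization <- match.arg(normalization)
  counts <- study$counts
  groups <- study$groups
  if (any(table(groups) < 2L)) stop("need >= 2 samples per group")
  sf <- if (normalization == "median_of_ratios") {
    size_factors(counts)
  } else {
    ls <- study$library_sizes
    ls / exp(mean(log(ls)))
  }
  norm <- sweep(counts, 2L, sf, "/")
  g1 <- groups == levels(groups)[1]   # control
  g2 <- !g1                            # case
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])

  # moment dispersion pooled within groups: var = mu + phi mu^2
  disp_raw <- vapply(seq_len(nrow(norm)), function(i) {
    x1 <- norm[i, g1]; x2 <- norm[i, g2]
    v <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
    mu <- (mean(x1) + mean(x2)) / 2
    if (mu <= 0) return(0)
    max(0, (v - mu) / mu^2)
  }, numeric(1))
  mu_all <- (m1 + m2) / 2
  ok <- mu_all > 0
  disp_trend <- rep(0, length(disp_raw))
  if (sum(ok) >= 10L) {
    lo <- lowess(log(mu_all[ok]), disp_raw[ok], f = 0.5)
    fitted <- approx(lo$x, lo$y, xout = log(mu_all[ok]), rule = 2)$y
    disp_trend[ok] <- pmax(0, fitted)
  } else {
    disp_trend[ok] <- mean(disp_raw[ok])
  }
  disp <- 0.5 * disp_raw + 0.5 * disp_trend

  # exact test on rounded group sums of normalized counts
  s1 <- round(rowSums(norm[, g1, drop = FALSE]))
  s2 <- round(rowSums(norm[, g2, drop = FALSE]))
  p <- vapply(seq_len(nrow(norm)), function(i) {
    exact_nb_p(s1[i], s2[i], n1, n2, disp[i])
  }, numeric(1))

  lfc <- log2((m2 + 0.5) / (m1 + 0.5))
  lfc[lfc > 20] <- 20; lfc[lfc < -20] <- -20
  out <- data.frame(genome = rownames(counts), log2FC = lfc, p = p,
                    adjusted_p = bh_adjust(p),
                    mean_control = m1, mean_case = m2,
                    dispersion = disp, row.names = NULL)
  class(out) <- c("marker_table", "data.frame")
  out
}

# Two-sided exact NB test of S1 vs S2 (totals over n1/n2 samples sharing
# mean mu and dispersion phi): condition on S = S1 + S2 and sum the
# conditional probabilities not exceeding that of the observed split.
exact_nb_p <- function(s1, s2, n1, n2, phi) {
  s <- s1 + s2
  if (s == 0) return(1)
  mu <- s / (n1 + n2)
  x <- 0:s
  if (phi <= 1e-8) {
    lp1 <- dpois(x, n1 * mu, log = TRUE)
    lp2 <- dpois(s - x, n2 * mu, log = TRUE)
  } else {
    lp1 <- dnbinom(x, size = n1 / phi, mu = n1 * mu, log = TRUE)
    lp2 <- dnbinom(s - x, size = n2 / phi, mu = n2 * mu, log = TRUE)
  }
  lp <- lp1 + lp2
  lp <- lp - max(lp)
  pr <- exp(lp)
  pr <- pr / sum(pr)
  obs <- pr[s1 + 1]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]) with input validation;
#' order-preserving and monotone.
#'
#' @param p Numeric vector of p values in `[0, 1]` (no NAs).
#' @return Adjusted p values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p))) stop("NA/NaN p values")
  if (any(p < 0 | p > 1)) stop("p values outside [0, 1]")
  p.adjust(p, method = "BH")
}

#' Select enriched/depleted marker genomes
#'
#' A genome is called case-enriched when `adjusted_p < alpha` and
#' `log2FC > lfc_min`, control-enriched when `adjusted_p < alpha` and
#' `log2FC < -lfc_min`, otherwise not significant. With cluster labels, the
#' roll-up counts distinct species clusters containing at least one selected
#' strain per direction.
#'
#' @param markers A [nb_test()] result.
#' @param alpha Adjusted-p threshold (default 0.01).
#' @param lfc_min Absolute log2 fold-change that must be exceeded
#'   (default 1; strict inequality).
#' @param clusters Optional named vector mapping genome to species cluster.
#' @return List: `table` (markers with `direction`), `case_enriched`,
#'   `control_enriched` (ids), `n_clusters_case`, `n_clusters_control`.
#' @export
select_markers <- function(markers, alpha = 0.01, lfc_min = 1,
                           clusters = NULL) {
  dir <- ifelse(markers$adjusted_p < alpha & markers$log2FC > lfc_min,
                "case_enriched",
                ifelse(markers$adjusted_p < alpha & markers$log2FC < -lfc_min,
                       "control_enriched", "ns"))
  markers$direction <- dir
  case_ids <- markers$genome[dir == "case_enriched"]
  ctrl_ids <- markers$genome[dir == "control_enriched"]
  n_cl <- function(ids) {
    if (is.null(clusters) || !length(ids)) return(NA_integer_)
    length(unique(clusters[ids]))
  }
  list(table = markers, case_enriched = case_ids,
       control_enriched = ctrl_ids,
       n_clusters_case = n_cl(case_ids),
       n_clusters_control = n_cl(ctrl_ids))
}

#' Co-occurrence network from an abundance study
#'
#' Correlations (Pearson by default, Spearman by flag) are computed between
#' genomes on `log10(relative abundance + 1e-6)` across samples; p values
#' come from the t-distribution transform of r and are BH-adjusted over all
#' pairs. Edges require `|r| > r_min` and adjusted p < alpha. Pairs
#' involving a constant vector are skipped with a warning.
#'
#' @param study An `abundance_study` with >= 5 samples.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param r_min Correlation magnitude threshold (default 0.3, strict).
#' @param alpha Adjusted-p threshold (default 0.01).
#' @param pseudo Pseudo-count added to relative abundances (default 1e-6).
#' @return Data frame of edges: `a`, `b`, `r`, `p`, `adjusted_p`, `sign`.
#' @export
cooccurrence_network <- function(study, method = c("pearson", "spearman"),
                                 r_min = 0.3, alpha = 0.01, pseudo = 1e-6) {
  method <- match.arg(method)
  if (ncol(study$counts) < 5L) stop("need at least 5 samples")
  rel <- sweep(study$counts, 2L, study$library_sizes, "/")
  x <- log10(rel + pseudo)
  const <- apply(x, 1L, function(v) sd(v) == 0)
  if (any(const)) {
    warning("constant abundance vector(s) skipped: ",
            paste(rownames(x)[const], collapse = ", "))
    x <- x[!const, , drop = FALSE]
  }
  ids <- rownames(x)
  ng <- length(ids)
  if (ng < 2L) return(data.frame(a = character(0), b = character(0),
                                 r = numeric(0), p = numeric(0),
                                 adjusted_p = numeric(0), sign = character(0)))
  cm <- cor(t(x), method = method)
  iu <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[iu]
  n <- ncol(x)
  tstat <- r * sqrt((n - 2) / pmax(1e-12, 1 - r^2))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  adj <- bh_adjust(p)
  keep <- abs(r) > r_min & adj < alpha
  data.frame(a = ids[iu[keep, 1]], b = ids[iu[keep, 2]],
             r = r[keep], p = p[keep], adjusted_p = adj[keep],
             sign = ifelse(r[keep] > 0, "positive", "negative"),
             row.names = NULL)
}
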