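#' Pearson correlation coefficient
#'
#' Sample Pearson correlation of two equal-length vectors (n >= 3, both
#' with nonzero variance).
#'
#' @param x,y numeric vectors.
#' @return The correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  stats::cor(x, y)
}

#' Two-tailed p-value for a Pearson correlation
#'
#' The t-transform `t = |rho| sqrt(n - 2) / sqrt(1 - rho^2)` referred to a
#' Student-t distribution with `n - 2` degrees of freedom, doubled for the
#' two-tailed test. `p` is strictly decreasing in |rho| at fixed n and in n
#' at fixed rho != 0; `rho = 0` gives `p = 1`; `|rho| = 1` returns the
#' limiting `p = 0` with a warning.
#'
#' @param rho correlation coefficient.
#' @param n number of paired observations (>= 3).
#' @return Two-tailed p-value.
#' @examples
#' pearson_p(-0.42, 43)  # ~0.0051
#' @export
pearson_p <- function(rho, n) {
  if (n < 3) stop("need n >= 3")
  if (abs(rho) > 1) stop("|rho| cannot exceed 1")
  if (abs(rho) == 1) {
    warning("|rho| = 1: returning the limiting p = 0")
    return(0)
  }
  t <- abs(rho) * sqrt(n - 2) / sqrt(1 - rho^2)
  2 * stats::pt(t, df = n - 2, lower.tail = FALSE)
}

match_subjects <- function(a, b) {
  common <- intersect(unique(a$subject), unique(b$subject))
  if (length(common) < 3)
    stop("insufficient cohort: fewer than 3 subjects common to both tables")
  common
}

#' Electrode-wise correlation map
#'
#' Pearson correlation (and two-tailed p) between a resting band-power
#' feature and a behavioral measure, for every (band, channel) cell of the
#' grid - 5 bands x 14 channels = 70 entries for the built-in montage.
#' Subjects are matched by id; subjects missing a cell are dropped
#' pairwise, with the per-cell n recorded.
#'
#' @param features a band-power table from [band_power_table()].
#' @param behavior data frame with `subject` and the behavioral measure.
#' @param measure column of `behavior` to correlate (`"mean_rt_ms"` or
#'   `"accuracy_pct"`).
#' @param condition resting condition to analyze (default eyes-closed, the
#'   condition the biomarker analysis targets).
#' @param power `"relative"` (default: fraction of total 1-46 Hz power) or
#'   `"absolute"` (mean density in uV^2/Hz).
#' @return A `correlation_map` data frame: band, channel, rho, p, n.
#' @export
correlation_map <- function(features, behavior, measure = "mean_rt_ms",
                            condition = "eyes_closed",
                            power = c("relative", "absolute")) {
  power <- match.arg(power)
  if (!measure %in% names(behavior))
    stop("behavior table has no column '", measure, "'")
  feats <- features[features$condition == condition, , drop = FALSE]
  if (nrow(feats) == 0) stop("no rows for condition ", condition)
  common <- match_subjects(feats, behavior)
  behavior <- behavior[match(common, behavior$subject), , drop = FALSE]
  value_col <- if (power == "relative") "relative_power" else
    "absolute_density"
  cells <- unique(feats[, c("band", "channel")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- feats$band == cells$band[i] & feats$channel == cells$channel[i]
    f <- feats[sel, , drop = FALSE]
    m <- match(common, f$subject)
    ok <- !is.na(m)
    x <- f[[value_col]][m[ok]]
    y <- behavior[[measure]][ok]
    n <- sum(ok)
    if (n < 3)
      return(data.frame(band = cells$band[i], channel = cells$channel[i],
                        rho = NA_real_, p = NA_real_, n = n))
    rho <- pearson_r(x, y)
    data.frame(band = cells$band[i], channel = cells$channel[i],
               rho = rho, p = pearson_p(rho, n), n = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "measure") <- measure
  attr(out, "power") <- power
  class(out) <- c("correlation_map", class(out))
  out
}

#' Edge-wise coherence correlation network
#'
#' Pearson correlation between each channel pair's band coherence and a
#' behavioral measure - 5 bands x 91 pairs = 455 edges for the built-in
#' montage - with a significance flag at level `alpha`. The default
#' multiplicity handling is none (each edge tested at alpha uncorrected);
#' a Benjamini-Hochberg switch is provided as an extension.
#'
#' @param edges a coherence edge table from [coherence_edge_table()].
#' @param behavior data frame with `subject` and the behavioral measure.
#' @param measure behavioral column to correlate.
#' @param condition resting condition to analyze.
#' @param alpha significance level.
#' @param method `"none"` (uncorrected, default) or `"BH"`.
#' @return An `edge_correlation_network` data frame: band, ch_i, ch_j,
#'   rho, p, n, significant.
#' @export
edge_correlation_network <- function(edges, behavior,
                                     measure = "mean_rt_ms",
                                     condition = "eyes_closed",
                                     alpha = 0.05,
                                     method = c("none", "BH")) {
  method <- match.arg(method)
  if (!measure %in% names(behavior))
    stop("behavior table has no column '", measure, "'")
  ed <- edges[edges$condition == condition, , drop = FALSE]
  if (nrow(ed) == 0) stop("no rows for condition ", condition)
  common <- match_subjects(ed, behavior)
  behavior <- behavior[match(common, behavior$subject), , drop = FALSE]
  cells <- unique(ed[, c("band", "ch_i", "ch_j")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- ed$band == cells$band[i] & ed$ch_i == cells$ch_i[i] &
      ed$ch_j == cells$ch_j[i]
    e <- ed[sel, , drop = FALSE]
    m <- match(common, e$subject)
    ok <- !is.na(m)
    x <- e$coherence[m[ok]]
    y <- behavior[[measure]][ok]
    n <- sum(ok)
    if (n < 3 || stats::sd(x) == 0)
      return(data.frame(band = cells$band[i], ch_i = cells$ch_i[i],
                        ch_j = cells$ch_j[i], rho = NA_real_, p = NA_real_,
                        n = n))
    rho <- pearson_r(x, y)
    data.frame(band = cells$band[i], ch_i = cells$ch_i[i],
               ch_j = cells$ch_j[i], rho = rho, p = pearson_p(rho, n),
               n = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  padj <- if (method == "BH") stats::p.adjust(out$p, "BH") else out$p
  out$significant <- !is.na(padj) & padj < alpha
  attr(out, "measure") <- measure
  attr(out, "alpha") <- alpha
  class(out) <- c("edge_correlation_network", class(out))
  out
}

#' Eyes-closed versus eyes-open occipital alpha contrast
#'
#' The standard data-quality check: occipital (O1, O2) alpha absolute
#' density is averaged per subject and condition, summarized as group
#' mean and SD per condition, and compared across conditions with the
#' Kruskal-Wallis rank test. Occipital alpha is expected to be higher
#' with eyes closed.
#'
#' @param features a band-power table covering both resting conditions.
#' @param channels occipital channels to average.
#' @return List with `summary` (data frame: condition, mean, sd, n) and
#'   `test` (the [kruskal_wallis()] result).
#' @export
ec_eo_alpha_contrast <- function(features, channels = c("O1", "O2")) {
  sel <- features$band == "alpha" & features$channel %in% channels &
    features$condition %in% c("eyes_closed", "eyes_open")
  f <- features[sel, , drop = FALSE]
  conds <- intersect(c("eyes_closed", "eyes_open"), unique(f$condition))
  if (length(conds) < 2)
    stop("both eyes-closed and eyes-open conditions are required")
  subj_means <- stats::aggregate(
    absolute_density ~ subject + condition, data = f, FUN = mean)
  missing <- setdiff(unique(subj_means$subject[subj_means$condition ==
                                                 conds[1]]),
                     unique(subj_means$subject[subj_means$condition ==
                                                 conds[2]]))
  if (length(missing) > 0)
    stop("subjects missing a condition: ", paste(missing, collapse = ", "))
  groups <- split(subj_means$absolute_density, subj_means$condition)
  summary <- do.call(rbind, lapply(conds, function(cn) {
    data.frame(condition = cn, mean = mean(groups[[cn]]),
               sd = stats::sd(groups[[cn]]), n = length(groups[[cn]]),
               stringsAsFactors = FALSE)
  }))
  list(summary = summary, test = kruskal_wallis(groups))
}
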