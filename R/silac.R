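#' Read a peptide-level SILAC table
#'
#' Expects a tab-separated file with header columns `sequence`, `ratio_hl`,
#' `intensity` and `protein`.
#'
#' @param path TSV file.
#' @return Data frame with those columns plus `serine_count` (number of
#'   'S' residues per sequence).
#' @export
read_peptides_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sequence", "ratio_hl", "intensity", "protein")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("peptide table lacks column(s): ", paste(miss, collapse = ", "))
  }
  df$serine_count <- serine_count(df$sequence)
  df
}

serine_count <- function(sequence) {
  vapply(gregexpr("S", sequence, fixed = TRUE), function(m) {
    if (m[1] == -1L) 0L else length(m)
  }, integer(1))
}

#' Keep single-serine peptides with valid ratios
#'
#' Incorporation is only interpretable for peptides carrying exactly one
#' serine; peptides with missing or non-positive heavy/light ratios carry no
#' signal. Input order is preserved; an empty result is allowed.
#'
#' @param peptides data frame with `sequence` and `ratio_hl` columns
#'   (`serine_count` is computed if absent).
#' @return The filtered data frame.
#' @export
filter_single_serine <- function(peptides) {
  if (is.null(peptides$serine_count)) {
    peptides$serine_count <- serine_count(peptides$sequence)
  }
  keep <- peptides$serine_count == 1L &
    is.finite(peptides$ratio_hl) & peptides$ratio_hl > 0
  peptides[which(keep), , drop = FALSE]
}

#' Convert a heavy/light ratio to an incorporation fraction
#'
#' Two formulas are provided. The default, `"as-printed"`, is
#' \eqn{1 - 1/(r - 1)}; it is undefined at \eqn{r = 1} (returned as `NA`
#' with a warning, and such records are excluded downstream). The
#' alternative, `"ratio-over-ratio-plus-one"`, is the standard
#' incorporation-check identity \eqn{r/(r + 1)}. Both are strictly
#' increasing in the ratio with limit 1; values falling outside \[0, 1\]
#' are returned as computed so the caller can flag them.
#'
#' @param ratio_hl positive heavy/light ratio(s).
#' @param formula which formula to apply.
#' @return Numeric vector of incorporation fractions.
#' @export
#' @examples
#' incorporation_from_ratio(11)                                   # 0.9
#' incorporation_from_ratio(15, "ratio-over-ratio-plus-one")      # 0.9375
incorporation_from_ratio <- function(ratio_hl,
                                     formula = c("as-printed",
                                                 "ratio-over-ratio-plus-one")) {
  formula <- match.arg(formula)
  bad <- !is.finite(ratio_hl) | ratio_hl <= 0
  if (any(bad)) stop("ratio_hl must be finite and positive")
  if (formula == "as-printed") {
    undef <- ratio_hl == 1
    if (any(undef)) {
      warning(sum(undef),
              " ratio(s) equal to 1 are undefined under the as-printed ",
              "formula and returned as NA")
    }
    out <- ifelse(undef, NA_real_, 1 - 1 / (ratio_hl - 1))
  } else {
    out <- ratio_hl / (ratio_hl + 1)
  }
  out
}

#' Estimate the incorporation level of a strain
#'
#' The incorporation level is the location of the maximum of a Gaussian
#' kernel density over the per-peptide incorporation values (bandwidth by
#' Silverman's rule unless overridden; 512 grid points spanning the data
#' plus three bandwidths on either side). Ties resolve to the lowest grid
#' point and are flagged. As a secondary statistic the fraction of peptides
#' with incorporation above one half (`labeled_fraction`) is reported.
#'
#' @param values incorporation fractions; at least 10 finite values.
#' @param bandwidth `"auto"` (Silverman) or a numeric bandwidth.
#' @param strain optional strain label.
#' @return An `incorporation_estimate`: list with `strain`, `level`
#'   (fraction in \[0, 1\]), `labeled_fraction`, `density` (data frame `x`,
#'   `y`), `bandwidth`, `n`, `tied`.
#' @export
incorporation_level <- function(values, bandwidth = "auto", strain = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 10L) {
    stop("need at least 10 finite incorporation values (got ",
         length(values), "); the density estimate is unstable")
  }
  dens <- if (identical(bandwidth, "auto")) {
    stats::density(values, bw = "nrd0", n = 512, cut = 3)
  } else {
    stats::density(values, bw = bandwidth, n = 512, cut = 3)
  }
  imax <- which.max(dens$y)  # first index: lowest grid point on ties
  tied <- sum(abs(dens$y - dens$y[imax]) < .Machine$double.eps^0.5) > 1L
  level <- if (diff(range(values)) == 0) values[1] else dens$x[imax]
  structure(list(
    strain = strain,
    level = level,
    labeled_fraction = mean(values > 0.5),
    density = data.frame(x = dens$x, y = dens$y),
    bandwidth = dens$bw,
    n = length(values),
    tied = tied
  ), class = "incorporation_estimate")
}

#' @export
print.incorporation_estimate <- function(x, ...) {
  cat(sprintf(
    "incorporation_estimate%s: level %.1f%% (n = %d, bw = %.4f)\n",
    if (is.null(x$strain)) "" else paste0(" [", x$strain, "]"),
    100 * x$level, x$n, x$bandwidth))
  invisible(x)
}

#' Estimate incorporation from a peptide table
#'
#' Convenience wrapper: filters to single-serine peptides with valid
#' ratios, converts ratios to incorporation fractions, drops records where
#' the formula is undefined, and estimates the level.
#'
#' @param peptides peptide data frame (see [read_peptides_tsv()]).
#' @inheritParams incorporation_from_ratio
#' @inheritParams incorporation_level
#' @return An [incorporation_level()] estimate.
#' @export
estimate_incorporation <- function(peptides,
                                   formula = c("as-printed",
                                               "ratio-over-ratio-plus-one"),
                                   bandwidth = "auto", strain = NULL) {
  formula <- match.arg(formula)
  flt <- filter_single_serine(peptides)
  vals <- suppressWarnings(
    incorporation_from_ratio(flt$ratio_hl, formula = formula))
  incorporation_level(vals[is.finite(vals)], bandwidth = bandwidth,
                      strain = strain)
}

#' Percent change in incorporation level between strains
#'
#' Reports the decrease of the test strain relative to the reference as a
#' positive percentage: \eqn{100 (ref - test)/ref}.
#'
#' @param test,reference [incorporation_level()] estimates or bare levels
#'   in (0, 1].
#' @return Percent decrease (negative when the test strain is higher).
#' @export
incorporation_change <- function(test, reference) {
  lvl <- function(x) if (inherits(x, "incorporation_estimate")) x$level else x
  t0 <- lvl(test); r0 <- lvl(reference)
  stopifnot(t0 > 0, t0 <= 1, r0 <= 1)
  if (r0 <= 0) stop("reference incorporation level must be positive")
  100 * (r0 - t0) / r0
}

#' Intensity-dependent outlier calling on protein SILAC ratios
#'
#' Flags proteins whose log2 SILAC ratio is extreme relative to proteins of
#' similar abundance. Proteins are sorted into equal-count intensity bins
#' (default 300 per bin); within each bin the spread is estimated robustly
#' from the distances of the 15.87th and 84.13th percentiles to the median
#' (one-sided robust standard deviations), each protein gets a z-score
#' against the spread on its side, and a two-sided normal tail p-value.
#' Tiers at p < 1e-11, p < 1e-4 and p < 0.05 are nested by construction.
#'
#' @param proteins data frame with columns `protein`, `ratio`, `intensity`
#'   (at least 50 rows with finite values).
#' @param bin_size target proteins per intensity bin.
#' @param tiers p-value cutoffs, strongest first.
#' @return Data frame with `protein`, `ratio`, `intensity`, `log2_ratio`,
#'   `z`, `p_value` and ordered factor `tier`
#'   (`"p<1e-11" < "p<1e-04" < "p<0.05" < "ns"` by severity).
#' @export
intensity_dependent_outliers <- function(proteins, bin_size = 300,
                                         tiers = c(1e-11, 1e-4, 0.05)) {
  need <- c("protein", "ratio", "intensity")
  miss <- setdiff(need, names(proteins))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  ok <- is.finite(proteins$ratio) & proteins$ratio > 0 &
    is.finite(proteins$intensity)
  proteins <- proteins[ok, , drop = FALSE]
  n <- nrow(proteins)
  if (n < 50L) {
    stop("need at least 50 proteins with finite ratio and intensity (got ",
         n, ")")
  }
  ord <- order(proteins$intensity)
  nbin <- max(1L, floor(n / bin_size))
  bin <- integer(n)
  bin[ord] <- pmin(nbin, 1L + floor((seq_len(n) - 1L) * nbin / n))
  l2 <- log2(proteins$ratio)
  z <- numeric(n)
  for (b in seq_len(nbin)) {
    i <- which(bin == b)
    med <- stats::median(l2[i])
    qs <- stats::quantile(l2[i], c(0.1587, 0.8413), names = FALSE)
    sd_dn <- med - qs[1]
    sd_up <- qs[2] - med
    dev <- l2[i] - med
    side_sd <- ifelse(dev >= 0, sd_up, sd_dn)
    z[i] <- ifelse(abs(dev) < .Machine$double.eps, 0,
                   ifelse(side_sd > 0, dev / side_sd, Inf * sign(dev)))
  }
  p <- pmin(1, 2 * stats::pnorm(-abs(z)))
  labs <- c(paste0("p<", vapply(tiers, function(t) {
    if (t >= 0.01) format(t) else sprintf("%.0e", t)
  }, "")), "ns")
  tier <- labs[findInterval(p, c(0, tiers)) ]
  out <- data.frame(protein = proteins$protein, ratio = proteins$ratio,
                    intensity = proteins$intensity, log2_ratio = l2,
                    z = z, p_value = p,
                    tier = factor(tier, levels = labs, ordered = TRUE),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
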