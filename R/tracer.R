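#' Uptake time-course quantification
#'
#' Converts background-subtracted scintillation counts into transported
#' serine per mg of protein. Per-time uptake is
#' `max(counts - background, 0) / specific_activity / protein_mg`
#' (nmol/mg); negative background-subtracted counts clamp to zero with a
#' warning, since transport cannot be negative. The initial rate is read at
#' `rate_time` minutes (default 5, the usual comparison point) as
#' uptake/time, or from a linear fit through the origin over all time
#' points with `fit = "linear"`. Replicates are aggregated as mean,
#' standard deviation and n.
#'
#' @param tc data frame with columns `strain`, `replicate`, `time_min`,
#'   `counts`, `background`, `protein_mg`, `specific_activity` (as produced
#'   by [simulate_uptake()] or [read_uptake_csv()]).
#' @param rate_time time point (min) for the initial rate.
#' @param fit `"point"` (default) or `"linear"`.
#' @return List with `uptake` (per sample and time, nmol/mg) and `rates`
#'   (per strain: `mean_rate`, `sd_rate`, `n`, nmol/mg/min).
#' @export
uptake_rate <- function(tc, rate_time = 5, fit = c("point", "linear")) {
  fit <- match.arg(fit)
  need <- c("strain", "replicate", "time_min", "counts", "background",
            "protein_mg", "specific_activity")
  miss <- setdiff(need, names(tc))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  stopifnot(all(tc$specific_activity > 0), all(tc$protein_mg > 0),
            all(tc$counts >= 0))
  net <- tc$counts - tc$background
  if (all(net <= 0)) {
    warning("background exceeds counts at all times; uptake is all zero")
  } else if (any(net < 0)) {
    warning(sum(net < 0),
            " background-subtracted count(s) were negative and clamped to 0")
  }
  tc$uptake_nmol_mg <- pmax(net, 0) / tc$specific_activity / tc$protein_mg
  key <- interaction(tc$strain, tc$replicate, drop = TRUE)
  per_rep <- vapply(split(seq_len(nrow(tc)), key), function(i) {
    sub <- tc[i, ]
    if (fit == "point") {
      j <- which(sub$time_min == rate_time)
      if (!length(j)) {
        stop("no observation at rate_time = ", rate_time, " min")
      }
      sub$uptake_nmol_mg[j[1]] / rate_time
    } else {
      sum(sub$uptake_nmol_mg * sub$time_min) / sum(sub$time_min^2)
    }
  }, numeric(1))
  strain_of <- vapply(split(tc$strain, key), `[`, "", 1)
  rates <- do.call(rbind, lapply(split(per_rep, strain_of), function(v) {
    data.frame(mean_rate = mean(v), sd_rate = stats::sd(v), n = length(v))
  }))
  rates <- data.frame(strain = rownames(rates), rates,
                      row.names = NULL, stringsAsFactors = FALSE)
  list(uptake = tc, rates = rates)
}

#' Read an uptake time-course CSV
#' @param path CSV with the columns documented in [uptake_rate()].
#' @return Data frame.
#' @export
read_uptake_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Percent reduction of a test value relative to a reference
#'
#' \eqn{100 (ref - test)/ref}: positive when the test value is lower.
#' Note the asymmetry: swapping test and reference changes the magnitude,
#' not just the sign.
#'
#' @param test,reference numeric values; `reference` must be positive.
#' @return Percent reduction.
#' @export
#' @examples
#' percent_reduction(3.5, 10)  # 65
percent_reduction <- function(test, reference) {
  if (any(reference <= 0)) stop("reference must be positive")
  100 * (reference - test) / reference
}

#' Percent change of a test value relative to a reference
#'
#' \eqn{100 (test - ref)/ref}: positive for an increase.
#'
#' @inheritParams percent_reduction
#' @return Percent change.
#' @export
percent_change <- function(test, reference) {
  if (any(reference <= 0)) stop("reference must be positive")
  100 * (test - reference) / reference
}

#' Internal-standard amino-acid quantification
#'
#' Converts LC-MS peak areas to concentrations via the norleucine internal
#' standard: `nmol per 1e8 cells = (area / IS area) * calibration /
#' cells_1e8`. Calibration factors come from a standard amino-acid mixture
#' and are required per analyte.
#'
#' @param peaks data frame with columns `sample`, `analyte`, `area`,
#'   `cells_1e8`, plus optional grouping columns carried through; internal
#'   standard rows have `analyte == is_analyte`.
#' @param calibration named numeric vector of calibration factors
#'   (nmol-equivalents per IS-normalized area unit), one per analyte.
#' @param analyte analyte(s) to quantify; default all calibrated ones.
#' @param is_analyte internal-standard name (default `"norleucine"`).
#' @return Data frame with `sample`, `analyte`, `nmol_per_1e8_cells` and
#'   any carried grouping columns.
#' @export
amino_acid_concentration <- function(peaks, calibration, analyte = NULL,
                                     is_analyte = "norleucine") {
  need <- c("sample", "analyte", "area", "cells_1e8")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(analyte)) {
    analyte <- setdiff(unique(peaks$analyte), is_analyte)
  }
  uncal <- setdiff(analyte, names(calibration))
  if (length(uncal)) {
    stop("no calibration factor for analyte(s): ",
         paste(uncal, collapse = ", "))
  }
  if (any(calibration[analyte] <= 0)) stop("calibration factors must be > 0")
  is_rows <- peaks[peaks$analyte == is_analyte, ]
  if (!nrow(is_rows)) stop("no internal-standard ('", is_analyte, "') rows")
  is_area <- stats::setNames(is_rows$area, is_rows$sample)
  if (any(is_area <= 0)) stop("internal-standard area must be positive")
  out <- peaks[peaks$analyte %in% analyte, , drop = FALSE]
  no_is <- setdiff(unique(out$sample), names(is_area))
  if (length(no_is)) {
    stop("sample(s) without internal standard: ", paste(no_is, collapse = ", "))
  }
  stopifnot(all(out$cells_1e8 > 0))
  out$nmol_per_1e8_cells <- out$area / is_area[out$sample] *
    calibration[out$analyte] / out$cells_1e8
  rownames(out) <- NULL
  out
}

#' Two-condition comparison of replicate measurements
#'
#' Mean, standard deviation, percent change of the test-condition mean
#' relative to the reference mean, and a Welch two-sample t-test.
#'
#' @param test,reference numeric replicate values.
#' @return List with `mean_test`, `mean_reference`, `sd_test`,
#'   `sd_reference`, `n_test`, `n_reference`, `percent_change`, `p_value`.
#' @export
compare_conditions <- function(test, reference) {
  tt <- stats::t.test(test, reference)
  list(mean_test = mean(test), mean_reference = mean(reference),
       sd_test = stats::sd(test), sd_reference = stats::sd(reference),
       n_test = length(test), n_reference = length(reference),
       percent_change = percent_change(mean(test), mean(reference)),
       p_value = tt$p.value)
}

#' Labeled-lipid mole percentage
#'
#' Mole percent of a (lipid class, label channel) cell relative to all
#' detected lipids of the sample: `100 * sum(amount in class/channel) /
#' sum(all amounts)`. Over all cells of a sample the values add to 100.
#'
#' @param table data frame with columns `sample`, `class`, `channel`,
#'   `amount` (and optionally `strain`, carried through).
#' @param class,channel optional filters; default all combinations.
#' @return Data frame with `sample` (and `strain` if present), `class`,
#'   `channel`, `mol_percent`.
#' @export
#' @examples
#' tab <- simulate_lipid_table()
#' head(lipid_label_molpercent(tab, class = "IPC", channel = "serine"))
lipid_label_molpercent <- function(table, class = NULL, channel = NULL) {
  need <- c("sample", "class", "channel", "amount")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(table)) stop("empty lipid table")
  stopifnot(all(table$amount >= 0))
  totals <- tapply(table$amount, table$sample, sum)
  if (any(totals <= 0)) {
    stop("sample(s) with zero total lipid: ",
         paste(names(totals)[totals <= 0], collapse = ", "))
  }
  agg <- stats::aggregate(amount ~ sample + class + channel, data = table,
                          FUN = sum)
  agg$mol_percent <- 100 * agg$amount / as.numeric(totals[agg$sample])
  if (!is.null(table$strain)) {
    map <- unique(table[, c("sample", "strain")])
    agg$strain <- map$strain[match(agg$sample, map$sample)]
  }
  if (!is.null(class)) agg <- agg[agg$class %in% class, , drop = FALSE]
  if (!is.null(channel)) agg <- agg[agg$channel %in% channel, , drop = FALSE]
  if (length(class) == 1L && length(channel) == 1L) {
    # a cell absent from a sample is a measured zero, not missing data
    absent <- setdiff(names(totals), agg$sample)
    if (length(absent)) {
      fill <- data.frame(sample = absent, class = class, channel = channel,
                         amount = 0, mol_percent = 0,
                         stringsAsFactors = FALSE)
      if (!is.null(table$strain)) {
        map <- unique(table[, c("sample", "strain")])
        fill$strain <- map$strain[match(fill$sample, map$sample)]
        fill <- fill[, names(agg)]
      }
      agg <- rbind(agg, fill)
    }
  }
  agg$amount <- NULL
  rownames(agg) <- NULL
  agg
}

#' Mean labeled mole percent per strain
#'
#' Replicate mean of [lipid_label_molpercent()] for one class/channel cell.
#'
#' @inheritParams lipid_label_molpercent
#' @return Data frame `strain`, `mean_mol_percent`, `sd_mol_percent`, `n`.
#' @export
lipid_label_summary <- function(table, class, channel) {
  mp <- lipid_label_molpercent(table, class = class, channel = channel)
  if (is.null(mp$strain)) stop("table lacks a 'strain' column to average over")
  out <- do.call(rbind, lapply(split(mp$mol_percent, mp$strain), function(v) {
    data.frame(mean_mol_percent = mean(v),
               sd_mol_percent = stats::sd(v), n = length(v))
  }))
  data.frame(strain = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Long-chain-base quantification and fold change
#'
#' Absolute amounts from the spiked internal standard:
#' `pmol/mg = intensity / IS intensity * IS spiked pmol / protein mg`;
#' fold changes are relative to the reference sample per species. A zero
#' reference amount leaves the fold change `NA` with a warning.
#'
#' @param samples data frame with columns `sample`, `species`, `intensity`,
#'   `is_intensity`, `is_pmol`, `protein_mg`.
#' @param reference reference sample id (e.g. the wild type).
#' @return Data frame with `sample`, `species`, `pmol_per_mg`,
#'   `fold_change`.
#' @export
lcb_fold_change <- function(samples, reference) {
  need <- c("sample", "species", "intensity", "is_intensity", "is_pmol",
            "protein_mg")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  stopifnot(all(samples$is_intensity > 0), all(samples$protein_mg > 0))
  if (!reference %in% samples$sample) {
    stop("reference sample '", reference, "' not present")
  }
  samples$pmol_per_mg <- samples$intensity / samples$is_intensity *
    samples$is_pmol / samples$protein_mg
  ref <- samples[samples$sample == reference, ]
  refamt <- stats::setNames(ref$pmol_per_mg, ref$species)
  fold <- refamt[samples$species]
  if (any(is.na(fold))) {
    stop("species missing from the reference sample: ",
         paste(unique(samples$species[is.na(fold)]), collapse = ", "))
  }
  zero <- fold == 0
  if (any(zero)) {
    warning("reference amount is zero for some species; fold change is NA")
  }
  samples$fold_change <- ifelse(zero, NA_real_,
                                samples$pmol_per_mg / fold)
  rownames(samples) <- NULL
  samples
}
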