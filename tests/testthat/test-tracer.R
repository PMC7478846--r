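test_that("uptake quantification follows the counting arithmetic", {
  tc <- simulate_uptake(rates = c(WT = 10), noise_sd = 0, seed = 1)
  # counts equal to background give zero uptake everywhere
  flat <- tc
  flat$counts <- flat$background
  expect_warning(r0 <- uptake_rate(flat), "all zero")
  expect_true(all(r0$uptake$uptake_nmol_mg == 0))
  # noise-free counts recover the programmed rate exactly
  r <- uptake_rate(tc)
  expect_equal(r$rates$mean_rate, 10, tolerance = 1e-12)
  expect_equal(r$rates$sd_rate, 0)
  # doubling protein mass at fixed counts halves per-mg uptake
  half <- tc
  half$protein_mg <- 2 * half$protein_mg
  expect_equal(uptake_rate(half)$uptake$uptake_nmol_mg,
               r$uptake$uptake_nmol_mg / 2)
  # the linear-fit rate agrees with the point rate on linear data
  expect_equal(uptake_rate(tc, fit = "linear")$rates$mean_rate, 10,
               tolerance = 1e-12)
})

test_that("the default study rates yield the expected strain reductions", {
  r <- uptake_rate(simulate_uptake(noise_sd = 0, seed = 2))$rates
  rate <- stats::setNames(r$mean_rate, r$strain)
  expect_equal(percent_reduction(rate[["gnp1"]], rate[["WT"]]), 65)
  expect_equal(percent_reduction(rate[["agp1"]], rate[["WT"]]), 34)
  expect_gt(percent_reduction(rate[["gnp1agp1"]], rate[["WT"]]), 90)
})

test_that("percent reduction and change behave at the edges", {
  expect_equal(percent_reduction(3.5, 10), 65)
  expect_equal(percent_reduction(7, 7), 0)
  expect_equal(percent_reduction(0, 4), 100)
  expect_error(percent_reduction(1, 0), "positive")
  expect_equal(percent_change(5, 4), 25)
  # reduction is not antisymmetric in value, only in sign of the difference
  expect_equal(percent_reduction(5, 10), 50)
  expect_equal(percent_reduction(10, 5), -100)
})

test_that("amino-acid concentrations follow the internal-standard arithmetic", {
  peaks <- data.frame(
    sample = rep(c("s1", "s2"), each = 2),
    analyte = rep(c("serine", "norleucine"), 2),
    area = c(100, 100, 100, 100),
    cells_1e8 = c(1, 1, 2, 2)
  )
  conc <- amino_acid_concentration(peaks, c(serine = 1))
  # area equal to IS area, calibration 1, 1e8 cells: 1 nmol/1e8 cells
  expect_equal(conc$nmol_per_1e8_cells[conc$sample == "s1"], 1)
  # doubling the cell count halves the concentration
  expect_equal(conc$nmol_per_1e8_cells[conc$sample == "s2"], 0.5)
  expect_error(amino_acid_concentration(peaks, c(glycine = 1),
                                        analyte = "serine"),
               "serine")
  expect_error(
    amino_acid_concentration(peaks[peaks$analyte != "norleucine", ],
                             c(serine = 1)),
    "internal-standard")
})

test_that("condition comparisons report percent change and a Welch test", {
  set.seed(4)
  a <- c(5.0, 5.1, 4.9)
  b <- c(3.0, 3.05, 2.95)
  cmp <- compare_conditions(a, b)
  expect_equal(cmp$percent_change, 100 * (mean(a) - mean(b)) / mean(b))
  expect_lt(cmp$p_value, 0.01)
  expect_equal(cmp$n_test, 3)
})

test_that("lipid mole percentages partition each sample to 100", {
  tab <- simulate_lipid_table(seed = 1)
  mp <- lipid_label_molpercent(tab)
  sums <- tapply(mp$mol_percent, mp$sample, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  # single labeled row is the whole sample
  one <- data.frame(sample = "x", class = "IPC", channel = "serine",
                    amount = 0.3)
  expect_equal(lipid_label_molpercent(one)$mol_percent, 100)
  # an absent channel is a measured zero
  z <- lipid_label_molpercent(one, class = "IPC", channel = "inositol")
  expect_equal(z$mol_percent, 0)
  expect_error(lipid_label_molpercent(one[0, ]), "empty")
  allzero <- one
  allzero$amount <- 0
  expect_error(lipid_label_molpercent(allzero), "zero total")
})

test_that("the default labeled fractions encode the strain decreases exactly", {
  tab <- simulate_lipid_table(seed = 3)   # deterministic amounts
  s <- lipid_label_summary(tab, "IPC", "serine")
  m <- stats::setNames(s$mean_mol_percent, s$strain)
  expect_equal(percent_reduction(m[["gnp1"]], m[["WT"]]), 64)
  expect_equal(percent_reduction(m[["gnp1agp1"]], m[["WT"]]), 73)
  expect_lt(abs(percent_reduction(m[["ser2"]], m[["WT"]])), 10)
})

test_that("long-chain-base amounts and fold changes track the internal standard", {
  lcb <- data.frame(
    sample = rep(c("WT", "mut", "same"), each = 2),
    species = rep(c("PHS", "DHS"), 3),
    intensity = c(100, 50, 40, 20, 100, 50),
    is_intensity = c(10, 10, 10, 10, 10, 10),
    is_pmol = 5,
    protein_mg = 0.5
  )
  out <- lcb_fold_change(lcb, reference = "WT")
  # amount = intensity / IS * spiked pmol / protein
  expect_equal(out$pmol_per_mg[out$sample == "WT" & out$species == "PHS"],
               100 / 10 * 5 / 0.5)
  # identical sample has fold change 1; the 40% sample reads 0.4
  expect_true(all(out$fold_change[out$sample == "same"] == 1))
  expect_true(all(out$fold_change[out$sample == "mut"] == 0.4))
  # doubling IS intensity halves the computed amount
  dbl <- lcb
  dbl$is_intensity <- 2 * dbl$is_intensity
  expect_equal(lcb_fold_change(dbl, "WT")$pmol_per_mg, out$pmol_per_mg / 2)
  # three replicates with programmed truth recover exactly
  truth <- c(r1 = 12, r2 = 30, r3 = 7.5)
  rep3 <- data.frame(sample = names(truth), species = "PHS",
                     intensity = truth * 0.5 / 5 * 20,
                     is_intensity = 20, is_pmol = 5, protein_mg = 0.5)
  expect_equal(lcb_fold_change(rep3, "r1")$pmol_per_mg, unname(truth))
  expect_error(lcb_fold_change(lcb, "absent"), "not present")
  zero <- lcb
  zero$intensity[zero$sample == "WT"] <- 0
  expect_warning(fz <- lcb_fold_change(zero, "WT"), "zero")
  expect_true(all(is.na(fz$fold_change[fz$sample == "mut"])))
})
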