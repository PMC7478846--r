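# Deterministic synthetic-data generators. Every generator draws from its
# own random stream (derived from the user seed plus the generator name), so
# adding a generator never perturbs fixtures produced by another, and the
# caller's RNG state is left untouched.

generator_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + as.numeric(seed)) %% 2147483647)
}

with_generator_seed <- function(seed, name, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(generator_seed(seed, name))
  force(code)
}

# attach ground truth and optionally write table + sidecar truth JSON
deliver_table <- function(df, truth, path = NULL, sep = ",") {
  attr(df, "truth") <- truth
  if (!is.null(path)) {
    utils::write.table(df, path, sep = sep, row.names = FALSE,
                       quote = FALSE)
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  df
}

#' Read the ground-truth sidecar of a generated table
#'
#' @param path path of the generated table (the sidecar is
#'   `<path>.truth.json`).
#' @return The truth list stored by the generator.
#' @export
read_truth <- function(path) {
  jsonlite::read_json(paste0(path, ".truth.json"), simplifyVector = TRUE)
}

#' Small stoichiometric test networks
#'
#' Constructs toy metabolic models whose flux variability envelopes are
#' known analytically (chain, parallel, yield-loss) or tractable for the
#' exhaustive vertex oracle (random). Random networks carry a backbone
#' uptake-conversion-biomass chain, so a nonzero biomass optimum exists by
#' construction; extra random reactions can always carry zero flux.
#'
#' @param kind `"chain"`, `"parallel"`, `"yield-loss"` or `"random"`.
#' @param size number of reactions for `"random"` (at most 8, to keep the
#'   vertex oracle exhaustive); for `"chain"`, the chain length including
#'   exchange and biomass (at least 3).
#' @param seed integer seed (random kind only); identical seeds give
#'   identical models.
#' @return A [metabolic_model()].
#' @export
#' @examples
#' fba_maximize(toy_network("chain"))$objective_value   # 10
toy_network <- function(kind = c("chain", "parallel", "yield-loss", "random"),
                        size = 3, seed = 1) {
  kind <- match.arg(kind)
  if (kind == "chain") {
    stopifnot(size >= 3)
    nmet <- size - 1L
    mets <- paste0("M", seq_len(nmet))
    rxn <- c("EX_M1", paste0("R", seq_len(nmet - 1L)), "BIOMASS")
    S <- matrix(0, nmet, size, dimnames = list(mets, rxn))
    S["M1", "EX_M1"] <- -1
    for (i in seq_len(nmet - 1L)) {
      S[i, i + 1L] <- -1
      S[i + 1L, i + 1L] <- 1
    }
    S[nmet, "BIOMASS"] <- -1
    return(metabolic_model(S, lb = c(-10, rep(0, size - 1L)),
                           ub = c(0, rep(1000, size - 1L)),
                           objective = "BIOMASS"))
  }
  if (kind == "parallel") {
    S <- cbind(EX_A = c(A = -1, B = 0),
               R1 = c(-1, 1), R2 = c(-1, 1),
               BIOMASS = c(0, -1))
    return(metabolic_model(S, lb = c(-10, 0, 0, 0),
                           ub = c(0, 1000, 1000, 1000),
                           objective = "BIOMASS"))
  }
  if (kind == "yield-loss") {
    S <- cbind(EX_A = c(A = -1, B = 0),
               R_HI = c(-1, 1),            # full yield
               R_LO = c(-1, 0.5),          # half yield
               BIOMASS = c(0, -1))
    return(metabolic_model(S, lb = c(-10, 0, 0, 0),
                           ub = c(0, 1000, 1000, 1000),
                           objective = "BIOMASS"))
  }
  stopifnot(size <= 8, size >= 3)
  with_generator_seed(seed, paste0("toy_network_random_", size), {
    for (try in 1:25) {
      nmet <- sample(2:min(4L, size - 1L), 1)
      mets <- paste0("M", seq_len(nmet))
      nextra <- size - 2L - (nmet - 1L)
      if (nextra < 0) next
      rxn <- c("EX_M1", paste0("C", seq_len(nmet - 1L)),
               if (nextra > 0) paste0("X", seq_len(nextra)), "BIOMASS")
      S <- matrix(0, nmet, length(rxn), dimnames = list(mets, rxn))
      S["M1", "EX_M1"] <- -1
      for (i in seq_len(nmet - 1L)) {
        S[i, 1L + i] <- -sample(1:2, 1)
        S[i + 1L, 1L + i] <- sample(1:2, 1)
      }
      if (nextra > 0) {
        for (k in seq_len(nextra)) {
          picked <- sample(nmet, sample(1:min(3L, nmet), 1))
          S[picked, nmet + k] <- sample(c(-2, -1, 1, 2), length(picked),
                                        replace = TRUE)
        }
      }
      S[nmet, "BIOMASS"] <- -1
      lb <- c(-round(stats::runif(1, 4, 10), 1),
              rep(0, length(rxn) - 1L))
      ub <- c(0, round(stats::runif(length(rxn) - 1L, 5, 20), 1))
      rev <- which(colnames(S) %in% paste0("X", seq_len(max(nextra, 0))))
      lb[rev] <- -ub[rev]
      m <- metabolic_model(S, lb, ub, objective = "BIOMASS")
      sol <- fba_maximize(m)
      if (identical(sol$status, "optimal") && sol$objective_value > 1e-6) {
        return(m)
      }
    }
    stop("failed to draw a feasible random network")
  })
}

#' The shipped serine toy model
#'
#' A fixed 11-reaction, 8-metabolite model of the main serine-producing and
#' -consuming processes in yeast: glucose uptake feeding a lumped
#' glycolysis, the 3-phosphoglycerate serine-synthesis branch (Ser1/Ser2),
#' the reversible serine hydroxymethyltransferase route (Shm1/Shm2,
#' serine to glycine plus a one-carbon unit), a protein-synthesis drain,
#' serine palmitoyltransferase (SPT) condensing serine with palmitoyl-CoA
#' into a long-chain base, and a biomass reaction consuming protein,
#' long-chain base and glycine. Stoichiometry and bounds are chosen so that
#' along a serine-uptake scan the net serine-production envelope changes
#' sign: biosynthesis dominates at low uptake, and excess imported serine is
#' converted to glycine at high uptake.
#'
#' @return A [metabolic_model()].
#' @export
#' @examples
#' serine_toy_model()
serine_toy_model <- function() {
  mets <- c("glc", "pg3", "ser", "gly", "c1", "palmcoa", "lcb", "prot")
  rxn <- list(
    EX_glc = c(glc = -1),
    EX_ser = c(ser = -1),
    EX_gly = c(gly = -1),
    GLYC = c(glc = -1, pg3 = 2),
    SER_SYNTH = c(pg3 = -1, ser = 1),
    SHM = c(ser = -1, gly = 1, c1 = 1),
    FAS = c(pg3 = -2, palmcoa = 1),
    SPT = c(ser = -1, palmcoa = -1, lcb = 1),
    PROT_SYNTH = c(ser = -0.5, pg3 = -0.5, prot = 1),
    C1_SINK = c(c1 = -1),
    BIOMASS = c(prot = -1, lcb = -0.1, gly = -0.5)
  )
  S <- matrix(0, length(mets), length(rxn),
              dimnames = list(mets, names(rxn)))
  for (j in seq_along(rxn)) S[names(rxn[[j]]), j] <- rxn[[j]]
  lb <- stats::setNames(rep(0, length(rxn)), names(rxn))
  ub <- stats::setNames(rep(1000, length(rxn)), names(rxn))
  lb["EX_glc"] <- -2; ub["EX_glc"] <- 0
  lb["SHM"] <- -1000
  gpr <- stats::setNames(rep("", length(rxn)), names(rxn))
  gpr["SER_SYNTH"] <- "SER1 and SER2"
  gpr["SHM"] <- "SHM1 or SHM2"
  gpr["SPT"] <- "LCB1 and LCB2"
  metabolic_model(S, lb, ub, objective = "BIOMASS", gpr = unname(gpr))
}

#' Standard flux targets for the serine toy model
#'
#' `ser2`: the serine-synthesis branch; `shm`: net serine production by the
#' hydroxymethyltransferase route (negative when serine is converted to
#' glycine); `spt`: flux into sphingolipid synthesis; `net`: the combined
#' net serine production of synthesis plus the Shm route.
#'
#' @return Named list of [flux_target()]s.
#' @export
serine_scan_targets <- function() {
  list(
    ser2 = flux_target("ser2", c(SER_SYNTH = 1)),
    shm = flux_target("shm", c(SHM = -1)),
    spt = flux_target("spt", c(SPT = 1)),
    net = flux_target("net", c(SER_SYNTH = 1, SHM = -1))
  )
}

#' Serine-incorporation levels of the study strains
#'
#' The per-strain incorporation levels used as generator defaults: wild
#' type 93.8%, the serine auxotroph (ser2) 92.7%, the gnp1 permease
#' deletion 59%, the agp1 deletion 90.8%, and the double permease deletion
#' at an 81% decrease from wild type.
#'
#' @return Named numeric vector of incorporation fractions.
#' @export
silac_strain_levels <- function() {
  c(WT = 0.938, ser2 = 0.927, gnp1 = 0.59, agp1 = 0.908,
    gnp1agp1 = 0.938 * (1 - 0.81))
}

#' Simulate a SILAC peptide table with known incorporation level
#'
#' Peptide sequences carry 0-3 serines; single-serine peptides receive H/L
#' ratios obtained by inverting the chosen incorporation formula at the true
#' level plus Gaussian noise, a fraction of uniform outliers, and a fraction
#' of missing ratios. Peptides with other serine counts are present so that
#' the single-serine filter has work to do.
#'
#' @param theta true incorporation level in (0, 1).
#' @param n number of peptides.
#' @param noise_sd Gaussian noise on the incorporation scale (default 0.03).
#' @param outlier_fraction fraction of single-serine peptides with uniform
#'   incorporation in \[0, 1\] (default 0.1).
#' @param missing_fraction fraction of blanked ratios (default 0.05).
#' @param serine_probs probabilities of 0-3 serines per peptide.
#' @param formula incorporation formula to invert; see
#'   [incorporation_from_ratio()].
#' @param seed integer seed.
#' @param path optional output TSV; a `.truth.json` sidecar stores `theta`.
#' @return Data frame with columns `sequence`, `ratio_hl`, `intensity`,
#'   `protein`; ground truth in `attr(, "truth")`.
#' @export
simulate_peptides <- function(theta, n = 2000, noise_sd = 0.03,
                              outlier_fraction = 0.1,
                              missing_fraction = 0.05,
                              serine_probs = c(0.25, 0.55, 0.15, 0.05),
                              formula = c("as-printed",
                                          "ratio-over-ratio-plus-one"),
                              seed = 1, path = NULL) {
  stopifnot(theta > 0, theta < 1)
  formula <- match.arg(formula)
  with_generator_seed(seed, "simulate_peptides", {
    nser <- sample(0:3, n, replace = TRUE, prob = serine_probs)
    aa_pool <- strsplit("ACDEFGHIKLMNPQRTVWY", "")[[1]]  # no serine
    seqs <- vapply(seq_len(n), function(i) {
      len <- sample(8:20, 1)
      body <- sample(aa_pool, len, replace = TRUE)
      if (nser[i] > 0) {
        pos <- sample(len, nser[i])
        body[pos] <- "S"
      }
      paste(body, collapse = "")
    }, character(1))
    inc <- theta + stats::rnorm(n, 0, noise_sd)
    out <- stats::runif(n) < outlier_fraction
    inc[out] <- stats::runif(sum(out))
    inc <- pmin(pmax(inc, 0.001), 0.995)
    ratio <- if (formula == "as-printed") 1 + 1 / (1 - inc) else inc / (1 - inc)
    ratio[stats::runif(n) < missing_fraction] <- NA_real_
    df <- data.frame(
      sequence = seqs,
      ratio_hl = round(ratio, 6),
      intensity = round(stats::rlnorm(n, meanlog = 20, sdlog = 1.5), 1),
      protein = paste0("P", sample.int(ceiling(n / 8), n, replace = TRUE)),
      stringsAsFactors = FALSE
    )
    deliver_table(df, list(theta = theta, formula = formula,
                           noise_sd = noise_sd,
                           outlier_fraction = outlier_fraction),
                  path = path, sep = "\t")
  })
}

#' Simulate radiolabeled-serine uptake time courses
#'
#' Scintillation counts accumulate linearly with time at a strain-specific
#' transport rate: `counts = background + rate * time * protein *
#' specific_activity + noise`. The default rates encode the study
#' conditions: the wild type at 10 nmol/mg/min, the gnp1 deletion reduced by
#' 65%, the agp1 deletion by 34%, and the double deletion with marginal
#' residual transport.
#'
#' @param rates named vector of transport rates (nmol/mg/min) per strain.
#' @param times sampling times in minutes.
#' @param background filter background counts.
#' @param specific_activity counts per nmol of labeled serine.
#' @param protein_mg protein mass per filtered sample.
#' @param replicates replicates per strain.
#' @param noise_sd Gaussian count noise (default 0: exact arithmetic).
#' @param seed integer seed.
#' @param path optional output CSV with `.truth.json` sidecar.
#' @return Data frame with columns `strain`, `replicate`, `time_min`,
#'   `counts`, `background`, `protein_mg`, `specific_activity`.
#' @export
simulate_uptake <- function(rates = c(WT = 10, gnp1 = 3.5, agp1 = 6.6,
                                      gnp1agp1 = 0.5),
                            times = c(5, 15, 30), background = 200,
                            specific_activity = 50, protein_mg = 0.1,
                            replicates = 3, noise_sd = 0, seed = 1,
                            path = NULL) {
  stopifnot(all(rates >= 0), !is.null(names(rates)))
  with_generator_seed(seed, "simulate_uptake", {
    df <- expand.grid(strain = names(rates),
                      replicate = seq_len(replicates),
                      time_min = times,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rate <- rates[df$strain]
    mu <- background + rate * df$time_min * protein_mg * specific_activity
    df$counts <- mu + stats::rnorm(nrow(df), 0, noise_sd)
    df$background <- background
    df$protein_mg <- protein_mg
    df$specific_activity <- specific_activity
    df <- df[order(df$strain, df$replicate, df$time_min), ]
    rownames(df) <- NULL
    deliver_table(df, list(rates = as.list(rates), background = background,
                           specific_activity = specific_activity,
                           noise_sd = noise_sd),
                  path = path)
  })
}

#' Simulate an isotope-labeled lipid-species table
#'
#' Each sample is a table of (lipid class, label channel, amount) rows whose
#' mole fractions follow the per-strain specification; the remainder of each
#' sample is unlabeled bulk lipid. The default fractions encode the study
#' conditions for serine-labeled inositol-phosphorylceramide (IPC): the
#' gnp1 deletion at 36% of wild type (a 64% decrease), the double deletion
#' at 27% (a 73% decrease), and the serine auxotroph in the wild-type range.
#'
#' @param fractions named list: strain to named numeric vector of mole
#'   fractions, names formatted `"<class>.<channel>"`.
#' @param total_pmol total lipid per sample.
#' @param replicates replicates per strain.
#' @param multinomial_size if positive, amounts are drawn multinomially with
#'   this many grains around the specified fractions; 0 (default) gives the
#'   exact expected amounts.
#' @param seed integer seed.
#' @param path optional output CSV with `.truth.json` sidecar.
#' @return Data frame with columns `sample`, `strain`, `class`, `channel`,
#'   `amount`.
#' @export
simulate_lipid_table <- function(fractions = list(
                                   WT = c(IPC.serine = 0.020,
                                          IPC.inositol = 0.030,
                                          Cer.serine = 0.004),
                                   gnp1 = c(IPC.serine = 0.0072,
                                            IPC.inositol = 0.036,
                                            Cer.serine = 0.0014),
                                   gnp1agp1 = c(IPC.serine = 0.0054,
                                                IPC.inositol = 0.037,
                                                Cer.serine = 0.0011),
                                   ser2 = c(IPC.serine = 0.019,
                                            IPC.inositol = 0.029,
                                            Cer.serine = 0.0038)),
                                 total_pmol = 1000, replicates = 2,
                                 multinomial_size = 0, seed = 1,
                                 path = NULL) {
  stopifnot(all(vapply(fractions, function(f) all(f >= 0) && sum(f) <= 1,
                       logical(1))))
  with_generator_seed(seed, "simulate_lipid_table", {
    rows <- list()
    for (strain in names(fractions)) {
      fr <- fractions[[strain]]
      full <- c(fr, bulk.unlabeled = 1 - sum(fr))
      for (rep in seq_len(replicates)) {
        amt <- if (multinomial_size > 0) {
          as.numeric(stats::rmultinom(1, multinomial_size, full)) /
            multinomial_size * total_pmol
        } else {
          full * total_pmol
        }
        parts <- strsplit(names(full), ".", fixed = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = paste0(strain, "_", rep),
          strain = strain,
          class = vapply(parts, `[`, "", 1),
          channel = vapply(parts, `[`, "", 2),
          amount = unname(amt),
          stringsAsFactors = FALSE
        )
      }
    }
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    deliver_table(df, list(fractions = lapply(fractions, as.list),
                           total_pmol = total_pmol,
                           multinomial_size = multinomial_size),
                  path = path)
  })
}

#' Simulate a genetic-interaction screen table
#'
#' Null epsilon scores are Gaussian with p-values computed from the same
#' null, so at threshold 0.05 about 5% of null genes are significant;
#' planted hits receive large negative epsilon scores and tiny p-values.
#' The default hits mirror the two strongest aggravating partners of the
#' serine-synthesis query (the GNP1 permease and the overlapping dubious
#' ORF YDR509W).
#'
#' @param n_genes number of null genes.
#' @param null_sd standard deviation of null epsilon scores.
#' @param hits data frame with columns `gene`, `epsilon`, `p` of planted
#'   hits (may be empty).
#' @param seed integer seed.
#' @param path optional output CSV with `.truth.json` sidecar.
#' @return Data frame with columns `gene`, `epsilon`, `p`.
#' @export
simulate_screen <- function(n_genes = 4000, null_sd = 0.05,
                            hits = data.frame(
                              gene = c("GNP1", "YDR509W"),
                              epsilon = c(-0.38, -0.35),
                              p = c(2e-14, 8e-13)),
                            seed = 1, path = NULL) {
  stopifnot(nrow(hits) <= n_genes)
  with_generator_seed(seed, "simulate_screen", {
    eps <- stats::rnorm(n_genes, 0, null_sd)
    p <- 2 * stats::pnorm(-abs(eps) / null_sd)
    df <- data.frame(gene = sprintf("ORF%04d", seq_len(n_genes)),
                     epsilon = eps, p = p, stringsAsFactors = FALSE)
    if (nrow(hits)) {
      df <- rbind(df, data.frame(gene = hits$gene, epsilon = hits$epsilon,
                                 p = hits$p, stringsAsFactors = FALSE))
    }
    rownames(df) <- NULL
    deliver_table(df, list(n_null = n_genes, null_sd = null_sd,
                           hits = if (nrow(hits)) as.list(hits$gene) else list()),
                  path = path)
  })
}
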