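test_that("FBA recovers known optima and reports infeasibility as status", {
  expect_equal(fba_maximize(chain3())$objective_value, 10)
  # all uptake closed: nothing to grow on
  closed <- apply_medium(chain3(),
                         medium_definition("none", stats::setNames(numeric(0),
                                                                   character(0))))
  expect_equal(fba_maximize(closed)$objective_value, 0)
  # yield-loss network: optimum equals the high-yield route's bound
  # (both routes share uptake 10; hand enumeration of the two routes gives
  # 10 via the full-yield route, 5 via the lossy one)
  expect_equal(fba_maximize(branched_net())$objective_value, 10)
  # infeasible model: forced uptake with no outlet
  m <- chain3()
  m$lb[2] <- 0; m$ub[2] <- 0            # block the interior conversion
  m$ub[1] <- -1                         # but force uptake
  sol <- fba_maximize(m)
  expect_identical(sol$status, "infeasible")
  expect_true(is.na(sol$objective_value))
})

test_that("optimal flux vectors satisfy mass balance and bounds", {
  models <- list(chain3(), branched_net(), serine_toy_model(),
                 toy_network("random", size = 7, seed = 11))
  for (m in models) {
    sol <- fba_maximize(m)
    expect_identical(sol$status, "optimal")
    expect_lt(max(abs(m$S %*% sol$fluxes)), 1e-8)
    expect_true(all(sol$fluxes >= m$lb - 1e-9))
    expect_true(all(sol$fluxes <= m$ub + 1e-9))
  }
})

test_that("run_fva reproduces hand-computed envelopes", {
  # chain interior reaction at fraction 0.99 is forced into [9.9, 10]
  env <- run_fva(chain3(), "R1", fraction = 0.99)
  expect_equal(env$min_flux, 9.9)
  expect_equal(env$max_flux, 10)
  # two equivalent parallel branches at fraction 1: each spans [0, 10]
  par <- toy_network("parallel")
  env2 <- run_fva(par, c("R1", "R2"), fraction = 1)
  expect_equal(env2$min_flux, c(0, 0))
  expect_equal(env2$max_flux, c(10, 10))
  expect_error(run_fva(chain3(), "R1", fraction = 0), "fraction")
})

test_that("run_fva matches the vertex-enumeration oracle on random networks", {
  for (seed in 1:25) {
    m <- toy_network("random", size = sample(4:8, 1), seed = seed)
    targets <- colnames(m$S)
    got <- run_fva(m, targets, fraction = 0.99)
    want <- fva_brute_force(m, targets, fraction = 0.99)
    expect_equal(got$min_flux, want$min_flux, tolerance = 1e-6)
    expect_equal(got$max_flux, want$max_flux, tolerance = 1e-6)
  }
})

test_that("the solver agrees with an independent simplex implementation", {
  skip_if_not_installed("boot")
  # boot::simplex handles x >= 0 with equality constraints; shift bounds
  for (seed in 1:10) {
    m <- toy_network("random", size = 6, seed = seed)
    n <- ncol(m$S)
    shift <- m$lb
    A3 <- m$S
    b3 <- -drop(m$S %*% shift)
    flip <- b3 < 0                      # boot::simplex wants rhs >= 0
    A3[flip, ] <- -A3[flip, , drop = FALSE]
    b3[flip] <- -b3[flip]
    A1 <- diag(n)
    b1 <- m$ub - m$lb
    cc <- as.numeric(colnames(m$S) == m$objective)
    ref <- boot::simplex(a = cc, A1 = A1, b1 = b1, A3 = A3, b3 = b3,
                         maxi = TRUE)
    expect_equal(fba_maximize(m)$objective_value,
                 unname(ref$value) + sum(cc * shift), tolerance = 1e-6)
  }
})

test_that("envelopes nest as the fraction of optimum tightens", {
  models <- list(serine_toy_model(), branched_net(),
                 toy_network("random", size = 7, seed = 3))
  for (m in models) {
    targets <- colnames(m$S)
    fr <- c(0.5, 0.9, 0.99, 1)
    envs <- lapply(fr, function(f) run_fva(m, targets, fraction = f))
    for (i in seq_len(length(fr) - 1L)) {
      expect_true(all(envs[[i + 1L]]$min_flux >= envs[[i]]$min_flux - 1e-7))
      expect_true(all(envs[[i + 1L]]$max_flux <= envs[[i]]$max_flux + 1e-7))
    }
  }
})

test_that("envelope bounds are deterministic across repeated runs", {
  m <- toy_network("random", size = 8, seed = 21)
  a <- run_fva(m, colnames(m$S), fraction = 0.99)
  b <- run_fva(m, colnames(m$S), fraction = 0.99)
  expect_identical(a, b)
})

test_that("serine_reaction_panel signs weights as production and drops null transport", {
  S <- cbind(MAKE = c(ser_c = 1, ser_m = 0, A = -1),
             USE = c(-1, 0, 0),
             TRANS = c(-1, 1, 0),
             EX_A = c(0, 0, -1),
             BIO = c(0, -1, 0))
  m <- metabolic_model(S, lb = c(0, 0, 0, -10, 0),
                       ub = c(10, 10, 10, 0, 10), objective = "BIO")
  panel <- serine_reaction_panel(m, c("ser_c", "ser_m"))
  names(panel) <- vapply(panel, `[[`, "", "name")
  expect_setequal(names(panel), c("MAKE", "USE", "BIO"))
  expect_equal(unname(panel$MAKE$weights), 1)    # producer: +1
  expect_equal(unname(panel$USE$weights), -1)    # consumer: -1
  # transport between two listed compartments cancels and is excluded
  expect_false("TRANS" %in% names(panel))
  with_trans <- serine_reaction_panel(m, c("ser_c", "ser_m"),
                                      include_zero = TRUE)
  expect_true("TRANS" %in% vapply(with_trans, `[[`, "", "name"))
  expect_error(serine_reaction_panel(m, "nope"), "not in the model")
  # a species no reaction touches yields an empty panel with a warning
  S2 <- rbind(S, orphan = 0)
  m2 <- metabolic_model(S2, lb = m$lb, ub = m$ub, objective = "BIO")
  expect_warning(empty <- serine_reaction_panel(m2, "orphan"), "no reaction")
  expect_length(empty, 0)
})

test_that("net_flux_envelope optimizes the combination, not the envelope sum", {
  m <- producer_consumer_net()
  # single producer: its own envelope passes through unchanged
  single <- net_flux_envelope(m, "P", serine_ids = "ser", fraction = 1)
  own <- run_fva(m, "P", fraction = 1)
  expect_equal(single$min_flux, own$min_flux)
  expect_equal(single$max_flux, own$max_flux)
  # producer [0,3] plus independent consumer: combined envelope [-3, 3],
  # cross-checked against the exhaustive vertex oracle
  net <- net_flux_envelope(m, c("P", "C"), serine_ids = "ser", fraction = 1)
  oracle <- fva_brute_force(
    m, list(flux_target("net", c(P = 1, C = -1))), fraction = 1)
  expect_equal(net$min_flux, oracle$min_flux, tolerance = 1e-9)
  expect_equal(net$max_flux, oracle$max_flux, tolerance = 1e-9)
  expect_equal(c(net$min_flux, net$max_flux), c(-3, 3))
})

test_that("uptake scans fix the exchange, re-optimize per point and flag infeasible points", {
  m <- serine_toy_model()
  tg <- serine_scan_targets()
  grid <- seq(0, 4, by = 0.5)
  scan <- uptake_scan(m, "EX_ser", grid, tg, fraction = 0.99)
  env <- scan$envelopes
  expect_equal(nrow(env), length(grid) * length(tg))
  expect_true(all(env$status == "ok"))
  # per-point biomass maximum grows with allowed uptake while serine limits
  biom <- unique(env[, c("uptake_rate", "max_biomass")])
  expect_true(all(diff(biom$max_biomass) >= -1e-9))
  # relaxed mode can never do worse than no uptake at all
  scan_max <- uptake_scan(m, "EX_ser", grid, tg["net"], fraction = 0.99,
                          mode = "max")
  b0 <- fba_maximize(m)$objective_value
  expect_true(all(scan_max$envelopes$max_biomass >= b0 - 1e-9))
  # an infeasible grid point is flagged and the scan continues: force
  # uptake beyond what the network can drain
  m2 <- m
  m2$ub[match("SHM", colnames(m2$S))] <- 1     # cap the overflow valve
  m2$ub[match("EX_gly", colnames(m2$S))] <- 1
  scan2 <- uptake_scan(m2, "EX_ser", c(0, 1, 50), tg["net"])
  st <- scan2$envelopes
  expect_identical(st$status[st$uptake_rate == 50], "invalid")
  expect_identical(st$status[st$uptake_rate == 0], "ok")
})

test_that("scan CSV output carries the unit header and full grid", {
  scan <- uptake_scan(serine_toy_model(), "EX_ser", c(0, 1, 2),
                      serine_scan_targets()["net"])
  path <- withr::local_tempfile(fileext = ".csv")
  write_scan_csv(scan, path)
  lines <- readLines(path)
  expect_match(lines[1], "mmol/gDW/h")
  got <- utils::read.csv(path, comment.char = "#")
  expect_equal(nrow(got), 3)
  expect_equal(got$uptake_rate, c(0, 1, 2))
})
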