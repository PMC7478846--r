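test_that("toy-json models load, validate and round-trip through both dialects", {
  m <- chain3()
  expect_s3_class(m, "metabolic_model")
  expect_equal(ncol(m$S), 3)
  expect_equal(sum(m$is_exchange), 1)

  json <- withr::local_tempfile(fileext = ".json")
  write_model(m, json)
  m2 <- load_model(json, dialect = "toy-json")
  expect_equal(m2$S, m$S)
  expect_equal(m2$lb, m$lb)
  expect_equal(m2$ub, m$ub)
  expect_identical(m2$objective, m$objective)

  # the SBML-FBC export of the same chain normalizes to the identical model
  xml <- withr::local_tempfile(fileext = ".xml")
  write_model(m, xml, dialect = "sbml-fbc")
  m3 <- load_model(xml)
  expect_equal(m3$S[rownames(m$S), colnames(m$S)], m$S)
  expect_equal(m3$lb, m$lb)
  expect_equal(m3$ub, m$ub)
  expect_identical(m3$objective, m$objective)
})

test_that("SBML round-trip preserves GPR rules and gene products", {
  m <- serine_toy_model()
  xml <- withr::local_tempfile(fileext = ".xml")
  write_model(m, xml, dialect = "sbml-fbc")
  m2 <- load_model(xml)
  expect_setequal(m2$genes, m$genes)
  # rule semantics survive even if parenthesisation differs
  for (j in which(nzchar(m$gpr))) {
    jj <- match(colnames(m$S)[j], colnames(m2$S))
    for (del in list(character(0), "SER1", c("SHM1", "SHM2"),
                     c("SER1", "SER2", "LCB1"))) {
      expect_identical(eval_gpr(parse_gpr(m2$gpr[jj]), del),
                       eval_gpr(parse_gpr(m$gpr[j]), del))
    }
  }
})

test_that("malformed or incomplete model files raise informative errors", {
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"metabolites": []}', bad)
  expect_error(load_model(bad), "reactions")
  writeLines("not json at all {", bad)
  expect_error(load_model(bad), "malformed")
  expect_error(load_model("no/such/file.json"), "not found")
  # missing objective in SBML
  m <- chain3()
  xml <- withr::local_tempfile(fileext = ".xml")
  txt <- serflux:::sbml_fbc_text(m)
  txt <- txt[!grepl("fbc:listOfObjectives|fbc:objective|fluxObjective", txt)]
  writeLines(txt, xml)
  expect_error(load_model(xml), "objective")
})

test_that("model invariants are enforced at construction", {
  S <- cbind(R1 = c(A = -1, B = 1), BIO = c(0, -1))
  expect_error(
    metabolic_model(S, lb = c(5, 0), ub = c(0, 10), objective = "BIO"),
    "lower bound exceeds upper")
  expect_error(
    metabolic_model(S, lb = c(0, 0), ub = c(10, 10), objective = "nope"),
    "objective")
  expect_error(
    metabolic_model(S, lb = c(0, 0), ub = c(10, 10), objective = "BIO",
                    gpr = c("G1", ""), genes = "OTHER"),
    "outside the gene set")
})

test_that("GPR parsing handles precedence, parentheses and errors", {
  expect_true(eval_gpr(parse_gpr(""), c("G1", "G2")))
  e <- parse_gpr("G1 or G2")
  expect_true(eval_gpr(e, "G1"))
  expect_false(eval_gpr(e, c("G1", "G2")))
  e2 <- parse_gpr("(G1 and G2) or G3")
  expect_true(eval_gpr(e2, "G2"))
  expect_false(eval_gpr(e2, c("G1", "G3")))
  # AND binds tighter than OR
  e3 <- parse_gpr("G1 or G2 and G3")
  expect_true(eval_gpr(e3, c("G2", "G3")))
  # case-insensitive keywords
  expect_true(eval_gpr(parse_gpr("G1 OR G2"), "G1"))
  expect_error(parse_gpr("(G1 and G2"), "position")
  expect_error(parse_gpr("G1 G2"), "stray")
  expect_error(parse_gpr("G1 and ) G2"), "unexpected")
})

test_that("gene deletions zero out unavailable reactions and are monotone", {
  m <- serine_toy_model()
  j <- match("SHM", colnames(m$S))
  one <- apply_gene_deletions(m, "SHM1")   # isozyme survives
  expect_equal(one$lb[j], m$lb[j])
  expect_equal(one$ub[j], m$ub[j])
  both <- apply_gene_deletions(m, c("SHM1", "SHM2"))
  expect_equal(both$lb[j], 0)
  expect_equal(both$ub[j], 0)
  # AND rule: one subunit suffices to kill the reaction
  spt <- apply_gene_deletions(m, "LCB1")
  expect_equal(spt$ub[match("SPT", colnames(m$S))], 0)
  # empty deletion set is the identity; unknown genes warn and no-op
  expect_equal(apply_gene_deletions(m, character(0)), m)
  expect_warning(noop <- apply_gene_deletions(m, "NOT_A_GENE"), "ignored")
  expect_equal(noop$lb, m$lb)
  # monotonicity: supersets never re-enable a reaction
  dels <- list("SER1", c("SER1", "SHM1"), c("SER1", "SHM1", "SHM2"),
               c("SER1", "SHM1", "SHM2", "LCB2"))
  prev_open <- rep(TRUE, ncol(m$S))
  for (d in dels) {
    md <- apply_gene_deletions(m, d)
    open <- md$ub > 0 | md$lb < 0
    expect_true(all(open <= prev_open))
    prev_open <- open
  }
})

test_that("media set uptake bounds, close defaults and are idempotent", {
  m <- serine_toy_model()
  med <- medium_definition("minimal", c(EX_glc = 5))
  m1 <- apply_medium(m, med, closed_default = TRUE)
  expect_equal(m1$lb[match("EX_glc", colnames(m1$S))], -5)
  expect_equal(m1$lb[match("EX_ser", colnames(m1$S))], 0)
  expect_equal(apply_medium(m1, med), m1, ignore_attr = TRUE)
  # empty medium with closed defaults starves the model: FBA optimum 0
  empty <- medium_definition("none", stats::setNames(numeric(0), character(0)))
  m0 <- apply_medium(m, empty, closed_default = TRUE)
  expect_equal(fba_maximize(m0)$objective_value, 0)
  expect_error(apply_medium(m, medium_definition("bad", c(SPT = 1))),
               "non-exchange")
  expect_error(medium_definition("neg", c(EX_glc = -1)), "nonnegative")
})

test_that("shipped media presets parse and apply to matching exchanges", {
  cfg <- read_media_config(system.file("extdata/media/media.yaml",
                                       package = "serflux"))
  expect_named(cfg, c("sdc", "ypd"))
  expect_equal(unname(cfg$ypd$uptake_bounds["EX_glc"]), 10)
  # 20 amino acids + 4 nucleobases + glucose in the YPD preset
  expect_length(cfg$ypd$uptake_bounds, 25)
  expect_true(all(cfg$ypd$uptake_bounds[-match("EX_glc", names(cfg$ypd$uptake_bounds))] == 1))
})

test_that("exchange bounds can be fixed or relaxed, repeatably", {
  m <- serine_toy_model()
  j <- match("EX_ser", colnames(m$S))
  f0 <- set_exchange_bound(m, "EX_ser", 0, "fixed")
  expect_equal(c(f0$lb[j], f0$ub[j]), c(0, 0))
  fx <- set_exchange_bound(m, "EX_ser", 2.5, "fixed")
  expect_equal(c(fx$lb[j], fx$ub[j]), c(-2.5, -2.5))
  back <- set_exchange_bound(fx, "EX_ser", 0, "fixed")
  expect_equal(c(back$lb[j], back$ub[j]), c(0, 0))
  mx <- set_exchange_bound(m, "EX_ser", 5, "max")
  expect_equal(mx$lb[j], -5)
  expect_equal(mx$ub[j], m$ub[j])
  expect_error(set_exchange_bound(m, "SPT", 1), "not an exchange")
  expect_error(set_exchange_bound(m, "EX_ser", -1), "uptake")
})

test_that("the SEY6210 genotype preset lists the auxotrophy deletions", {
  expect_setequal(sey6210_deletions(),
                  c("LEU2", "URA3", "HIS3", "TRP1", "LYS2", "SUC2"))
})
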