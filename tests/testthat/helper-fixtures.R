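# Shared fixtures built in code.

chain3 <- function() toy_network("chain", size = 3)

# two independent routes A -> B, one at half yield
branched_net <- function() toy_network("yield-loss")

# one serine producer and one serine consumer, both independent of the
# biomass route (growth runs on substrate D), so their combined envelope
# is the full [-3, 3] span regardless of the fraction of optimum
producer_consumer_net <- function() {
  S <- cbind(EX_A = c(A = -1, ser = 0, B = 0, D = 0),
             P = c(-1, 1, 0, 0),
             C = c(0, -1, 1, 0),
             EX_ser = c(0, -1, 0, 0),
             EX_B = c(0, 0, -1, 0),
             EX_D = c(0, 0, 0, -1),
             BIOMASS = c(0, 0, 0, -1))
  metabolic_model(S,
                  lb = c(-3, 0, 0, -3, 0, -5, 0),
                  ub = c(0, 3, 3, 3, 1000, 0, 1000),
                  objective = "BIOMASS")
}

# peptide table with known serine counts for filter tests
tiny_peptides <- function() {
  data.frame(
    sequence = c("ASDF", "SSA", "ASDF", "AKLM", "TTSVV"),
    ratio_hl = c(3, 3, NA, 2, -1),
    intensity = c(10, 10, 10, 10, 10),
    protein = paste0("P", 1:5),
    stringsAsFactors = FALSE
  )
}
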