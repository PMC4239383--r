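# shared fixtures built in code

toy_sample <- function(stage = "growth", time = 60, temperature = 300.15,
                       FW = 80, DW = 20, ...) {
  base <- data.frame(stage = stage, time = time, temperature = temperature,
                     FW = FW, DW = DW, K = 0.08, Mg = 0.008, Ca = 0.002,
                     P = 0.008, Cl = 0.004, citrate = 0.02, oxalate = 0.01,
                     stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

# random solvable sample rows for property tests
random_sample <- function(stage = "growth", time = 60) {
  comp <- random_composition()
  FW <- runif(1, 40, 150)
  data.frame(stage = stage, time = time, temperature = comp$temperature,
             FW = FW, DW = FW * runif(1, 0.15, 0.35),
             K = comp$K, Mg = comp$Mg, Ca = comp$Ca, P = comp$P,
             Cl = comp$Cl, citrate = comp$citrate, oxalate = comp$oxalate,
             stringsAsFactors = FALSE)
}
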