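# shared fixtures: tiny toy database and a fast SVR tuning grid for tests
toyDatabase <- function() {
  data.frame(
    name = c("PC(34:1)", "PE(34:1)", "toy500"),
    formula = c("C42H82NO8P", "C39H76NO8P", "C27H45N"),
    mass = c(759.5778, 717.5309, 500.000),
    class = c("PC", "PE", "other"))
}

fastGrid <- list(cost = c(10, 100), gamma = 1, epsilon = 0.01)

calIons <- function(k = 10) {
  list(ccs = stats::setNames(seq(200, 330, length.out = k), paste0("i", seq_len(k))),
       mz = seq(400, 950, length.out = k))
}
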