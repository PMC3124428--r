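# Shared state-space constants (file sorts first so every module sees them).

DNA_STATES <- c("A", "C", "G", "T")
AA_STATES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "W", "S", "T", "Y", "V")

# IUPAC nucleotide ambiguity -> state sets; fully missing -> all states.
DNA_STATE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G")
)
AA_STATE_SETS <- c(
  stats::setNames(as.list(AA_STATES), AA_STATES),
  list(B = c("N", "D"), Z = c("Q", "E"))
)

DNA_ALLOWED <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-", "?")
AA_ALLOWED <- c(AA_STATES, "X", "B", "Z", "-", "?", "*")

missing_codes <- function(alphabet) {
  if (identical(alphabet, "PROTEIN")) c("-", "?", "X", "*") else c("-", "?", "N", "X")
}
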