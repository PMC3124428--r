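# Tiny on-the-fly file fixtures (all built in code at test time).

write_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

fasta_toy <- function() write_tmp(c(">A", "ACGT", ">B", "ACGA"), ".fasta")

nexus_toy <- function() write_tmp(c(
  "#NEXUS",
  "BEGIN DATA;",
  "DIMENSIONS NTAX=2 NCHAR=6;",
  "FORMAT DATATYPE=DNA MISSING=? GAP=-;",
  "MATRIX",
  "A ACGTAC",
  "B ACGAAC",
  ";",
  "END;",
  "BEGIN SETS;",
  "charset exon1 = 1-6;",
  "charset pos3 = 3-6\\3;",
  "END;"), ".nex")

newick_balanced <- function() {
  write_tmp("((A:1,B:1):1,(C:1.5,D:1.5):0.5);", ".nwk")
}

# fast/slow pair from constructed rate vectors: 300 sites at 2, 300 at 0.1
fast_slow_rates <- function() {
  rates <- tibble::tibble(
    locus = rep(c("fast", "slow"), each = 300),
    site = rep(1:300, 2),
    rate = rep(c(2, 0.1), each = 300),
    status = "OK", loglik = NA_real_, model = "JC69")
  attr(rates, "depth") <- 3
  class(rates) <- c("pi_rates", class(rates))
  rates
}
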