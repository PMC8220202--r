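# Independent oracles used across tests.

# Brute-force restatement of the cell-enumeration rules, written as a plain
# scalar case analysis independent of classify_cell()'s vectorized path.
oracle_classify <- function(red, green, fusion) {
  if (fusion > 0) return("fusion_positive")
  if (red == 2 && green == 2) return("normal")
  if (max(red, green) >= 3) return("gain_or_break")
  "uninformative"
}

# Direct-ratio estimator of a planted signed fold change from the raw
# matrix: +r for r >= 1, -1/r otherwise.
oracle_signed_ratio <- function(a, b) {
  r <- a / b
  if (r >= 1) r else -1 / r
}

# Random aberration generator for property-style tests.
random_aberration <- function() {
  kind <- sample(c("gain", "loss", "add", "iso", "dup", "translocation"), 1)
  chrom <- function(n = 1) sample(c(as.character(1:22), "X", "Y"), n)
  band <- function(n = 1) {
    paste0(sample(c("p", "q"), n, replace = TRUE),
           sample(1:3, n, replace = TRUE),
           sample(c("", "1", "2"), n, replace = TRUE))
  }
  switch(kind,
    gain = aberration("gain", chrom()),
    loss = aberration("loss", chrom()),
    add = aberration("add", chrom(), band()),
    iso = aberration("iso", chrom(), band()),
    dup = aberration("dup", chrom(), band(2)),
    translocation = {
      n <- sample(2:3, 1)
      aberration("translocation", chrom(n), band(n))
    })
}

random_karyotype <- function(max_aberrations = 5) {
  n <- sample(0:max_aberrations, 1)
  karyotype(sample(44:50, 1), sample(c("XY", "XX", "XXY", "X"), 1),
            replicate(n, random_aberration(), simplify = FALSE))
}
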