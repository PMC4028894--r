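# shared simulation helpers for the test suite

# transmitted-state matrix for one parent simulated directly from meioses:
# m markers at `pos` (cM, starting at 0), n meioses, MCAR missingness
simStates <- function(m, L, n, sex = "female", bias = 0, miss = 0,
                      pos = seq(0, L, length.out = m)) {
  st <- matrix(NA_real_, m, n,
               dimnames = list(sprintf("mk%02d", seq_len(m)), NULL))
  for (j in seq_len(n))
    st[, j] <- simulateMeiosis(pos, sex, bias = bias, length_cM = L)$haplotype - 1L
  if (miss > 0) st[matrix(stats::runif(m * n) < miss, m)] <- NA
  st
}

# Kendall tau between a built map's order and the truth (rownames order),
# orientation-free
orderTau <- function(map, states) {
  abs(stats::cor(seq_along(map@markers),
                 match(map@markers, rownames(states)),
                 method = "kendall"))
}

# grid-search oracle for the two-point LOD: maximise the binomial log10
# likelihood ratio over r with a coarse grid refined around the argmax
gridLod <- function(N, R) {
  f <- function(r) (N - R) * log10(2 * (1 - r)) + R * log10(2 * r)
  coarse <- c(1e-12, seq(1e-4, 0.5, by = 1e-4))
  v <- f(coarse)
  i <- which.max(v)
  fine <- seq(max(1e-12, coarse[i] - 1e-4), min(0.5, coarse[i] + 1e-4),
              length.out = 20001)
  max(f(fine))
}

# tiny hand-genotyped family: 3 markers x (2 parents + 4 offspring)
toyFamily <- function() {
  g <- matrix(c(
    # mother father off1  off2  off3  off4
    "ab",   "aa",  "aa",  "ab", "aa", "ab",    # female-informative
    "aa",   "ab",  "ab",  "aa", "ab", "aa",    # male-informative
    "aa",   "bb",  "ab",  "ab", "ab", "ab"     # uninformative aaXbb
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("mkA", "mkB", "mkC"),
                  c("mo", "fa", "o1", "o2", "o3", "o4")))
  ind <- data.frame(id = colnames(g), family = "fam1",
                    role = c("mother", "father", rep("offspring", 4)),
                    stringsAsFactors = FALSE)
  genotypeMatrix(g, ind)
}

extfile <- function(name) system.file("extdata", name, package = "radlinkmap")
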