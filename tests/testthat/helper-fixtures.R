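# Shared helpers: plate builders and an independent enumeration oracle for
# the one-sided Fisher test.

# A plate whose treated means sit at a chosen fraction of the
# vehicle-blank span (fill = 1 means vehicle-level signal, 0 blank-level).
make_plate <- function(fill = rep(0.5, 6), vehicle = 1000, blank = 100,
                       specimen = "S1", drug = "Dox", reps = 3) {
  span <- vehicle - blank
  treated <- stats::setNames(
    lapply(fill, function(f) rep(blank + span * f, reps)),
    c(6.25, 12.5, 25, 50, 100, 200))
  dose_plate(specimen, drug, treated,
             vehicle = rep(vehicle, 3), blank = rep(blank, 2))
}

# Brute-force one-sided Fisher oracle: enumerate every table with the
# observed margins, weight by C(K, x) C(N-K, n-x), and sum tail masses.
# Uses plain binomial coefficients, independently of the package's
# log-space kernel.
fisher_enum <- function(tab) {
  N <- sum(tab); K <- sum(tab[, 2]); n <- sum(tab[1, ]); x <- tab[1, 2]
  ks <- max(0, n + K - N):min(n, K)
  w <- choose(K, ks) * choose(N - K, n - ks)
  w <- w / sum(w)
  list(upper = sum(w[ks >= x]), lower = sum(w[ks <= x]))
}

# Random 2x2 table with every cell bounded by `cell_max`.
random_table <- function(cell_max = 10) {
  repeat {
    cells <- sample.int(cell_max + 1L, 4L, replace = TRUE) - 1L
    if (sum(cells) >= 1L) return(contingency_2x2(cells[1], cells[2],
                                                 cells[3], cells[4]))
  }
}

# The published stratified count grid: per drug, STS / UPS / SS tables as
# c(mut_sensitive, mut_resistant, nomut_sensitive, nomut_resistant).
printed_grid <- function() {
  list(
    Dox = list(STS = c(1, 9, 13, 14), UPS = c(1, 6, 7, 11),
               SS = c(0, 3, 6, 3)),
    Ifo = list(STS = c(3, 7, 6, 11), UPS = c(2, 5, 5, 8),
               SS = c(1, 2, 1, 3)),
    `Dox+Ifo` = list(STS = c(4, 5, 12, 6), UPS = c(4, 3, 7, 6),
                     SS = c(1, 2, 3, 1)),
    Doc = list(STS = c(2, 8, 9, 18), UPS = c(1, 6, 7, 11),
               SS = c(1, 2, 2, 7)),
    Gem = list(STS = c(6, 4, 9, 18), UPS = c(4, 3, 7, 11),
               SS = c(2, 1, 2, 7)),
    `Doc+Gem` = list(STS = c(7, 3, 13, 14), UPS = c(5, 2, 10, 8),
                     SS = c(2, 1, 3, 6))
  )
}
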