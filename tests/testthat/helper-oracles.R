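## Independent literal transcriptions of the closed-form relaxation
## expressions, written from scratch (no package internals) so they can
## serve as an oracle for the implementation.

oracle_constants <- list(gH = 2.6752218744e8, gF = 2.5181480e8,
                         hbar = 1.054571817e-34, mu4pi = 1e-7)

oracle_J <- function(w, tc) (2 / 5) * tc / (1 + w^2 * tc^2)

oracle_d <- function(r_angstrom) {
  with(oracle_constants, mu4pi * gH * gF * hbar / (r_angstrom * 1e-10)^3)
}

## full pairwise rates for a set of distances + CSA, term by term
oracle_rates <- function(dists, ds_ppm, eta, tc, b0 = 14.1) {
  wH <- oracle_constants$gH * b0
  wF <- oracle_constants$gF * b0
  r1 <- 0; r2 <- 0
  for (r in dists) {
    d2 <- oracle_d(r)^2
    r1 <- r1 + d2 / 4 * (oracle_J(wH - wF, tc) + 3 * oracle_J(wF, tc) +
                         6 * oracle_J(wH + wF, tc))
    r2 <- r2 + d2 / 8 * (4 * oracle_J(0, tc) + oracle_J(wH - wF, tc) +
                         3 * oracle_J(wF, tc) + 6 * oracle_J(wH, tc) +
                         6 * oracle_J(wH + wF, tc))
  }
  c2 <- (ds_ppm * 1e-6 * wF)^2
  r1 <- r1 + c2 / 3 * (1 + eta^2 / 3) * oracle_J(wF, tc)
  r2 <- r2 + c2 / 18 * (1 + eta^2 / 3) *
    (4 * oracle_J(0, tc) + 3 * oracle_J(wF, tc))
  sig <- oracle_d(dists[1])^2 / 4 *
    (6 * oracle_J(wH + wF, tc) - oracle_J(wH - wF, tc))
  list(r1 = r1, r2 = r2, sigma_first = sig)
}

## Table-3-style distances used throughout the tests
exo_major_distances <- c(HG = 2.03, HB2 = 3.29, HB3 = 2.56,
                         HD2 = 3.3, HD3 = 2.5)

geom_exo_major <- function() fpro_geometries("(4R)-exo major")
geom_endo_major <- function() fpro_geometries("(4S)-endo major")

## deterministic sub-seeds below 2^31 for Monte-Carlo loops
mc_seeds <- function(master, n) {
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}
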