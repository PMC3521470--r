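# small fixtures built in code

# a trio: father 1, mother 2, child 3, with given genotype-code columns
trio_ped <- function(...) {
  g <- list(...)
  df <- data.frame(id = 1:3, father = c(NA, NA, 1), mother = c(NA, NA, 2),
                   sex = c(1L, 2L, 0L))
  for (l in seq_along(g)) df[[paste0("g", l)]] <- as.integer(g[[l]])
  as_zrhc_ped(df)
}

# nuclear family: couple 1, 2 with n_children
family_ped <- function(n_children, g = NULL) {
  n <- 2L + n_children
  df <- data.frame(id = seq_len(n),
                   father = c(NA, NA, rep(1L, n_children)),
                   mother = c(NA, NA, rep(2L, n_children)),
                   sex = c(1L, 2L, rep(0L, n_children)))
  if (!is.null(g)) for (l in seq_len(ncol(g))) df[[paste0("g", l)]] <- g[, l]
  as_zrhc_ped(df)
}

# random GF(2) expression for property tests
random_gf2 <- function(max_var = 6L) {
  gf2(sample(0:1, 1), sample(0:max_var, sample(0:3, 1)))
}

# enumerated family of a fit vs canonicalised brute-force set
family_equals_oracle <- function(sim, fit, max_vars = 14L, max_h_bits = 16L) {
  fam <- enumerate_solutions(fit, max_vars = max_vars)
  bf <- zrhc_bruteforce(sim$ped, max_h_bits = max_h_bits)
  canon <- unique(vapply(bf, function(p) {
    paste(canonical_phase(fit, p), collapse = "")
  }, character(1)))
  setequal(config_keys(fam), canon)
}

truth_in_family <- function(sim, fit, max_vars = 16L) {
  fam <- enumerate_solutions(fit, max_vars = max_vars)
  key <- paste(canonical_phase(fit, sim$pat), collapse = "")
  key %in% config_keys(fam)
}
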