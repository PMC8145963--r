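# Independent oracles used across the suite. These deliberately avoid the
# package's own formula/mass machinery.

# Atom-count bookkeeping on c(C, H, N, O, P) vectors.
atoms <- function(C = 0, H = 0, N = 0, O = 0, P = 0) c(C = C, H = H, N = N,
                                                       O = O, P = P)

# Building blocks for the structure-assembly oracle.
GLYCEROL <- atoms(C = 3, H = 8, O = 3)
PHOSPHORIC_ACID <- atoms(H = 3, O = 4, P = 1)
ETHANOLAMINE <- atoms(C = 2, H = 7, N = 1, O = 1)
SERINE <- atoms(C = 3, H = 7, N = 1, O = 3)
CYTIDINE <- atoms(C = 9, H = 13, N = 3, O = 5)
BUTANOL <- atoms(C = 4, H = 10, O = 1)
WATER <- atoms(H = 2, O = 1)

# A fatty acid with n carbons and m double-bond equivalents: CnH(2n-2m)O2.
fatty_acid <- function(n, m = 0) atoms(C = n, H = 2 * n - 2 * m, O = 2)

# Assemble a species formula from first principles: condense each
# component pair with loss of one water per bond formed.
assemble <- function(components, n_bonds) {
  Reduce(`+`, components) - n_bonds * WATER
}

# Structure-assembled formulas for one species of each class, written as
# (components, number of condensation bonds). Acyl chains are given as
# free fatty acids carrying all double-bond equivalents on one chain.
oracle_species_formula <- function(class, total_c, m) {
  fa2 <- list(fatty_acid(total_c - 2, m), fatty_acid(2))
  fa3 <- list(fatty_acid(total_c - 4, m), fatty_acid(2), fatty_acid(2))
  fa4 <- list(fatty_acid(total_c - 6, m), fatty_acid(2), fatty_acid(2),
              fatty_acid(2))
  switch(class,
    PA = assemble(c(list(GLYCEROL, PHOSPHORIC_ACID), fa2), 3),
    PE = assemble(c(list(GLYCEROL, PHOSPHORIC_ACID, ETHANOLAMINE), fa2), 4),
    PG = assemble(c(list(GLYCEROL, PHOSPHORIC_ACID, GLYCEROL), fa2), 4),
    PS = assemble(c(list(GLYCEROL, PHOSPHORIC_ACID, SERINE), fa2), 4),
    PGP = assemble(c(list(GLYCEROL, PHOSPHORIC_ACID, GLYCEROL,
                          PHOSPHORIC_ACID), fa2), 5),
    `CDP-DAG` = assemble(c(list(GLYCEROL, PHOSPHORIC_ACID, PHOSPHORIC_ACID,
                                CYTIDINE), fa2), 5),
    CL = assemble(c(list(GLYCEROL, PHOSPHORIC_ACID, GLYCEROL,
                         PHOSPHORIC_ACID, GLYCEROL), fa4), 8),
    DLCL = assemble(c(list(GLYCEROL, PHOSPHORIC_ACID, GLYCEROL,
                           PHOSPHORIC_ACID, GLYCEROL), fa2), 6),
    aPE = assemble(c(list(GLYCEROL, PHOSPHORIC_ACID, ETHANOLAMINE), fa3), 5),
    aPG = assemble(c(list(GLYCEROL, PHOSPHORIC_ACID, GLYCEROL), fa3), 5),
    PBut = assemble(c(list(GLYCEROL, PHOSPHORIC_ACID, BUTANOL), fa2), 4),
    stop("no oracle for class ", class)
  )
}

# Independent monoisotopic [M-H]- mass from literature atomic masses.
oracle_mz <- function(counts) {
  masses <- c(C = 12, H = 1.007825032, N = 14.003074005, O = 15.994914620,
              P = 30.973761630)
  sum(counts * masses) - 1.007276467
}

# Brute-force isotope distribution of n carbons: expand the polynomial
# ((1-p) + p z)^n by repeated convolution and take coefficient ratios.
oracle_isotope_ratio <- function(n, k, p = 0.011) {
  coefs <- 1
  for (i in seq_len(n)) coefs <- c(coefs, 0) * (1 - p) + c(0, coefs) * p
  coefs[k + 1] / coefs[1]
}

# Count C/H/N/O/P atoms in a Hill-order formula string without the
# package parser.
oracle_count_atoms <- function(s) {
  out <- atoms()
  for (el in c("C", "H", "N", "O", "P")) {
    m <- regmatches(s, regexec(paste0(el, "(?![a-z])([0-9]*)"), s,
                               perl = TRUE))[[1]]
    if (length(m) > 0 && m[1] != "") {
      out[el] <- if (m[2] == "") 1 else as.integer(m[2])
    }
  }
  out
}

# Small scaled study shared by slower tests (built once per run).
scaled_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(study_config(seed = 401, n_constructs = 16,
                                            replicates = 3,
                                            control_replicates = 5))
    }
    cache
  }
})
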