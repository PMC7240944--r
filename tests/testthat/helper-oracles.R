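# Independent oracles the implementation is checked against.  These are
# deliberately written by a different route than the package code:
# a separately transcribed atomic-mass table, a full isotopologue
# polynomial convolution, and an exhaustive match scan with no index
# structure.

options(mzFBA.quiet = TRUE)

# NIST monoisotopic masses transcribed independently, 9 decimals
ORACLE_MASS <- c(
  H = 1.007825032, C = 12, N = 14.003074004, O = 15.994914620,
  P = 30.973761999, S = 31.972071174, Na = 22.989769282,
  K = 38.963706487, Cl = 34.968852690, F = 18.998403163,
  Mg = 23.985041697, Ca = 39.962590863, Fe = 55.934936330,
  Zn = 63.929142010, Se = 79.916521800)

oracleMass <- function(formula_text) {
  toks <- regmatches(formula_text,
                     gregexpr("[A-Z][a-z]?[0-9]*", formula_text))[[1]]
  total <- 0
  for (tk in toks) {
    sym <- sub("[0-9]*$", "", tk)
    n <- sub("^[A-Z][a-z]?", "", tk)
    n <- if (n == "") 1L else as.integer(n)
    total <- total + n * ORACLE_MASS[[sym]]
  }
  total
}

# isotope distributions over integer Da offsets (NIST abundances)
ORACLE_ISOTOPES <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  P = 1,
  S = c(0.9499, 0.0075, 0.0425, 0, 0.0001))

polyMul <- function(a, b, keep = 4L) {
  n <- min(keep, length(a) + length(b) - 1L)
  out <- numeric(n)
  for (i in seq_along(a)) {
    j <- seq_along(b) + i - 1L
    ok <- j <= n
    out[j[ok]] <- out[j[ok]] + a[i] * b[ok]
  }
  out
}

# full isotopologue envelope of a CHNOPS formula by polynomial
# convolution; returns the M+1 / M intensity ratio
convolutionM1 <- function(counts, keep = 4L) {
  env <- 1
  for (sym in names(counts)) {
    atom <- ORACLE_ISOTOPES[[sym]]
    p <- 1
    n <- counts[[sym]]
    sq <- atom
    while (n > 0) {
      if (n %% 2 == 1) p <- polyMul(p, sq, keep)
      n <- n %/% 2
      if (n > 0) sq <- polyMul(sq, sq, keep)
    }
    env <- polyMul(env, p, keep)
  }
  if (length(env) < 2L) 0 else env[2] / env[1]
}

randomChnops <- function() {
  counts <- c(C = sample(1:40, 1), H = sample(1:80, 1),
              N = sample(0:20, 1), O = sample(0:30, 1),
              P = sample(0:3, 1), S = sample(0:5, 1))
  counts[counts > 0]
}

# exhaustive match scan: every (feature, compound, adduct) combination
# is tested directly, no sorted index
oracleMatch <- function(fdf, cdf, adducts, ppm_tol) {
  hits <- list()
  for (ai in seq_len(nrow(adducts))) {
    theo <- (adducts$multimer[ai] * cdf$mono_mass + adducts$delta_mass[ai]) /
      adducts$charge[ai]
    for (fi in seq_len(nrow(fdf))) {
      err <- 1e6 * (fdf$mz[fi] - theo) / theo
      ok <- which(theo > 0 & abs(err) <= ppm_tol)
      if (length(ok))
        hits[[length(hits) + 1L]] <- data.frame(
          feature_id = fdf$feature_id[fi],
          compound_id = cdf$compound_id[ok],
          adduct = adducts$name[ai])
    }
  }
  if (!length(hits))
    return(data.frame(feature_id = character(0), compound_id = character(0),
                      adduct = character(0)))
  do.call(rbind, hits)
}

matchKey <- function(df) sort(paste(df$feature_id, df$compound_id, df$adduct))

# random feature/compound instances for property tests
randomInstance <- function(n_feat, n_cmp, seed) {
  set.seed(seed)
  pool <- metabolitePool()
  idx <- sample.int(nrow(pool), min(n_cmp, nrow(pool)))
  cdf <- data.frame(compound_id = pool$compound_id[idx],
                    name = pool$name[idx], formula = pool$formula[idx])
  comp <- CompoundSet(cdf)
  masses <- compounds(comp)$mono_mass
  # half the features land near a real adduct m/z, half are random
  ad <- defaultAdducts("positive")
  near <- sample(length(masses), ceiling(n_feat / 2), replace = TRUE)
  arow <- sample(nrow(ad), length(near), replace = TRUE)
  mz_near <- (ad$multimer[arow] * masses[near] + ad$delta_mass[arow]) /
    ad$charge[arow] * (1 + runif(length(near), -8, 8) * 1e-6)
  mz_rand <- runif(n_feat - length(near), 60, 950)
  fdf <- data.frame(
    feature_id = sprintf("F%04d", seq_len(n_feat)),
    mz = c(mz_near, mz_rand),
    rt = runif(n_feat, 60, 1200),
    p_value = runif(n_feat, 0, 0.04),
    mid = 1, late = 2, stationary = 1.5)
  list(features = FeatureSet(fdf), compounds = comp, adducts = ad)
}
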