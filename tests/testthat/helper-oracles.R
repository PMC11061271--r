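# Independent brute-force oracles and fixture builders shared by the suite.

# Exhaustive single-locus likelihood: plain probability-space sum over all
# 3^n genotype vectors (1 = AA, 2 = Aa, 3 = aa), multiplying founder
# Hardy-Weinberg priors, Mendelian transmission, hard carrier evidence and
# liability-class phenotype terms. Deliberately naive; used as the oracle
# for the peeling engine.
oracle_likelihood <- function(ped, model, hypothesis) {
  n <- nrow(ped)
  fa <- match(ped$father_id, ped$id)
  mo <- match(ped$mother_id, ped$id)
  q <- model$allele_freq
  hw <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  tr <- c(0, 0.5, 1)  # P(transmit variant | genotype)
  f_car <- penetrance_lookup(model$penetrance, ped$sex, ped$age, TRUE)
  f_non <- penetrance_lookup(model$penetrance, ped$sex, ped$age, FALSE)
  G <- as.matrix(expand.grid(rep(list(1:3), n)))
  p <- rep(1, nrow(G))
  for (i in seq_len(n)) {
    g <- G[, i]
    p <- p * if (is.na(fa[i])) hw[g] else {
      tf <- tr[G[, fa[i]]]; tm <- tr[G[, mo[i]]]
      cbind((1 - tf) * (1 - tm), tf * (1 - tm) + (1 - tf) * tm,
            tf * tm)[cbind(seq_along(g), g)]
    }
    if (ped$carrier[i] == "carrier") p[g == 1] <- 0
    if (ped$carrier[i] == "non_carrier") p[g > 1] <- 0
    f <- if (hypothesis == "causal") {
      ifelse(g > 1, f_car[i], f_non[i])
    } else rep(f_non[i], length(g))
    p <- p * switch(ped$affected[i],
                    affected = f, unaffected = 1 - f, unknown = 1)
  }
  sum(p)
}

oracle_flb <- function(ped, model) {
  pr <- which(ped$proband)
  solo <- ped[pr, , drop = FALSE]
  solo$father_id <- NA_character_
  solo$mother_id <- NA_character_
  lc <- oracle_likelihood(ped, model, "causal")
  ln <- oracle_likelihood(ped, model, "neutral")
  pc <- oracle_likelihood(solo, model, "causal")
  pn <- oracle_likelihood(solo, model, "neutral")
  (lc / pc) / (ln / pn)
}

# Random structurally valid pedigree of n members; parents always precede
# children, so no ancestry cycles, but marriage loops can occur. Observed
# carrier statuses are taken from gene-dropped genotypes so the evidence is
# always Mendelian-consistent (positive likelihood).
rand_ped <- function(n, p_child = 0.8) {
  resample1 <- function(x) x[sample.int(length(x), 1)]
  id <- as.character(seq_len(n))
  fa_i <- rep(NA_integer_, n)
  mo_i <- rep(NA_integer_, n)
  sex <- c("male", "female", sample(c("male", "female"), n - 2, replace = TRUE))
  for (i in seq_len(n)) {
    if (i <= 2) next
    males <- which(sex[seq_len(i - 1)] == "male")
    females <- which(sex[seq_len(i - 1)] == "female")
    if (length(males) > 0 && length(females) > 0 && stats::runif(1) < p_child) {
      fa_i[i] <- resample1(males)
      mo_i[i] <- resample1(females)
    }
  }
  tr <- c(0, 0.5, 1)
  g <- integer(n)
  for (i in seq_len(n)) {
    g[i] <- if (is.na(fa_i[i])) {
      if (i == 1) 2L else resample1(c(1L, 1L, 2L))  # founder 1 always carries
    } else {
      1L + stats::rbinom(1, 1, tr[g[fa_i[i]]]) +
        stats::rbinom(1, 1, tr[g[mo_i[i]]])
    }
  }
  affected <- sample(c("affected", "unaffected", "unknown"), n,
                     replace = TRUE, prob = c(0.4, 0.4, 0.2))
  age <- ifelse(stats::runif(n) < 0.85, sample(20:85, n, replace = TRUE),
                NA_integer_)
  carrier <- ifelse(stats::runif(n) < 0.7,
                    ifelse(g >= 2, "carrier", "non_carrier"), "untested")
  pr <- resample1(which(g >= 2))
  affected[pr] <- "affected"
  carrier[pr] <- "carrier"
  pedigree(id = id, father_id = id[fa_i], mother_id = id[mo_i], sex = sex,
           affected = affected, age = age, carrier = carrier,
           proband = seq_len(n) == pr)
}

rand_model <- function() {
  disease_model(flat_penetrance(stats::runif(1, 0.3, 0.95),
                                stats::runif(1, 0.01, 0.25)),
                allele_freq = stats::runif(1, 1e-4, 0.05))
}

# A strongly co-segregating three-generation family used for sensitivity
# and contour checks: many affected carriers, a few unaffected
# non-carriers.
coseg_pedigree <- function() {
  pedigree(
    family_id = "SENS",
    id        = c("1", "2", "3", "4", "5", "6", "7", "8", "9"),
    father_id = c(NA, NA, "1", "1", "1", NA, "6", "6", "6"),
    mother_id = c(NA, NA, "2", "2", "2", NA, "3", "3", "3"),
    sex       = c("male", "female", "female", "male", "female",
                  "male", "female", "male", "female"),
    affected  = c("affected", "unaffected", "affected", "affected",
                  "unaffected", "unaffected", "affected", "affected",
                  "unaffected"),
    age       = c(75, 78, 52, 55, 50, 54, 33, 30, 28),
    carrier   = c("carrier", "non_carrier", "carrier", "carrier",
                  "non_carrier", "non_carrier", "carrier", "carrier",
                  "non_carrier"),
    proband   = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                  FALSE)
  )
}

# Synthetic stand-ins for carrier (Lynch-like) and population ("any
# cancer") incidence: log-linear hazards on a 5-year grid to age 85.
carrier_incidence <- function() sim_incidence(intercept = -7.5, slope = 0.055)
population_incidence <- function() sim_incidence(intercept = -11, slope = 0.09)

# Quadratic-time recount of the w statistic, the oracle for neighborhood_w.
w_recount <- function(sites, radius_bp = 1e6) {
  ibs <- ibs_state(sites$g1, sites$g2)
  vapply(seq_len(nrow(sites)), function(i) {
    win <- sites$chrom == sites$chrom[i] &
      abs(sites$pos - sites$pos[i]) <= radius_bp
    mean(ibs[win] == 0)
  }, numeric(1))
}
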