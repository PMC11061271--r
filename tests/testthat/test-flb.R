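test_that("FLB is 1 whenever carrier and non-carrier penetrance coincide", {
  set.seed(303)
  for (rep in 1:20) {
    f <- runif(1, 0.01, 0.9)
    model <- disease_model(flat_penetrance(f, f),
                           allele_freq = runif(1, 1e-4, 0.05))
    ped <- rand_ped(sample(3:8, 1))
    expect_equal(flb(ped, model)$flb, 1, tolerance = 1e-12)
  }
})

test_that("a pedigree containing only the proband carries no evidence", {
  model <- disease_model(flat_penetrance(0.8, 0.05))
  solo <- pedigree(id = "P", sex = "male", affected = "affected", age = 45,
                   carrier = "carrier", proband = TRUE)
  expect_equal(flb(solo, model)$flb, 1, tolerance = 1e-12)
})

test_that("FLB matches exhaustive-enumeration oracle on random pedigrees", {
  set.seed(404)
  worst <- 0
  for (rep in 1:60) {
    ped <- rand_ped(sample(4:8, 1))
    model <- rand_model()
    got <- flb(ped, model)$flb
    want <- oracle_flb(ped, model)
    worst <- max(worst, abs(got - want) / want)
  }
  expect_lt(worst, 1e-9)
})

test_that("five-member fully typed pedigree matches the brute-force ratio", {
  model <- disease_model(flat_penetrance(0.5, 0.05), allele_freq = 0.001)
  fam <- pedigree(id = c("F", "M", "C1", "C2", "C3"),
                  father_id = c(NA, NA, "F", "F", "F"),
                  mother_id = c(NA, NA, "M", "M", "M"),
                  sex = c("male", "female", "male", "female", "female"),
                  affected = c("affected", "unaffected", "affected",
                               "affected", "unaffected"),
                  age = c(70, 68, 45, 42, 40),
                  carrier = c("carrier", "non_carrier", "carrier", "carrier",
                              "non_carrier"),
                  proband = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  got <- flb(fam, model)$flb
  expect_equal(got, oracle_flb(fam, model), tolerance = 1e-11)
  expect_gt(got, 1)  # co-segregation in the right direction
})

test_that("likelihoods multiply over disconnected families and FLB combines", {
  model <- disease_model(flat_penetrance(0.7, 0.1), allele_freq = 0.005)
  set.seed(11)
  p1 <- rand_ped(5)
  p2 <- rand_ped(4)
  p2$id <- paste0("b", p2$id)
  p2$father_id <- ifelse(is.na(p2$father_id), NA, paste0("b", p2$father_id))
  p2$mother_id <- ifelse(is.na(p2$mother_id), NA, paste0("b", p2$mother_id))
  both <- rbind(as.data.frame(p1), as.data.frame(p2))
  both$proband[which(both$proband)[2]] <- FALSE  # unique flag in the union
  class(both) <- c("pedigree", "data.frame")
  for (hyp in c("causal", "neutral"))
    expect_equal(
      pedigree_likelihood(both, model, hyp, log = TRUE),
      pedigree_likelihood(p1, model, hyp, log = TRUE) +
        pedigree_likelihood(p2, model, hyp, log = TRUE),
      tolerance = 1e-10)
  # combined evidence is the product of per-family Bayes factors
  r1 <- flb(p1, model); r2 <- flb(p2, model)
  comb <- combine_flb(list(r1, r2))
  expect_equal(comb$flb, r1$flb * r2$flb, tolerance = 1e-12)
})

test_that("combining the two printed per-family scores gives ~98.4", {
  comb <- combine_flb(c(12.10, 8.13))
  expect_equal(comb$flb, 12.10 * 8.13, tolerance = 1e-12)
  expect_equal(comb$flb, 98.37, tolerance = 1e-3)
  expect_identical(comb$evidence_level, "strong")
  expect_identical(combine_flb(7)$flb, 7)
  expect_equal(combine_flb(c(5, 1, 1))$flb, 5, tolerance = 1e-12)
})

test_that("evidence levels follow the supporting/strong thresholds", {
  expect_identical(combine_flb(8)$evidence_level, "none")
  expect_identical(combine_flb(8.13)$evidence_level, "supporting")
  expect_identical(combine_flb(16)$evidence_level, "supporting")
  expect_identical(combine_flb(16.01)$evidence_level, "strong")
  # thresholds are configurable
  expect_identical(combine_flb(3, thresholds = c(supporting = 2, strong = 4))$
                     evidence_level, "supporting")
})

test_that("flb rejects missing or mis-specified probands", {
  model <- disease_model(flat_penetrance(0.8, 0.05))
  ped <- coseg_pedigree()
  none <- ped; none$proband <- FALSE
  expect_error(flb(none, model), "exactly one proband")
  bad <- ped; bad$carrier[bad$proband] <- "untested"
  expect_error(flb(bad, model), "affected carrier")
})

test_that("sensitivity surface is 1 at zero excess and anchored at baseline", {
  ped <- coseg_pedigree()
  ca <- carrier_incidence()
  nc <- population_incidence()
  sg <- flb_sensitivity(ped, ca, nc,
                        factors = seq(0.5, 1.5, length.out = 5),
                        excesses = seq(0, 1, length.out = 5))
  expect_true(all(abs(sg$flb[, 1] - 1) < 1e-9))
  base_model <- disease_model(incidence_to_penetrance(ca, nc))
  expect_equal(sg$baseline, flb(ped, base_model)$flb, tolerance = 1e-9)
  # FLB non-decreasing in the excess fraction for this co-segregating family
  for (i in seq_along(sg$factors))
    expect_true(all(diff(sg$flb[i, ]) >= -1e-9))
})

test_that("iso-FLB contour points re-evaluate to the level", {
  ped <- coseg_pedigree()
  sg <- flb_sensitivity(ped, carrier_incidence(), population_incidence(),
                        factors = seq(0.5, 1.5, length.out = 9),
                        excesses = seq(0, 1, length.out = 9))
  expect_gt(max(sg$flb), 16)  # surface must cross the strong threshold
  ct <- flb_contour(sg, level = 16)
  expect_gt(nrow(ct), 0)
  vals <- flb_interpolate(sg, ct$factor, ct$excess)
  expect_lt(max(abs(vals - 16)), 1e-6)
  # analytic check: a linear surface has its contour at e = level / slope
  lin <- sg
  lin$flb <- matrix(rep(lin$excesses * 30, each = length(lin$factors)),
                    nrow = length(lin$factors))
  ct_lin <- flb_contour(lin, 16)
  expect_gt(nrow(ct_lin), 0)
  expect_true(all(abs(ct_lin$excess - 16 / 30) < 1e-9))
  # constant surface never crosses the level
  flat <- sg
  flat$flb[] <- 1
  expect_identical(nrow(flb_contour(flat, 16)), 0L)
})

test_that("simulated causal pedigrees push FLB up; neutral ones center near 1", {
  model <- disease_model(flat_penetrance(0.8, 0.05), allele_freq = 0.001)
  scores <- function(hyp, n) {
    vapply(seq_len(n), function(i) {
      ped <- sim_pedigree("three_generation", model, hyp,
                          n_children = 2, n_grandchildren = 2,
                          seed = 5000 + i)
      flb(ped, model)$log_flb
    }, numeric(1))
  }
  causal <- scores("causal", 100)
  neutral <- scores("neutral", 100)
  expect_gt(median(causal), 0)            # median FLB > 1 under causality
  expect_lt(median(neutral), 0)           # no inflation under neutrality
  expect_lt(mean(exp(neutral)), 1.5)      # mean Bayes factor stays ~<= 1
  expect_gt(median(causal), median(neutral))
})
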