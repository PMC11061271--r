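# Seeded generators for synthetic study inputs: pedigrees segregating a
# dominant variant (gene dropping), 5-year-grid incidence tables, and paired
# diploid genotypes with planted IBD segments. Everything is deterministic
# under a fixed seed so downstream analyses are testable without external
# data.

.G_AA <- 1L; .G_Aa <- 2L; .G_aa <- 3L
.is_carrier_g <- function(g) g >= 2L

.drop_child <- function(gf, gm) {
  t_allele <- c(0, 0.5, 1)
  a1 <- stats::rbinom(1, 1, t_allele[gf])
  a2 <- stats::rbinom(1, 1, t_allele[gm])
  1L + a1 + a2
}

#' Simulate a pedigree segregating a dominant variant
#'
#' Gene dropping: founder genotypes are drawn from Hardy-Weinberg
#' proportions at the model allele frequency (optionally forcing the first
#' founder to be a heterozygous carrier), offspring genotypes by Mendelian
#' transmission. Each member's affection status is then sampled from their
#' liability class: under `hypothesis = "causal"` carriers use the carrier
#' penetrance, under `"neutral"` everyone uses the non-carrier penetrance.
#' The proband is chosen among affected carriers; if none arises the whole
#' pedigree is resampled up to `max_retry` times.
#'
#' @param template `"three_generation"` (a founder couple, their children
#'   with married-in spouses, and grandchildren) or `"nuclear"` (one couple
#'   and their children).
#' @param model A [disease_model()].
#' @param hypothesis `"causal"` or `"neutral"`.
#' @param founder_carrier Force the first founder to carry the variant.
#' @param n_children Children of the founder couple (per gen-2 couple in the
#'   three-generation template, also the number of grandchild sibships).
#' @param n_grandchildren Children per gen-2 couple (three-generation only).
#' @param age_ranges Named list of inclusive age ranges per generation,
#'   `list(g1 =, g2 =, g3 =)`.
#' @param typing_prob Probability that a member's true carrier status is
#'   observed (the proband is always typed).
#' @param family_id Family identifier.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param max_retry Resampling cap when no affected carrier arises.
#' @return A [pedigree()] with the true genotypes attached as
#'   `attr(, "genotype")` (1 = AA, 2 = Aa, 3 = aa).
#' @export
sim_pedigree <- function(template = c("three_generation", "nuclear"),
                         model, hypothesis = c("causal", "neutral"),
                         founder_carrier = TRUE, n_children = 3,
                         n_grandchildren = 2,
                         age_ranges = list(g1 = c(70, 85), g2 = c(45, 60),
                                           g3 = c(20, 40)),
                         typing_prob = 0.9, family_id = "SIM1",
                         seed = NULL, max_retry = 100) {
  template <- match.arg(template)
  hypothesis <- match.arg(hypothesis)
  if (!is.null(seed)) set.seed(seed)
  q <- model$allele_freq
  hw <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  for (try in seq_len(max_retry)) {
    id <- character(0); fa <- character(0); mo <- character(0)
    sex <- character(0); gen <- integer(0); geno <- integer(0)
    add <- function(i, f, m, s, g, gt) {
      id <<- c(id, i); fa <<- c(fa, f); mo <<- c(mo, m)
      sex <<- c(sex, s); gen <<- c(gen, g); geno <<- c(geno, gt)
    }
    founder_g <- function(force_carrier = FALSE) {
      if (force_carrier) .G_Aa else sample.int(3L, 1, prob = hw)
    }
    add("1", NA, NA, "male", 1L, founder_g(founder_carrier))
    add("2", NA, NA, "female", 1L, founder_g())
    if (template == "nuclear") {
      for (k in seq_len(n_children))
        add(paste0("c", k), "1", "2",
            sample(c("male", "female"), 1), 2L,
            .drop_child(geno[1], geno[2]))
    } else {
      for (k in seq_len(n_children)) {
        cid <- paste0("2-", k)
        csex <- sample(c("male", "female"), 1)
        add(cid, "1", "2", csex, 2L, .drop_child(geno[1], geno[2]))
        spid <- paste0("2-", k, "s")
        spsex <- if (csex == "male") "female" else "male"
        add(spid, NA, NA, spsex, 2L, founder_g())
        for (j in seq_len(n_grandchildren)) {
          f <- if (csex == "male") cid else spid
          m <- if (csex == "male") spid else cid
          add(paste0("3-", k, "-", j), f, m,
              sample(c("male", "female"), 1), 3L,
              .drop_child(geno[id == f], geno[id == m]))
        }
      }
    }
    n <- length(id)
    age <- integer(n)
    for (i in seq_len(n)) {
      r <- age_ranges[[paste0("g", gen[i])]]
      age[i] <- sample(r[1]:r[2], 1)
    }
    p_aff <- penetrance_lookup(model$penetrance, sex, age,
                               carrier = (hypothesis == "causal") &
                                 .is_carrier_g(geno))
    affected <- ifelse(stats::runif(n) < p_aff, "affected", "unaffected")
    typed <- stats::runif(n) < typing_prob
    carrier <- ifelse(typed,
                      ifelse(.is_carrier_g(geno), "carrier", "non_carrier"),
                      "untested")
    cand <- which(affected == "affected" & .is_carrier_g(geno))
    if (length(cand) == 0) next
    pr <- if (length(cand) == 1) cand else sample(cand, 1)
    carrier[pr] <- "carrier"
    ped <- pedigree(id = id, father_id = fa, mother_id = mo, sex = sex,
                    affected = affected, age = age, carrier = carrier,
                    proband = seq_len(n) == pr, family_id = family_id)
    attr(ped, "genotype") <- geno
    return(ped)
  }
  stop("no affected carrier arose in ", max_retry,
       " attempts; check penetrance and founder_carrier")
}

#' Simulate a synthetic incidence table
#'
#' Builds a 5-year-grid incidence table, either from a log-linear hazard
#' `rate(age) = exp(intercept + slope * midpoint)` or from explicitly given
#' rates, with event counts consistent with the rates and person-years
#' (optionally Poisson-perturbed).
#'
#' @param shape `"log_linear"` or `"table"`.
#' @param intercept,slope Log-linear hazard parameters (log rate per
#'   person-year at age 0, and per-year slope).
#' @param rates Explicit per-group rates (for `shape = "table"`).
#' @param age_max Upper bound of the last group (grid is `seq(0, age_max,
#'   5)`).
#' @param person_years Person-years at risk per group (recycled).
#' @param sexes Sexes to tabulate (same parameters per sex).
#' @param noise Draw event counts as Poisson around the expected counts.
#' @param seed Integer seed (used when `noise = TRUE`).
#' @return An [incidence_table()].
#' @export
sim_incidence <- function(shape = c("log_linear", "table"),
                          intercept = -11, slope = 0.09, rates = NULL,
                          age_max = 85, person_years = 1e5,
                          sexes = c("female", "male"),
                          noise = FALSE, seed = NULL) {
  shape <- match.arg(shape)
  if (!is.null(seed)) set.seed(seed)
  lo <- seq(0, age_max - 5, by = 5)
  hi <- lo + 5
  mid <- (lo + hi) / 2
  rate1 <- switch(shape,
    log_linear = exp(intercept + slope * mid),
    table = {
      if (is.null(rates) || length(rates) != length(lo))
        stop("shape = 'table' needs one rate per age group")
      if (any(rates < 0)) stop("negative rates")
      as.numeric(rates)
    })
  py <- rep_len(person_years, length(lo))
  out <- NULL
  for (s in sexes) {
    ev <- rate1 * py
    if (noise) ev <- stats::rpois(length(ev), ev)
    out <- rbind(out, data.frame(sex = s, age_lo = lo, age_hi = hi,
                                 events = ev, person_years = py,
                                 stringsAsFactors = FALSE))
  }
  incidence_table(sex = out$sex, age_lo = out$age_lo, age_hi = out$age_hi,
                  events = out$events, person_years = out$person_years,
                  rate = out$events / out$person_years)
}

#' Simulate paired genotypes with planted IBD segments
#'
#' Generates biallelic SNV sites along one chromosome for two individuals.
#' Outside planted segments the four haplotypes are independent
#' Hardy-Weinberg draws at each site's allele frequency; inside a planted
#' segment the two individuals share exactly one haplotype (the other two
#' remain independent), so opposite homozygotes cannot occur there except
#' through genotyping error. Errors flip a dosage to an adjacent value with
#' the stated per-genotype probability. DP, GQ and FILTER are drawn from the
#' supplied distributions so that [filter_sites()] has realistic work to do.
#'
#' @param chrom Chromosome name.
#' @param length_bp Chromosome length.
#' @param density Expected variants per bp (default 1e-3, i.e. 1 per kb).
#' @param af_range Allele-frequency range; each site's frequency is uniform
#'   within it.
#' @param segments Planted IBD segments: data frame with `start_bp` and
#'   `length_cm` (converted to bp via the map; must not overlap), or `NULL`.
#' @param error_rate Per-genotype probability of a dosage flip (default
#'   0.002).
#' @param map A [genetic_map()] for this chromosome, or `NULL` for a uniform
#'   1 cM/Mb map.
#' @param dp_fn,gq_fn,filter_fn Generators for per-sample DP, per-sample GQ
#'   and per-site FILTER given a count `n`.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A `variant_sites` data frame (`chrom`, `pos`, `ref`, `alt`,
#'   `g1`, `g2`, `filter`, `dp1`, `dp2`, `gq1`, `gq2`, `cm`) with the
#'   planted segments (bp and cM bounds) attached as
#'   `attr(, "planted")`.
#' @export
sim_pair <- function(chrom = "chr2", length_bp = 5e7, density = 1e-3,
                     af_range = c(0.05, 0.5), segments = NULL,
                     error_rate = 0.002, map = NULL,
                     dp_fn = function(n) stats::rpois(n, 35),
                     gq_fn = function(n) pmin(99L, 40L + stats::rpois(n, 35)),
                     filter_fn = function(n)
                       ifelse(stats::runif(n) < 0.98, "PASS", "LowQual"),
                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (density <= 0) stop("density must be > 0")
  if (is.null(map))
    map <- genetic_map(chrom, c(1, length_bp), c(0, length_bp / 1e6))
  n <- round(length_bp * density)
  pos <- sort(sample.int(length_bp, n))
  cm <- interpolate_cm(data.frame(chrom = chrom, pos = pos, cm = NA_real_,
                                  stringsAsFactors = FALSE), map)$cm
  # planted segments: cM spans converted back to bp via the map
  in_seg <- rep(FALSE, n)
  planted <- NULL
  if (!is.null(segments) && nrow(segments) > 0) {
    g <- map[map$chrom == chrom, ]
    cm_of <- function(p) stats::approx(g$pos, g$cm, xout = p, rule = 2)$y
    pos_of <- function(c) stats::approx(g$cm, g$pos, xout = c, rule = 2,
                                        ties = "ordered")$y
    start_cm <- cm_of(segments$start_bp)
    end_cm <- start_cm + segments$length_cm
    end_bp <- pos_of(end_cm)
    o <- order(segments$start_bp)
    if (any(segments$start_bp[o][-1] <= end_bp[o][-length(o)]))
      stop("planted segments overlap")
    if (any(end_bp > length_bp)) stop("planted segment extends past chromosome")
    for (k in seq_along(start_cm))
      in_seg <- in_seg | (pos >= segments$start_bp[k] & pos <= end_bp[k])
    planted <- data.frame(start_bp = segments$start_bp, end_bp = end_bp,
                          start_cm = start_cm, end_cm = end_cm,
                          length_cm = segments$length_cm)
  }
  p <- stats::runif(n, af_range[1], af_range[2])
  h1a <- stats::rbinom(n, 1, p); h1b <- stats::rbinom(n, 1, p)
  h2a <- stats::rbinom(n, 1, p); h2b <- stats::rbinom(n, 1, p)
  h2a[in_seg] <- h1a[in_seg]  # one shared haplotype inside IBD segments
  g1 <- h1a + h1b
  g2 <- h2a + h2b
  flip <- function(g) {
    hit <- stats::runif(n) < error_rate
    d <- ifelse(g == 0, 1L, ifelse(g == 2L, -1L,
                                   ifelse(stats::runif(n) < 0.5, -1L, 1L)))
    ifelse(hit, g + d, g)
  }
  g1 <- flip(g1); g2 <- flip(g2)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  sites <- data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
    g1 = as.integer(g1), g2 = as.integer(g2),
    filter = filter_fn(n),
    dp1 = dp_fn(n), dp2 = dp_fn(n), gq1 = gq_fn(n), gq2 = gq_fn(n),
    cm = cm, stringsAsFactors = FALSE)
  class(sites) <- c("variant_sites", "data.frame")
  attr(sites, "planted") <- planted
  sites
}
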