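#' Construct an incidence table
#'
#' Age-specific disease incidence on a contiguous grid of 5-year age groups
#' `[age_lo, age_hi)`, per sex, as events per person-year. The rate may be
#' given directly or derived from event counts and person-years at risk
#' (counts are required by [smooth_incidence()], which fits a Poisson model).
#'
#' @param sex Character vector, `"male"`/`"female"`.
#' @param age_lo,age_hi Lower (inclusive) and upper (exclusive) bounds of
#'   each age group, in years.
#' @param events Event counts per group (optional if `rate` given).
#' @param person_years Person-years at risk per group (optional if `rate`
#'   given).
#' @param rate Events per person-year; computed as `events / person_years`
#'   when omitted.
#' @return A data frame of class `incidence_table` with columns `sex`,
#'   `age_lo`, `age_hi`, `events`, `person_years`, `rate`, ordered by sex
#'   and age.
#' @export
incidence_table <- function(sex, age_lo, age_hi, events = NA_real_,
                            person_years = NA_real_, rate = NULL) {
  n <- length(age_lo)
  if (is.null(rate)) {
    if (any(is.na(events)) || any(is.na(person_years)))
      stop("rate must be given when events/person_years are incomplete")
    rate <- events / person_years
  }
  tab <- data.frame(
    sex = rep_len(as.character(sex), n),
    age_lo = as.numeric(age_lo), age_hi = as.numeric(age_hi),
    events = rep_len(as.numeric(events), n),
    person_years = rep_len(as.numeric(person_years), n),
    rate = rep_len(as.numeric(rate), n),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$sex, tab$age_lo), , drop = FALSE]
  rownames(tab) <- NULL
  for (s in unique(tab$sex)) {
    g <- tab[tab$sex == s, ]
    if (any(g$age_hi <= g$age_lo))
      stop("age groups must have age_hi > age_lo")
    if (nrow(g) > 1 && any(abs(g$age_hi[-nrow(g)] - g$age_lo[-1]) > 1e-9))
      stop("age groups for sex '", s, "' must be contiguous and non-overlapping")
  }
  if (any(tab$rate < 0)) stop("negative incidence rate")
  ok <- !is.na(tab$events) & !is.na(tab$person_years)
  if (any(ok & abs(tab$rate - tab$events / tab$person_years) >
            1e-8 * pmax(tab$rate, 1e-12)))
    stop("rate inconsistent with events / person_years")
  class(tab) <- c("incidence_table", "data.frame")
  tab
}

#' Read an incidence CSV
#'
#' Columns `sex`, `age_lo`, `age_hi`, `events`, `person_years`, `rate`;
#' `rate` is optional when `events` and `person_years` are present.
#'
#' @param path File path.
#' @return An [incidence_table()].
#' @export
read_incidence <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop(path, ": incidence table has no rows")
  need <- c("sex", "age_lo", "age_hi")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  incidence_table(
    sex = raw$sex, age_lo = raw$age_lo, age_hi = raw$age_hi,
    events = if ("events" %in% names(raw)) raw$events else NA_real_,
    person_years = if ("person_years" %in% names(raw)) raw$person_years else NA_real_,
    rate = if ("rate" %in% names(raw)) raw$rate else NULL
  )
}

#' @rdname read_incidence
#' @param tab An [incidence_table()].
#' @export
write_incidence <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' Pre-smooth age-specific incidence rates
#'
#' Fits, per sex, a penalized Poisson spline regression of event counts on
#' age-group midpoint with a log person-years offset, using a thin-plate
#' regression spline basis of dimension `k` with the smoothing parameter
#' chosen by generalized cross-validation (via [mgcv::gam()]). Intended to
#' reduce sampling noise in sparse age-specific rates before they enter
#' penetrance construction.
#'
#' @param tab An [incidence_table()] with `events` and `person_years`.
#' @param k Spline basis dimension (default 3; must be >= 3).
#' @param sp Optional fixed smoothing parameter; `sp = 0` disables the
#'   penalty (with `k` equal to the number of age groups this reproduces the
#'   raw rates).
#' @return An [incidence_table()] on the same age grid with fitted rates
#'   (and `events` replaced by fitted counts, so that
#'   `rate == events / person_years` still holds).
#' @export
smooth_incidence <- function(tab, k = 3, sp = NULL) {
  if (k < 3) stop("basis dimension k must be >= 3")
  if (any(is.na(tab$events)) || any(is.na(tab$person_years)))
    stop("smoothing requires events and person_years (Poisson likelihood)")
  if (all(tab$person_years == 0)) stop("all person_years are zero")
  out <- tab
  for (s in unique(tab$sex)) {
    i <- which(tab$sex == s)
    if (length(i) < k)
      stop("fewer age groups (", length(i), ") than basis dimension k = ", k)
    d <- data.frame(
      events = tab$events[i],
      mid = (tab$age_lo[i] + tab$age_hi[i]) / 2,
      off = log(tab$person_years[i])
    )
    fit <- suppressWarnings(mgcv::gam(
      events ~ s(mid, k = k, bs = "tp"), offset = off,
      family = stats::poisson(), data = d, method = "GCV.Cp", sp = sp
    ))
    mu <- as.numeric(stats::fitted(fit))  # fitted event counts
    out$events[i] <- mu
    out$rate[i] <- mu / tab$person_years[i]
  }
  out
}

#' Build a penetrance model from carrier and non-carrier incidence
#'
#' Converts age-specific incidence rates into cumulative probabilities of
#' disease by the end of each 5-year age group, per sex and carrier status,
#' under the survival model `F(k) = 1 - exp(-sum_{j<=k} lambda_j * width_j)`.
#' Individuals of unknown age are assigned an average class: by default the
#' unweighted mean of the cumulative risks across age groups (per sex and
#' carrier status); set `average = "person_years"` to weight by the
#' non-missing person-years of the corresponding table.
#'
#' @param carrier,noncarrier [incidence_table()]s on a common age grid per
#'   sex; `carrier` holds disease incidence in variant carriers, `noncarrier`
#'   the population (phenocopy) incidence.
#' @param average `"unweighted"` or `"person_years"`; how the unknown-age
#'   class is averaged over age groups.
#' @return An object of class `penetrance_model`: list with `classes`
#'   (data frame `sex`, `age_lo`, `age_hi`, `f_carrier`, `f_noncarrier`
#'   giving cumulative risk at the end of each group), `average`
#'   (per-sex unknown-age class) and `rates` (the input hazards, used to
#'   extrapolate beyond the last tabulated group at its constant rate).
#' @seealso [penetrance_lookup()], [flat_penetrance()]
#' @export
incidence_to_penetrance <- function(carrier, noncarrier,
                                    average = c("unweighted", "person_years")) {
  average <- match.arg(average)
  if (any(carrier$rate < 0) || any(noncarrier$rate < 0))
    stop("negative incidence rate")
  sexes <- sort(unique(c(carrier$sex, noncarrier$sex)))
  classes <- NULL
  rates <- NULL
  avg <- NULL
  for (s in sexes) {
    ca <- carrier[carrier$sex == s, , drop = FALSE]
    nc <- noncarrier[noncarrier$sex == s, , drop = FALSE]
    if (nrow(ca) == 0 || nrow(nc) == 0)
      stop("sex '", s, "' missing from one of the incidence tables")
    if (nrow(ca) != nrow(nc) ||
        any(abs(ca$age_lo - nc$age_lo) > 1e-9) ||
        any(abs(ca$age_hi - nc$age_hi) > 1e-9))
      stop("carrier and non-carrier age grids differ for sex '", s, "'")
    w <- ca$age_hi - ca$age_lo
    f_c <- 1 - exp(-cumsum(ca$rate * w))
    f_n <- 1 - exp(-cumsum(nc$rate * w))
    classes <- rbind(classes, data.frame(
      sex = s, age_lo = ca$age_lo, age_hi = ca$age_hi,
      f_carrier = f_c, f_noncarrier = f_n, stringsAsFactors = FALSE))
    rates <- rbind(rates, data.frame(
      sex = s, age_lo = ca$age_lo, age_hi = ca$age_hi,
      rate_carrier = ca$rate, rate_noncarrier = nc$rate,
      stringsAsFactors = FALSE))
    wt_c <- if (average == "person_years" && !any(is.na(ca$person_years)))
      ca$person_years else rep(1, nrow(ca))
    wt_n <- if (average == "person_years" && !any(is.na(nc$person_years)))
      nc$person_years else rep(1, nrow(nc))
    avg <- rbind(avg, data.frame(
      sex = s,
      f_carrier = sum(f_c * wt_c) / sum(wt_c),
      f_noncarrier = sum(f_n * wt_n) / sum(wt_n),
      stringsAsFactors = FALSE))
  }
  structure(list(classes = classes, average = avg, rates = rates),
            class = "penetrance_model")
}

#' Constant (liability-class-free) penetrance
#'
#' Convenience constructor for a penetrance model with a single
#' age-independent risk per carrier status, used for toy pedigrees and tests.
#'
#' @param f_carrier,f_noncarrier Probabilities of being affected.
#' @return A `penetrance_model`.
#' @export
flat_penetrance <- function(f_carrier, f_noncarrier) {
  classes <- data.frame(
    sex = rep(c("male", "female"), each = 1),
    age_lo = 0, age_hi = 150,
    f_carrier = f_carrier, f_noncarrier = f_noncarrier,
    stringsAsFactors = FALSE)
  avg <- data.frame(sex = c("male", "female"),
                    f_carrier = f_carrier, f_noncarrier = f_noncarrier,
                    stringsAsFactors = FALSE)
  structure(list(classes = classes, average = avg, rates = NULL),
            class = "penetrance_model")
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat("Penetrance model:", nrow(x$classes), "liability classes\n")
  print(utils::head(x$classes, 12), row.names = FALSE)
  if (nrow(x$classes) > 12) cat("...\n")
  cat("Unknown-age class:\n")
  print(x$average, row.names = FALSE)
  invisible(x)
}

#' Look up cumulative risk for a liability class
#'
#' Returns the cumulative probability of disease by the end of the age group
#' containing `age`, for the given sex and carrier status. Ages beyond the
#' last tabulated group accrue hazard at the last group's constant rate;
#' unknown ages (`NA`) map to the model's average class.
#'
#' @param pm A `penetrance_model`.
#' @param sex `"male"` or `"female"` (vectorized).
#' @param age Age in years or `NA` (vectorized).
#' @param carrier Logical: carrier-class risk or non-carrier (phenocopy)
#'   risk (vectorized).
#' @return Numeric vector of probabilities in `[0, 1)`.
#' @export
penetrance_lookup <- function(pm, sex, age, carrier) {
  n <- max(length(sex), length(age), length(carrier))
  sex <- rep_len(sex, n); age <- rep_len(age, n); carrier <- rep_len(carrier, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    col <- if (carrier[i]) "f_carrier" else "f_noncarrier"
    if (is.na(age[i])) {
      out[i] <- pm$average[pm$average$sex == sex[i], col]
      next
    }
    cl <- pm$classes[pm$classes$sex == sex[i], , drop = FALSE]
    if (nrow(cl) == 0) stop("no penetrance classes for sex '", sex[i], "'")
    j <- findInterval(age[i], cl$age_lo)  # group with age_lo <= age
    if (j < 1) j <- 1
    if (age[i] >= cl$age_hi[nrow(cl)]) {
      # extrapolate: hazard constant at the last tabulated rate
      f_last <- cl[[col]][nrow(cl)]
      if (is.null(pm$rates)) { out[i] <- f_last; next }
      rt <- pm$rates[pm$rates$sex == sex[i], , drop = FALSE]
      rcol <- if (carrier[i]) "rate_carrier" else "rate_noncarrier"
      lam <- rt[[rcol]][nrow(rt)]
      # cumulative risk at the end of the (virtual) group containing age
      wid <- cl$age_hi[nrow(cl)] - cl$age_lo[nrow(cl)]
      extra <- (ceiling((age[i] - cl$age_hi[nrow(cl)]) / wid) + 1) * wid
      out[i] <- 1 - (1 - f_last) * exp(-lam * extra)
    } else {
      out[i] <- cl[[col]][j]
    }
  }
  out
}

#' Specify the disease model for pedigree analysis
#'
#' Autosomal dominant single-locus model: founder genotypes follow
#' Hardy-Weinberg proportions at the variant allele frequency, transmission
#' is Mendelian, and heterozygous and homozygous carriers share the carrier
#' penetrance.
#'
#' @param penetrance A `penetrance_model` (see [incidence_to_penetrance()],
#'   [flat_penetrance()]).
#' @param allele_freq Population frequency of the variant allele (default
#'   0.001, i.e. 0.1%).
#' @return An object of class `disease_model`.
#' @export
disease_model <- function(penetrance, allele_freq = 0.001) {
  if (!(allele_freq > 0 && allele_freq < 1))
    stop("allele_freq must be in (0, 1)")
  if (!inherits(penetrance, "penetrance_model"))
    stop("penetrance must be a penetrance_model")
  structure(list(inheritance = "autosomal_dominant",
                 allele_freq = allele_freq,
                 penetrance = penetrance),
            class = "disease_model")
}
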