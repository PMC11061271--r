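#' Full-likelihood Bayes factor for co-segregation
#'
#' Computes the full-likelihood Bayes factor (FLB): the ratio of the
#' probability of a family's phenotype and carrier-status data under the
#' hypothesis that the variant is disease-causing versus neutral, each term
#' conditioned on the proband being a carrier to correct for ascertainment.
#' With `L(H)` the pedigree likelihood of [pedigree_likelihood()] and
#' `P0(H)` the marginal probability of the proband's own data (carrier
#' genotype and phenotype) under hypothesis `H`,
#'
#' \deqn{FLB = \frac{L(causal)/P_0(causal)}{L(neutral)/P_0(neutral)}}
#'
#' `P0(H)` is evaluated as the likelihood of the proband in isolation
#' (Hardy-Weinberg carrier probability times the penetrance of the proband's
#' liability class under `H`), which equals the proband's marginal within the
#' pedigree. A pedigree consisting only of the proband therefore has FLB = 1:
#' conditioning removes all of its evidence.
#'
#' Evidence levels follow the thresholds used for translation to variant
#' classification frameworks: `supporting` for FLB > 8 and `strong` for
#' FLB > 16 (configurable).
#'
#' @param ped A [pedigree()] with exactly one proband, recorded as an
#'   affected carrier.
#' @param model A [disease_model()].
#' @param thresholds Named numeric vector `c(supporting = 8, strong = 16)`.
#' @return An object of class `flb`: list with elements `flb`, `log_flb`,
#'   `family_id`, `evidence_level`, `thresholds`, and the component
#'   log-likelihoods (`loglik_causal`, `loglik_neutral`, and the proband
#'   conditioning terms).
#' @seealso [combine_flb()], [flb_sensitivity()]
#' @export
flb <- function(ped, model, thresholds = c(supporting = 8, strong = 16)) {
  .stop_if_invalid(ped)
  pr <- which(ped$proband)
  if (length(pr) != 1)
    stop("FLB requires exactly one proband (found ", length(pr), ")")
  if (ped$carrier[pr] != "carrier" || ped$affected[pr] != "affected")
    stop("the proband must be recorded as an affected carrier (conditioning event)")
  ll_c <- pedigree_likelihood(ped, model, "causal", log = TRUE)
  ll_n <- pedigree_likelihood(ped, model, "neutral", log = TRUE)
  solo <- ped[pr, , drop = FALSE]
  solo$father_id <- NA_character_
  solo$mother_id <- NA_character_
  class(solo) <- c("pedigree", "data.frame")
  lp_c <- pedigree_likelihood(solo, model, "causal", log = TRUE)
  lp_n <- pedigree_likelihood(solo, model, "neutral", log = TRUE)
  if (!is.finite(ll_n - lp_n))
    stop("neutral likelihood is zero; data impossible under the neutral model")
  log_flb <- (ll_c - lp_c) - (ll_n - lp_n)
  structure(list(
    flb = exp(log_flb), log_flb = log_flb,
    family_id = ped$family_id[1],
    evidence_level = .evidence_level(exp(log_flb), thresholds),
    thresholds = thresholds,
    loglik_causal = ll_c, loglik_neutral = ll_n,
    proband_cond_causal = lp_c, proband_cond_neutral = lp_n
  ), class = "flb")
}

.evidence_level <- function(flb, thresholds) {
  if (flb > thresholds[["strong"]]) "strong"
  else if (flb > thresholds[["supporting"]]) "supporting"
  else "none"
}

#' @export
print.flb <- function(x, ...) {
  cat(sprintf("Full-likelihood Bayes factor (family %s)\n", x$family_id))
  cat(sprintf("  FLB = %.4g (log FLB = %.4g)\n", x$flb, x$log_flb))
  cat(sprintf("  evidence level: %s (supporting > %g, strong > %g)\n",
              x$evidence_level, x$thresholds[["supporting"]],
              x$thresholds[["strong"]]))
  invisible(x)
}

#' Combine FLB evidence across independent families
#'
#' Independent families multiply: the combined Bayes factor is the product of
#' the per-family FLB values (equivalently, log-FLB values add). The evidence
#' level is recomputed for the combined score.
#'
#' @param results A list of `flb` objects, or a numeric vector of FLB values.
#' @param thresholds As in [flb()].
#' @return An `flb` object with `family_id` the concatenation of the inputs'.
#' @examples
#' combine_flb(c(12.10, 8.13))  # two families, combined score ~98.4
#' @export
combine_flb <- function(results, thresholds = c(supporting = 8, strong = 16)) {
  if (length(results) == 0) stop("no FLB results to combine")
  if (is.numeric(results)) {
    val <- prod(results)
    fam <- paste(seq_along(results), collapse = "+")
  } else {
    stopifnot(all(vapply(results, inherits, logical(1), "flb")))
    val <- prod(vapply(results, `[[`, numeric(1), "flb"))
    fam <- paste(vapply(results, `[[`, character(1), "family_id"),
                 collapse = "+")
  }
  structure(list(flb = val, log_flb = log(val), family_id = fam,
                 evidence_level = .evidence_level(val, thresholds),
                 thresholds = thresholds),
            class = "flb")
}

#' Penetrance sensitivity analysis of the FLB
#'
#' Recomputes the FLB over a grid of increasingly conservative penetrance
#' assumptions. For scale factor `f` and carrier excess `e`, the non-carrier
#' incidence rates are multiplied by `f`, and the carrier rates are replaced
#' by the weighted average `(1 - e) * lambda_nc + e * lambda_c` between the
#' (by default, scaled) non-carrier rates and the original carrier
#' estimates. At `e = 0` carriers and non-carriers coincide and the FLB is
#' identically 1; `(f = 1, e = 1)` is the unperturbed baseline.
#'
#' @param peds A [pedigree()] or list of pedigrees (independent families;
#'   their FLBs are combined by [combine_flb()]).
#' @param carrier,noncarrier [incidence_table()]s as in
#'   [incidence_to_penetrance()].
#' @param allele_freq Variant allele frequency.
#' @param factors Grid of non-carrier scale factors within `[0.5, 1.5]`.
#' @param excesses Grid of carrier excess fractions within `[0, 1]`.
#' @param weight_scaled If `TRUE` (default) the weighted average mixes the
#'   carrier rates with the *scaled* non-carrier rates; if `FALSE`, with the
#'   original ones.
#' @param thresholds Passed to [flb()].
#' @return An object of class `flb_sensitivity`: list with `factors`,
#'   `excesses`, matrix `flb` (`length(factors)` by `length(excesses)`) and
#'   `baseline` (the FLB at `f = 1, e = 1`, if on the grid).
#' @seealso [flb_contour()], [plot.flb_sensitivity()]
#' @export
flb_sensitivity <- function(peds, carrier, noncarrier, allele_freq = 0.001,
                            factors = seq(0.5, 1.5, length.out = 21),
                            excesses = seq(0, 1, length.out = 21),
                            weight_scaled = TRUE,
                            thresholds = c(supporting = 8, strong = 16)) {
  if (any(factors < 0.5 - 1e-9) || any(factors > 1.5 + 1e-9))
    stop("factors must lie within [0.5, 1.5]")
  if (any(excesses < -1e-9) || any(excesses > 1 + 1e-9))
    stop("excesses must lie within [0, 1]")
  if (inherits(peds, "pedigree")) peds <- list(peds)
  z <- matrix(NA_real_, length(factors), length(excesses),
              dimnames = list(factor = signif(factors, 6),
                              excess = signif(excesses, 6)))
  for (i in seq_along(factors)) {
    f <- factors[i]
    nc <- noncarrier
    nc$rate <- nc$rate * f
    nc$events <- nc$rate * nc$person_years
    base_nc <- if (weight_scaled) nc else noncarrier
    for (j in seq_along(excesses)) {
      e <- excesses[j]
      ca <- carrier
      ca$rate <- (1 - e) * base_nc$rate + e * carrier$rate
      ca$events <- ca$rate * ca$person_years
      pm <- incidence_to_penetrance(ca, nc)
      model <- disease_model(pm, allele_freq)
      res <- lapply(peds, flb, model = model, thresholds = thresholds)
      z[i, j] <- exp(sum(vapply(res, `[[`, numeric(1), "log_flb")))
    }
  }
  bi <- which(abs(factors - 1) < 1e-9)
  bj <- which(abs(excesses - 1) < 1e-9)
  baseline <- if (length(bi) == 1 && length(bj) == 1) z[bi, bj] else NA_real_
  structure(list(factors = factors, excesses = excesses, flb = z,
                 baseline = baseline),
            class = "flb_sensitivity")
}

#' Extract an iso-FLB contour from a sensitivity grid
#'
#' Piecewise-linear level curve of the FLB surface in (factor, excess) space
#' by marching squares with bilinear interpolation on grid cells (via
#' [grDevices::contourLines()]). Returned points re-evaluate to the level
#' under the bilinear interpolant of the grid.
#'
#' @param grid An `flb_sensitivity` object.
#' @param level Contour level (e.g. 16, the strong-evidence threshold).
#' @return A data frame with columns `factor`, `excess`, `piece` (one piece
#'   per connected contour component); zero rows if the surface never
#'   crosses `level`.
#' @export
flb_contour <- function(grid, level = 16) {
  if (level <= 0) stop("level must be positive")
  if (length(grid$factors) < 2 || length(grid$excesses) < 2)
    stop("degenerate grid: need at least 2 points per axis")
  cl <- if (diff(range(grid$flb)) == 0) list()  # constant surface: no crossing
  else grDevices::contourLines(x = grid$factors, y = grid$excesses,
                               z = grid$flb, levels = level)
  if (length(cl) == 0)
    return(data.frame(factor = numeric(0), excess = numeric(0),
                      piece = integer(0)))
  do.call(rbind, lapply(seq_along(cl), function(k)
    data.frame(factor = cl[[k]]$x, excess = cl[[k]]$y, piece = k)))
}

#' Bilinear interpolation on a sensitivity grid
#'
#' Evaluates the piecewise-bilinear interpolant of the FLB surface at
#' arbitrary (factor, excess) points; used to verify contour accuracy.
#'
#' @param grid An `flb_sensitivity` object.
#' @param factor,excess Numeric vectors of coordinates inside the grid range.
#' @return Interpolated FLB values.
#' @export
flb_interpolate <- function(grid, factor, excess) {
  xs <- grid$factors; ys <- grid$excesses; z <- grid$flb
  n <- max(length(factor), length(excess))
  factor <- rep_len(factor, n); excess <- rep_len(excess, n)
  out <- numeric(n)
  for (k in seq_len(n)) {
    i <- min(max(findInterval(factor[k], xs), 1), length(xs) - 1)
    j <- min(max(findInterval(excess[k], ys), 1), length(ys) - 1)
    tx <- (factor[k] - xs[i]) / (xs[i + 1] - xs[i])
    ty <- (excess[k] - ys[j]) / (ys[j + 1] - ys[j])
    out[k] <- (1 - tx) * (1 - ty) * z[i, j] + tx * (1 - ty) * z[i + 1, j] +
      (1 - tx) * ty * z[i, j + 1] + tx * ty * z[i + 1, j + 1]
  }
  out
}

#' @export
print.flb_sensitivity <- function(x, ...) {
  cat(sprintf("FLB sensitivity grid: %d factors x %d excesses\n",
              length(x$factors), length(x$excesses)))
  cat(sprintf("  FLB range: %.4g .. %.4g; baseline (f=1, e=1): %.4g\n",
              min(x$flb), max(x$flb), x$baseline))
  invisible(x)
}

#' Contour plot of an FLB sensitivity surface
#'
#' @param x An `flb_sensitivity` object.
#' @param levels Contour levels to draw.
#' @param ... Passed to [graphics::contour()].
#' @export
plot.flb_sensitivity <- function(x, levels = c(1, 8, 16), ...) {
  graphics::contour(x$factors, x$excesses, x$flb, levels = levels,
                    xlab = "non-carrier incidence scale factor",
                    ylab = "carrier excess fraction", ...)
  if (1 %in% round(x$factors, 9) && 1 %in% round(x$excesses, 9))
    graphics::points(1, 1, pch = 3, cex = 1.5)
  invisible(x)
}
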