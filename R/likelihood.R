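# Single-locus pedigree likelihood.
#
# Genotype states are coded 1 = AA (no variant), 2 = Aa, 3 = aa, with the
# variant allele at population frequency q. Founders carry Hardy-Weinberg
# priors; non-founders a Mendelian transmission factor. Observed carrier
# statuses enter as hard evidence (no genotyping-error term). Loop-free
# pedigrees are evaluated by peeling (variable elimination over the
# moralized genotype graph, eliminating one individual at a time);
# small looped pedigrees fall back to exhaustive genotype enumeration.
# All computation is scaled in log space to avoid underflow.

.TRANSMIT <- local({
  t_allele <- c(0, 0.5, 1)  # P(transmit variant | genotype)
  T <- array(0, dim = c(3, 3, 3))  # [child, father, mother]
  for (f in 1:3) for (m in 1:3) {
    tf <- t_allele[f]; tm <- t_allele[m]
    T[1, f, m] <- (1 - tf) * (1 - tm)
    T[2, f, m] <- tf * (1 - tm) + (1 - tf) * tm
    T[3, f, m] <- tf * tm
  }
  T
})

# Per-individual phenotype probability for each genotype state, under a
# hypothesis. Affected individuals contribute cumulative risk by their
# recorded age; unaffected contribute its complement; unknown contribute 1.
.phenotype_matrix <- function(ped, model, hypothesis) {
  pm <- model$penetrance
  f_car <- penetrance_lookup(pm, ped$sex, ped$age, carrier = TRUE)
  f_non <- penetrance_lookup(pm, ped$sex, ped$age, carrier = FALSE)
  n <- nrow(ped)
  out <- matrix(1, n, 3)
  for (i in seq_len(n)) {
    f_by_g <- if (hypothesis == "causal") c(f_non[i], f_car[i], f_car[i])
              else rep(f_non[i], 3)
    out[i, ] <- switch(ped$affected[i],
                       affected   = f_by_g,
                       unaffected = 1 - f_by_g,
                       unknown    = rep(1, 3))
  }
  out
}

.evidence_matrix <- function(ped) {
  ev <- matrix(1, nrow(ped), 3)
  ev[ped$carrier == "carrier", 1] <- 0
  ev[ped$carrier == "non_carrier", 2:3] <- 0
  ev
}

# A pedigree is loop-free iff the bipartite individual/mating graph is a
# forest; detected with union-find while adding parent-mating-child edges.
.has_loop <- function(fa, mo) {
  n <- length(fa)
  kids <- which(!is.na(fa))
  if (length(kids) == 0) return(FALSE)
  mat_key <- paste(fa[kids], mo[kids])
  mat_id <- n + match(mat_key, unique(mat_key))
  parent <- seq_len(n + length(unique(mat_key)))
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  link <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra == rb) return(TRUE)  # cycle
    parent[ra] <<- rb
    FALSE
  }
  edges <- unique(rbind(cbind(fa[kids], mat_id), cbind(mo[kids], mat_id)))
  edges <- rbind(edges, cbind(kids, mat_id))
  for (e in seq_len(nrow(edges))) if (link(edges[e, 1], edges[e, 2])) return(TRUE)
  FALSE
}

# --- tiny discrete-factor toolkit (3 states per variable) ------------------

.f_product <- function(flist) {
  vars <- Reduce(union, lapply(flist, `[[`, "vars"))
  k <- length(vars)
  grid <- as.matrix(do.call(expand.grid, rep(list(1:3), k)))
  vals <- rep(1, nrow(grid))
  for (f in flist) {
    cols <- match(f$vars, vars)
    sub <- grid[, cols, drop = FALSE]
    idx <- as.vector((sub - 1) %*% (3^(seq_along(cols) - 1))) + 1L
    vals <- vals * f$vals[idx]
  }
  list(vars = vars, vals = vals)
}

.f_marginalize <- function(f, v) {
  pos <- match(v, f$vars)
  k <- length(f$vars)
  if (k == 1) return(list(vars = integer(0), vals = sum(f$vals)))
  arr <- array(f$vals, dim = rep(3, k))
  keep <- setdiff(seq_len(k), pos)
  vals <- apply(arr, keep, sum)
  list(vars = f$vars[keep], vals = as.vector(vals))
}

.peel_likelihood <- function(factors, n) {
  logc <- 0
  # greedy min-degree elimination order on the factor interaction graph
  adj <- matrix(FALSE, n, n)
  for (f in factors) if (length(f$vars) > 1)
    adj[f$vars, f$vars] <- TRUE
  diag(adj) <- FALSE
  alive <- rep(TRUE, n)
  order <- integer(0)
  for (step in seq_len(n)) {
    deg <- rowSums(adj[, alive, drop = FALSE]) + ifelse(alive, 0, Inf)
    deg[!alive] <- Inf
    v <- which.min(deg)
    nb <- which(adj[v, ] & alive)
    if (length(nb) > 1) adj[nb, nb] <- TRUE
    adj[v, ] <- FALSE; adj[, v] <- FALSE
    alive[v] <- FALSE
    order <- c(order, v)
  }
  for (v in order) {
    hit <- which(vapply(factors, function(f) v %in% f$vars, logical(1)))
    if (length(hit) == 0) next
    prod <- .f_product(factors[hit])
    factors[hit] <- NULL
    prod <- .f_marginalize(prod, v)
    m <- max(prod$vals)
    if (m <= 0) return(-Inf)
    logc <- logc + log(m)
    prod$vals <- prod$vals / m
    factors <- c(factors, list(prod))
  }
  scal <- vapply(factors, function(f) f$vals[1], numeric(1))
  if (any(scal <= 0)) return(-Inf)
  logc + sum(log(scal))
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

.enum_likelihood <- function(fa, mo, prior, w) {
  n <- length(fa)
  allowed <- lapply(seq_len(n), function(i) which(w[i, ] > 0))
  if (any(lengths(allowed) == 0)) return(-Inf)
  sizes <- lengths(allowed)
  free <- which(sizes > 1)
  if (prod(sizes[free]) > 3^12)
    stop("looped pedigree too large for exhaustive enumeration (> 3^12 genotype vectors)")
  G <- as.matrix(do.call(expand.grid, allowed))
  ll <- numeric(nrow(G))
  founders <- which(is.na(fa))
  for (i in founders)
    ll <- ll + log(prior[G[, i]] * w[i, G[, i]])
  for (i in setdiff(seq_len(n), founders))
    ll <- ll + log(.TRANSMIT[cbind(G[, i], G[, fa[i]], G[, mo[i]])] * w[i, G[, i]])
  .logsumexp(ll)
}

#' Single-locus pedigree likelihood
#'
#' Computes the probability of the observed phenotypes and carrier statuses
#' in a pedigree under a causal or neutral hypothesis, summing over all
#' unobserved genotypes. Founder genotypes follow Hardy-Weinberg proportions
#' at the model allele frequency and transmission is Mendelian. Under the
#' `causal` hypothesis each individual's phenotype probability is the
#' penetrance of their genotype class (heterozygous and homozygous carriers
#' share the carrier penetrance); under `neutral` every individual uses the
#' non-carrier penetrance regardless of genotype, so phenotypes carry no
#' information about the variant.
#'
#' Loop-free pedigrees are evaluated by peeling (variable elimination);
#' looped pedigrees fall back to exhaustive genotype enumeration when at most
#' twelve members have more than one admissible genotype, and are rejected
#' otherwise. Computation is carried out in log space.
#'
#' @param ped A [pedigree()].
#' @param model A [disease_model()].
#' @param hypothesis `"causal"` or `"neutral"`.
#' @param log Return the log-likelihood instead of the likelihood.
#' @return The likelihood (a probability in `[0, 1]`), or its log.
#' @export
pedigree_likelihood <- function(ped, model,
                                hypothesis = c("causal", "neutral"),
                                log = FALSE) {
  hypothesis <- match.arg(hypothesis)
  .stop_if_invalid(ped)
  fa <- match(ped$father_id, ped$id)
  mo <- match(ped$mother_id, ped$id)
  q <- model$allele_freq
  prior <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  w <- .phenotype_matrix(ped, model, hypothesis) * .evidence_matrix(ped)
  n <- nrow(ped)
  if (.has_loop(fa, mo)) {
    ll <- .enum_likelihood(fa, mo, prior, w)
  } else {
    factors <- vector("list", n)
    for (i in seq_len(n)) {
      if (is.na(fa[i])) {
        factors[[i]] <- list(vars = i, vals = prior * w[i, ])
      } else {
        vals <- .TRANSMIT * rep(w[i, ], times = 9)  # scales over child axis
        factors[[i]] <- list(vars = c(i, fa[i], mo[i]), vals = as.vector(vals))
      }
    }
    ll <- .peel_likelihood(factors, n)
  }
  if (log) ll else exp(ll)
}
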