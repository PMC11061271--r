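#' Construct a pedigree
#'
#' Builds a `pedigree` object: a data frame with one row per individual and a
#' directed family structure given by parent references. Founders have neither
#' parent recorded; non-founders must have both.
#'
#' @param id Character vector of unique individual identifiers.
#' @param father_id,mother_id Character vectors of parent identifiers
#'   (`NA` for founders). An individual must have either both parents or
#'   neither.
#' @param sex `"male"` or `"female"`.
#' @param affected Affection status: `"affected"`, `"unaffected"` or
#'   `"unknown"`.
#' @param age Integer age in years, or `NA` if unknown. For affected
#'   individuals this is the age at diagnosis; otherwise the age at last
#'   observation.
#' @param carrier Observed carrier status from genotyping: `"carrier"`,
#'   `"non_carrier"` or `"untested"`.
#' @param proband Logical; the index individual through whom the family was
#'   ascertained. [flb()] requires exactly one proband, recorded as an
#'   affected carrier.
#' @param family_id Single family identifier.
#'
#' @return A data frame of class `pedigree` with columns `family_id`, `id`,
#'   `father_id`, `mother_id`, `sex`, `affected`, `age`, `carrier`,
#'   `proband`.
#' @seealso [validate_pedigree()], [read_pedigree()], [flb()]
#' @examples
#' trio <- pedigree(
#'   id        = c("F", "M", "C"),
#'   father_id = c(NA, NA, "F"),
#'   mother_id = c(NA, NA, "M"),
#'   sex       = c("male", "female", "female"),
#'   affected  = c("unaffected", "affected", "affected"),
#'   age       = c(70, 65, 40),
#'   carrier   = c("non_carrier", "carrier", "carrier"),
#'   proband   = c(FALSE, FALSE, TRUE)
#' )
#' validate_pedigree(trio)
#' @export
pedigree <- function(id, father_id = NA_character_, mother_id = NA_character_,
                     sex, affected = "unknown", age = NA_integer_,
                     carrier = "untested", proband = FALSE,
                     family_id = "FAM1") {
  n <- length(id)
  ped <- data.frame(
    family_id = rep_len(as.character(family_id), n),
    id        = as.character(id),
    father_id = rep_len(as.character(father_id), n),
    mother_id = rep_len(as.character(mother_id), n),
    sex       = rep_len(as.character(sex), n),
    affected  = rep_len(as.character(affected), n),
    age       = rep_len(as.integer(age), n),
    carrier   = rep_len(as.character(carrier), n),
    proband   = rep_len(as.logical(proband), n),
    stringsAsFactors = FALSE
  )
  bad_sex <- !ped$sex %in% c("male", "female")
  if (any(bad_sex))
    stop("invalid sex value(s): ", paste(unique(ped$sex[bad_sex]), collapse = ", "))
  bad_aff <- !ped$affected %in% c("affected", "unaffected", "unknown")
  if (any(bad_aff))
    stop("invalid affection value(s): ", paste(unique(ped$affected[bad_aff]), collapse = ", "))
  bad_car <- !ped$carrier %in% c("carrier", "non_carrier", "untested")
  if (any(bad_car))
    stop("invalid carrier value(s): ", paste(unique(ped$carrier[bad_car]), collapse = ", "))
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree '%s': %d members (%d founders, %d affected, %d typed)\n",
              x$family_id[1], nrow(x),
              sum(is.na(x$father_id) & is.na(x$mother_id)),
              sum(x$affected == "affected"),
              sum(x$carrier != "untested")))
  if (any(x$proband))
    cat("Proband:", paste(x$id[x$proband], collapse = ", "), "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Validate a pedigree's structural invariants
#'
#' Checks parent references, sexes of parents, founder/non-founder parent
#' completeness, absence of ancestry cycles, id uniqueness, and that at most
#' one proband is flagged. Violations are reported, never thrown.
#'
#' @param ped A [pedigree()].
#' @return Character vector of violation descriptions, each naming the
#'   individual and the rule broken; empty if the pedigree is well formed.
#' @export
validate_pedigree <- function(ped) {
  v <- character(0)
  if (anyDuplicated(ped$id))
    v <- c(v, paste0("duplicate individual id(s): ",
                     paste(unique(ped$id[duplicated(ped$id)]), collapse = ", ")))
  fa <- match(ped$father_id, ped$id)
  mo <- match(ped$mother_id, ped$id)
  for (i in seq_len(nrow(ped))) {
    has_f <- !is.na(ped$father_id[i]); has_m <- !is.na(ped$mother_id[i])
    if (has_f != has_m)
      v <- c(v, paste0(ped$id[i], ": has one parent recorded; founders need neither, non-founders both"))
    if (has_f && is.na(fa[i]))
      v <- c(v, paste0(ped$id[i], ": father '", ped$father_id[i], "' not in pedigree"))
    if (has_m && is.na(mo[i]))
      v <- c(v, paste0(ped$id[i], ": mother '", ped$mother_id[i], "' not in pedigree"))
    if (has_f && !is.na(fa[i]) && ped$sex[fa[i]] != "male")
      v <- c(v, paste0(ped$id[i], ": father '", ped$father_id[i], "' is not male"))
    if (has_m && !is.na(mo[i]) && ped$sex[mo[i]] != "female")
      v <- c(v, paste0(ped$id[i], ": mother '", ped$mother_id[i], "' is not female"))
  }
  # ancestry cycles: walk parent links from each individual
  n <- nrow(ped)
  for (i in seq_len(n)) {
    seen <- logical(n)
    frontier <- c(fa[i], mo[i])
    frontier <- frontier[!is.na(frontier)]
    cyclic <- FALSE
    while (length(frontier) > 0 && !cyclic) {
      if (any(frontier == i)) { cyclic <- TRUE; break }
      seen[frontier] <- TRUE
      nxt <- unique(c(fa[frontier], mo[frontier]))
      nxt <- nxt[!is.na(nxt)]
      frontier <- nxt[!seen[nxt]]
    }
    if (cyclic)
      v <- c(v, paste0(ped$id[i], ": is their own ancestor (pedigree cycle)"))
  }
  if (sum(ped$proband) > 1)
    v <- c(v, paste0("more than one proband flagged (",
                     paste(ped$id[ped$proband], collapse = ", "),
                     "); analyses condition on a unique proband"))
  v
}

.stop_if_invalid <- function(ped) {
  v <- validate_pedigree(ped)
  if (length(v) > 0)
    stop("invalid pedigree: ", paste(v, collapse = "; "))
  invisible(ped)
}

#' Read / write the pedigree file format
#'
#' Tab-separated, one row per individual, a superset of the standard PED
#' columns 1-6: `family_id`, `id`, `father_id` (0 = none), `mother_id`
#' (0 = none), `sex` (1 = male, 2 = female), `affected` (0 unknown /
#' 1 unaffected / 2 affected), `age` (integer or NA), `carrier`
#' (C / N / U), `proband` (0/1). A header line is expected.
#'
#' @param path File path.
#' @return `read_pedigree()` returns a [pedigree()]; `write_pedigree()`
#'   returns `path` invisibly.
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = "NA")
  need <- c("family_id", "id", "father_id", "mother_id", "sex",
            "affected", "age", "carrier", "proband")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(raw) == 0) stop(path, ": no individuals in pedigree file")
  dec <- function(x, map, what) {
    out <- map[x]
    bad <- which(is.na(out) & !is.na(x))
    if (length(bad) > 0)
      stop(path, ": line ", bad[1] + 1L, ": bad ", what, " code '", x[bad[1]], "'")
    unname(out)
  }
  ped <- pedigree(
    family_id = raw$family_id,
    id        = raw$id,
    father_id = ifelse(raw$father_id == "0", NA_character_, raw$father_id),
    mother_id = ifelse(raw$mother_id == "0", NA_character_, raw$mother_id),
    sex       = dec(raw$sex, c("1" = "male", "2" = "female"), "sex"),
    affected  = dec(raw$affected,
                    c("0" = "unknown", "1" = "unaffected", "2" = "affected"),
                    "affection"),
    age       = suppressWarnings(as.integer(raw$age)),
    carrier   = dec(raw$carrier,
                    c(C = "carrier", N = "non_carrier", U = "untested"),
                    "carrier"),
    proband   = dec(raw$proband, c("0" = FALSE, "1" = TRUE), "proband")
  )
  v <- validate_pedigree(ped)
  if (length(v) > 0)
    stop(path, ": invalid pedigree: ", paste(v, collapse = "; "))
  ped
}

#' @rdname read_pedigree
#' @param ped A [pedigree()] to serialize.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(
    family_id = ped$family_id,
    id        = ped$id,
    father_id = ifelse(is.na(ped$father_id), "0", ped$father_id),
    mother_id = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    sex       = ifelse(ped$sex == "male", "1", "2"),
    affected  = c(unknown = "0", unaffected = "1", affected = "2")[ped$affected],
    age       = ifelse(is.na(ped$age), "NA", as.character(ped$age)),
    carrier   = c(carrier = "C", non_carrier = "N", untested = "U")[ped$carrier],
    proband   = ifelse(ped$proband, "1", "0"),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
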