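# Coordinate arithmetic and HGVS-style annotation for a
# duplication-insertion structural variant: a donor interval copied and
# inserted elsewhere on the same reference sequence. All coordinates are
# 1-based inclusive (HGVS convention).

#' Define a duplication-insertion breakpoint set
#'
#' @param reference Sequence accession (e.g. `"NC_000002.12"`).
#' @param insertion_pos Breakpoint coordinate: the first reference base
#'   immediately 3' of the inserted sequence (the insertion sits between
#'   `insertion_pos - 1` and `insertion_pos`).
#' @param donor_start,donor_end 1-based inclusive bounds of the duplicated
#'   donor interval.
#' @param donor_orientation `"forward"` or `"reverse"`; recorded for
#'   display, not used in arithmetic.
#' @return An object of class `breakpoint_set`.
#' @examples
#' b <- breakpoint_set("NC_000002.12", 47432457, 47682947, 47721794)
#' insertion_length(b)   # 38848 bp, the "39 kb" insertion
#' locus_distance(b)     # 250490 bp between breakpoint and donor
#' hgvs_ins(b)
#' @export
breakpoint_set <- function(reference, insertion_pos, donor_start, donor_end,
                           donor_orientation = c("forward", "reverse")) {
  donor_orientation <- match.arg(donor_orientation)
  if (donor_start > donor_end) stop("donor_start must be <= donor_end")
  if (insertion_pos < 2) stop("insertion_pos must be >= 2 (needs a left flank)")
  structure(list(reference = as.character(reference),
                 insertion_pos = as.numeric(insertion_pos),
                 donor_start = as.numeric(donor_start),
                 donor_end = as.numeric(donor_end),
                 donor_orientation = donor_orientation),
            class = "breakpoint_set")
}

#' @export
print.breakpoint_set <- function(x, ...) {
  cat(sprintf("Duplication-insertion on %s\n", x$reference))
  cat(sprintf("  insertion between %s and %s\n",
              format(x$insertion_pos - 1, big.mark = ","),
              format(x$insertion_pos, big.mark = ",")))
  cat(sprintf("  donor interval %s-%s (%s bp, %s)\n",
              format(x$donor_start, big.mark = ","),
              format(x$donor_end, big.mark = ","),
              format(insertion_length(x), big.mark = ","),
              x$donor_orientation))
  cat(" ", hgvs_ins(x), "\n")
  invisible(x)
}

#' Length of the inserted (duplicated) sequence
#'
#' Inclusive-interval arithmetic: `donor_end - donor_start + 1` bp.
#'
#' @param b A [breakpoint_set()].
#' @return Length in bp.
#' @export
insertion_length <- function(b) {
  b$donor_end - b$donor_start + 1
}

#' Signed distance from insertion breakpoint to donor interval
#'
#' `donor_start - insertion_pos`: positive when the donor lies downstream
#' (higher coordinates) of the insertion point, negative when upstream.
#'
#' @param b A [breakpoint_set()].
#' @return Signed distance in bp.
#' @export
locus_distance <- function(b) {
  b$donor_start - b$insertion_pos
}

#' HGVS-style genomic insertion string
#'
#' Serializes the breakpoint set as
#' `<reference>:g.<left>_<right>ins<donor_start>_<donor_end>`, where the
#' flank positions are the adjacent bases around the insertion point
#' (`right = insertion_pos`, `left = insertion_pos - 1`).
#'
#' @param b A [breakpoint_set()].
#' @return A single string.
#' @seealso [parse_hgvs_ins()]
#' @export
hgvs_ins <- function(b) {
  sprintf("%s:g.%.0f_%.0fins%.0f_%.0f", b$reference,
          b$insertion_pos - 1, b$insertion_pos, b$donor_start, b$donor_end)
}

#' Parse an HGVS-style genomic insertion string
#'
#' Inverse of [hgvs_ins()]; requires the shape
#' `<acc>:g.<L>_<L+1>ins<S>_<E>` with adjacent flank positions and
#' `S <= E`.
#'
#' @param s String to parse.
#' @return A [breakpoint_set()] (orientation defaults to forward).
#' @export
parse_hgvs_ins <- function(s) {
  m <- regmatches(s, regexec(
    "^([A-Za-z0-9_.]+):g\\.([0-9]+)_([0-9]+)ins([0-9]+)_([0-9]+)$", s))[[1]]
  if (length(m) == 0) stop("malformed HGVS insertion string: ", s)
  left <- as.numeric(m[3]); right <- as.numeric(m[4])
  if (right != left + 1)
    stop("flank positions ", left, "_", right,
         " are not adjacent; not a pure insertion")
  ds <- as.numeric(m[5]); de <- as.numeric(m[6])
  if (ds > de) stop("donor interval reversed: ", ds, " > ", de)
  breakpoint_set(m[2], right, ds, de)
}
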