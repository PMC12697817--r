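## Percentile-threshold binarization of electrochemical features and the
## seven-gate Boolean panel over five inputs (three SWV peak currents and
## the early/late mean capacitances).

#' Binarize electrochemical features by percentile thresholds
#'
#' Each feature belongs to a family (e.g. `"current"`, `"capacitance"`)
#' with its own high (75th percentile) and low (25th percentile)
#' thresholds. A feature is active (state 1) when its value is at or
#' above the family's high threshold, otherwise 0; the low threshold is
#' retained as provenance only. Thresholds may be given explicitly or
#' computed as linear-interpolation percentiles of a reference value
#' list per family.
#'
#' @param features Named numeric vector of feature values.
#' @param families Character vector (same length/names) assigning each
#'   feature to a family.
#' @param thresholds Named list: per family either `c(hi =, lo =)` or
#'   `NULL` to compute from `reference`.
#' @param reference Named list of numeric reference vectors per family
#'   (used when a family's thresholds are not supplied).
#' @param hi_pct,lo_pct Percentiles (0-100) used when computing
#'   thresholds from a reference list.
#' @return A list of class `gate_inputs`: `states` (named 0/1 integer
#'   vector, input order preserved) and `provenance` (data frame with
#'   feature, family, value, hi, lo).
#' @export
#' @examples
#' binarize_features(
#'   c(swv5 = 176.10, cap_late = 4.94e-8),
#'   families = c("current", "capacitance"),
#'   thresholds = list(current = c(hi = 160.71, lo = 154.30),
#'                     capacitance = c(hi = 5.34e-8, lo = 4.66e-8)))
binarize_features <- function(features, families, thresholds = list(),
                              reference = list(), hi_pct = 75,
                              lo_pct = 25) {
  if (is.null(names(features)))
    names(features) <- paste0("f", seq_along(features))
  if (length(families) != length(features))
    stop("families must match features", call. = FALSE)
  fam_names <- unique(families)
  thr <- list()
  for (fam in fam_names) {
    if (!is.null(thresholds[[fam]])) {
      th <- thresholds[[fam]]
      thr[[fam]] <- c(hi = unname(th["hi"]), lo = unname(th["lo"]))
    } else if (!is.null(reference[[fam]])) {
      q <- stats::quantile(reference[[fam]], c(hi_pct, lo_pct) / 100,
                           names = FALSE, type = 7)
      thr[[fam]] <- c(hi = q[1], lo = q[2])
    } else {
      stop(sprintf("no thresholds or reference values for family '%s'", fam),
           call. = FALSE)
    }
    if (!is.na(thr[[fam]]["lo"]) && thr[[fam]]["lo"] > thr[[fam]]["hi"])
      stop(sprintf("family '%s': lo threshold exceeds hi", fam),
           call. = FALSE)
  }
  hi <- vapply(families, function(f) thr[[f]]["hi"], numeric(1))
  lo <- vapply(families, function(f) thr[[f]]["lo"], numeric(1))
  states <- as.integer(features >= hi)
  names(states) <- names(features)
  structure(
    list(states = states,
         provenance = data.frame(feature = names(features),
                                 family = families,
                                 value = unname(features),
                                 hi = unname(hi), lo = unname(lo))),
    class = "gate_inputs"
  )
}

#' Evaluate the Boolean gate panel on five binary inputs
#'
#' NOT per input, AND, OR, NAND, NOR, XOR and XNOR over the ordered
#' quintuple (A, B, C, D, E). XOR is the left-fold parity
#' `(((A != B) != (C != D)) != E)`, i.e. 1 for an odd number of true
#' inputs; XNOR is its negation (1 for an even count). NAND/NOR/XNOR are
#' always the exact complements of AND/OR/XOR.
#'
#' @param states Integer/logical vector of exactly 5 values in {0, 1},
#'   or a `gate_inputs` object.
#' @return A list of class `gate_table`: `inputs`, `not` (named per
#'   input), `and`, `or`, `nand`, `nor`, `xor`, `xnor` (each 0 or 1).
#' @export
#' @examples
#' gate_panel(c(1, 1, 0, 1, 0))
gate_panel <- function(states) {
  if (inherits(states, "gate_inputs")) states <- states$states
  s <- as.integer(states)
  if (length(s) != 5L || any(!s %in% c(0L, 1L)))
    stop("need exactly 5 binary states", call. = FALSE)
  if (is.null(names(s)))
    names(s) <- c("A", "B", "C", "D", "E")
  and <- as.integer(all(s == 1L))
  or <- as.integer(any(s == 1L))
  xorv <- as.integer(sum(s) %% 2L)
  structure(
    list(inputs = s, not = 1L - s, and = and, or = or,
         nand = 1L - and, nor = 1L - or, xor = xorv, xnor = 1L - xorv),
    class = "gate_table"
  )
}

#' @export
print.gate_table <- function(x, ...) {
  cat("inputs:", paste(x$inputs, collapse = ""), "\n")
  cat(sprintf("AND %d  OR %d  NAND %d  NOR %d  XOR %d  XNOR %d\n",
              x$and, x$or, x$nand, x$nor, x$xor, x$xnor))
  invisible(x)
}
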