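# Activity-class assignment from triple-target IC50 profiles.
#
# Each compound carries (possibly censored) IC50 values in micromolar
# against ABCB1, ABCC1 and ABCG2. A censored value ">B" is known only to be
# at least B: it satisfies lower-bound conditions ("ter >= t" whenever
# B >= t) and never satisfies an upper-bound condition "< x" or "<= x".
# Classes are assigned by the first matching rule, in order:
#
#   1 SUPERIOR_CLASS7   all three < 5
#   2 MEDIUM_CLASS7     all three < 10 and at least one in [5, 10)
#   3 SEMI_CLASS7       all three <= 15 and at least one in [10, 15]
#   4 WEAK_PAN          exactly two in [20, 200) and the third < 10
#   5 VERY_WEAK_PAN     exactly two in [20, 200) and the third in [10, 200)
#   6 UNCLASSIFIED_PAN  all three < 200 (pan inhibitor, no named tier)
#   7 SEMI_CLASS0       no value < 10 and one or two values in [10, 200]
#   8 REAL_CLASS0       all three censored at >= 200 (no activity)
#   9 OTHER             anything else (e.g. potent on one target, inactive
#                       on another; or missing measurements)
#
# Boundary conventions: "< 5", "< 10", "< 200" strict; "<= 15" and the
# interval ends of [10, 15], ">= 20" and [10, 200] inclusive; the
# very-weak window [10, 200) is half-open so that a compound weak on all
# three targets stays inside the pan set.

.classify_one <- function(v, cens) {
  if (anyNA(v) || anyNA(cens)) return("OTHER")
  lt <- function(x) !cens & v < x          # upper bounds: censored never pass
  ge <- function(x) v >= x                 # lower bounds: ">B" counts as >= B
  between <- function(a, b, right_open = FALSE) {
    !cens & v >= a & (if (right_open) v < b else v <= b)
  }
  if (all(lt(5))) return("SUPERIOR_CLASS7")
  if (all(lt(10)) && any(between(5, 10, right_open = TRUE)))
    return("MEDIUM_CLASS7")
  if (all(!cens & v <= 15) && any(between(10, 15))) return("SEMI_CLASS7")
  w <- ge(20) & lt(200)
  if (sum(w) == 2) {
    rest <- which(!w)
    if (lt(10)[rest]) return("WEAK_PAN")
    if (between(10, 200, right_open = TRUE)[rest]) return("VERY_WEAK_PAN")
  }
  if (all(lt(200))) return("UNCLASSIFIED_PAN")
  n_weak <- sum(between(10, 200))
  if (!any(lt(10)) && n_weak >= 1 && n_weak <= 2) return("SEMI_CLASS0")
  if (all((cens & v >= 200) | (!cens & v > 200))) return("REAL_CLASS0")
  "OTHER"
}

#' Classify compounds by triple-target activity profile
#'
#' Assigns every compound exactly one activity class from
#' [activity_classes()] by the first matching rule of the potency scheme
#' (see the package vignette for the full rule table). Compounds with an
#' absent measurement on any target are classified `OTHER` with a warning.
#'
#' @param x A `capa_compounds` data frame (see [read_compounds()]).
#' @return Factor of classes with levels [activity_classes()], named by
#'   `compound_id`.
#' @export
#' @examples
#' d <- as_compounds(data.frame(
#'   id = c("a", "b"), smiles = c("CCO", "CCN"),
#'   ic50_abcb1 = c("3", "33.1"), ic50_abcc1 = c("4", "38.6"),
#'   ic50_abcg2 = c("4.2", "15.9")))
#' classify(d)
classify <- function(x) {
  stopifnot(inherits(x, "capa_compounds") || is.data.frame(x))
  v <- as.matrix(x[, paste0("ic50_", .TARGETS)])
  cens <- as.matrix(x[, paste0("cens_", .TARGETS)])
  if (any(v <= 0, na.rm = TRUE)) {
    stop("IC50 values must be positive", call. = FALSE)
  }
  out <- vapply(seq_len(nrow(x)),
                function(i) .classify_one(v[i, ], cens[i, ]), "")
  absent <- apply(is.na(v), 1, any)
  if (any(absent)) {
    warning(sum(absent), " compound(s) with absent measurement(s) ",
            "classified OTHER: ", .id_preview(x$compound_id[absent]),
            call. = FALSE)
  }
  stats::setNames(factor(out, levels = .ACTIVITY_CLASSES), x$compound_id)
}

#' Classify a single activity profile
#'
#' Convenience wrapper around the classification rules for one IC50 triple,
#' accepting the same cell notation as the CSV reader (numbers, `">200"`,
#' `"n.i."`, `""`).
#'
#' @param abcb1,abcc1,abcg2 IC50 values in micromolar (numeric or character
#'   cell).
#' @return Single class label (character).
#' @export
#' @examples
#' classify_profile(33.1, 38.6, 15.9)      # VERY_WEAK_PAN
#' classify_profile(22.7, "n.i.", 7.89)    # OTHER
classify_profile <- function(abcb1, abcc1, abcg2) {
  p <- .parse_activity(c(abcb1, abcc1, abcg2))
  .classify_one(p$ic50, p$censored)
}

#' Class census of a dataset
#'
#' Tallies the classification of a dataset: per-class counts plus the
#' derived totals used throughout the pattern analysis (pan inhibitors,
#' classified pan inhibitors, Class 7 = Superior + Medium, Class 0 tiers).
#'
#' @param classes Factor returned by [classify()].
#' @return A `capa_census` list with elements `counts` (named integer
#'   vector over [activity_classes()]), `n_total`, `n_pan`,
#'   `n_classified_pan`, `n_unclassified_pan`, `n_class7`, `n_class0`,
#'   `n_real_class0`, `n_semi_class0`.
#' @export
class_census <- function(classes) {
  counts <- table(factor(classes, levels = .ACTIVITY_CLASSES))
  counts <- stats::setNames(as.integer(counts), names(counts))
  out <- list(
    counts = counts,
    n_total = sum(counts),
    n_classified_pan = sum(counts[.CLASSIFIED_PAN]),
    n_unclassified_pan = counts[["UNCLASSIFIED_PAN"]],
    n_class7 = counts[["SUPERIOR_CLASS7"]] + counts[["MEDIUM_CLASS7"]],
    n_class0 = counts[["SEMI_CLASS0"]] + counts[["REAL_CLASS0"]],
    n_real_class0 = counts[["REAL_CLASS0"]],
    n_semi_class0 = counts[["SEMI_CLASS0"]]
  )
  out$n_pan <- out$n_classified_pan + out$n_unclassified_pan
  class(out) <- "capa_census"
  out
}

#' @export
print.capa_census <- function(x, ...) {
  cat("<capa_census> ", x$n_total, " compounds\n", sep = "")
  cat("  pan inhibitors: ", x$n_pan,
      " (classified ", x$n_classified_pan,
      ", unclassified ", x$n_unclassified_pan, ")\n", sep = "")
  cat("  Class 7 (Superior + Medium): ", x$n_class7, "\n", sep = "")
  cat("  Class 0: ", x$n_class0, " (Real ", x$n_real_class0,
      ", Semi ", x$n_semi_class0, ")\n", sep = "")
  for (cl in .ACTIVITY_CLASSES) {
    cat(sprintf("  %-18s %d\n", cl, x$counts[[cl]]))
  }
  invisible(x)
}
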