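# Individual pattern analysis: two-axis point scoring of substructures and
# landscape group assignment.
#
# Every substructure is graded on two ordinal axes (0 < + < ++ < +++):
# the *inner* axis measures association with potent pan inhibition
# (Superior/Medium Class 7 groups, IC50 < 10 uM on all targets), the
# *outer* axis association with weak pan inhibition (Semi Class 7, Weak
# and Very Weak Pan groups, 10-200 uM regime). Both axes are contrasted
# against the Class 0 groups. The numeric thresholds of the grading rules
# are configuration, not constants: `rule_config()` documents the shipped
# defaults and every analysis records which rule fired per substructure.

#' Rule configuration for the point-score engine
#'
#' Thresholds parameterizing the score predicates, per axis:
#' `*_strong`/`*_moderate`/`*_weak` are the minimum percentage a
#' substructure must reach in the best of the axis's positive groups to be
#' graded `+++`/`++`/`+` (must be non-increasing), `*_class0_max` caps the
#' Class 0 percentage allowed for a `+++` grade, and `*_min_ratio` is the
#' minimum positive-group : Class 0 contrast ratio required for `+++`/`++`.
#' `ratio_basis` chooses whether that contrast divides percentages or raw
#' hit counts. `inconclusive_spread` is the maximum max-min percentage
#' spread (points) across all groups under which a present-everywhere
#' intermediate substructure is called equally distributed, hence
#' inconclusive.
#'
#' The shipped defaults are implementer-calibrated, deliberately monotone
#' (raising a substructure's positive-group percentages can never lower its
#' score) and are documented in the package vignette.
#'
#' @param inner_strong,inner_moderate,inner_weak Inner-axis percentage
#'   thresholds for `+++`, `++`, `+`.
#' @param inner_class0_max Maximum Class 0 percentage compatible with an
#'   inner `+++`.
#' @param inner_min_ratio Minimum inner-positive : Class 0 ratio for
#'   `+++`/`++`.
#' @param outer_strong,outer_moderate,outer_weak,outer_class0_max,outer_min_ratio
#'   Same thresholds for the outer axis.
#' @param ratio_basis `"pct"` or `"count"`.
#' @param inconclusive_spread Percentage-point tolerance for the
#'   equal-distribution test.
#' @return A `capa_rule_config` list.
#' @export
rule_config <- function(inner_strong = 50, inner_moderate = 20,
                        inner_weak = 5, inner_class0_max = 10,
                        inner_min_ratio = 2,
                        outer_strong = 50, outer_moderate = 20,
                        outer_weak = 5, outer_class0_max = 10,
                        outer_min_ratio = 2,
                        ratio_basis = c("pct", "count"),
                        inconclusive_spread = 5) {
  ratio_basis <- match.arg(ratio_basis)
  cfg <- list(
    inner = list(strong = inner_strong, moderate = inner_moderate,
                 weak = inner_weak, class0_max = inner_class0_max,
                 min_ratio = inner_min_ratio),
    outer = list(strong = outer_strong, moderate = outer_moderate,
                 weak = outer_weak, class0_max = outer_class0_max,
                 min_ratio = outer_min_ratio),
    ratio_basis = ratio_basis,
    inconclusive_spread = inconclusive_spread
  )
  for (ax in c("inner", "outer")) {
    a <- cfg[[ax]]
    if (!(a$strong >= a$moderate && a$moderate >= a$weak)) {
      stop(ax, " axis thresholds must satisfy strong >= moderate >= weak",
           call. = FALSE)
    }
  }
  class(cfg) <- "capa_rule_config"
  cfg
}

.INNER_POSITIVE <- c("SUPERIOR_CLASS7", "MEDIUM_CLASS7")
.OUTER_POSITIVE <- c("SEMI_CLASS7", "WEAK_PAN", "VERY_WEAK_PAN")
.CLASS0_GROUPS <- c("SEMI_CLASS0", "REAL_CLASS0")

# score one axis from the distribution rows of a single substructure
.axis_score <- function(rows, pos_groups, axis_cfg, basis) {
  col <- if (basis == "pct") "pct" else "n_hits"
  p <- max(rows[[col]][rows$group %in% pos_groups])
  c0 <- max(rows[[col]][rows$group %in% .CLASS0_GROUPS])
  contrast_ok <- function() c0 == 0 || p / c0 >= axis_cfg$min_ratio
  p_pct <- max(rows$pct[rows$group %in% pos_groups])
  c0_pct <- max(rows$pct[rows$group %in% .CLASS0_GROUPS])
  if (p > 0 && p_pct >= axis_cfg$strong && c0_pct <= axis_cfg$class0_max &&
      contrast_ok()) {
    return(list(score = "+++", rule = "strong-presence, low Class 0"))
  }
  if (p > 0 && p_pct >= axis_cfg$moderate && contrast_ok()) {
    return(list(score = "++", rule = "moderate presence, Class 0 contrast"))
  }
  if (p_pct >= axis_cfg$weak && p > 0) {
    return(list(score = "+", rule = "weak presence"))
  }
  list(score = "0", rule = "no qualifying presence")
}

#' Point score of one substructure
#'
#' Grades a substructure on the inner and outer axes from its distribution
#' table rows, against the rule configuration.
#'
#' @param sub_id Substructure identifier present in `table`.
#' @param table Distribution table from [distribution_table()].
#' @param cfg A [rule_config()].
#' @return List with `inner` and `outer` (each one of `"0"`, `"+"`, `"++"`,
#'   `"+++"`) and the matching `rule_inner`/`rule_outer` descriptions.
#' @export
score_substructure <- function(sub_id, table, cfg = rule_config()) {
  rows <- table[table$sub_id == sub_id, ]
  if (!nrow(rows)) stop("unknown sub_id: ", sub_id, call. = FALSE)
  need <- c(.INNER_POSITIVE, .OUTER_POSITIVE, .CLASS0_GROUPS)
  miss <- setdiff(need, rows$group)
  if (length(miss)) stop("distribution table lacks group(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  inner <- .axis_score(rows, .INNER_POSITIVE, cfg$inner, cfg$ratio_basis)
  outer <- .axis_score(rows, .OUTER_POSITIVE, cfg$outer, cfg$ratio_basis)
  list(inner = inner$score, outer = outer$score,
       rule_inner = inner$rule, rule_outer = outer$rule)
}

#' Landscape group from a point score
#'
#' Deterministic mapping with inner-axis precedence: `+++` inner gives the
#' Superior Inner landscape, `++` inner the Inferior Inner landscape (this
#' is where a (++, ++) substructure such as an amino or indole pattern
#' lands), then `+++`/`++` outer give the Superior/Inferior Outer
#' landscape; every remaining combination (`+`/`+`, `+`/`0`, `0`/`+`,
#' `0`/`0`) is Intermediate.
#'
#' @param inner,outer Point-score levels (`"0"`, `"+"`, `"++"`, `"+++"`).
#' @return One of `"SUPERIOR_INNER"`, `"INFERIOR_INNER"`,
#'   `"SUPERIOR_OUTER"`, `"INFERIOR_OUTER"`, `"INTERMEDIATE"`.
#' @export
#' @examples
#' assign_landscape("+++", "0")   # SUPERIOR_INNER
#' assign_landscape("++", "++")   # INFERIOR_INNER (inner precedence)
assign_landscape <- function(inner, outer) {
  stopifnot(inner %in% .POINT_LEVELS, outer %in% .POINT_LEVELS)
  if (inner == "+++") return("SUPERIOR_INNER")
  if (inner == "++") return("INFERIOR_INNER")
  if (outer == "+++") return("SUPERIOR_OUTER")
  if (outer == "++") return("INFERIOR_OUTER")
  "INTERMEDIATE"
}

#' Sub-population of an Intermediate substructure
#'
#' Refines an Intermediate substructure from the raw presence pattern:
#' \describe{
#'   \item{UNTOLERATED_NEGATIVE}{present, but only in Real Class 0
#'     compounds -- it impedes pan inhibition outright.}
#'   \item{INCONCLUSIVE}{present in no compound at all, or present with a
#'     (near-)equal percentage across all groups (max-min spread within
#'     `cfg$inconclusive_spread`).}
#'   \item{TOLERATED_NEGATIVE}{present in Semi Class 0 compounds (weak
#'     residual activity on one or two targets) while absent from the
#'     unclassified pan inhibitors.}
#'   \item{PLAIN}{any other Intermediate pattern.}
#' }
#'
#' @param sub_id Substructure identifier (a matrix column).
#' @param matrix Binary matrix from [build_matrix()] covering the full
#'   dataset (including unclassified pan compounds).
#' @param classes Factor from [classify()] covering every matrix row.
#' @param cfg A [rule_config()].
#' @return One of `"UNTOLERATED_NEGATIVE"`, `"INCONCLUSIVE"`,
#'   `"TOLERATED_NEGATIVE"`, `"PLAIN"`.
#' @export
refine_intermediate <- function(sub_id, matrix, classes,
                                cfg = rule_config()) {
  if (!sub_id %in% colnames(matrix)) {
    stop("unknown sub_id: ", sub_id, call. = FALSE)
  }
  hits <- matrix[, sub_id]
  cls <- classes[rownames(matrix)]
  if (sum(hits) == 0) return("INCONCLUSIVE")
  hit_cls <- cls[hits]
  if (all(hit_cls == "REAL_CLASS0")) return("UNTOLERATED_NEGATIVE")
  nonempty <- .DISTRIBUTION_GROUPS[vapply(.DISTRIBUTION_GROUPS, function(g)
    any(cls == g, na.rm = TRUE), TRUE)]
  pct <- vapply(nonempty, function(g) {
    100 * sum(hits & cls == g, na.rm = TRUE) / sum(cls == g, na.rm = TRUE)
  }, 0)
  # near-equal presence across every (populated) group carries no signal
  if (min(pct) > 0 && max(pct) - min(pct) <= cfg$inconclusive_spread) {
    return("INCONCLUSIVE")
  }
  in_semi0 <- any(hit_cls == "SEMI_CLASS0")
  in_unclassified <- any(hit_cls == "UNCLASSIFIED_PAN")
  if (in_semi0 && !in_unclassified) return("TOLERATED_NEGATIVE")
  "PLAIN"
}

#' Full individual pattern analysis of a catalogue
#'
#' Scores every catalogue substructure on both axes, assigns its landscape
#' group, and refines Intermediate substructures into their
#' sub-populations.
#'
#' @param matrix Binary matrix from [build_matrix()] over the full dataset.
#' @param classes Factor from [classify()] covering every matrix row.
#' @param substructures The `capa_substructures` catalogue (matrix
#'   columns).
#' @param cfg A [rule_config()].
#' @return A `capa_landscape` data frame: `sub_id`, `name`, `provenance`,
#'   `inner`, `outer`, `group`, `subtype`, `rule_inner`, `rule_outer`.
#' @export
landscape_analysis <- function(matrix, classes, substructures,
                               cfg = rule_config()) {
  stopifnot(all(substructures$sub_id %in% colnames(matrix)))
  table <- distribution_table(matrix, classes)
  rows <- lapply(substructures$sub_id, function(id) {
    sc <- score_substructure(id, table, cfg)
    grp <- assign_landscape(sc$inner, sc$outer)
    sub <- if (grp == "INTERMEDIATE") {
      refine_intermediate(id, matrix, classes, cfg)
    } else "NONE"
    data.frame(sub_id = id, inner = sc$inner, outer = sc$outer,
               group = grp, subtype = sub,
               rule_inner = sc$rule_inner, rule_outer = sc$rule_outer,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(out[, "sub_id", drop = FALSE],
               name = substructures$name[match(out$sub_id,
                                               substructures$sub_id)],
               provenance = substructures$provenance[
                 match(out$sub_id, substructures$sub_id)],
               out[, -1])
  class(out) <- c("capa_landscape", "data.frame")
  out
}

#' Landscape census
#'
#' Counts substructures per landscape group and Intermediate sub-population.
#' Group counts always sum to the catalogue size.
#'
#' @param landscape A `capa_landscape` data frame from
#'   [landscape_analysis()].
#' @return List with `groups` (named counts over the five landscape groups)
#'   and `subtypes` (named counts over the Intermediate sub-populations).
#' @export
landscape_census <- function(landscape) {
  groups <- table(factor(landscape$group, levels = .LANDSCAPE_GROUPS))
  subtypes <- table(factor(landscape$subtype[
    landscape$group == "INTERMEDIATE"],
    levels = setdiff(.INTERMEDIATE_SUBTYPES, "NONE")))
  list(groups = stats::setNames(as.integer(groups), names(groups)),
       subtypes = stats::setNames(as.integer(subtypes), names(subtypes)),
       n = nrow(landscape))
}

#' @export
print.capa_landscape <- function(x, ...) {
  cen <- landscape_census(x)
  cat("<capa_landscape> ", cen$n, " substructures\n", sep = "")
  for (g in names(cen$groups)) {
    cat(sprintf("  %-15s %d\n", g, cen$groups[[g]]))
  }
  cat("  Intermediate sub-populations: ",
      paste0(names(cen$subtypes), "=", cen$subtypes, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Screening filter sets from a landscape analysis
#'
#' Extracts the four pairwise-disjoint substructure sets the screening
#' cascade uses: Untolerated Negative, Tolerated Negative, Inner landscape
#' (Superior + Inferior Inner) and Outer landscape (Superior + Inferior
#' Outer). Intermediate substructures other than the two negative
#' sub-populations take no part in screening.
#'
#' @param landscape A `capa_landscape` data frame.
#' @param substructures The catalogue (source of the query patterns).
#' @return A `capa_filter_sets` list of four data frames (`untolerated`,
#'   `tolerated`, `inner`, `outer`), each with `sub_id`, `name`, `query`.
#' @export
filter_sets <- function(landscape, substructures) {
  pick <- function(ids) {
    i <- match(ids, substructures$sub_id)
    data.frame(sub_id = substructures$sub_id[i],
               name = substructures$name[i],
               query = substructures$query[i],
               stringsAsFactors = FALSE)
  }
  sets <- list(
    untolerated = pick(landscape$sub_id[
      landscape$subtype == "UNTOLERATED_NEGATIVE"]),
    tolerated = pick(landscape$sub_id[
      landscape$subtype == "TOLERATED_NEGATIVE"]),
    inner = pick(landscape$sub_id[
      landscape$group %in% c("SUPERIOR_INNER", "INFERIOR_INNER")]),
    outer = pick(landscape$sub_id[
      landscape$group %in% c("SUPERIOR_OUTER", "INFERIOR_OUTER")])
  )
  all_ids <- unlist(lapply(sets, `[[`, "sub_id"))
  if (anyDuplicated(all_ids)) {
    stop("filter sets are not disjoint: ",
         .id_preview(all_ids[duplicated(all_ids)]), call. = FALSE)
  }
  class(sets) <- "capa_filter_sets"
  sets
}

#' @export
print.capa_filter_sets <- function(x, ...) {
  cat("<capa_filter_sets>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-12s %d substructures\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}
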