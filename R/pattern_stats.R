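# Binary distribution scheme and per-class percentage/ratio statistics.
#
# The binary matrix records, for every compound and catalogue substructure,
# whether at least one embedding exists (boolean; embedding multiplicity is
# deliberately ignored here). Percentages follow
#
#     pct = 100 * (compounds of the group containing the substructure)
#               / (compounds of the group)
#
# computed per (substructure, activity-class group). Reports round to one
# decimal (half-up); all rule comparisons use unrounded values.

#' Binary compound-by-substructure presence matrix
#'
#' @param compounds A `capa_compounds` data frame.
#' @param substructures A `capa_substructures` catalogue.
#' @return Logical matrix with `compound_id` rows and `sub_id` columns;
#'   `TRUE` iff the substructure has at least one embedding in the compound.
#' @export
build_matrix <- function(compounds, substructures) {
  stopifnot(nrow(substructures) > 0)
  m <- .hit_matrix(compounds$smiles, substructures)
  rownames(m) <- compounds$compound_id
  message("binary matrix: ", nrow(m), " x ", ncol(m), "; positives per ",
          "substructure: ",
          paste0(colnames(m), "=", colSums(m), collapse = ", "))
  m
}

#' Per-group substructure distribution percentages
#'
#' Applies the percentage formula per (substructure, group) over the
#' activity-class groups of [distribution_groups()]. Empty groups yield 0
#' with a warning rather than an error, so subsets remain usable.
#'
#' @param matrix Logical matrix from [build_matrix()].
#' @param classes Factor from [classify()], named by compound id, covering
#'   every matrix row.
#' @param groups Groups to tabulate (default [distribution_groups()]).
#' @return Tidy data frame `sub_id`, `group`, `n_group`, `n_hits`, `pct`
#'   (unrounded) of class `capa_distribution`.
#' @export
distribution_table <- function(matrix, classes,
                               groups = distribution_groups()) {
  ids <- rownames(matrix)
  miss <- ids[!ids %in% names(classes)]
  if (length(miss)) stop("no class for compound(s): ", .id_preview(miss),
                         call. = FALSE)
  cls <- classes[ids]
  empty <- character(0)
  rows <- lapply(groups, function(g) {
    in_g <- !is.na(cls) & cls == g
    n_g <- sum(in_g)
    if (n_g == 0) empty <<- c(empty, g)
    n_hits <- if (n_g == 0) rep(0L, ncol(matrix)) else
      colSums(matrix[in_g, , drop = FALSE])
    data.frame(sub_id = colnames(matrix), group = g,
               n_group = n_g, n_hits = as.integer(n_hits),
               pct = if (n_g == 0) 0 else 100 * n_hits / n_g,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  if (length(empty)) {
    warning("empty group(s), percentage reported as 0: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("capa_distribution", "data.frame")
  out
}

#' Rounded percentage for reports
#'
#' One decimal, half-up. Internal comparisons always use unrounded values;
#' this formatting is only for exported tables.
#'
#' @param pct Numeric vector of percentages.
#' @return Numeric vector rounded to one decimal.
#' @export
report_pct <- function(pct) round_half_up(pct, 1)

#' Inter-group percentage ratios
#'
#' Per-substructure ratio between two groups' distribution values. Where
#' the denominator is zero the ratio is flagged rather than computed:
#' `"undefined_high"` when only the numerator group contains the
#' substructure (ratio reported as `Inf`), `"absent"` when neither does
#' (ratio `NA`).
#'
#' @param table Distribution table from [distribution_table()].
#' @param g1,g2 Group labels (numerator, denominator).
#' @param basis `"pct"` to divide percentages (default) or `"count"` to
#'   divide raw hit counts; the two differ only by the group-size factor.
#' @return Data frame `sub_id`, `ratio`, `status`.
#' @export
group_ratios <- function(table, g1, g2, basis = c("pct", "count")) {
  basis <- match.arg(basis)
  col <- if (basis == "pct") "pct" else "n_hits"
  t1 <- table[table$group == g1, ]
  t2 <- table[table$group == g2, ]
  if (!nrow(t1) || !nrow(t2)) stop("group not in table", call. = FALSE)
  t2 <- t2[match(t1$sub_id, t2$sub_id), ]
  a <- t1[[col]]
  b <- t2[[col]]
  status <- ifelse(b > 0, "ok", ifelse(a > 0, "undefined_high", "absent"))
  ratio <- ifelse(b > 0, a / b, ifelse(a > 0, Inf, NA_real_))
  data.frame(sub_id = t1$sub_id, ratio = ratio, status = status,
             stringsAsFactors = FALSE)
}

#' Export the distribution scheme
#'
#' Writes the binary matrix (dense 0/1 and sparse triplet forms) and the
#' tidy distribution table with report-rounded percentages.
#'
#' @param matrix Logical matrix from [build_matrix()].
#' @param table Distribution table from [distribution_table()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_distribution <- function(matrix, table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dense <- file.path(dir, "binary_matrix.csv")
  utils::write.csv(data.frame(compound_id = rownames(matrix),
                              1L * matrix, check.names = FALSE),
                   dense, row.names = FALSE)
  idx <- which(matrix, arr.ind = TRUE)
  sparse <- file.path(dir, "binary_matrix_triplets.csv")
  utils::write.csv(data.frame(compound_id = rownames(matrix)[idx[, 1]],
                              sub_id = colnames(matrix)[idx[, 2]],
                              value = 1L),
                   sparse, row.names = FALSE)
  tab <- as.data.frame(table)
  tab$pct <- report_pct(tab$pct)
  dist <- file.path(dir, "distribution.csv")
  utils::write.csv(tab, dist, row.names = FALSE)
  invisible(c(dense, sparse, dist))
}
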