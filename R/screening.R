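# Six-stage outer-landscape virtual-screening cascade.
#
# Stage order is fixed: (i) stereo-redundancy removal, (ii) drop compounds
# with any Untolerated Negative Substructure, (iii) drop compounds with
# more than `max_tolerated` Tolerated Negative Substructures, (iv) drop
# compounds with any Inner landscape substructure, (v) keep only compounds
# with at least one Outer landscape substructure, (vi) score and rank the
# survivors. All substructure counting is by distinct substructure
# identity, never embedding multiplicity. The final manual hit selection
# of a screening campaign is out of computational scope: the cascade ends
# with the ranked candidate table (outer-substructure count, matched
# substructures, composition label) a chemist would select from.

.as_library <- function(library) {
  if (is.character(library)) {
    library <- data.frame(compound_id = paste0("lib", seq_along(library)),
                          smiles = library, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(library),
            all(c("compound_id", "smiles") %in% names(library)))
  if (!"structure_key" %in% names(library)) {
    library$structure_key <- make_structure_key(library$smiles)
  }
  library
}

.stage_result <- function(kept, removed) {
  list(kept = kept, removed = removed)
}

#' Remove stereo-redundant library members
#'
#' Keeps one representative per stereo-free structure key (the first
#' occurrence in input order); stereoisomers and SMILES-rewriting
#' duplicates of an earlier entry are removed.
#'
#' @param library Data frame with `compound_id` and `smiles` (a
#'   `structure_key` column is computed if absent), or a character vector
#'   of SMILES.
#' @return List with `kept` and `removed` data frames.
#' @export
dedup_stereo <- function(library) {
  library <- .as_library(library)
  dup <- duplicated(library$structure_key)
  .stage_result(library[!dup, , drop = FALSE], library[dup, , drop = FALSE])
}

# distinct substructure hits per library compound against one filter set
.set_hits <- function(library, set) {
  if (nrow(set) == 0) {
    return(matrix(FALSE, nrow(library), 0,
                  dimnames = list(NULL, character(0))))
  }
  .hit_matrix(library$smiles, set)
}

#' Substructure exclusion/inclusion filters
#'
#' The four substructure filters of the cascade, each returning the kept
#' and removed library subsets:
#' \describe{
#'   \item{filter_untolerated}{removes compounds containing at least one
#'     Untolerated Negative Substructure.}
#'   \item{filter_tolerated}{removes compounds containing more than
#'     `max_tolerated` distinct Tolerated Negative Substructures (default
#'     1: one tolerated hit keeps a compound in play, acknowledging the
#'     residual weak activity of Semi Class 0 chemistry).}
#'   \item{filter_inner}{removes compounds containing any Inner landscape
#'     substructure, widening the gap to the potent landscape.}
#'   \item{require_outer}{removes compounds containing no Outer landscape
#'     substructure.}
#' }
#'
#' @param library Library data frame (see [dedup_stereo()]).
#' @param sets A `capa_filter_sets` object from [filter_sets()].
#' @param max_tolerated Maximum number of distinct Tolerated Negative
#'   Substructures a compound may carry.
#' @return List with `kept` and `removed` data frames.
#' @name screening_filters
NULL

#' @rdname screening_filters
#' @export
filter_untolerated <- function(library, sets) {
  library <- .as_library(library)
  n <- rowSums(.set_hits(library, sets$untolerated))
  .stage_result(library[n == 0, , drop = FALSE],
                library[n > 0, , drop = FALSE])
}

#' @rdname screening_filters
#' @export
filter_tolerated <- function(library, sets, max_tolerated = 1) {
  library <- .as_library(library)
  n <- rowSums(.set_hits(library, sets$tolerated))
  .stage_result(library[n <= max_tolerated, , drop = FALSE],
                library[n > max_tolerated, , drop = FALSE])
}

#' @rdname screening_filters
#' @export
filter_inner <- function(library, sets) {
  library <- .as_library(library)
  n <- rowSums(.set_hits(library, sets$inner))
  .stage_result(library[n == 0, , drop = FALSE],
                library[n > 0, , drop = FALSE])
}

#' @rdname screening_filters
#' @export
require_outer <- function(library, sets) {
  library <- .as_library(library)
  n <- rowSums(.set_hits(library, sets$outer))
  .stage_result(library[n > 0, , drop = FALSE],
                library[n == 0, , drop = FALSE])
}

# composition of the matched outer substructures on one molecule:
# "single" for one matched substructure, "concentrated" when every pair of
# matched substructures shares atoms, "distributed" when all pairs are
# atom-disjoint, "mixed" otherwise. Each matched substructure contributes
# the union of its embedding atom sets.
.composition <- function(smiles, outer_set, hit_ids) {
  if (length(hit_ids) == 1) return("single")
  atom_sets <- lapply(hit_ids, function(id) {
    q <- outer_set$query[outer_set$sub_id == id]
    sort(unique(unlist(match_atom_sets(smiles, q, sub_id = id))))
  })
  pairs <- utils::combn(length(atom_sets), 2)
  overlap <- apply(pairs, 2, function(p) {
    length(intersect(atom_sets[[p[1]]], atom_sets[[p[2]]])) > 0
  })
  if (all(overlap)) "concentrated" else if (!any(overlap)) "distributed"
  else "mixed"
}

#' Score and rank cascade survivors
#'
#' Counts the distinct Outer landscape substructures each survivor
#' contains, labels how those substructures sit on the molecule
#' (composition), and ranks by descending outer count with ties broken
#' lexicographically by compound id.
#'
#' @param survivors Library data frame that passed [require_outer()].
#' @param sets A `capa_filter_sets` object.
#' @return Data frame `compound_id`, `smiles`, `outer_count`,
#'   `outer_sub_ids` (';'-joined), `composition`, ranked; with a
#'   `histogram` attribute mapping outer count to number of compounds.
#' @export
score_candidates <- function(survivors, sets) {
  survivors <- .as_library(survivors)
  hits <- .set_hits(survivors, sets$outer)
  outer_count <- as.integer(rowSums(hits))
  stopifnot(all(outer_count >= 1))
  hit_ids <- lapply(seq_len(nrow(survivors)),
                    function(i) colnames(hits)[hits[i, ]])
  composition <- vapply(seq_len(nrow(survivors)), function(i) {
    .composition(survivors$smiles[i], sets$outer, hit_ids[[i]])
  }, "")
  out <- data.frame(
    compound_id = survivors$compound_id,
    smiles = survivors$smiles,
    outer_count = outer_count,
    outer_sub_ids = vapply(hit_ids, paste, "", collapse = ";"),
    composition = composition,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$outer_count, out$compound_id), , drop = FALSE]
  rownames(out) <- NULL
  counts <- table(out$outer_count)
  attr(out, "histogram") <- stats::setNames(as.integer(counts),
                                            names(counts))
  out
}

#' Run the full screening cascade
#'
#' Executes the six stages in fixed order with complete bookkeeping: per
#' stage the incoming count, removed count and removed compound ids; then
#' the ranked survivor table and the outer-count histogram. The survivor
#' sets are nested down the cascade and
#' `n_in(stage k+1) = n_in(stage k) - removed(stage k)` holds exactly.
#'
#' @param library Screening library (data frame with `compound_id`,
#'   `smiles`, or a character vector of SMILES).
#' @param sets A `capa_filter_sets` object from [filter_sets()].
#' @param max_tolerated Tolerated-negative allowance of stage (iii).
#' @return A `capa_screening_report` list: `stages` data frame (`name`,
#'   `n_in`, `n_removed`), `removed_ids` (list per stage), `survivors`
#'   (ranked, from [score_candidates()]), `histogram`.
#' @export
run_cascade <- function(library, sets, max_tolerated = 1) {
  library <- .as_library(library)
  stage_names <- c("unique_compounds", "untolerated_negative_substructures",
                   "tolerated_negative_substructures",
                   "inner_landscape_substructures",
                   "outer_landscape_substructure", "scoring")
  steps <- list(
    function(l) dedup_stereo(l),
    function(l) filter_untolerated(l, sets),
    function(l) filter_tolerated(l, sets, max_tolerated),
    function(l) filter_inner(l, sets),
    function(l) require_outer(l, sets)
  )
  n_in <- integer(0)
  n_removed <- integer(0)
  removed_ids <- list()
  current <- library
  for (k in seq_along(steps)) {
    res <- steps[[k]](current)
    n_in <- c(n_in, nrow(current))
    n_removed <- c(n_removed, nrow(res$removed))
    removed_ids[[stage_names[k]]] <- res$removed$compound_id
    current <- res$kept
  }
  survivors <- if (nrow(current)) score_candidates(current, sets) else {
    s <- data.frame(compound_id = character(0), smiles = character(0),
                    outer_count = integer(0), outer_sub_ids = character(0),
                    composition = character(0), stringsAsFactors = FALSE)
    attr(s, "histogram") <- stats::setNames(integer(0), character(0))
    s
  }
  n_in <- c(n_in, nrow(current))
  n_removed <- c(n_removed, 0L)
  removed_ids[["scoring"]] <- character(0)
  report <- list(
    stages = data.frame(name = stage_names, n_in = n_in,
                        n_removed = n_removed, stringsAsFactors = FALSE),
    removed_ids = removed_ids,
    survivors = survivors,
    histogram = attr(survivors, "histogram"),
    max_tolerated = max_tolerated
  )
  class(report) <- "capa_screening_report"
  report
}

#' @export
print.capa_screening_report <- function(x, ...) {
  cat("<capa_screening_report>\n")
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  %-36s in %5d  removed %5d\n", x$stages$name[i],
                x$stages$n_in[i], x$stages$n_removed[i]))
  }
  cat("  survivors:", nrow(x$survivors), "\n")
  if (length(x$histogram)) {
    cat("  outer-count histogram: ",
        paste0(names(x$histogram), ":", x$histogram, collapse = " "), "\n")
  }
  invisible(x)
}

#' Write a screening report
#'
#' Persists the stage log and histogram as JSON and the ranked survivor
#' table as CSV.
#'
#' @param report A `capa_screening_report`.
#' @param json_path Path for the JSON stage log (`NULL` to skip).
#' @param hits_path Path for the survivor CSV (`NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_screening_report <- function(report, json_path = NULL,
                                   hits_path = NULL) {
  written <- character(0)
  if (!is.null(json_path)) {
    payload <- list(
      stages = lapply(seq_len(nrow(report$stages)), function(i) {
        list(name = report$stages$name[i],
             n_in = report$stages$n_in[i],
             n_removed = report$stages$n_removed[i],
             removed_ids = report$removed_ids[[report$stages$name[i]]])
      }),
      histogram = as.list(report$histogram),
      max_tolerated = report$max_tolerated
    )
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE)
    written <- c(written, json_path)
  }
  if (!is.null(hits_path)) {
    utils::write.csv(report$survivors, hits_path, row.names = FALSE)
    written <- c(written, hits_path)
  }
  invisible(written)
}
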