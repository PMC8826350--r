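# Synthetic screening libraries with a planted cascade design.
#
# Every library compound is assigned a role before any chemistry is built:
# removed at the untolerated stage, removed at the tolerated stage (two
# tolerated-negative fragments), removed at the inner stage, removed for
# lacking outer substructures, or survivor with a prescribed number of
# distinct outer-landscape fragments. Stereo duplicates are appended after
# the unique compounds. The cascade outcome on such a library is known
# exactly from the ledger by set logic alone, independent of the matcher.

.SCREEN_CATALOGUE <- function() {
  data.frame(
    sub_id = c("u_cf3",
               "t_tetrazole", "t_nitrile",
               "i_benzene", "i_pyridine",
               "o_piperazine", "o_morpholine", "o_thiophene",
               "o_imidazole", "o_furan", "o_sulfonamide"),
    name = c("trifluoromethyl", "tetrazole", "nitrile", "benzene",
             "pyridine", "piperazine", "morpholine", "thiophene",
             "imidazole", "furan", "sulfonamide"),
    query = c("C(F)(F)F", "c1nnn[nH]1", "C#N", "c1ccccc1", "c1ccncc1",
              "C1CNCCN1", "C1COCCN1", "c1ccsc1", "c1c[nH]cn1", "c1ccoc1",
              "S(=O)(=O)N"),
    provenance = c("primary_negative", "putative_negative",
                   "putative_negative", "primary_basic_scaffold",
                   "suggested_positive", "extended_positive",
                   "extended_positive", "extended_positive",
                   "putative_positive", "putative_positive",
                   "suggested_positive"),
    role = c("untolerated", "tolerated", "tolerated", "inner", "inner",
             "outer", "outer", "outer", "outer", "outer", "outer"),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic screening library
#'
#' Describes a screening library by its intended cascade outcome. Defaults
#' emulate the dimensions of an established ABCC1-focused screening set:
#' 1229 unique compounds plus 281 stereo-redundant entries (1510 total),
#' with stage removals 129 (untolerated), 10 (more than one tolerated
#' negative), 776 (inner landscape) and 31 (no outer substructure), and
#' survivors carrying 1..6 distinct outer substructures with multiplicities
#' 30/76/102/53/19/3.
#'
#' @param seed Integer seed.
#' @param n_unique Number of distinct constitutions.
#' @param n_stereo_dups Stereoisomer duplicates appended to the library.
#' @param removals Named integer vector with elements `untolerated`,
#'   `tolerated`, `inner`, `no_outer`.
#' @param outer_histogram Integer vector; element k is the number of
#'   survivors carrying exactly k distinct outer substructures (length at
#'   most the number of outer fragments in the built-in screening
#'   catalogue, 6).
#' @return A `capa_screen_spec` list.
#' @export
screen_spec <- function(seed = 1L, n_unique = 1229L, n_stereo_dups = 281L,
                        removals = c(untolerated = 129L, tolerated = 10L,
                                     inner = 776L, no_outer = 31L),
                        outer_histogram = c(30L, 76L, 102L, 53L, 19L, 3L)) {
  stopifnot(all(c("untolerated", "tolerated", "inner", "no_outer") %in%
                  names(removals)),
            length(outer_histogram) <= 6,
            n_stereo_dups <= n_unique)
  n_survivors <- sum(outer_histogram)
  if (sum(removals) + n_survivors != n_unique) {
    stop("removals plus survivors (", sum(removals) + n_survivors,
         ") must equal n_unique (", n_unique, ")", call. = FALSE)
  }
  spec <- list(seed = as.integer(seed), n_unique = as.integer(n_unique),
               n_stereo_dups = as.integer(n_stereo_dups),
               removals = removals,
               outer_histogram = as.integer(outer_histogram))
  class(spec) <- "capa_screen_spec"
  spec
}

#' Generate a synthetic screening library
#'
#' Builds the library, filter sets and truth ledger for a [screen_spec()].
#' Some survivors and some inner-removed compounds additionally carry one
#' tolerated-negative fragment, exercising the rule that a single tolerated
#' hit does not remove a compound.
#'
#' @param spec A [screen_spec()].
#' @param verify Passed to the planted-fragment verification as in
#'   [generate()] (`"planted"`, `"full"` or `"none"`).
#' @return List with `library` (data frame `compound_id`, `smiles`),
#'   `substructures` (catalogue), `sets` (a `capa_filter_sets`), and
#'   `ledger` (data frame `compound_id`, `role`, `planted`,
#'   `stereo_parent`, plus attributes `expected_stages` and
#'   `expected_histogram`).
#' @export
generate_screening <- function(spec, verify = c("planted", "full", "none")) {
  verify <- match.arg(verify)
  stopifnot(inherits(spec, "capa_screen_spec"))
  cat_df <- .SCREEN_CATALOGUE()
  outer_ids <- cat_df$sub_id[cat_df$role == "outer"]
  tol_ids <- cat_df$sub_id[cat_df$role == "tolerated"]
  inner_ids <- cat_df$sub_id[cat_df$role == "inner"]
  unt_ids <- cat_df$sub_id[cat_df$role == "untolerated"]

  withr::with_seed(spec$seed, {
    n <- spec$n_unique
    roles <- rep(c("untolerated", "tolerated", "inner", "no_outer",
                   "survivor"),
                 c(spec$removals[["untolerated"]],
                   spec$removals[["tolerated"]],
                   spec$removals[["inner"]],
                   spec$removals[["no_outer"]],
                   sum(spec$outer_histogram)))
    planted <- rep(list(character(0)), n)
    outer_counts <- rep(seq_along(spec$outer_histogram),
                        spec$outer_histogram)
    s_idx <- 0L
    for (i in seq_len(n)) {
      planted[[i]] <- switch(
        roles[i],
        untolerated = unt_ids,
        tolerated = tol_ids,                       # two tolerated hits
        inner = c(sample(inner_ids, 1),
                  if (i %% 3 == 0) sample(tol_ids, 1)),
        no_outer = if (i %% 2 == 0) sample(tol_ids, 1) else character(0),
        survivor = {
          s_idx <- s_idx + 1L
          c(sample(outer_ids, outer_counts[s_idx]),
            if (i %% 2 == 0) sample(tol_ids, 1))
        })
    }
    width <- max(2L, ceiling(log(n + 1, 3)))
    dup_of <- if (spec$n_stereo_dups > 0)
      sort(sample(n, spec$n_stereo_dups)) else integer(0)
    chiral <- seq_len(n) %in% dup_of
    frag_of <- function(ids) cat_df$query[match(ids, cat_df$sub_id)]
    ids <- sprintf("LIB%05d", seq_len(n))
    smiles <- vapply(seq_len(n), function(i) {
      .assemble_smiles(frag_of(planted[[i]]), .serial_tail(i, width),
                       chiral = chiral[i])
    }, "")
    library <- data.frame(compound_id = ids, smiles = smiles,
                          stringsAsFactors = FALSE)
    ledger <- data.frame(compound_id = ids, role = roles,
                         stereo_parent = NA_character_,
                         stringsAsFactors = FALSE)
    ledger$planted <- planted
    if (length(dup_of)) {
      dup_ids <- sprintf("LIB%05dS", dup_of)
      library <- rbind(library, data.frame(
        compound_id = dup_ids,
        smiles = vapply(seq_along(dup_of), function(k) {
          i <- dup_of[k]
          .assemble_smiles(frag_of(planted[[i]]), .serial_tail(i, width),
                           chiral = TRUE, flipped = TRUE)
        }, ""),
        stringsAsFactors = FALSE))
      dl <- data.frame(compound_id = dup_ids, role = roles[dup_of],
                       stereo_parent = ids[dup_of], stringsAsFactors = FALSE)
      dl$planted <- planted[dup_of]
      ledger <- rbind(ledger, dl)
    }
  })

  catalogue <- suppressMessages(
    as_substructures(cat_df[, c("sub_id", "name", "query", "provenance")]))
  pick <- function(ids) cat_df[match(ids, cat_df$sub_id),
                               c("sub_id", "name", "query")]
  sets <- structure(list(untolerated = pick(unt_ids),
                         tolerated = pick(tol_ids),
                         inner = pick(inner_ids),
                         outer = pick(outer_ids)),
                    class = "capa_filter_sets")

  surv <- sum(spec$outer_histogram)
  attr(ledger, "expected_stages") <- data.frame(
    name = c("unique_compounds", "untolerated_negative_substructures",
             "tolerated_negative_substructures",
             "inner_landscape_substructures",
             "outer_landscape_substructure", "scoring"),
    n_in = c(spec$n_unique + spec$n_stereo_dups, spec$n_unique,
             spec$n_unique - spec$removals[["untolerated"]],
             spec$n_unique - sum(spec$removals[c("untolerated",
                                                 "tolerated")]),
             surv + spec$removals[["no_outer"]], surv),
    n_removed = c(spec$n_stereo_dups, spec$removals[["untolerated"]],
                  spec$removals[["tolerated"]], spec$removals[["inner"]],
                  spec$removals[["no_outer"]], 0L),
    stringsAsFactors = FALSE
  )
  attr(ledger, "expected_histogram") <- stats::setNames(
    spec$outer_histogram[spec$outer_histogram > 0],
    seq_along(spec$outer_histogram)[spec$outer_histogram > 0])

  if (verify != "none") {
    truth <- list(compounds = ledger)
    if (verify == "full") {
      m <- .hit_matrix(library$smiles, catalogue)
      expected <- vapply(catalogue$sub_id, function(id) {
        vapply(ledger$planted, function(p) id %in% p, TRUE)
      }, logical(nrow(library)))
      if (!identical(unname(m[, catalogue$sub_id] * 1L),
                     unname(expected * 1L))) {
        stop("screening library deviates from planted truth", call. = FALSE)
      }
    } else {
      for (i in seq_len(nrow(library))) {
        for (id in ledger$planted[[i]]) {
          if (!matches(library$smiles[i],
                       cat_df$query[cat_df$sub_id == id], sub_id = id)) {
            stop("planted substructure ", id, " not recovered in ",
                 library$compound_id[i], call. = FALSE)
          }
        }
      }
    }
  }
  list(library = library, substructures = catalogue, sets = sets,
       ledger = ledger)
}

#' Write a small fixture suite
#'
#' Emits deterministic plain-text fixtures covering the package's corner
#' cases: a boundary compound table (IC50 values sitting exactly on the
#' 5/10/15/20/200 class boundaries, censored values, absent measurements),
#' a small substructure catalogue including a zero-hit pattern, a
#' Real-Class-0-only pattern and a tetrazole-like tolerated-negative
#' pattern, and a ten-compound mini screening library (two stereo
#' duplicates) that exercises all six cascade stages.
#'
#' @param dir Output directory (created if needed).
#' @return Named list of the file paths written, invisibly.
#' @export
make_fixture_suite <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  boundary <- data.frame(
    id = paste0("bnd", 1:8),
    name = c("all on 5", "all on 10", "all on 15", "weak pan boundary",
             "very weak boundary", "censored everywhere", "one absent",
             "semi class 0"),
    smiles = c("CCO", "CCN", "CCC", "CCCC", "CCCCC", "CCCCCC", "CCCCCCC",
               "CCCCCCCC"),
    ic50_abcb1 = c("5", "10", "15", "20", "20", "n.i.", "3", "12"),
    ic50_abcc1 = c("1", "1", "1", "20", "20", ">200", "", ">200"),
    ic50_abcg2 = c("1", "1", "1", "5", "10", "n.i.", "4", ">200"),
    stringsAsFactors = FALSE
  )
  compounds_path <- file.path(dir, "boundary_compounds.csv")
  utils::write.table(boundary, compounds_path, sep = ";",
                     row.names = FALSE, quote = FALSE)

  subs <- .SCREEN_CATALOGUE()[, c("sub_id", "name", "query", "provenance")]
  subs_path <- file.path(dir, "substructures.tsv")
  utils::write.table(subs, subs_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)

  mini <- generate_screening(screen_spec(
    seed = 42L, n_unique = 8L, n_stereo_dups = 2L,
    removals = c(untolerated = 1L, tolerated = 1L, inner = 2L,
                 no_outer = 1L),
    outer_histogram = c(1L, 1L, 1L)))
  mini_path <- file.path(dir, "mini_library.csv")
  utils::write.table(
    data.frame(id = mini$library$compound_id, name = "",
               smiles = mini$library$smiles,
               ic50_abcb1 = "", ic50_abcc1 = "", ic50_abcg2 = ""),
    mini_path, sep = ";", row.names = FALSE, quote = FALSE)

  invisible(list(boundary_compounds = compounds_path,
                 substructures = subs_path,
                 mini_library = mini_path))
}
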