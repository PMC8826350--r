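# Deterministic synthetic-data generator with a ground-truth ledger.
#
# Molecules are assembled, not sampled from real chemistry: every compound
# is an aliphatic backbone carrying (i) zero or more planted catalogue
# fragments as branches and (ii) a unique linear C/O/N "serial tail" that
# encodes the compound index, guaranteeing distinct constitutions. Planted
# fragments are single rings or hetero-functional groups chosen to be
# mutually non-matching, so the binary matrix of the generated library is
# known exactly by construction (and verified post hoc with the matcher).
# IC50 triples are drawn from class-conditional intervals shrunk away from
# every classification boundary, so classify() recovers the intended class
# with certainty. All randomness flows from the spec seed.

.TAIL_ATOMS <- c("C", "O", "N")

# fixed-width base-3 serial tail for compound index i (1-based)
.serial_tail <- function(i, width) {
  i <- i - 1L
  digits <- integer(width)
  for (k in seq_len(width)) {
    digits[k] <- i %% 3L
    i <- i %/% 3L
  }
  paste(.TAIL_ATOMS[digits + 1L], collapse = "")
}

# assemble a molecule SMILES from planted fragment queries
.assemble_smiles <- function(fragments, tail, chiral = FALSE,
                             flipped = FALSE) {
  head <- if (!chiral) "CC(C)C" else if (!flipped) "C[C@H](O)C" else
    "C[C@@H](O)C"
  branches <- paste0(vapply(fragments, function(f) paste0("C(", f, ")"), ""),
                     collapse = "")
  paste0(head, branches, tail)
}

# class-conditional IC50 sampling; intervals sit strictly inside each
# class's defining region so floating-point comparisons cannot flip a class
.sample_ic50 <- function(class) {
  v <- c(NA_real_, NA_real_, NA_real_)
  cens <- c(FALSE, FALSE, FALSE)
  perm <- sample(3L)
  r <- function(a, b) stats::runif(1, a, b)
  if (class == "SUPERIOR_CLASS7") {
    v <- c(r(0.1, 4.9), r(0.1, 4.9), r(0.1, 4.9))
  } else if (class == "MEDIUM_CLASS7") {
    v[perm[1]] <- r(5.05, 9.9)
    v[perm[2]] <- r(0.1, 9.9)
    v[perm[3]] <- r(0.1, 9.9)
  } else if (class == "SEMI_CLASS7") {
    v[perm[1]] <- r(10.05, 14.9)
    v[perm[2]] <- r(0.1, 14.9)
    v[perm[3]] <- r(0.1, 14.9)
  } else if (class == "WEAK_PAN") {
    v[perm[1]] <- r(20.5, 198)
    v[perm[2]] <- r(20.5, 198)
    v[perm[3]] <- r(0.1, 9.9)
  } else if (class == "VERY_WEAK_PAN") {
    v[perm[1]] <- r(20.5, 198)
    v[perm[2]] <- r(20.5, 198)
    v[perm[3]] <- r(10.05, 19.0)
  } else if (class == "UNCLASSIFIED_PAN") {
    v <- c(r(15.6, 19.4), r(15.6, 19.4), r(15.6, 19.4))
  } else if (class == "SEMI_CLASS0") {
    k <- sample(1:2, 1)
    for (j in seq_len(k)) v[perm[j]] <- r(10.5, 198)
    for (j in seq_len(3 - k)) {
      v[perm[k + j]] <- 200
      cens[perm[k + j]] <- TRUE
    }
  } else if (class == "REAL_CLASS0") {
    v <- c(200, 200, 200)
    cens <- c(TRUE, TRUE, TRUE)
  } else { # OTHER: potent on one target, inactive on the rest
    v[perm[1]] <- r(0.5, 9.0)
    v[perm[2]] <- 200
    v[perm[3]] <- 200
    cens[perm[2]] <- TRUE
    cens[perm[3]] <- TRUE
  }
  list(ic50 = v, censored = cens)
}

#' Default class quotas of the synthetic activity dataset
#'
#' The default dataset composition emulates the curated multitarget
#' dataset the pattern analysis was designed around: 1160 compounds, of
#' which 138 are focused pan inhibitors (92 classified: 22 Superior
#' Class 7, 34 Medium Class 7, 22 Semi Class 7, 8 Weak and 6 Very Weak
#' Pan; 46 unclassified) and 304 are Class 0 (186 Semi, 118 Real); the
#' remainder are `OTHER` profiles (e.g. potent on one target only).
#'
#' @return Named integer vector over [activity_classes()].
#' @export
default_class_quotas <- function() {
  c(SUPERIOR_CLASS7 = 22L, MEDIUM_CLASS7 = 34L, SEMI_CLASS7 = 22L,
    WEAK_PAN = 8L, VERY_WEAK_PAN = 6L, UNCLASSIFIED_PAN = 46L,
    SEMI_CLASS0 = 186L, REAL_CLASS0 = 118L, OTHER = 718L)
}

#' Default catalogue plan of the synthetic generator
#'
#' A ten-substructure catalogue of mutually non-matching fragments with
#' per-class planted-presence fractions chosen to span the full landscape
#' spectrum: an inner-strong and an inner-moderate pattern, an outer-strong
#' and two outer-moderate patterns, a flat (inconclusive) pattern, an
#' absent pattern, a Real-Class-0-only (untolerated negative) pattern, a
#' tetrazole-like tolerated-negative pattern (mostly Real Class 0, rarely
#' Semi Class 0, never in unclassified pan compounds), and a scattered
#' plain-intermediate pattern.
#'
#' @return Data frame with catalogue columns (`sub_id`, `name`, `query`,
#'   `provenance`) plus one `f_<class>` planted-fraction column per
#'   activity class.
#' @export
default_catalogue_plan <- function() {
  plan <- data.frame(
    sub_id = c("s_benzene", "s_pyridine", "s_piperazine", "s_morpholine",
               "s_sulfonamide", "s_thiophene", "s_imidazole", "s_furan",
               "s_cf3", "s_tetrazole"),
    name = c("benzene", "pyridine", "piperazine", "morpholine",
             "sulfonamide", "thiophene", "imidazole", "furan",
             "trifluoromethyl", "tetrazole"),
    query = c("c1ccccc1", "c1ccncc1", "C1CNCCN1", "C1COCCN1", "S(=O)(=O)N",
              "c1ccsc1", "c1c[nH]cn1", "c1ccoc1", "C(F)(F)F",
              "c1nnn[nH]1"),
    provenance = c("primary_basic_scaffold", "suggested_positive",
                   "extended_basic_scaffold", "putative_positive",
                   "suggested_positive", "extended_positive",
                   "putative_positive", "putative_negative",
                   "primary_negative", "putative_negative"),
    stringsAsFactors = FALSE
  )
  f <- matrix(0, nrow(plan), length(.ACTIVITY_CLASSES),
              dimnames = list(plan$sub_id, .ACTIVITY_CLASSES))
  f["s_benzene", ] <- c(0.90, 0.85, 0.20, 0.10, 0.10, 0.30, 0.05, 0.02, 0.10)
  f["s_pyridine", ] <- c(0.40, 0.35, 0.15, 0.10, 0.10, 0.15, 0.05, 0.02, 0.05)
  f["s_piperazine", ] <- c(0.05, 0.05, 0.85, 0.80, 0.80, 0.20, 0.05, 0, 0.05)
  f["s_morpholine", ] <- c(0.05, 0.05, 0.35, 0.30, 0.30, 0.10, 0.08, 0, 0.05)
  f["s_sulfonamide", ] <- c(0.05, 0.04, 0.30, 0.25, 0.25, 0.10, 0.15, 0.02,
                            0.05)
  f["s_thiophene", ] <- c(0.10, 0.08, 0.10, 0.12, 0.15, 0.08, 0.10, 0.03,
                          0.05)
  f["s_imidazole", ] <- c(0.15, 0.15, 0.15, 0.15, 0.15, 0.15, 0.15, 0.15,
                          0.15)
  # s_furan: planted nowhere (zero-hit inconclusive)
  f["s_cf3", ] <- c(0, 0, 0, 0, 0, 0, 0, 0.20, 0)
  f["s_tetrazole", ] <- c(0, 0, 0, 0, 0, 0, 0.06, 0.25, 0.02)
  for (cl in .ACTIVITY_CLASSES) plan[[paste0("f_", cl)]] <- f[, cl]
  plan
}

#' Specification of a synthetic activity dataset
#'
#' @param seed Integer seed; the single source of randomness.
#' @param n_per_class Named integer vector of compounds per activity class
#'   (defaults to [default_class_quotas()]).
#' @param catalogue_plan Catalogue plus planted-presence fractions
#'   (defaults to [default_catalogue_plan()]). Planted counts per class are
#'   `round(f * n_class)`.
#' @param stereo_dup_fraction Fraction of compounds that additionally
#'   receive a stereoisomer duplicate (flipped tetrahedral descriptor,
#'   identical activities) in the output, in `[0, 1]`.
#' @return A `capa_synth_spec` list.
#' @export
synth_spec <- function(seed = 1L, n_per_class = default_class_quotas(),
                       catalogue_plan = default_catalogue_plan(),
                       stereo_dup_fraction = 0) {
  stopifnot(all(n_per_class >= 0),
            stereo_dup_fraction >= 0, stereo_dup_fraction <= 1,
            all(names(n_per_class) %in% .ACTIVITY_CLASSES))
  fcols <- paste0("f_", .ACTIVITY_CLASSES)
  stopifnot(all(c("sub_id", "name", "query", "provenance", fcols) %in%
                  names(catalogue_plan)))
  fr <- as.matrix(catalogue_plan[, fcols])
  stopifnot(all(fr >= 0), all(fr <= 1))
  spec <- list(seed = as.integer(seed), n_per_class = n_per_class,
               catalogue_plan = catalogue_plan,
               stereo_dup_fraction = stereo_dup_fraction)
  class(spec) <- "capa_synth_spec"
  spec
}

#' Generate a synthetic activity dataset with ground truth
#'
#' Builds the compound library, activity profiles and substructure
#' catalogue described by a [synth_spec()], together with a truth ledger
#' recording every planted fact: the intended class per compound, the
#' planted substructures (hence exact binary-matrix column sums) and
#' stereo-duplicate parentage. Same seed, same output, byte for byte.
#'
#' @param spec A [synth_spec()].
#' @param verify `"planted"` (default) asserts that every planted fragment
#'   is recovered by [matches()] on its host molecule; `"full"`
#'   additionally requires the complete binary matrix to equal the planted
#'   truth (no accidental extra matches); `"none"` skips verification.
#' @return List with `compounds` (a `capa_compounds` table),
#'   `substructures` (the catalogue) and `ledger` (list: `compounds` data
#'   frame with `compound_id`, `class`, `planted`, `stereo_parent`;
#'   `column_sums`; `census`).
#' @export
generate <- function(spec, verify = c("planted", "full", "none")) {
  verify <- match.arg(verify)
  stopifnot(inherits(spec, "capa_synth_spec"))
  plan <- spec$catalogue_plan
  quotas <- spec$n_per_class[spec$n_per_class > 0]
  withr::with_seed(spec$seed, {
    classes <- rep(names(quotas), quotas)
    n_base <- length(classes)
    n_dup <- round(spec$stereo_dup_fraction * n_base)
    width <- max(2L, ceiling(log(n_base + 1, 3)))
    dup_of <- if (n_dup > 0) sort(sample(n_base, n_dup)) else integer(0)

    planted <- rep(list(character(0)), n_base)
    for (cl in names(quotas)) {
      idx_cl <- which(classes == cl)
      for (j in seq_len(nrow(plan))) {
        k <- round(plan[[paste0("f_", cl)]][j] * length(idx_cl))
        if (k > 0) {
          chosen <- if (k >= length(idx_cl)) idx_cl else
            sample(idx_cl, k)
          for (i in chosen) {
            planted[[i]] <- c(planted[[i]], plan$sub_id[j])
          }
        }
      }
    }
    frag_of <- function(ids) plan$query[match(ids, plan$sub_id)]
    chiral <- seq_len(n_base) %in% dup_of
    smiles <- vapply(seq_len(n_base), function(i) {
      .assemble_smiles(frag_of(planted[[i]]), .serial_tail(i, width),
                       chiral = chiral[i])
    }, "")
    act <- lapply(classes, .sample_ic50)

    ids <- sprintf("SYN%05d", seq_len(n_base))
    rows <- data.frame(
      compound_id = ids,
      name = paste0("synthetic ", ids),
      smiles = smiles,
      stringsAsFactors = FALSE
    )
    ledger_rows <- data.frame(compound_id = ids, class = classes,
                              stereo_parent = NA_character_,
                              stringsAsFactors = FALSE)
    ledger_rows$planted <- planted

    if (n_dup > 0) {
      dup_ids <- sprintf("SYN%05dS", dup_of)
      dup_rows <- data.frame(
        compound_id = dup_ids,
        name = paste0("stereoisomer of ", ids[dup_of]),
        smiles = vapply(seq_along(dup_of), function(k) {
          i <- dup_of[k]
          .assemble_smiles(frag_of(planted[[i]]), .serial_tail(i, width),
                           chiral = TRUE, flipped = TRUE)
        }, ""),
        stringsAsFactors = FALSE
      )
      rows <- rbind(rows, dup_rows)
      dl <- data.frame(compound_id = dup_ids, class = classes[dup_of],
                       stereo_parent = ids[dup_of], stringsAsFactors = FALSE)
      dl$planted <- planted[dup_of]
      ledger_rows <- rbind(ledger_rows, dl)
      act <- c(act, act[dup_of])
    }

    a <- list()
    for (t in seq_along(.TARGETS)) {
      a[[paste0("ic50_", .TARGETS[t])]] <- vapply(act, function(x)
        x$ic50[t], 0)
      a[[paste0("cens_", .TARGETS[t])]] <- vapply(act, function(x)
        x$censored[t], TRUE)
    }
    compounds <- .new_compounds(rows$compound_id, rows$name, rows$smiles, a)
  })

  key_clash <- duplicated(compounds$structure_key) &
    is.na(ledger_rows$stereo_parent)
  if (any(key_clash)) {
    stop("generator produced colliding constitutions: ",
         .id_preview(compounds$compound_id[key_clash]), call. = FALSE)
  }

  catalogue <- suppressMessages(
    as_substructures(plan[, c("sub_id", "name", "query", "provenance")]))
  column_sums <- vapply(plan$sub_id, function(id) {
    sum(vapply(ledger_rows$planted, function(p) id %in% p, TRUE))
  }, 0L)
  census <- table(factor(ledger_rows$class, levels = .ACTIVITY_CLASSES))
  ledger <- list(
    compounds = ledger_rows,
    column_sums = column_sums,
    census = stats::setNames(as.integer(census), names(census))
  )

  if (verify != "none") .verify_generated(compounds, catalogue, ledger,
                                          full = verify == "full")
  list(compounds = compounds, substructures = catalogue, ledger = ledger)
}

.verify_generated <- function(compounds, catalogue, ledger, full = FALSE) {
  if (full) {
    m <- suppressMessages(build_matrix(compounds, catalogue))
    expected <- vapply(catalogue$sub_id, function(id) {
      vapply(ledger$compounds$planted, function(p) id %in% p, TRUE)
    }, logical(nrow(compounds)))
    if (!identical(unname(m[, catalogue$sub_id] * 1L),
                   unname(expected * 1L))) {
      stop("generated matrix deviates from planted truth", call. = FALSE)
    }
  } else {
    for (i in seq_len(nrow(compounds))) {
      for (id in ledger$compounds$planted[[i]]) {
        q <- catalogue$query[catalogue$sub_id == id]
        if (!matches(compounds$smiles[i], q, sub_id = id)) {
          stop("planted substructure ", id, " not recovered in ",
               compounds$compound_id[i], call. = FALSE)
        }
      }
    }
  }
  invisible(TRUE)
}
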