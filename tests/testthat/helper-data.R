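# in-code fixture builders shared by the test files

# compound table from a compact profile list: list(id = c(b1, c1, g2)) with
# numeric or cell-notation entries; SMILES default to distinct alkanes
make_profile_compounds <- function(profiles, smiles = NULL) {
  ids <- names(profiles)
  if (is.null(smiles)) {
    smiles <- vapply(seq_along(ids), function(i)
      paste(rep("C", i + 1), collapse = ""), "")
  }
  df <- data.frame(
    id = ids, name = ids, smiles = smiles,
    ic50_abcb1 = vapply(profiles, function(p) as.character(p[1]), ""),
    ic50_abcc1 = vapply(profiles, function(p) as.character(p[2]), ""),
    ic50_abcg2 = vapply(profiles, function(p) as.character(p[3]), ""),
    stringsAsFactors = FALSE
  )
  as_compounds(df)
}

# minimal catalogue
make_catalogue <- function(sub_id, query,
                           name = sub_id,
                           provenance = rep("putative_positive",
                                            length(sub_id))) {
  suppressMessages(as_substructures(data.frame(
    sub_id = sub_id, name = name, query = query, provenance = provenance,
    stringsAsFactors = FALSE)))
}

# small synthetic activity spec used across tests
small_synth_spec <- function(seed = 11) {
  synth_spec(
    seed = seed,
    n_per_class = c(SUPERIOR_CLASS7 = 6L, MEDIUM_CLASS7 = 6L,
                    SEMI_CLASS7 = 6L, WEAK_PAN = 4L, VERY_WEAK_PAN = 4L,
                    UNCLASSIFIED_PAN = 5L, SEMI_CLASS0 = 10L,
                    REAL_CLASS0 = 8L, OTHER = 5L)
  )
}

small_screen_spec <- function(seed = 5) {
  screen_spec(
    seed = seed, n_unique = 40L, n_stereo_dups = 8L,
    removals = c(untolerated = 4L, tolerated = 3L, inner = 12L,
                 no_outer = 3L),
    outer_histogram = c(8L, 6L, 2L, 1L, 1L, 0L)
  )
}
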