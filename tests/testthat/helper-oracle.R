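# Brute-force substructure-matching oracle.
#
# Exhaustively enumerates every injective assignment of query atoms to
# molecule atoms (compatible element + aromaticity), then checks that each
# query bond lands on a molecule bond of the same type. No search-order
# heuristics, no solver: this is the definitional subgraph monomorphism
# test, used to validate the package's LAD-based matcher on small
# molecules.

oracle_matches <- function(smiles, query) {
  q <- capa:::.mol_graph(query)
  t <- capa:::.mol_graph(smiles)
  nq <- igraph::vcount(q)
  nt <- igraph::vcount(t)
  if (nq == 0 || nq > nt) return(FALSE)
  qe <- igraph::V(q)$elem; qa <- igraph::V(q)$arom
  te <- igraph::V(t)$elem; ta <- igraph::V(t)$arom
  qedges <- igraph::as_edgelist(q, names = FALSE)
  qbt <- igraph::E(q)$btype
  # adjacency lookup: bond type by target atom pair ("i-j", i < j)
  tedges <- igraph::as_edgelist(t, names = FALSE)
  tbt <- igraph::E(t)$btype
  bond_key <- function(i, j) paste0(pmin(i, j), "-", pmax(i, j))
  tbonds <- stats::setNames(tbt, bond_key(tedges[, 1], tedges[, 2]))
  cand <- lapply(seq_len(nq), function(i) which(te == qe[i] & ta == qa[i]))

  assign_next <- function(mapping) {
    k <- length(mapping) + 1L
    if (k > nq) {
      if (nrow(qedges) == 0) return(TRUE)
      for (e in seq_len(nrow(qedges))) {
        bt <- tbonds[bond_key(mapping[qedges[e, 1]], mapping[qedges[e, 2]])]
        if (is.na(bt) || bt != qbt[e]) return(FALSE)
      }
      return(TRUE)
    }
    for (v in cand[[k]]) {
      if (!v %in% mapping && assign_next(c(mapping, v))) return(TRUE)
    }
    FALSE
  }
  assign_next(integer(0))
}

# panel of small molecules (<= 12 heavy atoms) and queries used by the
# oracle-equivalence suites
oracle_panel_molecules <- function() c(
  "CCO", "CCN", "CCC", "C1CC1", "C1CCC1", "c1ccccc1", "Cc1ccccc1",
  "c1ccncc1", "c1ccc2ccccc2c1", "c1ccccc1-c1ccccc1", "C1CNCCN1",
  "C1COCCN1", "c1c[nH]cn1", "c1nnn[nH]1", "CC(=O)N", "CS(=O)(=O)N",
  "CC(F)(F)F", "C#N", "CC#N", "c1ccsc1", "c1ccoc1", "CC(C)CC(O)C",
  "OCC(O)CO", "CNC", "CC(=O)OC", "N#Cc1ccccc1"
)

oracle_panel_queries <- function() c(
  "C", "N", "CC", "CCO", "CCC", "C1CC1", "c1ccccc1", "c1ccncc1",
  "C#N", "CNC", "C(F)(F)F", "S(=O)(=O)N", "c1c[nH]cn1", "CC(=O)"
)
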