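# Structure handling: canonicalization, stereo-free structure keys, and
# substructure matching.
#
# SMILES parsing and canonical SMILES generation are delegated to Open Babel
# (through ChemmineOB). For substructure matching, each molecule/query is
# turned into a coloured graph (vertices: element + aromaticity; edges: bond
# type, with aromatic and amide bonds kept distinct) built from Open Babel's
# TRIPOS MOL2 rendering, which carries perceived aromaticity explicitly.
# Embedding enumeration is a subgraph *monomorphism* search (a C-C-C chain
# query must match cyclopropane) performed with igraph's LAD solver
# constrained by per-atom candidate domains, followed by a bond-type
# compatibility filter.

# per-session cache: SMILES -> canonical form / molecule graph
.capa_cache <- new.env(parent = emptyenv())

.ob_convert <- function(from, to, text) {
  out <- tryCatch(
    ChemmineOB::convertFormat(from, to, paste0(text, "\n")),
    error = function(e) ""
  )
  if (is.null(out) || !nzchar(out)) "" else out
}

.canonical_one <- function(smiles) {
  key <- paste0("can\r", smiles)
  hit <- .capa_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- .ob_convert("SMI", "CAN", smiles)
  out <- sub("[ \t].*$", "", sub("\\s+$", "", out))   # drop title/trailing ws
  .capa_cache[[key]] <- out
  out
}

#' Canonical SMILES
#'
#' Rewrites SMILES strings into Open Babel canonical form, so that different
#' writing orders of the same structure compare equal.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES.
#'   Unparseable input raises an error naming the offending string.
#' @export
#' @examples
#' canonical_smiles(c("c1ccccc1C", "Cc1ccccc1"))
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- vapply(smiles, .canonical_one, "", USE.NAMES = FALSE)
  bad <- !nzchar(out) | !nzchar(trimws(smiles))
  if (any(bad)) {
    stop("unparseable SMILES: ", .id_preview(smiles[bad]), call. = FALSE)
  }
  out
}

# strip stereo descriptors from a SMILES string (tetrahedral @/@@ and
# cis/trans bond slashes); the result is re-canonicalized afterwards
.strip_stereo <- function(smiles) {
  s <- gsub("@", "", smiles, fixed = TRUE)
  s <- gsub("/", "", s, fixed = TRUE)
  gsub("\\", "", s, fixed = TRUE)
}

# heavy (non-hydrogen) atom count of a single-component SMILES
.n_heavy <- function(smiles) {
  mol2 <- .ob_convert("SMI", "MOL2", smiles)
  if (!nzchar(mol2)) return(NA_integer_)
  m <- .parse_mol2(mol2)
  sum(m$elem != "H")
}

# keep the largest component of a (canonical) SMILES; ties broken in favour
# of carbon-containing fragments, then first occurrence
.largest_fragment <- function(canonical) {
  if (!grepl(".", canonical, fixed = TRUE)) return(canonical)
  parts <- strsplit(canonical, ".", fixed = TRUE)[[1]]
  n_heavy <- vapply(parts, .n_heavy, 1L)
  has_c <- grepl("C|c", gsub("Cl|Ca|Cd|Co|Cu|Cr|Sc", "", parts))
  ord <- order(-n_heavy, -has_c)
  parts[ord[1]]
}

#' Stereo-free structure key
#'
#' Deterministic identifier for a compound's constitution: the canonical
#' SMILES of the largest fragment after removing all stereo descriptors.
#' Stereoisomers of the same constitution map to the same key, which is the
#' basis of stereo-redundancy removal in the screening cascade.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of structure keys.
#' @export
#' @examples
#' make_structure_key("C[C@@H](N)C(=O)O") == make_structure_key("C[C@H](N)C(=O)O")
make_structure_key <- function(smiles) {
  canon <- canonical_smiles(smiles)
  vapply(canon, function(s) .canonical_one(.strip_stereo(.largest_fragment(s))),
         "", USE.NAMES = FALSE)
}

# ---- molecular graphs ------------------------------------------------------

.parse_mol2 <- function(txt) {
  ln <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  mi <- which(ln == "@<TRIPOS>MOLECULE")[1]
  ai <- which(ln == "@<TRIPOS>ATOM")[1]
  bi <- which(ln == "@<TRIPOS>BOND")[1]
  counts <- strsplit(trimws(ln[mi + 2]), "\\s+")[[1]]
  na <- as.integer(counts[1])
  nb <- as.integer(counts[2])
  fields <- function(s) strsplit(trimws(s), "\\s+")[[1]]
  atype <- vapply(ln[(ai + 1):(ai + na)], function(s) fields(s)[6], "",
                  USE.NAMES = FALSE)
  if (!is.na(bi) && nb > 0) {
    bd <- t(vapply(ln[(bi + 1):(bi + nb)], function(s) fields(s)[2:4],
                   character(3), USE.NAMES = FALSE))
  } else {
    bd <- matrix(character(0), 0, 3)
  }
  list(
    elem = sub("\\..*$", "", atype),
    arom = grepl("\\.ar$", atype),
    b1 = as.integer(bd[, 1]), b2 = as.integer(bd[, 2]), btype = bd[, 3]
  )
}

# coloured molecule graph of the largest fragment, hydrogens removed
.mol_graph <- function(smiles) {
  key <- paste0("mg\r", smiles)
  hit <- .capa_cache[[key]]
  if (!is.null(hit)) return(hit)
  frag <- .largest_fragment(canonical_smiles(smiles))
  mol2 <- .ob_convert("SMI", "MOL2", frag)
  if (!nzchar(mol2)) stop("unparseable SMILES: ", smiles, call. = FALSE)
  m <- .parse_mol2(mol2)
  keep <- m$elem != "H"
  idx <- cumsum(keep)
  g <- igraph::make_empty_graph(sum(keep), directed = FALSE)
  kb <- keep[m$b1] & keep[m$b2]
  if (any(kb)) {
    g <- igraph::add_edges(g, rbind(idx[m$b1[kb]], idx[m$b2[kb]]))
  }
  igraph::V(g)$elem <- m$elem[keep]
  igraph::V(g)$arom <- m$arom[keep]
  igraph::E(g)$btype <- m$btype[kb]
  .capa_cache[[key]] <- g
  g
}

# all bond-compatible monomorphism embeddings of query graph q in target
# graph t, as a list of integer mapping vectors (query atom i -> target atom)
.embeddings <- function(q, t) {
  nq <- igraph::vcount(q)
  if (nq == 0 || nq > igraph::vcount(t)) return(list())
  qe <- igraph::V(q)$elem
  qa <- igraph::V(q)$arom
  te <- igraph::V(t)$elem
  ta <- igraph::V(t)$arom
  dom <- lapply(seq_len(nq), function(i) which(te == qe[i] & ta == qa[i]))
  if (any(lengths(dom) == 0)) return(list())
  if (nq == 1) return(as.list(dom[[1]]))
  maps <- igraph::subgraph_isomorphisms(q, t, method = "lad",
                                        domains = dom, induced = FALSE)
  if (length(maps) == 0) return(list())
  qedges <- igraph::as_edgelist(q, names = FALSE)
  qbt <- igraph::E(q)$btype
  tbt <- igraph::E(t)$btype
  keep <- vapply(maps, function(mp) {
    mv <- as.integer(mp)
    eid <- igraph::get_edge_ids(t, rbind(mv[qedges[, 1]], mv[qedges[, 2]]))
    all(eid > 0) && all(tbt[eid] == qbt)
  }, TRUE)
  lapply(maps[keep], as.integer)
}

.query_graph <- function(query, sub_id = NULL) {
  tryCatch(.mol_graph(query), error = function(e) {
    stop("substructure query failed to parse",
         if (!is.null(sub_id)) paste0(" [", sub_id, "]"),
         ": ", query, call. = FALSE)
  })
}

.smiles_of <- function(x) {
  if (is.character(x)) x else {
    stopifnot(is.data.frame(x), "smiles" %in% names(x))
    x$smiles
  }
}

#' Substructure presence
#'
#' Tests whether a query substructure has at least one embedding in each
#' molecule. Queries are substructure patterns written as SMILES; aromaticity
#' is perceived on both molecule and query before matching, and matching is
#' on element, aromaticity and bond type. Salt counter-ions are dropped
#' (largest fragment) before matching.
#'
#' @param x Character vector of molecule SMILES, or a compound table with a
#'   `smiles` column.
#' @param query A single substructure query (SMILES).
#' @param sub_id Optional identifier used in error messages when the query
#'   does not parse.
#' @return Logical vector, one element per molecule.
#' @seealso [match_atom_sets()] for the embeddings themselves.
#' @export
#' @examples
#' matches(c("Cc1ccccc1", "CCO"), "c1ccccc1")
matches <- function(x, query, sub_id = NULL) {
  smiles <- .smiles_of(x)
  qg <- .query_graph(query, sub_id)
  vapply(smiles, function(s) length(.embeddings(qg, .mol_graph(s))) > 0,
         TRUE, USE.NAMES = FALSE)
}

#' Substructure embeddings as atom-index sets
#'
#' Enumerates all distinct embeddings of a query substructure in one
#' molecule and returns them as sorted atom-index sets (indices refer to the
#' heavy atoms of the molecule's largest fragment, in Open Babel canonical
#' order). Symmetry-equivalent mappings that cover the same atoms are
#' collapsed to one set. Used for labelling whether several matched
#' substructures overlap ("concentrated") or sit on disjoint parts of a
#' molecule ("distributed").
#'
#' @param smiles A single molecule SMILES.
#' @param query A single substructure query (SMILES).
#' @param sub_id Optional identifier used in error messages.
#' @return List of sorted integer vectors; empty list iff [matches()] is
#'   `FALSE`.
#' @export
#' @examples
#' match_atom_sets("c1ccc2ccccc2c1", "c1ccccc1")  # two sets sharing 2 atoms
match_atom_sets <- function(smiles, query, sub_id = NULL) {
  stopifnot(length(smiles) == 1)
  qg <- .query_graph(query, sub_id)
  emb <- .embeddings(qg, .mol_graph(smiles))
  unique(lapply(emb, function(m) sort(unique(m))))
}

# distinct-substructure hit count per molecule over a catalogue subset;
# queries: data.frame(sub_id, query). Returns a logical matrix
# molecules x queries.
.hit_matrix <- function(smiles, queries) {
  out <- matrix(FALSE, nrow = length(smiles), ncol = nrow(queries),
                dimnames = list(NULL, queries$sub_id))
  for (j in seq_len(nrow(queries))) {
    out[, j] <- matches(smiles, queries$query[j], sub_id = queries$sub_id[j])
  }
  out
}
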