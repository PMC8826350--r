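# Reading and writing compound activity tables and substructure catalogues.
#
# Compound CSV dialect: header row, ';' or ',' separated (auto-detected),
# columns id, name, smiles, ic50_abcb1, ic50_abcc1, ic50_abcg2. IC50 cells
# may be numeric (micromolar), ">N" (censored: no inhibition up to N), the
# literature shorthand "n.i." (no inhibition; encoded as censored at 200),
# or empty (no measurement). SDF input carries the same information as
# property tags IC50_ABCB1 / IC50_ABCC1 / IC50_ABCG2 (and optionally ID,
# NAME).

# parse one vector of IC50 cells -> list(ic50 = numeric, censored = logical)
# censored NA <=> ic50 NA <=> absent measurement
.parse_activity <- function(x) {
  x <- trimws(as.character(x))
  n <- length(x)
  ic50 <- rep(NA_real_, n)
  cens <- rep(NA, n)
  absent <- is.na(x) | x == "" | toupper(x) == "NA"
  ni <- grepl("^n\\.?i\\.?$", x, ignore.case = TRUE)
  gt <- grepl("^>", x)
  num <- !absent & !ni & !gt
  ic50[ni] <- 200
  cens[ni] <- TRUE
  ic50[gt] <- suppressWarnings(as.numeric(sub("^>\\s*", "", x[gt])))
  cens[gt] <- TRUE
  ic50[num] <- suppressWarnings(as.numeric(x[num]))
  cens[num] <- FALSE
  bad <- !absent & is.na(ic50)
  if (any(bad)) stop("unparseable IC50 value(s): ", .id_preview(x[bad]),
                     call. = FALSE)
  if (any(ic50 <= 0, na.rm = TRUE)) {
    stop("IC50 values must be positive", call. = FALSE)
  }
  list(ic50 = ic50, censored = cens)
}

# render ic50/censored back into the CSV cell notation
.format_activity <- function(ic50, censored) {
  out <- ifelse(is.na(ic50), "",
                ifelse(censored, paste0(">", ic50), as.character(ic50)))
  out
}

.detect_sep <- function(line) {
  if (lengths(regmatches(line, gregexpr(";", line))) >=
      lengths(regmatches(line, gregexpr(",", line)))) ";" else ","
}

# assemble a validated compound table; activities arrive as parallel
# ic50_*/cens_* vectors
.new_compounds <- function(compound_id, name, smiles, act,
                           failures = NULL) {
  df <- data.frame(
    compound_id = as.character(compound_id),
    name = as.character(name),
    smiles = as.character(smiles),
    structure_key = make_structure_key(smiles),
    stringsAsFactors = FALSE
  )
  for (t in .TARGETS) {
    df[[paste0("ic50_", t)]] <- act[[paste0("ic50_", t)]]
    df[[paste0("cens_", t)]] <- act[[paste0("cens_", t)]]
  }
  dup <- duplicated(df$compound_id)
  if (any(dup)) stop("duplicate compound_id: ",
                     .id_preview(unique(df$compound_id[dup])), call. = FALSE)
  class(df) <- c("capa_compounds", "data.frame")
  attr(df, "failures") <- failures %||%
    data.frame(record = character(0), reason = character(0))
  df
}

#' Build a compound table from raw columns
#'
#' Constructor used by the readers and the synthetic generator: validates
#' SMILES (unparseable rows are dropped into the `failures` attribute),
#' parses IC50 cells including censoring notation, and computes stereo-free
#' structure keys.
#'
#' @param df Data frame with columns `id` (or `compound_id`), `name`,
#'   `smiles`, `ic50_abcb1`, `ic50_abcc1`, `ic50_abcg2`.
#' @return A `capa_compounds` data frame with one row per valid molecule,
#'   columns `compound_id`, `name`, `smiles`, `structure_key` and per-target
#'   `ic50_*` / `cens_*` pairs, and a `failures` attribute listing skipped
#'   records with reasons.
#' @export
as_compounds <- function(df) {
  names(df) <- tolower(names(df))
  if (!"compound_id" %in% names(df) && "id" %in% names(df)) {
    names(df)[names(df) == "id"] <- "compound_id"
  }
  need <- c("compound_id", "smiles", paste0("ic50_", .TARGETS))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!"name" %in% names(df)) df$name <- df$compound_id

  smi <- trimws(as.character(df$smiles))
  ok <- nzchar(smi)
  ok[ok] <- vapply(smi[ok], function(s) nzchar(.canonical_one(s)), TRUE)
  failures <- data.frame(
    record = as.character(df$compound_id[!ok]),
    reason = ifelse(nzchar(smi[!ok]), "unparseable SMILES", "empty SMILES"),
    stringsAsFactors = FALSE
  )
  kept <- df[ok, , drop = FALSE]
  act <- list()
  for (t in .TARGETS) {
    p <- .parse_activity(kept[[paste0("ic50_", t)]])
    act[[paste0("ic50_", t)]] <- p$ic50
    act[[paste0("cens_", t)]] <- p$censored
  }
  .new_compounds(kept$compound_id, kept$name, smi[ok], act, failures)
}

#' Read a compound activity table
#'
#' Reads a compound table from CSV (';' or ',' separated, auto-detected) or
#' SDF (property tags `IC50_ABCB1`, `IC50_ABCC1`, `IC50_ABCG2`). Rows whose
#' SMILES (or molblock) cannot be parsed are skipped, logged and counted in
#' the `failures` attribute; `">N"` and `"n.i."` cells become censored
#' activity values (n.i. at the dataset's 200 uM inactivity bound) and empty
#' cells absent measurements.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"sdf"`.
#' @return A `capa_compounds` data frame; see [as_compounds()].
#' @export
read_compounds <- function(path, format = c("auto", "csv", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) %in% c("sdf", "sd", "mol"))
      "sdf" else "csv"
  }
  if (format == "csv") .read_compounds_csv(path) else .read_compounds_sdf(path)
}

.read_compounds_csv <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- .detect_sep(header)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE, colClasses = "character")
  out <- as_compounds(df)
  f <- attr(out, "failures")
  if (nrow(f)) message(nrow(f), " record(s) skipped: ",
                       .id_preview(f$record))
  out
}

.read_compounds_sdf <- function(path) {
  txt <- readLines(path, warn = FALSE)
  ends <- which(trimws(txt) == "$$$$")
  if (!length(ends)) stop("no SDF records in ", path, call. = FALSE)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  rows <- lapply(seq_along(ends), function(k) {
    rec <- txt[starts[k]:ends[k]]
    tag_lines <- grep("^>\\s*<", rec)
    molblock <- rec[seq_len(if (length(tag_lines)) min(tag_lines) - 1L
                            else length(rec) - 1L)]
    tags <- list()
    for (tl in tag_lines) {
      nm <- toupper(sub("^>\\s*<([^>]+)>.*$", "\\1", rec[tl]))
      tags[[nm]] <- trimws(rec[tl + 1L])
    }
    smi <- .ob_convert("SDF", "CAN", paste(c(molblock, "$$$$"),
                                           collapse = "\n"))
    smi <- sub("[ \t].*$", "", sub("\\s+$", "", smi))
    data.frame(
      compound_id = tags[["ID"]] %||% trimws(molblock[1]) %||%
        paste0("mol", k),
      name = tags[["NAME"]] %||% trimws(molblock[1]),
      smiles = smi,
      ic50_abcb1 = tags[["IC50_ABCB1"]] %||% "",
      ic50_abcc1 = tags[["IC50_ABCC1"]] %||% "",
      ic50_abcg2 = tags[["IC50_ABCG2"]] %||% "",
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  blank <- !nzchar(df$compound_id)
  df$compound_id[blank] <- paste0("mol", which(blank))
  out <- as_compounds(df)
  f <- attr(out, "failures")
  if (nrow(f)) message(nrow(f), " record(s) skipped: ", .id_preview(f$record))
  out
}

#' Write a compound table
#'
#' Writes a `capa_compounds` table back to the CSV dialect read by
#' [read_compounds()]; censored activities are rendered as `">N"` and absent
#' measurements as empty cells, so a write/read round trip reproduces the
#' records field-for-field.
#'
#' @param x A `capa_compounds` data frame.
#' @param path Output file path.
#' @param sep Field separator, `";"` (default) or `","`.
#' @return `path`, invisibly.
#' @export
write_compounds <- function(x, path, sep = ";") {
  out <- data.frame(id = x$compound_id, name = x$name, smiles = x$smiles,
                    stringsAsFactors = FALSE)
  for (t in .TARGETS) {
    out[[paste0("ic50_", t)]] <-
      .format_activity(x[[paste0("ic50_", t)]], x[[paste0("cens_", t)]])
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.capa_compounds <- function(x, ...) {
  cat("<capa_compounds> ", nrow(x), " compounds\n", sep = "")
  f <- attr(x, "failures")
  if (!is.null(f) && nrow(f)) cat("  skipped records: ", nrow(f), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("  ... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}

#' Read a substructure catalogue
#'
#' Reads a catalogue of named substructure queries (TSV/CSV with columns
#' `sub_id`, `name`, `query`, `provenance`). Queries are substructure
#' patterns written as SMILES and are validated on load; `provenance` must
#' be one of [provenance_groups()]. Per-group cardinalities are reported.
#'
#' @param path File path (separator auto-detected among tab, ';' and ',').
#' @return Data frame `sub_id`, `name`, `query`, `provenance` of class
#'   `capa_substructures`.
#' @export
read_substructures <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else .detect_sep(header)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE,
                          colClasses = "character")
  as_substructures(df)
}

#' Validate a substructure catalogue
#'
#' @param df Data frame with columns `sub_id`, `name`, `query`,
#'   `provenance`.
#' @return The validated catalogue, class `capa_substructures`.
#' @export
as_substructures <- function(df) {
  names(df) <- tolower(names(df))
  need <- c("sub_id", "name", "query", "provenance")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  df <- df[, need]
  dup <- duplicated(df$sub_id)
  if (any(dup)) stop("duplicate sub_id: ",
                     .id_preview(unique(df$sub_id[dup])), call. = FALSE)
  bad_prov <- !df$provenance %in% .PROVENANCE_GROUPS
  if (any(bad_prov)) {
    stop("unknown provenance group(s): ",
         .id_preview(unique(df$provenance[bad_prov])),
         "; expected one of: ", paste(.PROVENANCE_GROUPS, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(df))) .query_graph(df$query[i], df$sub_id[i])
  tab <- table(factor(df$provenance, levels = .PROVENANCE_GROUPS))
  message("catalogue: ", nrow(df), " substructures (",
          paste0(names(tab)[tab > 0], ": ", tab[tab > 0], collapse = ", "),
          ")")
  class(df) <- c("capa_substructures", "data.frame")
  df
}

#' Write a substructure catalogue
#'
#' @param x A `capa_substructures` data frame.
#' @param path Output path; written tab-separated.
#' @return `path`, invisibly.
#' @export
write_substructures <- function(x, path) {
  utils::write.table(as.data.frame(x)[, c("sub_id", "name", "query",
                                          "provenance")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
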